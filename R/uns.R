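# Undifferentiation Network Signature (UNS) construction: a curated seed
# list of undifferentiation markers expanded by "connector" genes that
# interact heavily with it. A candidate outside the seed list joins the UNS
# only if it has at least `k_min` distinct interaction partners within the
# seed list (15 by default), counted on the undirected simple graph with
# edge types ignored.

#' Connector selection rule
#'
#' @param k_min Minimum number of distinct seed-gene interaction partners a
#'   candidate needs to qualify as a connector (default 15, inclusive).
#' @return A `connector_rule` list.
#' @export
connector_rule <- function(k_min = 15L) {
  assert_that(k_min >= 1L, "k_min must be >= 1")
  structure(list(k_min = as.integer(k_min)), class = "connector_rule")
}

#' Select network connectors and assemble the UNS
#'
#' For every network node outside the seed list, counts its distinct seed
#' neighbours on the simple undirected graph (self-loops and duplicate edges
#' have no effect; edge-type labels are ignored). Nodes reaching
#' `rule$k_min` distinct seed partners become connectors; the UNS is the
#' union of seed and connectors. Seed genes absent from the network stay in
#' the UNS. Symbol matching is case-insensitive.
#'
#' @param seed A [gene_set] or character vector of seed symbols (non-empty).
#' @param network An undirected [igraph::igraph].
#' @param rule A [connector_rule()].
#' @return List of class `uns_result`: `seed`, `connectors`, `uns`
#'   ([gene_set]s), and `seed_degree` (named integer vector of distinct seed
#'   partners per connector).
#' @export
select_connectors <- function(seed, network, rule = connector_rule()) {
  seed_members <- as_members(seed)
  assert_that(length(seed_members) > 0L, "seed gene set is empty")
  g <- igraph::simplify(network, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(type = merge_edge_types))
  nodes <- igraph::V(g)$name
  is_seed <- nodes %in_ci% seed_members
  el <- igraph::as_edgelist(g, names = FALSE)
  # distinct seed partners per node: each simple edge with exactly one seed
  # endpoint contributes one seed partner to the other endpoint
  seed_deg <- integer(length(nodes))
  a <- el[, 1L]; b <- el[, 2L]
  contrib <- c(a[is_seed[b]], b[is_seed[a]])
  if (length(contrib)) {
    tab <- tabulate(contrib, nbins = length(nodes))
    seed_deg <- tab
  }
  is_conn <- !is_seed & seed_deg >= rule$k_min
  connectors <- nodes[is_conn]
  deg <- seed_deg[is_conn]
  names(deg) <- connectors
  conn_set <- if (length(connectors)) {
    gene_set("connectors", connectors, "network connectors of the seed list")
  } else {
    structure(list(name = "connectors", description = "network connectors of the seed list",
                   members = character(0)), class = "gene_set")
  }
  seed_set <- gene_set("seed", seed_members, "curated undifferentiation markers")
  structure(list(seed = seed_set,
                 connectors = conn_set,
                 uns = gene_set("UNS", c(seed_members, connectors),
                                "undifferentiation network signature"),
                 seed_degree = deg),
            class = "uns_result")
}

#' Summarize a UNS
#'
#' @param uns A `uns_result` from [select_connectors()].
#' @return Data frame with `n_seed`, `n_connectors`, `n_uns` and
#'   `connector_fraction`.
#' @export
uns_summary <- function(uns) {
  stopifnot(inherits(uns, "uns_result"))
  n_seed <- length(uns$seed$members)
  n_conn <- length(uns$connectors$members)
  data.frame(n_seed = n_seed, n_connectors = n_conn,
             n_uns = n_seed + n_conn,
             connector_fraction = n_conn / (n_seed + n_conn))
}

#' @export
print.uns_result <- function(x, ...) {
  s <- uns_summary(x)
  cat(sprintf("<uns_result> %d seed + %d connectors = %d UNS genes\n",
              s$n_seed, s$n_connectors, s$n_uns))
  invisible(x)
}
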