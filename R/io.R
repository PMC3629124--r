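# Readers and writers for every file format the pipeline touches.
# All formats are plain text: TSV (expression, groups, attributes,
# annotations), GMT (gene sets), SIF + GraphML (networks), flat key=value
# config. Writers produce files their paired readers accept.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample IDs, one gene per row with the gene symbol
#' in the first column, and numeric intensities in all remaining cells.
#' Validation is strict: ragged rows, duplicate gene IDs and non-numeric
#' cells are reported with line numbers rather than silently coerced.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns (colnames = sample IDs). Row and column order are preserved.
#' @seealso [write_expression_tsv()]
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) >= 2L, sprintf("'%s': need a header and at least one gene row", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell for the gene-id column
  body <- fields[-1L]
  widths <- lengths(body)
  n_col <- widths[1L]
  bad <- which(widths != n_col)
  assert_that(length(bad) == 0L,
              sprintf("'%s': ragged row at line %d (%d fields, expected %d)",
                      path, bad[1L] + 1L, widths[bad[1L]], n_col))
  samples <- if (length(header) == n_col) header[-1L] else header
  assert_that(length(samples) == n_col - 1L,
              sprintf("'%s': header has %d sample IDs but rows have %d value columns",
                      path, length(samples), n_col - 1L))
  genes <- vapply(body, `[[`, "", 1L)
  dup <- genes[duplicated(genes)]
  assert_that(length(dup) == 0L,
              sprintf("'%s': duplicate gene ID '%s'", path, dup[1L]))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n_col - 1L))
  )
  vals <- matrix(vals, ncol = length(body))  # robust when n_col - 1L == 1
  if (anyNA(vals)) {
    bad_row <- which(colSums(is.na(vals)) > 0L)[1L]
    stop(sprintf("'%s': non-numeric cell at line %d (gene '%s')",
                 path, bad_row + 1L, genes[bad_row]), call. = FALSE)
  }
  m <- t(vals)
  dimnames(m) <- list(genes, samples)
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  assert_that(is.matrix(matrix) && !is.null(rownames(matrix)) && !is.null(colnames(matrix)),
              "expression matrix must have gene rownames and sample colnames")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(matrix)), collapse = "\t"), con)
  body <- paste(rownames(matrix),
                apply(matrix, 1L, function(r) paste(format(r, trim = TRUE, digits = 15), collapse = "\t")),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read / write a sample-to-group map
#'
#' Two tab-separated columns: sample ID, group label. Returns a named factor
#' (names = sample IDs).
#'
#' @param path Path to a two-column TSV (no header).
#' @return Named factor of group labels.
#' @export
read_group_tsv <- function(path) {
  d <- utils::read.delim(path, header = FALSE, colClasses = "character")
  assert_that(ncol(d) == 2L, sprintf("'%s': group map must have 2 columns", path))
  g <- factor(d[[2L]])
  names(g) <- d[[1L]]
  g
}

#' @rdname read_group_tsv
#' @param groups Named factor or character vector of group labels.
#' @export
write_group_tsv <- function(groups, path) {
  assert_that(!is.null(names(groups)), "group map must be named by sample ID")
  utils::write.table(data.frame(sample = names(groups), group = as.character(groups)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one or more member symbols, all
#' tab-separated. Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  assert_that(length(short) == 0L,
              sprintf("'%s': line %d has fewer than 3 tab-separated fields",
                      path, short[1L]))
  sets <- lapply(fields, function(f) gene_set(f[1L], f[-(1:2)], description = f[2L]))
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set] or list of them; each must have at least one member.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    assert_that(length(s$members) > 0L,
                sprintf("gene set '%s' has no members", s$name))
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' Used for curated seed lists. Blank lines and lines starting with `#` are
#' skipped.
#'
#' @param path Path to the list file.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

# ---- networks ----------------------------------------------------------------

SIF_EDGE_TYPES <- c("physical", "biochemical", "functional", "both", "unspecified")

# Merge the set of type labels on a collapsed multi-edge into one label:
# physical + biochemical (in any combination) -> "both", a single label stays,
# anything else joins sorted with "|" so no information is dropped.
merge_edge_types <- function(labels) {
  u <- sort(unique(unlist(strsplit(labels, "|", fixed = TRUE))))
  if (length(u) == 1L) return(u)
  if (all(u %in% c("physical", "biochemical", "both"))) return("both")
  paste(u, collapse = "|")
}

#' Read a network from a SIF file
#'
#' Simple interaction format: each line is either `A <type> B [C ...]`
#' (edges from A to every listed partner) or a single node name (isolated
#' node). The graph is undirected; self-loops are dropped with a warning and
#' duplicate edges are collapsed, merging their type labels (`physical` +
#' `biochemical` becomes `both`, matching the convention that an edge can
#' carry both interaction modes). Untyped duplicate-free labels are kept
#' verbatim, so unknown edge types survive a round trip.
#'
#' @param path Path to a SIF file.
#' @param attributes_path Optional node-attribute TSV (see
#'   [read_node_attributes()]); attributes are attached to matching vertices.
#' @return An [igraph::igraph] undirected graph with edge attribute `type`
#'   and, when attributes are supplied, vertex attributes `compartment`,
#'   `general_function`, `specific_function`.
#' @export
read_sif <- function(path, attributes_path = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[\t ]+")
  n_tok <- lengths(fields)
  bad <- which(n_tok == 2L)
  assert_that(length(bad) == 0L,
              sprintf("'%s': line %d has 2 tokens; SIF lines are 'A type B...' or a lone node",
                      path, bad[1L]))
  iso <- unlist(fields[n_tok == 1L])
  edge_fields <- fields[n_tok >= 3L]
  from <- character(0); to <- character(0); type <- character(0)
  for (f in edge_fields) {
    partners <- f[-(1:2)]
    from <- c(from, rep(f[1L], length(partners)))
    to <- c(to, partners)
    type <- c(type, rep(f[2L], length(partners)))
  }
  nodes <- unique(c(from, to, iso))  # keep self-loop nodes even after dropping their edges
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("'%s': dropped %d self-loop(s) (e.g. '%s')",
                    path, sum(loops), from[which(loops)[1L]]))
    from <- from[!loops]; to <- to[!loops]; type <- type[!loops]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, type = type, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(type = merge_edge_types))
  if (!is.null(attributes_path)) {
    g <- attach_node_attributes(g, read_node_attributes(attributes_path))
  }
  g
}

#' Write a network as SIF
#'
#' Edges are written as `A <type> B` (one per line, `unspecified` when the
#' type attribute is absent); isolated nodes are written as bare node lines so
#' the full node set survives a round trip.
#'
#' @param network An igraph graph.
#' @param path Output path.
#' @export
write_sif <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  type <- if ("type" %in% igraph::edge_attr_names(network)) {
    igraph::E(network)$type
  } else {
    rep("unspecified", nrow(el))
  }
  lines <- if (nrow(el)) paste(el[, 1L], type, el[, 2L], sep = "\t") else character(0)
  iso <- igraph::V(network)$name[igraph::degree(network) == 0L]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read / write node attributes
#'
#' Tab-separated with header columns `node`, `compartment`,
#' `general_function`, `specific_function`. Compartments follow the four
#' cellular locations used throughout (`nucleus`, `cytoplasm`,
#' `plasma membrane`, `extracellular space`); other values load untouched.
#'
#' @param path Path to the attribute TSV.
#' @return Data frame with one row per node.
#' @export
read_node_attributes <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("node", "compartment", "general_function", "specific_function")
  assert_that(all(need %in% names(d)),
              sprintf("'%s': attribute table needs columns %s",
                      path, paste(need, collapse = ", ")))
  d
}

#' @rdname read_node_attributes
#' @param attrs Data frame as returned by [read_node_attributes()].
#' @export
write_node_attributes <- function(attrs, path) {
  utils::write.table(attrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Attach an attribute table to graph vertices (case-insensitive symbol match).
# Rows for nodes absent from the graph warn rather than error.
attach_node_attributes <- function(g, attrs) {
  idx <- match_ci(attrs$node, igraph::V(g)$name)
  missing <- attrs$node[is.na(idx)]
  if (length(missing)) {
    warning(sprintf("attribute rows for %d node(s) absent from the graph (e.g. '%s')",
                    length(missing), missing[1L]))
  }
  keep <- !is.na(idx)
  for (col in c("compartment", "general_function", "specific_function")) {
    v <- rep(NA_character_, igraph::vcount(g))
    v[idx[keep]] <- attrs[[col]][keep]
    g <- igraph::set_vertex_attr(g, col, value = v)
  }
  g
}

#' Read / write a flat key=value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values are returned as strings; numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config_kv <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  assert_that(length(bad) == 0L,
              sprintf("'%s': line %d is not 'key = value'", path, bad[1L]))
  keys <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- keys
  out
}

#' @rdname read_config_kv
#' @param config Named list of scalar values.
#' @export
write_config_kv <- function(config, path) {
  assert_that(!is.null(names(config)) && all(nzchar(names(config))),
              "config entries must be named")
  writeLines(paste(names(config), "=",
                   vapply(config, function(v) paste(format(v, digits = 15), collapse = ","), "")),
             path)
  invisible(path)
}
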