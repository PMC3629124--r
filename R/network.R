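# Signature subnetwork extraction, degree and hub statistics, compartment
# breakdowns, and export in Cytoscape-loadable formats.

#' Induced subnetwork on a gene set
#'
#' Returns the subgraph induced by the given genes. Members without internal
#' edges are retained as isolated nodes, and members absent from the network
#' are added as isolated nodes (with missing attributes), so the node set
#' always equals the requested gene set.
#'
#' @param network An [igraph::igraph].
#' @param genes A [gene_set] or character vector (matched case-insensitively).
#' @return The induced [igraph::igraph].
#' @export
subnetwork <- function(network, genes) {
  members <- as_members(genes)
  idx <- match_ci(members, igraph::V(network)$name)
  sub <- igraph::induced_subgraph(network, idx[!is.na(idx)])
  absent <- members[is.na(idx)]
  if (length(absent)) {
    sub <- igraph::add_vertices(sub, length(absent), name = absent)
  }
  sub
}

#' Degree and compartment report for a signature
#'
#' Degrees are counted within the induced subnetwork on `genes`. Each gene's
#' neighbours are broken down by their (primary) compartment attribute;
#' neighbours without one count under `unspecified`, so compartment counts
#' always partition the neighbour set. Genes with degree 0 form the unbound
#' list.
#'
#' @param network An [igraph::igraph] with optional vertex attribute
#'   `compartment`.
#' @param genes A [gene_set] or character vector.
#' @return Data frame with columns `gene`, `degree`, one `n_<compartment>`
#'   column per compartment (nucleus, cytoplasm, plasma membrane,
#'   extracellular space, unspecified); attribute `unbound` lists the
#'   degree-0 genes.
#' @export
degree_report <- function(network, genes) {
  sub <- subnetwork(network, genes)
  nodes <- igraph::V(sub)$name
  comp <- if ("compartment" %in% igraph::vertex_attr_names(sub)) {
    igraph::V(sub)$compartment
  } else {
    rep(NA_character_, length(nodes))
  }
  comp[is.na(comp) | !nzchar(comp)] <- "unspecified"
  comp_levels <- c(COMPARTMENTS, "unspecified")
  comp[!comp %in% comp_levels] <- "unspecified"
  deg <- igraph::degree(sub)
  counts <- matrix(0L, nrow = length(nodes), ncol = length(comp_levels),
                   dimnames = list(nodes, comp_levels))
  el <- igraph::as_edgelist(sub, names = FALSE)
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1L]; b <- el[k, 2L]
    counts[a, comp[b]] <- counts[a, comp[b]] + 1L
    counts[b, comp[a]] <- counts[b, comp[a]] + 1L
  }
  out <- data.frame(gene = nodes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  for (cl in comp_levels) {
    out[[paste0("n_", gsub(" ", "_", cl))]] <- counts[, cl]
  }
  rownames(out) <- NULL
  structure(out, unbound = nodes[deg == 0L])
}

#' Export a network for external visualization
#'
#' Writes SIF (plus a node-attribute TSV covering every node) or GraphML.
#' Both outputs are loadable by the package's own readers and by Cytoscape.
#'
#' @param network An [igraph::igraph].
#' @param path Output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @param attributes_path Optional path for the node-attribute table
#'   (SIF format only).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("SIF", "GraphML"),
                           attributes_path = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network export format",
                                              call. = FALSE))
  if (format == "SIF") {
    write_sif(network, path)
    if (!is.null(attributes_path)) {
      get_attr <- function(nm) {
        if (nm %in% igraph::vertex_attr_names(network)) {
          v <- igraph::vertex_attr(network, nm)
          ifelse(is.na(v), "", v)
        } else {
          rep("", igraph::vcount(network))
        }
      }
      write_node_attributes(
        data.frame(node = igraph::V(network)$name,
                   compartment = get_attr("compartment"),
                   general_function = get_attr("general_function"),
                   specific_function = get_attr("specific_function"),
                   stringsAsFactors = FALSE),
        attributes_path)
    }
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}
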