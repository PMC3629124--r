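# End-to-end orchestration: preprocess -> PCA -> differential expression ->
# UNS construction -> cluster assignment -> subnetwork statistics ->
# enrichment, with optional file outputs and a summary report mirroring the
# seven-cluster count structure.

#' Run the full signature-derivation pipeline
#'
#' Takes the study inputs in memory (expression matrix, group labels, seed
#' list, interaction network, annotations, slim vocabulary) and executes
#' every stage. When `out_dir` is given, all stage outputs are written there
#' in the package's text formats along with a run manifest.
#'
#' @param exprs Numeric genes x samples matrix. Log2 scale unless
#'   `normexp = TRUE`, in which case raw intensities are background-corrected
#'   with the normexp model and log2-transformed first.
#' @param groups Named factor (levels blastomere, ICM, hESC).
#' @param seed Seed [gene_set] or character vector.
#' @param network Interaction [igraph::igraph].
#' @param annotations Data frame `gene`, `term`.
#' @param slim Slim vocabulary (see [slim_rollup()]).
#' @param config A [significance_config()].
#' @param rule A [connector_rule()].
#' @param normexp Apply normexp background correction + log2 (default FALSE:
#'   input is already log2).
#' @param quantile Apply quantile normalization (default TRUE).
#' @param mode Cluster-assignment mode, see [assign_clusters()].
#' @param out_dir Optional output directory.
#' @return List of class `stemsig_run`: `exprs` (normalized matrix), `pca_all`,
#'   `pca_uns`, `contrasts`, `uns`, `assignment`, `summary`, `signature_sets`,
#'   `subnetworks`, `degree_reports`, `enrichment`, `report`.
#' @export
run_all <- function(exprs, groups, seed, network, annotations, slim,
                    config = significance_config(), rule = connector_rule(),
                    normexp = FALSE, quantile = TRUE,
                    mode = "and_or", out_dir = NULL) {
  stage <- "preprocess"
  result <- tryCatch({
    if (normexp) {
      params <- normexp_fit(as.vector(exprs))
      exprs <- matrix(log2(normexp_adjust(as.vector(exprs), params)),
                      nrow = nrow(exprs), dimnames = dimnames(exprs))
    }
    if (quantile) exprs <- quantile_normalize(exprs)

    stage <- "uns_builder"
    uns <- select_connectors(seed, network, rule)

    stage <- "pca"
    pca_all <- pca_expr(exprs)
    pca_uns <- pca_expr(exprs, uns$uns)

    stage <- "diffexpr"
    contrasts <- contrast_table(exprs, groups, config)

    stage <- "signatures"
    assignment <- assign_clusters(contrasts, uns, config, mode = mode)
    summary <- summarize_signatures(assignment, uns)
    sets <- signature_gene_sets(assignment)

    stage <- "network_analysis"
    subnets <- lapply(sets, function(s) subnetwork(network, s))
    degrees <- lapply(sets, function(s) degree_report(network, s))

    stage <- "enrichment"
    enr <- run_comparison_battery(sets, uns, rownames(exprs), annotations,
                                  slim, config)

    stage <- "report"
    report <- report_summary(assignment, uns, summary)

    list(exprs = exprs, pca_all = pca_all, pca_uns = pca_uns,
         contrasts = contrasts, uns = uns, assignment = assignment,
         summary = summary, signature_sets = sets, subnetworks = subnets,
         degree_reports = degrees, enrichment = enr, report = report)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(result) <- "stemsig_run"
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' Seven-cluster summary report
#'
#' One row per cluster (1-7) with its size, connector count and up to three
#' representative genes, followed by per-signature totals. The partition
#' check (signature totals + cluster 7 = assigned UNS size) is asserted.
#'
#' @param assignment A `signature_assignment`.
#' @param uns A `uns_result` (for connector counts) or `NULL`.
#' @param summaries Output of [summarize_signatures()].
#' @return Data frame of class `cluster_report` with columns `cluster`,
#'   `signature`, `direction`, `n`, `n_connectors`, `representative`;
#'   attributes `signature_totals` and `n_significant`.
#' @export
report_summary <- function(assignment, uns = NULL, summaries = NULL) {
  connectors <- if (!is.null(uns)) uns$connectors$members else character(0)
  rows <- lapply(1:7, function(cl) {
    g <- assignment$gene[assignment$cluster == cl]
    data.frame(cluster = cl,
               signature = CLUSTER_SIGNATURE[cl],
               direction = if (cl == 7L) "none" else if (cl %% 2L) "up" else "down",
               n = length(g),
               n_connectors = sum(g %in_ci% connectors),
               representative = paste(utils::head(g, 3L), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_sig <- sum(out$n[1:6])
  assert_that(n_sig + out$n[7L] == nrow(assignment),
              "internal error: cluster report does not partition the UNS")
  totals <- if (!is.null(summaries)) summaries else summarize_signatures(assignment, uns)
  structure(out, signature_totals = totals, n_significant = n_sig,
            class = c("cluster_report", "data.frame"))
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster report (", attr(x, "n_significant"), "genes significant,",
      x$n[7L], "in cluster 7)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Write every stage output of a run as plain text under `dir`.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_expression_tsv(run$exprs, p("normalized.tsv"))
  utils::write.table(
    data.frame(sample = rownames(run$pca_all$scores),
               round(run$pca_all$scores[, 1:min(3, ncol(run$pca_all$scores))], 6)),
    p("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(component = seq_along(run$pca_all$variance_fraction),
               all_genes = run$pca_all$variance_fraction,
               uns_genes = c(run$pca_uns$variance_fraction,
                             rep(NA, max(0, length(run$pca_all$variance_fraction) -
                                           length(run$pca_uns$variance_fraction))))),
    p("pca_variance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(gene = rownames(run$contrasts),
                           as.data.frame(run$contrasts)),
                     p("contrasts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(list(run$uns$seed, run$uns$connectors, run$uns$uns)[
    lengths(list(run$uns$seed$members, run$uns$connectors$members,
                 run$uns$uns$members)) > 0], p("uns.gmt"))
  utils::write.table(run$assignment, p("assignment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$summary, p("signature_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(run$signature_sets)) {
    write_gmt(run$signature_sets, p("signatures.gmt"))
  }
  for (nm in names(run$subnetworks)) {
    export_network(run$subnetworks[[nm]], p(sprintf("subnet_%s.sif", nm)),
                   "SIF", p(sprintf("subnet_%s_attrs.tsv", nm)))
    utils::write.table(run$degree_reports[[nm]],
                       p(sprintf("degrees_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$enrichment$records)) {
    utils::write.table(run$enrichment$records, p("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cbind(term = rownames(run$enrichment$percent_table),
                           as.data.frame(run$enrichment$percent_table)),
                     p("slim_percentages.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(run$report, p("cluster_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a study and run the full pipeline on it
#'
#' Convenience wrapper joining the synthetic-data generators to [run_all()];
#' the returned object carries the ground truth for recovery checks.
#'
#' @param config A [sim_config()].
#' @param ... Passed to [run_all()] (e.g. `out_dir`, `config`, `mode`).
#' @return A `stemsig_run` with extra elements `truth` and `sim_config`.
#' @export
run_simulation_study <- function(config = sim_config(), ...) {
  sim <- simulate_expression(config)
  net <- simulate_network(config, sim$truth)
  ann <- simulate_annotations(config, sim$truth)
  seed <- gene_set("seed", sim$truth$gene[sim$truth$is_seed])
  run <- run_all(sim$exprs, sim$groups, seed, net, ann$annotations, ann$slim, ...)
  run$truth <- sim$truth
  run$sim_config <- config
  run$enriched_term <- ann$enriched_term
  run
}

#' Fraction of planted signature genes recovered
#'
#' Compares a run's cluster assignment to the simulation ground truth:
#' a planted gene counts as recovered when it receives exactly its true
#' cluster (signature and direction both correct).
#'
#' @param run A `stemsig_run` from [run_simulation_study()].
#' @return List with `recovered`, `planted` and `fraction`.
#' @export
signature_recovery <- function(run) {
  assert_that(!is.null(run$truth), "run carries no ground truth")
  truth <- run$truth
  planted <- truth[truth$true_signature != "none", ]
  m <- match(planted$gene, run$assignment$gene)
  ok <- !is.na(m) & run$assignment$cluster[m] == planted$true_cluster
  list(recovered = sum(ok), planted = nrow(planted),
       fraction = sum(ok) / nrow(planted))
}
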