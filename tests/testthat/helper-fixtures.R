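# Fixture builders shared across test files. Everything is generated in code;
# gene names that appear are the well-known marker symbols used for realism
# via the simulator's alias mechanism.

# A small, fast simulation design for unit tests (the full-size design is
# exercised in the acceptance suite).
small_config <- function(...) {
  defaults <- list(n_blastomere = 12L, n_icm = 2L, n_hesc = 4L,
                   n_genes = 400L, n_seed = 80L, n_connector_true = 20L,
                   planted = list(TS = c(up = 6L, down = 10L),
                                  IVVPS = c(up = 5L, down = 2L),
                                  IVTPS = c(up = 18L, down = 6L)))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Cluster assignment carrying the published seven-cluster count structure:
# TS 17 up / 44 down, IVVPS 17 up / 4 down, IVTPS 83 up / 24 down,
# 77 genes without significant differences; 266 genes in all.
fig2_assignment <- function() {
  sizes <- c(17L, 44L, 17L, 4L, 83L, 24L, 77L)
  cluster <- rep(1:7, sizes)
  sig <- c("TS", "TS", "IVVPS", "IVVPS", "IVTPS", "IVTPS", "none")[cluster]
  dir <- ifelse(cluster == 7L, "none", ifelse(cluster %% 2L == 1L, "up", "down"))
  owner <- c("B", "B", "I", "I", "H", "H", "none")[cluster]
  structure(
    data.frame(gene = sprintf("G%06d", seq_along(cluster)),
               cluster = cluster, signature = sig, direction = dir,
               owner = owner, ambiguous = FALSE, stringsAsFactors = FALSE),
    skipped = character(0),
    class = c("signature_assignment", "data.frame"))
}

# Star network around POU5F1 with its 29 reported in-vitro-signature
# partners: 16 nuclear, 3 cytoplasmic, 5 plasma-membrane, 5 extracellular.
pou5f1_star <- function() {
  nucleus <- c("GATA3", "KLF4", "MKI67", "SOX2", "ESR1", "MYC", "CCND1",
               "HMGB1", "RELA", "POU2F1", "TERT", "TERF1", "DPPA5", "NR6A1",
               "RUVBL1", "TP53")
  cytoplasm <- c("NES", "VIM", "GAS6")
  membrane <- c("FZD5", "NOTCH1", "THY1", "CDH1", "CD44")
  extracellular <- c("LEFTY2", "TDGF1", "FN1", "EGFR", "TNF")
  partners <- c(nucleus, cytoplasm, membrane, extracellular)
  g <- igraph::graph_from_data_frame(
    data.frame(from = "POU5F1", to = partners, type = "functional"),
    directed = FALSE)
  igraph::V(g)$compartment <- c("nucleus",
                                rep(c("nucleus", "cytoplasm", "plasma membrane",
                                      "extracellular space"),
                                    c(16L, 3L, 5L, 5L)))
  g
}

# The 16 printed members of the cell-surface term in the TS-versus-IVTPS
# comparison, plus the term annotation table around them.
cell_surface_fixture <- function() {
  members <- c("ACVR2B", "BRCA1", "CAV1", "CD44", "GATA2", "GATA3", "HSPD1",
               "ITGA5", "ITGA6", "KLF4", "RARA", "RELA", "TDGF1", "TGFB1",
               "THY1", "TNF")
  other <- sprintf("X%03d", 1:40)
  list(members = members,
       query = c(members, other[1:20]),
       background = c(members, other),
       annotations = data.frame(gene = members, term = "GO:0009986",
                                stringsAsFactors = FALSE))
}

# Independent BH step-up oracle: adjusted_i = min over j with p_(j) >= p_(i)
# of m * p_(j) / j, clipped to 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent quantile-normalization oracle for small matrices without ties:
# replace each column's sorted values by the across-column mean of order
# statistics.
qn_oracle <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(x) target[rank(x)])
}
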