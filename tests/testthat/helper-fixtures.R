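# Small fixtures built in code.

make_table <- function(counts, ages = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  ages <- ages %||% seq(1200, by = 25, length.out = nrow(counts))
  chron <- data.frame(sample_id = rownames(counts), depth_cm = NA_real_,
                      age_year_ce = ages)
  taxon_table(counts, chron, taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two tight clusters whose between-group distances all exceed within-group ones
two_cluster_matrix <- function(n_per = 5, gap = 10, spread = 0.05, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2, 0, spread), n_per),
               matrix(rnorm(n_per * 2, gap, spread), n_per))
    rownames(x) <- sprintf("p%02d", seq_len(2 * n_per))
    x
  })
}

# independent rank-based ANOSIM oracle, written directly from the definition
anosim_R_oracle <- function(d, labels) {
  labels <- factor(labels)
  n <- attr(d, "Size")
  rd <- rank(as.vector(d))
  same <- as.vector(stats::as.dist(outer(labels, labels, "=="))) > 0
  (mean(rd[!same]) - mean(rd[same])) / (n * (n - 1) / 4)
}
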