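test_that("taxon tables round-trip through TSV identically", {
  sc <- transition_scenario(seed = 7, n_samples = 35)
  tab <- sc$table
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "tab.tsv"); f2 <- file.path(dir, "chron.tsv")
  write_taxon_table(tab, f1, f2)
  back <- read_taxon_table(f1, f2)
  expect_identical(back$counts, tab$counts)
  expect_equal(back$chronology$age_year_ce, tab$chronology$age_year_ce)
  expect_equal(unname(back$taxonomy), unname(tab$taxonomy))
})

test_that("reading validates counts and chronology", {
  tab <- make_table(matrix(c(3L, 1L, 0L, 5L), 2, 2), ages = c(1300, 1400))
  expect_equal(dim(tab$counts), c(2, 2))
  expect_equal(tab$chronology$age_year_ce, c(1300, 1400))
  # age-disordered input gets sorted with a warning
  expect_warning(
    t2 <- make_table(matrix(1:4, 2, 2), ages = c(1400, 1300)),
    "re-sorted")
  expect_equal(t2$chronology$age_year_ce, c(1300, 1400))
  # missing age names the sample
  chron <- data.frame(sample_id = "s01", depth_cm = NA, age_year_ce = 1300)
  m <- matrix(1:4, 2, 2, dimnames = list(c("s01", "s02"), c("a", "b")))
  expect_error(taxon_table(m, chron), "s02")
  # negative counts name the cell
  expect_error(make_table(matrix(c(1L, -2L, 3L, 4L), 2, 2)), "negative")
})

test_that("rarefaction conserves depth, is seed-reproducible and unbiased", {
  tab <- make_table(matrix(c(10L, 0L, 7L, 3L), 2, 2, byrow = TRUE))
  r5 <- suppressWarnings(rarefy(tab, depth = 5, seed = 1))
  expect_equal(unname(rowSums(r5$counts)), c(5, 5))
  expect_equal(unname(r5$counts[1, ]), c(5L, 0L))  # single-taxon mass
  # already at depth -> unchanged
  expect_identical(suppressWarnings(rarefy(tab, depth = 10, seed = 1))$counts[1, ],
                   tab$counts[1, ])
  # identical seeds are bit-identical
  big <- make_table(matrix(rpois(200, 50) + 1L, 10, 20))
  expect_identical(rarefy(big, seed = 9)$counts, rarefy(big, seed = 9)$counts)
  # depth above a sample total names the sample
  expect_error(rarefy(tab, depth = 11), "s0")
  # hypergeometric mean: (600, 400) rarefied to 100 over many draws
  n_rep <- 4000
  reps <- make_table(matrix(rep(c(600L, 400L), each = n_rep), ncol = 2),
                     ages = seq_len(n_rep))
  cnt <- rarefy(reps, depth = 100, seed = 3)$counts[, 1]
  sd_hyper <- sqrt(100 * 0.6 * 0.4 * (1000 - 100) / (1000 - 1))
  expect_lt(abs(mean(cnt) - 60), 3 * sd_hyper / sqrt(n_rep))
})

test_that("relative abundance preserves ratios and row sums", {
  tab <- make_table(matrix(c(3L, 1L, 0L, 5L), 2, 2, byrow = TRUE))
  rel <- to_relative(tab)
  expect_equal(unname(rel[1, ]), c(0.75, 0.25))
  expect_equal(unname(rel[2, ]), c(0, 1))
  sc <- transition_scenario(seed = 2)
  rel2 <- to_relative(sc$table)
  expect_true(all(abs(rowSums(rel2) - 1) < 1e-12))
  zero <- make_table(matrix(c(1L, 1L, 0L, 0L), 2, 2, byrow = TRUE))
  expect_error(to_relative(zero), "zero-total")
})

test_that("taxonomic collapsing sums within ranks and conserves totals", {
  tax <- c("k__Bacteria; p__X; c__Cytophagia",
           "k__Bacteria; p__X; c__Cytophagia",
           "k__Bacteria; p__Y; c__Other",
           "k__Bacteria; p__Y")          # no class label
  counts <- matrix(c(3L, 4L, 2L, 6L,
                     1L, 2L, 3L, 4L), 2, 4, byrow = TRUE)
  tab <- make_table(counts, taxonomy = tax)
  col <- collapse_taxonomy(tab, "class")
  expect_setequal(colnames(col$counts), c("Cytophagia", "Other", "unclassified"))
  expect_equal(unname(col$counts[, "Cytophagia"]), c(7L, 3L))
  expect_equal(unname(col$counts[, "unclassified"]), c(6L, 4L))
  expect_equal(rowSums(col$counts), rowSums(tab$counts))  # mass conservation
  expect_error(collapse_taxonomy(tab, "species"), "no taxon")
  # mass conservation on a larger random fixture: 40 OTUs in 12 classes
  withr::with_seed(5, {
    cls <- sample(sprintf("c__C%02d", 1:12), 40, replace = TRUE)
    tax2 <- sprintf("k__B; p__P; %s", cls)
    m <- matrix(rpois(40 * 6, 20), 6, 40)
    tab2 <- make_table(m, taxonomy = tax2)
  })
  col2 <- collapse_taxonomy(tab2, "class")
  expect_lte(ncol(col2$counts), 13)
  expect_equal(rowSums(col2$counts), rowSums(tab2$counts))
})

test_that("collapse then normalize commutes with normalizing proportions", {
  sc <- transition_scenario(seed = 3)
  tab <- sc$table
  col <- collapse_taxonomy(tab, "class")
  a <- to_relative(col)
  # same collapse on proportions directly
  lab <- ifelse(colnames(tab$counts) == "unclassified", "unclassified",
                sub("^.*c__", "", tab$taxonomy[colnames(tab$counts)]))
  p <- to_relative(tab)
  b <- vapply(colnames(a), function(g)
    rowSums(p[, lab == g, drop = FALSE]), numeric(nrow(p)))
  expect_equal(unclass(a), b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("modeled-taxa selection applies the abundance rule and renormalizes", {
  m <- matrix(c(0.60, 0.30, 0.001, 0.099,
                0.60, 0.30, 0.001, 0.099), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3", "t4")))
  cm <- community_matrix(m, ages = c(1, 2))
  sel <- select_modeled_taxa(cm, min_mean_abund = 0.01, max_taxa = 12)
  expect_setequal(colnames(sel), c("t1", "t2", "t4"))
  expect_true(all(abs(rowSums(sel) - 1) < 1e-12))
  # all above threshold -> unchanged up to renormalization
  sel2 <- select_modeled_taxa(cm, min_mean_abund = 0, max_taxa = 10)
  expect_setequal(colnames(sel2), colnames(cm))
  # kept set equals the brute-force filter of column means
  sc <- transition_scenario(seed = 5)
  rel <- to_relative(sc$table)
  kept <- colnames(select_modeled_taxa(rel, 0.01, 12))
  pool <- setdiff(colnames(rel), "unclassified")
  brute <- pool[colMeans(rel[, pool]) >= 0.01]
  brute <- brute[rank(-colMeans(rel[, brute]), ties.method = "first") <= 12]
  expect_setequal(kept, brute)
  # fewer than two taxa retained is an error
  expect_error(select_modeled_taxa(cm, min_mean_abund = 0.5), "S >= 2")
})
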