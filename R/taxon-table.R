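#' Taxon-by-sample count table with a calibrated chronology
#'
#' The basic data container of the package: a non-negative integer count
#' matrix (samples in rows, taxa in columns), an optional taxonomy string per
#' taxon, and a chronology assigning every sample a calibrated calendar age
#' (years CE). Samples are kept in stratigraphic order, oldest first, so the
#' row order is also the time order used by all downstream analyses.
#'
#' @param counts non-negative integer matrix, samples x taxa. Row names are
#'   sample ids, column names taxon ids; both must be unique.
#' @param chronology data frame with columns `sample_id`, `depth_cm` (optional,
#'   `NA` allowed) and `age_year_ce`, one row per sample.
#' @param taxonomy optional character vector of rank-delimited taxonomy strings
#'   (e.g. `"k__Bacteria; p__Bacteroidota; c__Cytophagia"`), one per taxon.
#' @return An object of class `taxon_table`: a list with elements `counts`,
#'   `chronology` and `taxonomy`.
#' @examples
#' counts <- matrix(c(3L, 1L, 0L, 5L), 2, 2,
#'                  dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' chron <- data.frame(sample_id = c("s1", "s2"), depth_cm = c(10, 6),
#'                     age_year_ce = c(1300, 1400))
#' taxon_table(counts, chron)
#' @export
taxon_table <- function(counts, chronology, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("counts must have sample (row) and taxon (column) names")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop_("counts must be finite and numeric")
  storage.mode(counts) <- "integer"
  chronology <- as.data.frame(chronology)
  if (!all(c("sample_id", "age_year_ce") %in% names(chronology)))
    stop_("chronology needs columns sample_id and age_year_ce")
  if (!"depth_cm" %in% names(chronology)) chronology$depth_cm <- NA_real_
  x <- structure(list(counts = counts,
                      chronology = chronology[c("sample_id", "depth_cm", "age_year_ce")],
                      taxonomy = taxonomy),
                 class = "taxon_table")
  validate_taxon_table(x)
}

validate_taxon_table <- function(x) {
  counts <- x$counts
  chron <- x$chronology
  if (anyDuplicated(rownames(counts))) stop_("duplicated sample ids")
  if (anyDuplicated(colnames(counts))) stop_("duplicated taxon ids")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_(sprintf("negative count at sample '%s', taxon '%s'",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  missing_age <- setdiff(rownames(counts), chron$sample_id)
  if (length(missing_age) > 0)
    stop_("no age for sample(s): ", paste(missing_age, collapse = ", "))
  chron <- chron[match(rownames(counts), chron$sample_id), , drop = FALSE]
  if (any(!is.finite(chron$age_year_ce))) stop_("non-finite ages in chronology")
  ord <- order(chron$age_year_ce)
  if (any(diff(chron$age_year_ce[ord]) <= 0))
    stop_("chronology ages must be strictly monotonic across samples")
  if (is.unsorted(chron$age_year_ce, strictly = TRUE)) {
    warning("samples re-sorted into age order (oldest first)", call. = FALSE)
    counts <- counts[ord, , drop = FALSE]
    chron <- chron[ord, , drop = FALSE]
  }
  if (!is.null(x$taxonomy)) {
    if (length(x$taxonomy) != ncol(counts))
      stop_("taxonomy length must equal the number of taxa")
    names(x$taxonomy) <- colnames(counts)
  }
  rownames(chron) <- NULL
  x$counts <- counts
  x$chronology <- chron
  x
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d samples x %d taxa\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  ages %s to %s CE (oldest first)\n",
              format(min(x$chronology$age_year_ce)),
              format(max(x$chronology$age_year_ce))))
  cat(sprintf("  total counts per sample: %s to %s\n",
              format(min(rowSums(x$counts))), format(max(rowSums(x$counts)))))
  if (!is.null(x$taxonomy)) cat("  taxonomy strings present\n")
  invisible(x)
}

#' Sample ages of a table or community matrix
#' @param x a `taxon_table` or `community_matrix`.
#' @return numeric vector of calibrated ages (years CE), oldest first.
#' @export
sample_ages <- function(x) {
  if (inherits(x, "taxon_table")) return(x$chronology$age_year_ce)
  a <- attr(x, "ages")
  if (is.null(a)) stop_("no ages attached to this object")
  a
}

#' Read a taxon table and its chronology from disk
#'
#' The table is tab-separated with taxa as rows and samples as columns; the
#' first column holds taxon ids and an optional last column named `taxonomy`
#' holds rank-delimited taxonomy strings. BIOM-format JSON (`.biom`/`.json`)
#' is also accepted (via the biomformat package). The chronology is a
#' three-column TSV: `sample_id`, `depth_cm`, `age_year_ce`. Samples are
#' returned sorted by age, oldest first; a warning is raised if the file order
#' disagreed with age order.
#'
#' @param path path to the count table (TSV or BIOM JSON).
#' @param chronology_path path to the chronology TSV.
#' @return a [taxon_table].
#' @export
read_taxon_table <- function(path, chronology_path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  if (!file.exists(chronology_path)) stop_("no such file: ", chronology_path)
  chron <- read_tsv_plain(chronology_path)
  if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    counts <- t(as.matrix(biomformat::biom_data(b)))
    tax <- tryCatch({
      om <- biomformat::observation_metadata(b)
      if (is.null(om)) NULL else apply(as.data.frame(om), 1, paste, collapse = "; ")
    }, error = function(e) NULL)
  } else {
    raw <- read_tsv_plain(path)
    taxon_ids <- as.character(raw[[1]])
    tax <- NULL
    val <- raw[-1]
    if ("taxonomy" %in% names(val)) {
      tax <- as.character(val$taxonomy)
      val$taxonomy <- NULL
    }
    m <- as.matrix(val)
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
      stop_(sprintf("non-numeric count at table row %d, column '%s'",
                    bad[1, 1], colnames(m)[bad[1, 2]]))
    }
    if (any(m < 0)) {
      bad <- which(m < 0, arr.ind = TRUE)
      stop_(sprintf("negative count at table row %d, column '%s'",
                    bad[1, 1], colnames(m)[bad[1, 2]]))
    }
    if (any(m != round(m)))
      stop_("counts must be integers")
    counts <- t(m)
    colnames(counts) <- taxon_ids
    if (!is.null(tax)) names(tax) <- taxon_ids
  }
  taxon_table(counts, chron, taxonomy = tax)
}

#' Write a taxon table and chronology to disk
#'
#' Emits the same UTF-8 tab-delimited formats [read_taxon_table()] consumes,
#' with a commented provenance header line. Round-trips losslessly.
#'
#' @param x a [taxon_table].
#' @param path output path for the count table TSV.
#' @param chronology_path output path for the chronology TSV.
#' @param seed optional integer recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(x, path, chronology_path, seed = NULL) {
  m <- t(x$counts)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  write_tsv_prov(df, path, "taxon table (taxa x samples)", seed)
  write_tsv_prov(x$chronology, chronology_path, "chronology", seed)
  invisible(path)
}

#' Rarefy all samples to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`, the convention behind "rarefied to the
#' minimum number of reads". Reproducible for a fixed seed.
#'
#' @param x a [taxon_table].
#' @param depth target depth; defaults to the minimum sample total.
#' @param seed integer RNG seed.
#' @return a [taxon_table] whose rows all sum exactly to `depth`.
#' @export
rarefy <- function(x, depth = NULL, seed = 1L) {
  stopifnot(inherits(x, "taxon_table"))
  totals <- rowSums(x$counts)
  depth <- as.integer(depth %||% min(totals))
  if (depth <= 0) stop_("depth must be positive")
  low <- totals < depth
  if (any(low))
    stop_("depth ", depth, " exceeds total reads of sample(s): ",
          paste(rownames(x$counts)[low], collapse = ", "))
  counts <- withCallingHandlers(
    with_seed_(seed, vegan::rrarefy(x$counts, sample = depth)),
    # vegan's advisory note about count provenance; the inputs here are counts
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(counts) <- "integer"
  x$counts <- counts
  x
}

#' Convert counts to a relative-abundance community matrix
#'
#' @param x a [taxon_table].
#' @return a `community_matrix`: samples x taxa matrix of proportions with
#'   rows summing to 1, carrying the sample ages as an attribute.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "taxon_table"))
  totals <- rowSums(x$counts)
  if (any(totals == 0))
    stop_("zero-total sample(s): ",
          paste(rownames(x$counts)[totals == 0], collapse = ", "))
  rel <- x$counts / totals
  community_matrix(rel, ages = x$chronology$age_year_ce)
}

#' Construct a relative-abundance community matrix
#'
#' @param rel samples x taxa matrix of proportions; rows must sum to 1.
#' @param ages numeric vector of sample ages (years CE), oldest first.
#' @return a `community_matrix`.
#' @export
community_matrix <- function(rel, ages) {
  rel <- as.matrix(rel)
  if (any(rel < -1e-12) || any(rel > 1 + 1e-12))
    stop_("relative abundances must lie in [0, 1]")
  if (any(abs(rowSums(rel) - 1) > 1e-9))
    stop_("community matrix rows must sum to 1")
  if (length(ages) != nrow(rel)) stop_("one age per sample required")
  structure(rel, ages = as.numeric(ages),
            class = c("community_matrix", class(rel)))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d taxa (rows sum to 1)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

# Extract the label at `rank` from a rank-prefixed, semicolon-delimited
# taxonomy string; "" when absent/unclassified.
rank_prefixes <- c(kingdom = "k", domain = "k", phylum = "p", class = "c",
                   order = "o", family = "f", genus = "g", species = "s")

parse_rank <- function(taxonomy, rank, rank_index = NULL) {
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  parts <- lapply(parts, trimws)
  if (!is.null(rank_index)) {
    lab <- vapply(parts, function(p)
      if (length(p) >= rank_index) p[[rank_index]] else "", "")
  } else {
    if (!rank %in% names(rank_prefixes))
      stop_("unknown rank '", rank, "'; use one of: ",
            paste(unique(names(rank_prefixes)), collapse = ", "),
            " or give rank_index")
    pre <- paste0(rank_prefixes[[rank]], "__")
    lab <- vapply(parts, function(p) {
      hit <- p[startsWith(p, pre)]
      if (length(hit) == 0) "" else sub(pre, "", hit[[1]], fixed = TRUE)
    }, "")
  }
  lab[is.na(lab)] <- ""
  trimws(lab)
}

#' Collapse a taxon table to a taxonomic rank
#'
#' Taxa sharing the same label at `rank` are summed; taxa with no label at
#' that rank are pooled into a reserved `"unclassified"` taxon. Per-sample
#' totals are conserved exactly.
#'
#' @param x a [taxon_table] with taxonomy strings.
#' @param rank rank name (`"class"` by default) for rank-prefixed
#'   semicolon-delimited strings (`k__;p__;c__;...`).
#' @param rank_index optional 1-based position in the taxonomy string, for
#'   dialects without rank prefixes.
#' @return a [taxon_table] with one column per rank-level group.
#' @export
collapse_taxonomy <- function(x, rank = "class", rank_index = NULL) {
  stopifnot(inherits(x, "taxon_table"))
  if (is.null(x$taxonomy)) stop_("table has no taxonomy strings")
  lab <- parse_rank(x$taxonomy, rank, rank_index)
  if (all(lab == ""))
    stop_("no taxon is classified at rank '", rank, "'")
  lab[lab == ""] <- "unclassified"
  groups <- unique(lab)
  agg <- vapply(groups, function(g)
    rowSums(x$counts[, lab == g, drop = FALSE]), numeric(nrow(x$counts)))
  if (nrow(x$counts) == 1) agg <- matrix(agg, 1, dimnames = list(rownames(x$counts), groups))
  storage.mode(agg) <- "integer"
  taxon_table(agg, x$chronology)
}

#' Select the taxon set used for dynamical modeling
#'
#' Retains taxa whose mean relative abundance across samples meets
#' `min_mean_abund`, capped at the `max_taxa` most abundant, then renormalizes
#' each sample over the retained set. Defaults follow the convention of
#' modeling the ~12 dominant class-level groups (mean abundance >= 1%).
#'
#' @param x a `community_matrix`.
#' @param min_mean_abund minimum mean relative abundance (fraction).
#' @param max_taxa maximum number of taxa retained.
#' @param drop_unclassified drop a taxon literally named "unclassified" before
#'   selection (default TRUE): the pooled remainder is not a dynamical unit.
#' @return a `community_matrix` over the retained taxa, rows re-summing to 1,
#'   with the selection recorded in the `"selection"` attribute.
#' @export
select_modeled_taxa <- function(x, min_mean_abund = 0.01, max_taxa = 12,
                                drop_unclassified = TRUE) {
  stopifnot(inherits(x, "community_matrix"))
  if (min_mean_abund < 0 || min_mean_abund >= 1)
    stop_("min_mean_abund must lie in [0, 1)")
  keep_pool <- colnames(x)
  if (drop_unclassified) keep_pool <- setdiff(keep_pool, "unclassified")
  mu <- colMeans(x[, keep_pool, drop = FALSE])
  keep <- names(mu)[mu >= min_mean_abund]
  keep <- keep[order(mu[keep], decreasing = TRUE)]
  if (length(keep) > max_taxa) keep <- keep[seq_len(max_taxa)]
  if (length(keep) < 2)
    stop_("fewer than 2 taxa retained; the gLV model needs S >= 2")
  keep <- keep_pool[keep_pool %in% keep]  # restore stratigraphic column order
  sub <- x[, keep, drop = FALSE]
  sub <- sub / rowSums(sub)
  out <- community_matrix(sub, ages = attr(x, "ages"))
  attr(out, "selection") <- list(rule = sprintf("mean >= %g, cap %d", min_mean_abund, max_taxa),
                                 kept = keep, mean_abund = mu[keep])
  out
}
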