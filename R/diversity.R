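#' Alpha diversity per sample
#'
#' Computes observed richness, Shannon entropy and Gini-Simpson diversity for
#' every sample. Richness is the number of taxa with non-zero abundance and is
#' conventionally computed on rarefied counts; Shannon is \eqn{-\sum p \ln p}
#' (natural log, with \eqn{0 \ln 0 := 0}); Simpson is the Gini-Simpson index
#' \eqn{1 - \sum p^2}, bounded in [0, 1]. An inverse-Simpson variant is
#' available via `simpson = "inverse"`.
#'
#' @param x a [taxon_table] (richness from counts, proportions computed
#'   internally) or a `community_matrix`.
#' @param simpson `"gini"` (default) or `"inverse"`.
#' @return data frame with columns `sample_id`, `age_year_ce`, `richness`,
#'   `shannon`, `simpson`.
#' @examples
#' p <- community_matrix(matrix(rep(0.25, 8), 2, 4,
#'        dimnames = list(c("a", "b"), paste0("t", 1:4))), ages = c(1, 2))
#' alpha_diversity(p)  # shannon = log(4), simpson = 0.75
#' @export
alpha_diversity <- function(x, simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  if (inherits(x, "taxon_table")) {
    counts <- x$counts
    ages <- x$chronology$age_year_ce
    p <- counts / rowSums(counts)
  } else if (inherits(x, "community_matrix")) {
    p <- unclass(x)
    counts <- p
    ages <- attr(x, "ages")
  } else stop_("x must be a taxon_table or community_matrix")
  if (nrow(p) == 0 || ncol(p) == 0) stop_("empty matrix")
  shannon <- vegan::diversity(p, index = "shannon")
  gini <- vegan::diversity(p, index = "simpson")
  data.frame(sample_id = rownames(p),
             age_year_ce = ages,
             richness = as.integer(rowSums(counts > 0)),
             shannon = as.numeric(shannon),
             simpson = if (simpson == "gini") as.numeric(gini) else 1 / rowSums(p^2),
             row.names = NULL)
}

#' Kruskal-Wallis rank test
#'
#' Non-parametric test for differences between groups, used to compare alpha
#' diversity between community states. Midranks with tie correction; the
#' p-value comes from the chi-square approximation with (groups - 1) degrees
#' of freedom.
#'
#' @param values numeric observations.
#' @param labels group labels, one per observation; at least two non-empty
#'   groups.
#' @return list with `H` (the test statistic), `df` and `p`.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_("need at least two groups")
  if (any(table(labels) == 0)) stop_("every group needs observations")
  if (length(values) != length(labels)) stop_("values and labels differ in length")
  if (length(unique(values)) == 1)  # all-tied data: H degenerates to 0
    return(list(H = 0, df = nlevels(labels) - 1, p = 1))
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = if (is.nan(kt$p.value)) 1 else kt$p.value)
}

#' Compare alpha-diversity indices between community states
#'
#' Runs [kruskal_wallis()] for each index in an [alpha_diversity()] table
#' against a state labelling (typically the two-state zonation cut).
#'
#' @param alpha data frame from [alpha_diversity()].
#' @param labels state label per sample.
#' @return data frame with columns `index`, `H`, `df`, `p`.
#' @export
alpha_compare <- function(alpha, labels) {
  idx <- c("richness", "shannon", "simpson")
  out <- lapply(idx, function(i) {
    kt <- kruskal_wallis(alpha[[i]], labels)
    data.frame(index = i, H = kt$H, df = kt$df, p = kt$p)
  })
  do.call(rbind, out)
}
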