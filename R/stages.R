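#' Stage-wise gLV inference, stability and interaction typing
#'
#' Runs the full model-analysis chain over overlapping stage windows (see
#' [stage_windows()]): per stage, taxa absent from the window are dropped, a
#' gLV model is fitted by ridge regression with cross-validated penalty, the
#' interior equilibrium and Jacobian spectrum are computed, and pairwise
#' interactions are classified. Failures in a stage (e.g. an interaction
#' matrix too ill-conditioned to solve for the equilibrium) are logged and do
#' not abort the remaining stages.
#'
#' @param x samples x taxa relative-abundance matrix (`community_matrix`).
#' @param ages sample ages in years; defaults to the ages carried by `x`.
#' @param w,s stage window length and step (defaults 10 and 5).
#' @param lambda_grid,k_folds,pseudocount,global_lambda passed to [glv()];
#'   `k_folds` is reduced to the number of available equations for truncated
#'   trailing windows.
#' @param cond_max condition-number threshold for the equilibrium solve.
#' @param equilibrium how the per-stage linearization point is obtained:
#'   `"pinv"` (default) solves the fitted system A N* = r by a truncated
#'   singular-value pseudoinverse (see [steady_state()]) - a window of w
#'   samples gives only w - 1 equations per taxon, so the fitted A of a
#'   richer community is structurally rank-deficient and a strict inverse
#'   does not exist; `"solve"` insists on it anyway (and fails in that
#'   case); `"observed"` linearizes at the window's mean composition, the
#'   empirical quasi-steady state.
#' @return object of class `glv_stages`: `stages` (summary data frame with
#'   one row per stage: sample range, age range, taxa used, chosen penalty,
#'   CV error, eigenvalue centroid, stability and feasibility flags,
#'   interaction-type proportions and strengths), `fits`, `stability`,
#'   `interactions` (per-stage lists; `NULL` where a step failed), `windows`,
#'   `errors` (per-stage messages).
#' @export
stage_analysis <- function(x, ages = NULL, w = 10, s = 5,
                           lambda_grid = default_lambda_grid(), k_folds = 5,
                           pseudocount = NULL, global_lambda = FALSE,
                           cond_max = 1e8,
                           equilibrium = c("pinv", "solve", "observed")) {
  equilibrium <- match.arg(equilibrium)
  ages <- ages %||% attr(x, "ages")
  if (is.null(ages)) stop_("ages required (none attached to x)")
  win <- stage_windows(nrow(x), w, s)
  K <- nrow(win)
  fits <- stab <- inter <- vector("list", K)
  errors <- character(K)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- win$start[k]:win$end[k]
    sub <- unclass(x)[sel, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    sub <- sub / rowSums(sub)
    row <- data.frame(stage = k, start = win$start[k], end = win$end[k],
                      age_from = ages[win$start[k]], age_to = ages[win$end[k]],
                      S_used = ncol(sub), lambda = NA_real_, cv_error = NA_real_,
                      centroid_re = NA_real_, max_re = NA_real_,
                      stable = NA, feasible = NA,
                      prop_mutualism = NA_real_, prop_antagonism = NA_real_,
                      prop_exploitation = NA_real_,
                      strength_mutualism = NA_real_, strength_antagonism = NA_real_,
                      strength_exploitation = NA_real_)
    res <- tryCatch({
      fit <- glv(sub, ages = ages[sel], lambda_grid = lambda_grid,
                 k_folds = min(k_folds, length(sel) - 1), pseudocount = pseudocount,
                 global_lambda = global_lambda)
      fits[[k]] <- fit
      row$lambda <- mean(fit$lambda)
      row$cv_error <- mean(fit$cv_error)
      ia <- classify_interactions(fit)
      inter[[k]] <- ia
      row$prop_mutualism <- ia$proportions[["mutualism"]]
      row$prop_antagonism <- ia$proportions[["antagonism"]]
      row$prop_exploitation <- ia$proportions[["exploitation"]]
      row$strength_mutualism <- ia$strength[["mutualism"]]
      row$strength_antagonism <- ia$strength[["antagonism"]]
      row$strength_exploitation <- ia$strength[["exploitation"]]
      st <- if (equilibrium == "observed")
        stability(fit, N = colMeans(sub)[fit$taxa])
      else stability(fit, cond_max = cond_max, method = equilibrium)
      stab[[k]] <- st
      row$centroid_re <- st$centroid_re
      row$max_re <- st$max_re
      row$stable <- st$stable
      row$feasible <- st$feasible
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[k] <- res
    rows[[k]] <- row
  }
  structure(list(stages = do.call(rbind, rows), fits = fits,
                 stability = stab, interactions = inter,
                 windows = win, errors = errors),
            class = "glv_stages")
}

#' @export
print.glv_stages <- function(x, ...) {
  cat(sprintf("stage-wise gLV analysis: %d stages\n", nrow(x$stages)))
  df <- x$stages[c("stage", "start", "end", "age_from", "age_to", "S_used",
                   "centroid_re", "stable", "feasible")]
  print(format(df, digits = 4), row.names = FALSE)
  failed <- which(nzchar(x$errors))
  for (k in failed)
    cat(sprintf("  stage %d incomplete: %s\n", k, x$errors[k]))
  invisible(x)
}

#' @export
summary.glv_stages <- function(object, ...) object$stages

#' @export
plot.glv_stages <- function(x, ...) {
  df <- x$stages
  graphics::plot(df$stage, df$centroid_re, type = "b", pch = 19,
                 xlab = "stage", ylab = "eigenvalue centroid (Re)",
                 main = "Stability trajectory across stages", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
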