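#' Default ridge-penalty grid for gLV inference
#'
#' 25 log-spaced values between 1e-4 and 1e2.
#' @return numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-4, 2, length.out = 25)

#' Overlapping stage windows over a stratigraphic series
#'
#' Splits n ordered samples into overlapping windows of length `w` advancing
#' by step `s`: window k covers samples `1 + (k-1)s` to `min((k-1)s + w, n)`,
#' for every start `<= n - s + 1`. The trailing window may be truncated but is
#' never shorter than `s`. With the defaults (w = 10, s = 5) a 35-sample core
#' yields 7 stages, the last holding 5 samples.
#'
#' @param n number of samples.
#' @param w window length (default 10).
#' @param s step size (default 5); must be smaller than `w` so successive
#'   windows overlap.
#' @return data frame with columns `stage`, `start`, `end`, `length`.
#' @examples
#' stage_windows(35)  # 7 stages; stage 7 = samples 31-35
#' @export
stage_windows <- function(n, w = 10, s = 5) {
  if (w <= s) stop_("w must exceed s so that successive windows overlap")
  if (n < w) stop_("need at least w samples")
  starts <- seq(1, n - s + 1, by = s)
  ends <- pmin(starts + w - 1, n)
  data.frame(stage = seq_along(starts), start = starts, end = ends,
             length = ends - starts + 1)
}

#' Forward-difference regression design for gLV inference
#'
#' Linearizes the gLV dynamics by forward differences of log abundances: for
#' each taxon i the response over consecutive sample pairs is
#' \eqn{y_k = \Delta \ln N_i(t_k) / \Delta t_k} and the predictor row is
#' \eqn{(1, -N_1(t_k), \ldots, -N_S(t_k))}, so the regression coefficients
#' are \eqn{(r_i, a_{i1}, \ldots, a_{iS})} directly. Zeros are replaced,
#' before taking logs, by a pseudocount defaulting to half the smallest
#' non-zero relative abundance in the data. Taxa with no non-zero abundance
#' anywhere are flagged and their equations dropped.
#'
#' @param x samples x taxa matrix of relative abundances (rows in time order).
#' @param ages sample ages (strictly increasing within each episode), in
#'   years.
#' @param pseudocount replacement for zero abundances before the log;
#'   `NULL` for the default rule.
#' @param episodes optional factor (one level per observation series): sample
#'   pairs are formed only within an episode, so independent time series -
#'   e.g. separate perturbation-relaxation experiments - can be pooled into
#'   one regression without forming differences across series boundaries.
#' @return list of class `glv_design`: `X` (rows = sample pairs, columns
#'   intercept + S negated abundances), `Y` (responses, one column per taxon),
#'   `taxa`, `dropped` (all-zero taxa), `pseudocount`, `ages`.
#' @export
glv_design <- function(x, ages, pseudocount = NULL, episodes = NULL) {
  x <- as.matrix(unclass(x))
  m <- nrow(x)
  if (m < 3) stop_("need at least 3 samples to form a design")
  if (length(ages) != m) stop_("one age per sample required")
  episodes <- episodes %||% rep(1L, m)
  if (length(episodes) != m) stop_("one episode label per sample required")
  dropped <- colnames(x)[colSums(x) == 0]
  keep <- setdiff(colnames(x), dropped)
  if (length(keep) < 2) stop_("fewer than 2 taxa with data; cannot build design")
  x <- x[, keep, drop = FALSE]
  if (is.null(pseudocount)) {
    nz <- x[x > 0]
    pseudocount <- min(nz) / 2
  }
  xl <- x
  xl[xl == 0] <- pseudocount
  Xs <- list(); Ys <- list()
  for (ep in unique(episodes)) {
    sel <- which(episodes == ep)
    if (length(sel) < 2) next
    if (any(diff(ages[sel]) <= 0))
      stop_("ages must be strictly increasing within an episode")
    dt <- diff(ages[sel])
    Ys[[length(Ys) + 1]] <-
      diff(log(xl[sel, , drop = FALSE])) / dt
    Xs[[length(Xs) + 1]] <-
      cbind(intercept = 1, -x[sel[-length(sel)], , drop = FALSE])
  }
  Y <- do.call(rbind, Ys)
  X <- do.call(rbind, Xs)
  if (is.null(Y) || nrow(Y) < 2) stop_("too few sample pairs to form a design")
  structure(list(X = X, Y = Y, taxa = keep, dropped = dropped,
                 pseudocount = pseudocount, ages = ages),
            class = "glv_design")
}

# Ridge solve of (X'X + lambda * D) beta = X'y with an unpenalized intercept.
ridge_solve <- function(XtX, Xty, lambda) {
  D <- diag(c(0, rep(1, ncol(XtX) - 1)))
  solve(XtX + lambda * D, Xty)
}

# Per-taxon k-fold CV error over a lambda grid; folds are contiguous blocks
# of equations so serial dependence stays within folds.
ridge_cv <- function(X, y, lambda_grid, k_folds) {
  n <- nrow(X)
  if (n < k_folds) stop_("fewer equations (", n, ") than folds; use smaller k")
  fold <- cut(seq_len(n), breaks = k_folds, labels = FALSE)
  err <- matrix(NA_real_, k_folds, length(lambda_grid))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    XtX <- crossprod(X[tr, , drop = FALSE])
    Xty <- crossprod(X[tr, , drop = FALSE], y[tr])
    for (l in seq_along(lambda_grid)) {
      beta <- tryCatch(ridge_solve(XtX, Xty, lambda_grid[l]),
                       error = function(e) NULL)
      err[f, l] <- if (is.null(beta)) Inf else
        mean((y[!tr] - X[!tr, , drop = FALSE] %*% beta)^2)
    }
  }
  colMeans(err)
}

#' Fit a generalized Lotka-Volterra model by Tikhonov-regularized regression
#'
#' The central estimator of the package. The community dynamics
#' \deqn{dN_i/dt = N_i (r_i - \sum_j a_{ij} N_j)}
#' are linearized by forward differences of log relative abundances (see
#' [glv_design()]) and each taxon's growth rate \eqn{r_i} and interaction row
#' \eqn{a_{i\cdot}} are estimated by ridge (Tikhonov) regression with the
#' intercept unpenalized. The penalty weight is chosen per taxon (or globally
#' with `global_lambda = TRUE`) to minimize the mean k-fold out-of-fold
#' squared prediction error, with contiguous folds respecting the serial
#' structure of the equations.
#'
#' @param x samples x taxa relative-abundance matrix (a `community_matrix`
#'   or plain matrix), rows in time order.
#' @param ages sample ages in years; defaults to the ages carried by `x`.
#' @param lambda_grid candidate ridge penalties (default
#'   [default_lambda_grid()]).
#' @param k_folds number of CV folds (default 5).
#' @param lambda fixed penalty; skips cross-validation when given (0 gives
#'   ordinary least squares on a well-posed system).
#' @param pseudocount,episodes passed to [glv_design()].
#' @param global_lambda if TRUE a single penalty, minimizing the mean CV
#'   error across taxa, is used for all taxa.
#' @return object of class `glv`: list with `taxa`, `S`, `r` (growth rates,
#'   per year), `A` (S x S interaction matrix; `A[i, j]` is the inhibition of
#'   taxon i by taxon j), `lambda` (per taxon), `cv_error` (per taxon; NA when
#'   `lambda` was fixed), `design`, `fitted`, `residuals`, `dropped`.
#' @seealso [steady_state()], [stability()], [classify_interactions()],
#'   [stage_analysis()]
#' @export
glv <- function(x, ages = NULL, lambda_grid = default_lambda_grid(),
                k_folds = 5, lambda = NULL, pseudocount = NULL,
                global_lambda = FALSE, episodes = NULL) {
  if (inherits(x, "glv_design")) {
    des <- x
  } else {
    ages <- ages %||% attr(x, "ages")
    if (is.null(ages)) stop_("ages required (none attached to x)")
    des <- glv_design(x, ages, pseudocount, episodes = episodes)
  }
  X <- des$X; Y <- des$Y
  S <- length(des$taxa)
  if (length(lambda_grid) == 0 && is.null(lambda)) stop_("empty lambda grid")
  chosen <- numeric(S); cverr <- rep(NA_real_, S)
  if (is.null(lambda)) {
    cvmat <- vapply(seq_len(S), function(i)
      ridge_cv(X, Y[, i], lambda_grid, k_folds), numeric(length(lambda_grid)))
    if (global_lambda) {
      l <- which.min(rowMeans(cvmat))
      chosen[] <- lambda_grid[l]
      cverr <- cvmat[l, ]
    } else {
      for (i in seq_len(S)) {
        l <- which.min(cvmat[, i])
        chosen[i] <- lambda_grid[l]
        cverr[i] <- cvmat[l, i]
      }
    }
  } else chosen[] <- lambda
  XtX <- crossprod(X); XtY <- crossprod(X, Y)
  beta <- vapply(seq_len(S), function(i) {
    if (chosen[i] == 0) as.numeric(qr.solve(X, Y[, i]))
    else as.numeric(ridge_solve(XtX, XtY[, i], chosen[i]))
  }, numeric(S + 1))
  r <- beta[1, ]
  A <- t(beta[-1, , drop = FALSE])  # row i = interactions onto taxon i
  dimnames(A) <- list(des$taxa, des$taxa)
  names(r) <- des$taxa
  fitted <- X %*% t(cbind(r, A))
  colnames(fitted) <- des$taxa
  structure(list(taxa = des$taxa, S = S, r = r, A = A,
                 lambda = stats::setNames(chosen, des$taxa),
                 cv_error = stats::setNames(cverr, des$taxa),
                 design = des, fitted = fitted, residuals = Y - fitted,
                 dropped = des$dropped, k_folds = k_folds),
            class = "glv")
}

#' @export
print.glv <- function(x, digits = 3, ...) {
  cat(sprintf("Generalized Lotka-Volterra fit: S = %d taxa, %d equations per taxon\n",
              x$S, nrow(x$design$X)))
  cat("  growth rates r (per year):\n")
  print(round(x$r, digits))
  cat(sprintf("  ridge penalty lambda: %s\n",
              paste(format(signif(range(x$lambda), 3)), collapse = " .. ")))
  if (!all(is.na(x$cv_error)))
    cat(sprintf("  mean CV error: %.4g\n", mean(x$cv_error)))
  if (length(x$dropped) > 0)
    cat("  dropped (all-zero) taxa: ", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.glv <- function(object, ...) cbind(r = object$r, object$A)

#' @export
fitted.glv <- function(object, ...) object$fitted

#' @export
residuals.glv <- function(object, ...) object$residuals

#' @export
predict.glv <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  N <- as.matrix(unclass(newdata))[, object$taxa, drop = FALSE]
  out <- matrix(object$r, nrow(N), object$S, byrow = TRUE) - N %*% t(object$A)
  dimnames(out) <- list(rownames(N), object$taxa)
  out
}

#' @export
summary.glv <- function(object, ...) {
  st <- tryCatch(stability(object), error = function(e) e)
  ia <- classify_interactions(object)
  structure(list(fit = object, stability = st, interactions = ia),
            class = "summary.glv")
}

#' @export
print.summary.glv <- function(x, ...) {
  print(x$fit)
  if (inherits(x$stability, "error")) {
    cat("  stability: not assessable (", conditionMessage(x$stability), ")\n")
  } else print(x$stability)
  print(x$interactions)
  invisible(x)
}

#' @export
plot.glv <- function(x, ...) {
  st <- tryCatch(stability(x), error = function(e) NULL)
  if (is.null(st)) stop_("equilibrium not solvable; nothing to plot")
  ev <- st$eigenvalues
  graphics::plot(Re(ev), Im(ev), xlab = "Re(eigenvalue)", ylab = "Im(eigenvalue)",
                 main = "Jacobian spectrum at equilibrium", pch = 19, ...)
  graphics::abline(v = 0, lty = 2)
  graphics::points(st$centroid_re, 0, pch = 4, cex = 1.5, col = 2)
  invisible(st)
}

#' @export
simulate.glv <- function(object, nsim = 1, seed = NULL, N0 = NULL,
                         times = NULL, noise_sd = 0, ...) {
  N0 <- N0 %||% tryCatch(steady_state(object)$equilibrium,
                         error = function(e) stop_("supply N0: ", conditionMessage(e)))
  times <- times %||% seq(0, 100, by = 1)
  sims <- with_seed_(seed, lapply(seq_len(nsim), function(i)
    simulate_glv(object$r, object$A, N0, times, noise_sd = noise_sd)))
  if (nsim == 1) sims[[1]] else sims
}

#' Right-hand side of the gLV system
#'
#' \eqn{f_i(N) = N_i (r_i - \sum_j a_{ij} N_j)}.
#'
#' @param fit a `glv` object, or a list with elements `r` and `A`.
#' @param N abundance vector of length S.
#' @return vector of growth rates dN/dt.
#' @export
glv_rhs <- function(fit, N) {
  r <- fit$r; A <- fit$A
  if (length(N) != length(r)) stop_("N must have one entry per taxon")
  as.numeric(N * (r - A %*% N))
}

#' Interior steady state of a fitted gLV system
#'
#' Solves \eqn{A N^* = r} for the coexistence equilibrium where all
#' per-capita growth rates vanish. Fails when A is ill-conditioned beyond
#' `cond_max`, reporting the condition number. The equilibrium is feasible
#' when every component is positive; analysis downstream proceeds either way
#' but the flag is always reported.
#'
#' @param fit a `glv` object (or list with `r`, `A`).
#' @param cond_max condition-number threshold (default 1e8) for
#'   `method = "solve"`.
#' @param method `"solve"` (default) requires an invertible A and errors,
#'   reporting the condition number, when it is ill-conditioned beyond
#'   `cond_max`. `"pinv"` returns the minimum-norm least-squares equilibrium
#'   via a truncated singular-value pseudoinverse; this is the appropriate
#'   choice for stage-wise fits, where a window of w samples yields only
#'   w - 1 equations per taxon and the estimated A of a richer community is
#'   structurally rank-deficient.
#' @param tol relative singular-value truncation for `method = "pinv"`:
#'   directions of A whose singular value falls below `tol` times the
#'   dominant one are treated as unresolved by the regression and excluded
#'   from the equilibrium rather than amplified into it (default 0.01).
#' @return list with `equilibrium`, `feasible`, `condition_number`,
#'   `residual_norm` (`||A N* - r||`, 0 for an exact solve).
#' @export
steady_state <- function(fit, cond_max = 1e8, method = c("solve", "pinv"),
                         tol = 1e-2) {
  method <- match.arg(method)
  A <- fit$A
  cn <- kappa(A, exact = TRUE)
  if (method == "solve") {
    if (!is.finite(cn) || cn > cond_max)
      stop_(sprintf("interaction matrix too ill-conditioned to solve (condition number %.3g)", cn))
    Nstar <- as.numeric(solve(A, fit$r))
  } else {
    sv <- svd(A)
    pos <- sv$d >= tol * max(sv$d)
    Nstar <- as.numeric(sv$v[, pos, drop = FALSE] %*%
                          ((crossprod(sv$u[, pos, drop = FALSE], fit$r)) / sv$d[pos]))
  }
  names(Nstar) <- rownames(A)
  list(equilibrium = Nstar, feasible = all(Nstar > 0), condition_number = cn,
       residual_norm = sqrt(sum((A %*% Nstar - fit$r)^2)))
}

#' Jacobian of the gLV system at a state
#'
#' \eqn{J_{ik} = \delta_{ik} (r_i - \sum_j a_{ij} N_j) - N_i a_{ik}}. At an
#' interior equilibrium the first term vanishes and the Jacobian reduces to
#' \eqn{-\mathrm{diag}(N^*) A}.
#'
#' @param fit a `glv` object (or list with `r`, `A`).
#' @param N state vector.
#' @return S x S Jacobian matrix.
#' @export
glv_jacobian <- function(fit, N) {
  r <- fit$r; A <- fit$A
  diag(as.numeric(r - A %*% N), length(r)) - diag(N, length(N)) %*% A
}

#' Eigenvalue spectrum and stability verdict of a Jacobian
#'
#' Local stability analysis: the state is asymptotically stable when all
#' eigenvalue real parts are negative. The mean of the real parts (the
#' "centroid" of the bulk eigenvalues) is reported as the mean stability
#' level: more negative means faster return to equilibrium.
#'
#' @param J square Jacobian matrix.
#' @return list with `eigenvalues` (complex), `centroid_re`, `max_re`,
#'   `stable`.
#' @export
stability_spectrum <- function(J) {
  if (any(!is.finite(J))) stop_("non-finite entries in Jacobian")
  ev <- eigen(J, only.values = TRUE)$values
  list(eigenvalues = ev, centroid_re = mean(Re(ev)),
       max_re = max(Re(ev)), stable = max(Re(ev)) < 0)
}

#' Full local stability analysis of a fitted gLV system
#'
#' Combines [steady_state()], [glv_jacobian()] and [stability_spectrum()]:
#' equilibrium, feasibility, Jacobian, eigenvalues, eigenvalue centroid and
#' the stability verdict.
#'
#' @param fit a `glv` object.
#' @param N optional state at which to linearize; defaults to the interior
#'   equilibrium.
#' @param cond_max,method passed to [steady_state()].
#' @return object of class `glv_stability`.
#' @export
stability <- function(fit, N = NULL, cond_max = 1e8,
                      method = c("solve", "pinv"), tol = 1e-2) {
  if (is.null(N)) {
    ss <- steady_state(fit, cond_max, method = method, tol = tol)
    N <- ss$equilibrium
    feasible <- ss$feasible
    cn <- ss$condition_number
  } else {
    feasible <- all(N > 0)
    cn <- NA_real_
  }
  J <- glv_jacobian(fit, N)
  sp <- stability_spectrum(J)
  structure(list(equilibrium = N, feasible = feasible, J = J,
                 eigenvalues = sp$eigenvalues, centroid_re = sp$centroid_re,
                 max_re = sp$max_re, stable = sp$stable,
                 condition_number = cn),
            class = "glv_stability")
}

#' @export
print.glv_stability <- function(x, ...) {
  cat(sprintf("local stability: %s (max Re = %.4g, centroid Re = %.4g)\n",
              if (x$stable) "stable" else "unstable", x$max_re, x$centroid_re))
  cat(sprintf("  equilibrium %s\n",
              if (x$feasible) "feasible (all components > 0)" else "not feasible"))
  invisible(x)
}

#' Classify pairwise interactions of a fitted gLV system
#'
#' Interaction typing on growth effects \eqn{e_{ij} = -a_{ij}} (the effect of
#' taxon j on taxon i's growth, positive = activation): a pair is mutualism
#' when both effects are positive (+/+), antagonism when both are negative
#' (-/-), and exploitation when the signs differ (+/-). Note the sign flip:
#' the model's \eqn{a_{ij}} measures inhibition, so classifying on raw
#' coefficients would invert the ecological reading; raw coefficients remain
#' available via `on = "coefficients"`. Pairs with an exactly zero effect are
#' flagged null and excluded from the proportions. The per-type strength is
#' the mean absolute effect over that type's entries.
#'
#' @param fit a `glv` object (or list with `A`).
#' @param on classify on `"effects"` (default, e = -a) or raw
#'   `"coefficients"`.
#' @return object of class `glv_interactions`: data frame `pairs`
#'   (`taxon_i`, `taxon_j`, `e_ij`, `e_ji`, `type`), `proportions`,
#'   `strength` (mean |e| per type), `n_null`.
#' @export
classify_interactions <- function(fit, on = c("effects", "coefficients")) {
  on <- match.arg(on)
  A <- fit$A
  S <- nrow(A)
  if (S < 2) stop_("need at least 2 taxa")
  E <- if (on == "effects") -A else A
  taxa <- rownames(A) %||% as.character(seq_len(S))
  idx <- which(upper.tri(A), arr.ind = TRUE)
  e_ij <- E[idx]                       # effect of j on i  (row i, col j)
  e_ji <- E[idx[, c(2, 1), drop = FALSE]]
  type <- ifelse(e_ij == 0 | e_ji == 0, "null",
          ifelse(e_ij > 0 & e_ji > 0, "mutualism",
          ifelse(e_ij < 0 & e_ji < 0, "antagonism", "exploitation")))
  pairs <- data.frame(taxon_i = taxa[idx[, 1]], taxon_j = taxa[idx[, 2]],
                      e_ij = e_ij, e_ji = e_ji, type = type)
  classified <- pairs$type != "null"
  lev <- c("mutualism", "antagonism", "exploitation")
  counts <- table(factor(pairs$type[classified], levels = lev))
  props <- if (sum(classified) > 0) as.numeric(counts) / sum(classified) else rep(NA_real_, 3)
  strength <- vapply(lev, function(tp) {
    sel <- pairs$type == tp
    if (!any(sel)) return(NA_real_)
    mean(abs(c(pairs$e_ij[sel], pairs$e_ji[sel])))
  }, 0)
  structure(list(pairs = pairs,
                 proportions = stats::setNames(props, lev),
                 strength = strength,
                 n_null = sum(!classified), on = on),
            class = "glv_interactions")
}

#' @export
print.glv_interactions <- function(x, ...) {
  cat(sprintf("pairwise interactions (%d pairs, on %s):\n",
              nrow(x$pairs), x$on))
  for (tp in names(x$proportions))
    cat(sprintf("  %-13s %5.1f%%  mean |effect| = %.4g\n", tp,
                100 * x$proportions[tp], x$strength[tp]))
  if (x$n_null > 0) cat(sprintf("  (%d null pair(s) excluded)\n", x$n_null))
  invisible(x)
}
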