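#' Structural-change breakpoints by exact RSS minimization
#'
#' Segments a series into piecewise-constant-mean regimes by exact dynamic
#' programming: for each candidate number of breaks m <= `max_m` the
#' segmentation minimizing the total residual sum of squares is found, and m
#' is then chosen by BIC. Used on alpha-diversity series to locate the tipping
#' point; when ages are supplied each break is reported as the age interval
#' between the two samples it separates.
#'
#' @param series numeric vector in stratigraphic (time) order.
#' @param max_m maximum number of breakpoints considered (default 3).
#' @param min_seg minimum samples per segment; default
#'   `max(3, ceiling(0.15 * n))`, the conventional 15% trimming.
#' @param ages optional ages (years CE), one per observation.
#' @return list of class `breakpoints`: `m` (chosen number of breaks),
#'   `breaks` (indices of the last sample of each segment but the final one),
#'   `break_ages` (2-column matrix of bracketing ages, when ages given),
#'   `rss` (RSS per candidate m, names "0".."max_m"), `bic`, `segments`
#'   (per-segment start/end/mean for the chosen m).
#' @export
detect_breakpoints <- function(series, max_m = 3, min_seg = NULL, ages = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  min_seg <- as.integer(min_seg %||% max(3, ceiling(0.15 * n)))
  if (n < 2 * min_seg) stop_("series too short for min_seg = ", min_seg)
  max_feasible <- n %/% min_seg - 1L
  if (max_m > max_feasible)
    stop_("max_m = ", max_m, " infeasible with min_seg = ", min_seg,
          " and n = ", n, " (max ", max_feasible, ")")
  if (!is.null(ages) && length(ages) != n) stop_("one age per observation required")

  # segment cost: RSS of the mean over x[i..j], via cumulative sums
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  seg_rss <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    max(cs2[j + 1] - cs2[i] - s^2 / (j - i + 1), 0)
  }
  # dp[m+1, j] = minimal RSS of x[1..j] split into m+1 segments
  dp <- matrix(Inf, max_m + 1, n)
  bt <- matrix(NA_integer_, max_m + 1, n)
  for (j in min_seg:n) dp[1, j] <- seg_rss(1, j)
  if (max_m >= 1) {
    for (m in 1:max_m) {
      for (j in seq((m + 1) * min_seg, n)) {
        ks <- seq(m * min_seg, j - min_seg)  # last index of previous part
        tot <- dp[m, ks] + vapply(ks, function(k) seg_rss(k + 1, j), 0)
        i <- which.min(tot)
        dp[m + 1, j] <- tot[i]
        bt[m + 1, j] <- ks[i]
      }
    }
  }
  rss <- dp[, n]
  names(rss) <- as.character(0:max_m)
  # BIC over m: n log(RSS/n) + k log n with k = (m+1) means + m breaks + sigma^2
  floor_rss <- pmax(rss, 1e-12 * (sum(x^2) + 1))
  bic <- n * log(floor_rss / n) + (2 * (0:max_m) + 2) * log(n)
  m_hat <- unname(which.min(bic)) - 1L
  breaks <- integer(0)
  j <- n
  if (m_hat > 0) for (m in m_hat:1) {
    k <- bt[m + 1, j]
    breaks <- c(k, breaks)
    j <- k
  }
  bounds <- c(0L, breaks, n)
  segments <- data.frame(start = bounds[-length(bounds)] + 1L, end = bounds[-1])
  segments$mean <- vapply(seq_len(nrow(segments)), function(i)
    mean(x[segments$start[i]:segments$end[i]]), 0)
  break_ages <- if (!is.null(ages) && m_hat > 0)
    cbind(before = ages[breaks], after = ages[breaks + 1]) else NULL
  structure(list(m = m_hat, breaks = breaks, break_ages = break_ages,
                 rss = rss, bic = bic, segments = segments,
                 min_seg = min_seg, n = n),
            class = "breakpoints")
}

#' @export
print.breakpoints <- function(x, ...) {
  cat(sprintf("breakpoint analysis: n = %d, chosen m = %d (BIC)\n", x$n, x$m))
  if (x$m > 0) {
    cat("  breaks after sample(s): ", paste(x$breaks, collapse = ", "), "\n")
    if (!is.null(x$break_ages))
      for (i in seq_len(nrow(x$break_ages)))
        cat(sprintf("  break %d between ages %.0f and %.0f\n",
                    i, x$break_ages[i, 1], x$break_ages[i, 2]))
  }
  invisible(x)
}

#' Sliding-window early-warning signals
#'
#' Computes, over a right-aligned sliding window, the sample variance
#' (denominator n - 1) and the lag-1 autocorrelation (Pearson correlation of
#' the window with itself shifted by one) of a community state series, the two
#' classical indicators of critical slowing down. Each window's value is
#' assigned to the window's last sample, so rising signals lead up to the
#' transition. Trends are summarized by Kendall's tau of each indicator
#' against time over a declared pre-transition range.
#'
#' @param state numeric state series (e.g. NMDS1 scores), time order.
#' @param window window length in samples (default 5, minimum 3).
#' @param ages optional ages per observation; defaults to the sample index.
#' @param pre_end index of the last observation of the pre-transition segment
#'   over which trends are assessed; default the whole series.
#' @return list of class `ews_series`: data frame `ews` with columns
#'   `window_end`, `age`, `variance`, `lag1_ac`, `degenerate`; `window`;
#'   `tau_var`, `tau_ac` (Kendall tau with normal-approximation p-values over
#'   windows ending in the pre-transition range).
#' @export
sliding_ews <- function(state, window = 5, ages = NULL, pre_end = NULL) {
  x <- as.numeric(state)
  n <- length(x)
  if (window < 3) stop_("window must be at least 3")
  if (n < window + 1) stop_("need at least window + 1 observations")
  ages <- ages %||% seq_len(n)
  ends <- window:n
  v <- ac <- numeric(length(ends))
  degen <- logical(length(ends))
  for (i in seq_along(ends)) {
    w <- x[(ends[i] - window + 1):ends[i]]
    v[i] <- stats::var(w)
    if (v[i] == 0 || stats::sd(w[-1]) == 0 || stats::sd(w[-window]) == 0) {
      ac[i] <- 0; degen[i] <- TRUE
    } else {
      ac[i] <- stats::cor(w[-window], w[-1])
    }
  }
  ews <- data.frame(window_end = ends, age = ages[ends],
                    variance = v, lag1_ac = ac, degenerate = degen)
  pre_end <- pre_end %||% n
  pre <- ews$window_end <= pre_end
  tau_of <- function(y) {
    if (sum(pre) < 3 || stats::sd(y[pre]) == 0)
      return(list(tau = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(ews$age[pre], y[pre], method = "kendall"))
    list(tau = unname(ct$estimate), p = ct$p.value)
  }
  structure(list(ews = ews, window = window,
                 tau_var = tau_of(ews$variance), tau_ac = tau_of(ews$lag1_ac),
                 pre_end = pre_end),
            class = "ews_series")
}

#' @export
print.ews_series <- function(x, ...) {
  cat(sprintf("early-warning signals: window = %d, %d windows\n",
              x$window, nrow(x$ews)))
  cat(sprintf("  pre-transition trend (windows ending <= %d):\n", x$pre_end))
  cat(sprintf("    variance: tau = %.3f (p = %.3g)\n", x$tau_var$tau, x$tau_var$p))
  cat(sprintf("    lag-1 AC: tau = %.3f (p = %.3g)\n", x$tau_ac$tau, x$tau_ac$p))
  invisible(x)
}

#' Fit an ARIMA model to a community state series
#'
#' Thin wrapper around `stats::arima` with the (1, 1, 0) default used for
#' state forecasting: first-difference the series, fit an AR(1). A warning
#' flag is raised (without failing) when the AR polynomial is estimated at or
#' outside the unit circle.
#'
#' @param series numeric state series (state1 segment).
#' @param order `(p, d, q)` ARIMA order, default `c(1, 1, 0)`.
#' @param include_drift include a linear drift term when `d >= 1` (default
#'   TRUE, via a time-trend regressor), so a differenced series with a
#'   non-zero mean is forecast along its trend rather than held flat.
#' @param search if TRUE, select `p, q <= 2`, `d <= 1` by AIC instead.
#' @return list of class `state_arima`: the fitted `stats::arima` object
#'   (`fit`), `order`, `coefficients`, `sigma2`, `n`, `drift`,
#'   `nonstationary` flag.
#' @export
fit_state_arima <- function(series, order = c(1, 1, 0), include_drift = TRUE,
                            search = FALSE) {
  x <- as.numeric(series)
  # a series whose d-th difference is exactly constant (e.g. a noiseless
  # ramp) is deterministic: arima's information matrix is singular, so the
  # polynomial continuation is returned directly with zero innovation
  # variance
  d0 <- order[2]
  dx <- if (d0 > 0) diff(x, differences = d0) else x
  if (stats::sd(dx) == 0 && d0 > 0) {
    tt <- seq_along(x)
    poly_fit <- stats::lm(x ~ stats::poly(tt, degree = d0, raw = TRUE))
    return(structure(list(fit = poly_fit, order = unname(order),
                          coefficients = stats::coef(poly_fit), sigma2 = 0,
                          n = length(x), drift = FALSE, degenerate = TRUE,
                          nonstationary = FALSE),
                     class = "state_arima"))
  }
  fit1 <- function(ord) {
    args <- list(x, order = ord)
    if (include_drift && ord[2] >= 1)
      args$xreg <- matrix(seq_along(x), ncol = 1,
                          dimnames = list(NULL, "drift"))
    # do.call so the xreg value is embedded in the call (predict needs it);
    # CSS-ML can fail on short, nearly-flat segments - fall back to full ML
    tryCatch(do.call(stats::arima, args),
             error = function(e) do.call(stats::arima, c(args, method = "ML")))
  }
  if (search) {
    grid <- expand.grid(p = 0:2, d = 0:1, q = 0:2)
    fits <- lapply(seq_len(nrow(grid)), function(i)
      tryCatch(fit1(unlist(grid[i, ])), error = function(e) NULL))
    ok <- !vapply(fits, is.null, TRUE)
    best <- which.min(vapply(fits[ok], stats::AIC, 0))
    fit <- fits[ok][[best]]
    order <- unlist(grid[ok, ][best, ])
  } else {
    if (length(x) < order[1] + order[2] + 2) stop_("series too short for this order")
    fit <- fit1(order)
  }
  ar <- fit$coef[grepl("^ar", names(fit$coef))]
  nonstat <- length(ar) > 0 && any(Mod(polyroot(c(1, -ar))) <= 1 + 1e-8)
  if (nonstat) warning("AR estimate at or outside the stationarity boundary", call. = FALSE)
  structure(list(fit = fit, order = unname(order), coefficients = fit$coef,
                 sigma2 = fit$sigma2, n = length(x),
                 drift = "drift" %in% names(fit$coef), degenerate = FALSE,
                 nonstationary = nonstat),
            class = "state_arima")
}

#' @export
print.state_arima <- function(x, ...) {
  cat(sprintf("ARIMA(%d,%d,%d) state model\n", x$order[1], x$order[2], x$order[3]))
  print(round(x$coefficients, 4))
  cat(sprintf("  innovation variance %.4g%s\n", x$sigma2,
              if (x$nonstationary) " [non-stationary AR estimate]" else ""))
  invisible(x)
}

#' Forecast deviation of a new state segment from a fitted ARIMA model
#'
#' Projects the fitted model `horizon` steps ahead with normal-theory
#' prediction intervals (widening with horizon) and measures the fraction of
#' observed values falling outside the interval. Under the fitted process
#' about 5% of observations fall outside a 95% band, so a fraction well above
#' that indicates the new segment no longer follows the old regime's
#' dynamics - the forecast-deviation signature of a regime shift.
#'
#' @param model a `state_arima` fit (trained on the state1 segment).
#' @param observed observed values of the following segment (state2); the
#'   forecast horizon equals its length.
#' @param level prediction-interval coverage (default 0.95).
#' @return list of class `forecast_deviation`: data frame `forecast`
#'   (`step`, `predicted`, `lo`, `hi`, `observed`, `outside`),
#'   `outside_fraction`, `deviates` (fraction > 1 - level).
#' @export
forecast_deviation <- function(model, observed, level = 0.95) {
  stopifnot(inherits(model, "state_arima"))
  h <- length(observed)
  if (h <= 0) stop_("need at least one observed value")
  pr <- if (isTRUE(model$degenerate)) {
    tt <- model$n + seq_len(h)
    list(pred = unname(stats::predict(model$fit, newdata = data.frame(tt = tt))),
         se = rep(0, h))
  } else if (model$drift) {
    stats::predict(model$fit, n.ahead = h,
                   newxreg = matrix(model$n + seq_len(h), ncol = 1,
                                    dimnames = list(NULL, "drift")))
  } else stats::predict(model$fit, n.ahead = h)
  z <- stats::qnorm((1 + level) / 2)
  lo <- pr$pred - z * pr$se
  hi <- pr$pred + z * pr$se
  outside <- observed < lo | observed > hi
  fc <- data.frame(step = seq_len(h), predicted = as.numeric(pr$pred),
                   lo = as.numeric(lo), hi = as.numeric(hi),
                   observed = as.numeric(observed), outside = outside)
  frac <- mean(outside)
  structure(list(forecast = fc, outside_fraction = frac, level = level,
                 deviates = frac > (1 - level)),
            class = "forecast_deviation")
}

#' @export
print.forecast_deviation <- function(x, ...) {
  cat(sprintf("forecast deviation: %.1f%% of %d observations outside the %d%% band -> %s\n",
              100 * x$outside_fraction, nrow(x$forecast), round(100 * x$level),
              if (x$deviates) "deviates from the old regime" else "consistent with the old regime"))
  invisible(x)
}
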