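test_that("stage windows follow the overlap rule", {
  w35 <- stage_windows(35, 10, 5)
  expect_equal(nrow(w35), 7)
  expect_equal(w35$start, seq(1, 31, by = 5))
  expect_equal(w35$end[7], 35)
  expect_equal(w35$length[7], 5)       # truncated trailing window
  w10 <- stage_windows(10, 10, 5)
  expect_equal(nrow(w10), 2)
  expect_equal(w10$start, c(1, 6))
  expect_equal(w10$end, c(10, 10))
  expect_gte(nrow(stage_windows(10)), 1)  # n = w boundary
  expect_true(all(stage_windows(40)$length >= 5))
  expect_error(stage_windows(35, 5, 5), "exceed")
  expect_error(stage_windows(5, 10, 5), "at least w")
})

test_that("the forward-difference design encodes the linearized dynamics", {
  # constant composition -> all responses zero
  m <- matrix(rep(c(0.6, 0.4), each = 5), 5,
              dimnames = list(paste0("s", 1:5), c("a", "b")))
  des <- glv_design(m, ages = 1:5)
  expect_true(all(des$Y == 0))
  expect_equal(unname(des$X[, 1]), rep(1, 4))
  expect_equal(unname(des$X[, -1]), -m[-5, ], ignore_attr = TRUE)
  # doubling all time gaps halves all responses
  withr::with_seed(71, {
    x <- matrix(rgamma(12 * 3, 2), 12); x <- x / rowSums(x)
    dimnames(x) <- list(paste0("s", 1:12), paste0("t", 1:3))
  })
  d1 <- glv_design(x, ages = 1:12)
  d2 <- glv_design(x, ages = seq(2, 24, by = 2))
  expect_equal(d2$Y, d1$Y / 2)
  expect_error(glv_design(x, ages = rep(1, 12)), "strictly increasing")
})

test_that("a densely sampled logistic trajectory is recovered to 1%", {
  r <- 0.8; a <- 2
  tg <- seq(0, 12, by = 0.005)
  traj <- simulate_glv(r = c(main = r), A = matrix(a, 1, 1,
                       dimnames = list("main", "main")),
                       N0 = 0.01, t_grid = tg)
  # a second near-passive taxon so S >= 2 (slight variation keeps the
  # design full rank); its tiny abundance barely perturbs the main taxon
  x <- cbind(main = traj[, 1],
             other = 1e-3 * seq(1, 1.2, length.out = nrow(traj)))
  fit <- glv(x, ages = tg, lambda = 0)
  expect_equal(unname(fit$r["main"]), r, tolerance = 0.01)
  expect_equal(unname(fit$A["main", "main"]), a, tolerance = 0.01)
})

test_that("ridge limits behave as ordinary least squares and total shrinkage", {
  withr::with_seed(72, {
    # abundance-index data (not closed to 1, so the design is full rank)
    x <- matrix(rgamma(30 * 3, 5), 30)
    dimnames(x) <- list(paste0("s", 1:30), paste0("t", 1:3))
  })
  des <- glv_design(x, ages = 1:30)
  # lambda = 0 equals the direct linear solve
  f0 <- glv(des, lambda = 0)
  beta_ols <- qr.solve(des$X, des$Y[, 1])
  expect_equal(unname(c(f0$r[1], f0$A[1, ])), unname(beta_ols), tolerance = 1e-8)
  # lambda -> huge shrinks interactions but keeps the intercept
  fL <- glv(des, lambda = 1e6)
  expect_lt(max(abs(fL$A)), 1e-3)
  expect_lt(max(abs(fL$r - colMeans(des$Y))), 1e-2)
  # CV: chosen lambda attains the grid minimum and cv errors are finite
  fcv <- glv(des, k_folds = 5)
  expect_true(all(is.finite(fcv$cv_error)))
  expect_true(all(fcv$lambda %in% default_lambda_grid()))
  expect_error(glv(des, k_folds = 40), "folds")
})

test_that("ridge fit recovers known parameters from a perturbation experiment", {
  ex <- recovery_experiment(seed = 101)
  fit <- glv(ex$observed, ages = ex$ages, episodes = ex$episodes)
  A <- ex$truth$A
  offm <- row(A) != col(A)
  expect_gt(cor(as.vector(fit$A), as.vector(A)), 0.85)
  expect_gte(mean(sign(fit$A[offm]) == sign(A[offm])), 5 / 6)
})

test_that("the gLV right-hand side matches term-by-term evaluation", {
  withr::with_seed(73, {
    S <- 4
    r <- runif(S); A <- matrix(rnorm(S * S), S); N <- runif(S)
  })
  fit <- list(r = r, A = A)
  expect_equal(glv_rhs(fit, rep(0, S)), rep(0, S))       # extinction equilibrium
  expect_equal(glv_rhs(list(r = 2, A = matrix(4, 1, 1)), 0.5), 0)  # N = r/a
  hand <- vapply(1:S, function(i) N[i] * (r[i] - sum(A[i, ] * N)), 0)
  expect_equal(glv_rhs(fit, N), hand, tolerance = 1e-12)
})

test_that("steady states solve A N* = r with conditioning guards", {
  expect_equal(steady_state(list(r = 2, A = matrix(4, 1, 1)))$equilibrium, 0.5,
               ignore_attr = TRUE)
  ss <- steady_state(list(r = c(1, 1), A = diag(c(1, 2))))
  expect_equal(unname(ss$equilibrium), c(1, 0.5))
  expect_true(ss$feasible)
  ssI <- steady_state(list(r = rep(1, 3), A = diag(3)))
  expect_equal(unname(ssI$equilibrium), rep(1, 3))
  sing <- list(r = c(1, 1), A = matrix(c(1, 1, 1, 1 + 1e-12), 2))
  expect_error(steady_state(sing), "condition number")
  # pinv agrees with solve on a well-posed system
  ok <- list(r = c(1, 2), A = matrix(c(2, 0.3, -0.4, 3), 2))
  expect_equal(steady_state(ok, method = "pinv")$equilibrium,
               steady_state(ok)$equilibrium, tolerance = 1e-10)
})

test_that("the Jacobian matches finite differences and the equilibrium identity", {
  withr::with_seed(74, {
    for (rep in 1:20) {
      S <- sample(2:6, 1)
      r <- runif(S, 0.5, 1.5)
      A <- matrix(rnorm(S * S, 0, 0.5), S); diag(A) <- runif(S, 1, 2)
      N <- runif(S, 0.1, 1)
      fit <- list(r = r, A = A)
      J <- glv_jacobian(fit, N)
      # central differences are exact for a quadratic rhs
      h <- 1e-5
      Jfd <- vapply(1:S, function(k) {
        e <- rep(0, S); e[k] <- h
        (glv_rhs(fit, N + e) - glv_rhs(fit, N - e)) / (2 * h)
      }, numeric(S))
      expect_equal(J, Jfd, tolerance = 1e-6, ignore_attr = TRUE)
      # at an interior equilibrium J = -diag(N*) A
      Nstar <- tryCatch(solve(A, r), error = function(e) NULL)
      if (!is.null(Nstar)) {
        J2 <- glv_jacobian(fit, Nstar)
        expect_equal(J2, -diag(Nstar, S) %*% A, tolerance = 1e-10,
                     ignore_attr = TRUE)
      }
    }
  })
  # S = 1 at N* = r/a: J = -r (logistic linearization)
  expect_equal(glv_jacobian(list(r = 0.7, A = matrix(2, 1, 1)), 0.35)[1, 1],
               -0.7, tolerance = 1e-12)
})

test_that("the spectral verdict agrees with closed forms and ODE behaviour", {
  sp <- stability_spectrum(diag(c(-1, -2)))
  expect_equal(sp$centroid_re, -1.5)
  expect_true(sp$stable)
  rot <- stability_spectrum(matrix(c(0, -1, 1, 0), 2))
  expect_equal(sort(Im(rot$eigenvalues)), c(-1, 1))
  expect_equal(rot$centroid_re, 0)
  expect_false(rot$stable)
  # random matrices away from the margin: verdict matches linear-ODE decay
  withr::with_seed(75, {
    done <- 0
    while (done < 15) {
      J <- matrix(rnorm(36, 0, 0.7), 6)
      mr <- max(Re(eigen(J, only.values = TRUE)$values))
      if (abs(mr) < 0.05) next
      done <- done + 1
      # integrate dx = Jx with renormalization, track log growth
      x <- rnorm(6); x <- x / sqrt(sum(x^2))
      lg <- 0
      h <- 0.02; Ttot <- 60 / abs(mr); steps <- ceiling(Ttot / h)
      for (i in seq_len(min(steps, 40000))) {
        k1 <- J %*% x; k2 <- J %*% (x + h / 2 * k1)
        k3 <- J %*% (x + h / 2 * k2); k4 <- J %*% (x + h * k3)
        x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        nr <- sqrt(sum(x^2)); lg <- lg + log(nr); x <- x / nr
      }
      expect_equal(stability_spectrum(J)$stable, lg < 0)
    }
  })
  expect_error(stability_spectrum(matrix(c(1, NA, 0, 1), 2)), "non-finite")
})

test_that("interaction typing follows the effect sign convention", {
  taxa <- c("x", "y")
  A <- matrix(c(1, -1, -1, 1), 2, dimnames = list(taxa, taxa))
  ia <- classify_interactions(list(A = A))
  # e = -a: both cross effects +1 -> mutualism
  expect_equal(ia$pairs$type, "mutualism")
  expect_equal(ia$pairs$e_ij, 1)
  A2 <- matrix(c(1, -1, 1, 1), 2, dimnames = list(taxa, taxa))
  ia2 <- classify_interactions(list(A = A2))
  expect_equal(ia2$pairs$type, "exploitation")
  # raw-coefficient mode inverts the reading
  expect_equal(classify_interactions(list(A = A), on = "coefficients")$pairs$type,
               "antagonism")
  # zero effects flagged null and excluded
  A3 <- matrix(c(1, 0, 0.5, 1), 2, dimnames = list(taxa, taxa))
  ia3 <- classify_interactions(list(A = A3))
  expect_equal(ia3$n_null, 1)
  expect_true(all(is.na(ia3$proportions)))
})

test_that("interaction typing matches brute-force pair enumeration", {
  withr::with_seed(76, {
    S <- 5
    A <- matrix(rnorm(S * S), S,
                dimnames = list(paste0("t", 1:S), paste0("t", 1:S)))
  })
  ia <- classify_interactions(list(A = A))
  expect_equal(nrow(ia$pairs), S * (S - 1) / 2)
  expect_equal(sum(ia$proportions), 1)
  # oracle: direct enumeration on effects
  E <- -A
  types <- character(0)
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    types <- c(types,
               if (E[i, j] > 0 && E[j, i] > 0) "mutualism"
               else if (E[i, j] < 0 && E[j, i] < 0) "antagonism"
               else "exploitation")
  }
  expect_equal(as.vector(table(factor(ia$pairs$type, levels = sort(unique(types))))),
               as.vector(table(factor(types, levels = sort(unique(types))))))
  # invariance under simultaneous row/column permutation
  perm <- c(3, 1, 5, 2, 4)
  iap <- classify_interactions(list(A = A[perm, perm]))
  expect_equal(sort(iap$pairs$type), sort(ia$pairs$type))
  expect_equal(iap$proportions, ia$proportions)
})

test_that("fitted gLV dynamics reproduce a noiseless window trajectory", {
  # self-consistency: fit a dense noiseless 2-taxon relaxation, re-simulate
  r <- c(a = 0.9, b = 0.6)
  A <- matrix(c(2, 0.4, 0.3, 1.5), 2, dimnames = list(c("a", "b"), c("a", "b")))
  Nstar <- solve(A, r)
  tg <- seq(0, 15, by = 0.05)
  traj <- simulate_glv(r, A, Nstar * c(1.6, 0.5), tg)
  fit <- glv(traj, ages = tg, lambda = 0)
  resim <- simulate_glv(fit$r, fit$A, traj[1, ], tg)
  expect_equal(resim, traj, tolerance = 5e-3, ignore_attr = TRUE)
})

test_that("glv methods expose coefficients, predictions and residuals", {
  ex <- recovery_experiment(seed = 5, n_episodes = 3)
  fit <- glv(ex$observed, ages = ex$ages, episodes = ex$episodes)
  co <- coef(fit)
  expect_equal(dim(co), c(3, 4))
  expect_equal(co[, "r"], fit$r)
  expect_equal(dim(fitted(fit)), dim(residuals(fit)))
  expect_equal(fitted(fit) + residuals(fit), fit$design$Y, ignore_attr = TRUE)
  pr <- predict(fit, newdata = ex$observed[1:4, ])
  expect_equal(dim(pr), c(4, 3))
  expect_equal(unname(pr[1, 1]),
               unname(fit$r[1] - sum(fit$A[1, ] * ex$observed[1, ])),
               tolerance = 1e-12)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.glv")
  sim <- simulate(fit, N0 = rep(0.3, 3), times = seq(0, 5, 0.5))
  expect_equal(nrow(sim), 11)
})

test_that("stage analysis runs all stages and flags transition instability", {
  sc <- transition_scenario(seed = 14)
  sel <- select_modeled_taxa(to_relative(sc$table))
  st <- stage_analysis(sel)
  expect_equal(nrow(st$stages), 7)
  expect_true(all(is.finite(st$stages$centroid_re)))
  tt <- sc$truth$transition_time
  ages <- sample_ages(sc$table)
  contain <- which(ages[st$windows$start] <= tt & ages[st$windows$end] >= tt)
  expect_true(which.max(st$stages$centroid_re) %in% contain)
  # single-regime record shows no comparable instability signal
  sc0 <- transition_scenario(seed = 14, transition = FALSE)
  st0 <- stage_analysis(select_modeled_taxa(to_relative(sc0$table)))
  expect_equal(nrow(st0$stages), 7)
  expect_lt(max(st0$stages$centroid_re, na.rm = TRUE),
            max(st$stages$centroid_re))
})
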