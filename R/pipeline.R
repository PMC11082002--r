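#' Pipeline configuration
#'
#' Assembles and validates the settings of the full analysis. Unknown
#' settings are rejected; every numeric setting is checked against its
#' documented range.
#'
#' @param input path to the taxon count table (TSV or BIOM JSON).
#' @param chronology path to the chronology TSV.
#' @param out_dir output directory for all artifacts.
#' @param rank taxonomic rank to collapse to (default `"class"`).
#' @param min_mean_abund,max_taxa taxon-selection rule (defaults 0.01 and 12).
#' @param nmds_k,nmds_restarts NMDS settings (defaults 2 and 20).
#' @param ews_window sliding EWS window (default 5).
#' @param stage_w,stage_s stage window length and step (defaults 10 and 5;
#'   `stage_w` must exceed `stage_s`).
#' @param lambda_grid ridge penalty grid.
#' @param k_folds CV folds (default 5).
#' @param n_perm permutations for ANOSIM/PERMANOVA (default 999).
#' @param breakpoint_max_m maximum breakpoints considered (default 3).
#' @param arima_order ARIMA order for state forecasting (default `c(1,1,0)`).
#' @param seed master seed; per-module seeds are derived from it
#'   deterministically.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, chronology, out_dir, rank = "class",
                            min_mean_abund = 0.01, max_taxa = 12,
                            nmds_k = 2, nmds_restarts = 20, ews_window = 5,
                            stage_w = 10, stage_s = 5,
                            lambda_grid = default_lambda_grid(), k_folds = 5,
                            n_perm = 999, breakpoint_max_m = 3,
                            arima_order = c(1, 1, 0), seed = 1L) {
  cfg <- list(input = input, chronology = chronology, out_dir = out_dir,
              rank = rank, min_mean_abund = min_mean_abund,
              max_taxa = max_taxa, nmds_k = nmds_k,
              nmds_restarts = nmds_restarts, ews_window = ews_window,
              stage_w = stage_w, stage_s = stage_s,
              lambda_grid = lambda_grid, k_folds = k_folds, n_perm = n_perm,
              breakpoint_max_m = breakpoint_max_m, arima_order = arima_order,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c("input", "chronology", "out_dir", "rank", "min_mean_abund",
             "max_taxa", "nmds_k", "nmds_restarts", "ews_window", "stage_w",
             "stage_s", "lambda_grid", "k_folds", "n_perm",
             "breakpoint_max_m", "arima_order", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop_("unknown config setting(s): ", paste(unknown, collapse = ", "))
  chk <- function(cond, msg) if (!cond) stop_("config: ", msg)
  chk(cfg$min_mean_abund >= 0 && cfg$min_mean_abund < 1,
      "min_mean_abund must lie in [0, 1)")
  chk(cfg$max_taxa >= 2, "max_taxa must be >= 2")
  chk(cfg$nmds_k >= 1, "nmds_k must be >= 1")
  chk(cfg$nmds_restarts >= 1, "nmds_restarts must be >= 1")
  chk(cfg$ews_window >= 3, "ews_window must be >= 3")
  chk(cfg$stage_w > cfg$stage_s, "stage_w must exceed stage_s")
  chk(cfg$stage_s >= 1, "stage_s must be >= 1")
  chk(all(cfg$lambda_grid >= 0) && length(cfg$lambda_grid) > 0,
      "lambda_grid must be non-empty and non-negative")
  chk(cfg$k_folds >= 2, "k_folds must be >= 2")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(length(cfg$arima_order) == 3 && all(cfg$arima_order >= 0),
      "arima_order must be three non-negative integers")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a key = value text file
#'
#' Flat TOML-style `key = value` lines; `#` starts a comment. Vector values
#' are comma-separated. Keys not matching a documented setting are rejected.
#'
#' @param path config file path.
#' @param ... overrides applied after reading (take precedence).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2]
  if (length(bad) > 0) stop_("malformed config line: ", bad[1])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    parts <- gsub('^"|"$', "", parts)
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  cfg <- stats::setNames(lapply(vals, parse_val), keys)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(pipeline_config, cfg)
}

# deterministic per-module seeds derived from the master seed
derive_seeds <- function(seed) {
  stats::setNames(as.integer((as.integer(seed) * 1000003L + 7L * seq_len(6)) %% .Machine$integer.max),
                  c("rarefy", "nmds", "anosim", "permanova", "glv", "sim"))
}

#' Run the full critical-transition analysis pipeline
#'
#' Executes, in order: table reading, taxonomic collapsing, rarefaction,
#' alpha diversity with between-state tests, Bray-Curtis distances,
#' stratigraphically constrained zonation (two states), NMDS, ANOSIM and
#' PERMANOVA on the two states, Gaussian-KDE bimodality of NMDS1,
#' breakpoint detection on Shannon diversity, sliding-window early-warning
#' signals on NMDS1, an ARIMA forecast-deviation test of state 2 from a
#' model fitted to state 1, and stage-wise gLV inference with stability and
#' interaction analysis. All artifacts are written as provenance-headed
#' TSVs under `out_dir`; identical configs and seeds give byte-identical
#' outputs.
#'
#' @param config a `pipeline_config` (or path to a config file).
#' @return list of class `pipeline_result` with all intermediate objects and
#'   a `summary` list (number of states, boundary age, test results,
#'   breakpoint ages, EWS trends, per-stage stability).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  seeds <- derive_seeds(cfg$seed)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  tab <- read_taxon_table(cfg$input, cfg$chronology)
  if (!is.null(tab$taxonomy)) tab <- collapse_taxonomy(tab, rank = cfg$rank)
  tab <- rarefy(tab, seed = seeds["rarefy"])
  ages <- sample_ages(tab)

  alpha <- alpha_diversity(tab)
  rel <- to_relative(tab)
  sel <- select_modeled_taxa(rel, cfg$min_mean_abund, cfg$max_taxa)
  d <- bray_curtis(sel)

  zon <- constrained_zonation(d)
  states <- zon$states
  nm <- nmds_state(d, k = cfg$nmds_k, restarts = cfg$nmds_restarts,
                   seed = seeds["nmds"], ages = ages)
  an <- anosim_test(d, states, n_perm = cfg$n_perm, seed = seeds["anosim"])
  pm <- permanova_test(d, states, n_perm = cfg$n_perm, seed = seeds["permanova"])
  kde <- kde_bimodality(nm$points[, 1])
  atest <- alpha_compare(alpha, states)
  bp <- detect_breakpoints(alpha$shannon, max_m = cfg$breakpoint_max_m,
                           ages = ages)
  ews <- sliding_ews(nm$points[, 1], window = cfg$ews_window, ages = ages,
                     pre_end = zon$boundary)
  n1 <- sum(states == 1)
  fc <- NULL
  if (n1 >= sum(cfg$arima_order[1:2]) + 2 && n1 < length(states)) {
    am <- fit_state_arima(nm$points[states == 1, 1], order = cfg$arima_order)
    fc <- forecast_deviation(am, nm$points[states == 2, 1])
  }
  st <- stage_analysis(sel, w = cfg$stage_w, s = cfg$stage_s,
                       lambda_grid = cfg$lambda_grid, k_folds = cfg$k_folds)

  write_tsv_prov(alpha, out("alpha_diversity.tsv"), "alpha diversity", cfg$seed)
  write_tsv_prov(atest, out("alpha_state_tests.tsv"), "Kruskal-Wallis by state", cfg$seed)
  dm <- as.matrix(d)
  write_tsv_prov(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
                 out("bray_curtis.tsv"), "Bray-Curtis distances", cfg$seed)
  write_tsv_prov(data.frame(sample_id = rownames(dm), age_year_ce = ages,
                            state = states, nm$points, check.names = FALSE),
                 out("nmds.tsv"),
                 sprintf("NMDS coordinates | stress=%.6f", nm$stress), cfg$seed)
  write_tsv_prov(ews$ews, out("ews.tsv"),
                 sprintf("sliding EWS | tau_var=%.4f p=%.4g | tau_ac=%.4f p=%.4g",
                         ews$tau_var$tau, ews$tau_var$p,
                         ews$tau_ac$tau, ews$tau_ac$p), cfg$seed)
  bp_df <- data.frame(m = bp$m,
                      breaks = paste(bp$breaks, collapse = ","),
                      break_ages = if (bp$m > 0)
                        paste(apply(bp$break_ages, 1, paste, collapse = "-"),
                              collapse = ",") else "",
                      bic = paste(signif(bp$bic, 6), collapse = ","))
  write_tsv_prov(bp_df, out("breakpoints.tsv"), "breakpoint analysis", cfg$seed)
  if (!is.null(fc))
    write_tsv_prov(fc$forecast, out("forecast_deviation.tsv"),
                   sprintf("ARIMA forecast deviation | outside=%.3f", fc$outside_fraction),
                   cfg$seed)
  write_tsv_prov(st$stages, out("stages.tsv"), "stage-wise gLV analysis", cfg$seed)
  for (k in seq_along(st$interactions)) {
    if (is.null(st$interactions[[k]])) next
    write_tsv_prov(st$interactions[[k]]$pairs,
                   out(sprintf("interactions_stage%d.tsv", k)),
                   sprintf("interaction typing, stage %d", k), cfg$seed)
  }
  for (k in seq_along(st$fits)) {
    fit <- st$fits[[k]]
    if (is.null(fit)) next
    write_tsv_prov(data.frame(taxon = fit$taxa, r = fit$r, fit$A,
                              check.names = FALSE),
                   out(sprintf("glv_coefficients_stage%d.tsv", k)),
                   sprintf("gLV growth rates and interaction matrix, stage %d", k),
                   cfg$seed)
    if (!is.null(st$stability[[k]])) {
      ev <- st$stability[[k]]$eigenvalues
      write_tsv_prov(data.frame(re = Re(ev), im = Im(ev)),
                     out(sprintf("eigenvalues_stage%d.tsv", k)),
                     sprintf("Jacobian spectrum, stage %d", k), cfg$seed)
    }
  }

  summary <- list(
    n_samples = nrow(tab$counts),
    n_states = max(states),
    state_boundary_age = c(ages[zon$boundary], ages[zon$boundary + 1]),
    anosim = an, permanova = pm,
    nmds_stress = nm$stress,
    kde_modes = kde$n_modes,
    breakpoint_m = bp$m,
    breakpoint_ages = bp$break_ages,
    ews_tau_var = ews$tau_var, ews_tau_ac = ews$tau_ac,
    forecast_outside = if (is.null(fc)) NA_real_ else fc$outside_fraction,
    n_stages = nrow(st$stages),
    stage_centroids = st$stages$centroid_re)
  res <- structure(list(config = cfg, table = tab, alpha = alpha,
                        community = sel, dist = d, zonation = zon,
                        nmds = nm, anosim = an, permanova = pm, kde = kde,
                        alpha_tests = atest, breakpoints = bp, ews = ews,
                        forecast = fc, stages = st, summary = summary),
                   class = "pipeline_result")
  saveRDS_safe(res, out("summary.txt"))
  res
}

# plain-text summary report (no binary artifacts)
saveRDS_safe <- function(res, path) {
  s <- res$summary
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header("pipeline summary", res$config$seed), con)
  writeLines(sprintf("samples: %d", s$n_samples), con)
  writeLines(sprintf("states: %d (boundary between ages %.1f and %.1f)",
                     s$n_states, s$state_boundary_age[1], s$state_boundary_age[2]), con)
  writeLines(sprintf("ANOSIM R = %.4f, p = %.4g; PERMANOVA F = %.3f, p = %.4g",
                     s$anosim$R, s$anosim$p, s$permanova$F, s$permanova$p), con)
  writeLines(sprintf("NMDS stress = %.4f; NMDS1 KDE modes = %d",
                     s$nmds_stress, s$kde_modes), con)
  if (s$breakpoint_m > 0)
    writeLines(sprintf("breakpoint(s) at: %s",
                       paste(apply(s$breakpoint_ages, 1, paste, collapse = "-"),
                             collapse = ", ")), con)
  writeLines(sprintf("EWS trends (pre-transition): var tau = %.3f (p = %.3g), AC tau = %.3f (p = %.3g)",
                     s$ews_tau_var$tau, s$ews_tau_var$p,
                     s$ews_tau_ac$tau, s$ews_tau_ac$p), con)
  if (!is.na(s$forecast_outside))
    writeLines(sprintf("ARIMA forecast: %.1f%% of state2 outside the 95%% band",
                       100 * s$forecast_outside), con)
  writeLines(sprintf("stages: %d; eigenvalue centroids: %s", s$n_stages,
                     paste(signif(s$stage_centroids, 4), collapse = ", ")), con)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline result: %d samples, %d states, %d stages\n",
              s$n_samples, s$n_states, s$n_stages))
  cat(sprintf("  ANOSIM R = %.3f (p = %.4g); KDE modes = %d\n",
              s$anosim$R, s$anosim$p, s$kde_modes))
  if (s$breakpoint_m > 0)
    cat(sprintf("  diversity breakpoint between %.0f and %.0f CE\n",
                s$breakpoint_ages[1, 1], s$breakpoint_ages[1, 2]))
  cat(sprintf("  stage centroids: %s\n",
              paste(signif(s$stage_centroids, 3), collapse = " ")))
  invisible(x)
}

#' Simulate a scenario and write its fixture files
#'
#' Convenience wrapper: generates a [transition_scenario()] and writes the
#' count table, chronology and ground-truth sidecar to `dir`.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param transition produce a two-regime record (default) or a stationary
#'   single-regime one.
#' @param ... further arguments to [transition_scenario()].
#' @return file paths (named character vector), invisibly; the scenario as
#'   the `"scenario"` attribute.
#' @export
simulate_scenario_files <- function(dir, seed = 1L, transition = TRUE, ...) {
  sc <- transition_scenario(seed = seed, transition = transition, ...)
  paths <- write_scenario(sc, dir)
  attr(paths, "scenario") <- sc
  invisible(paths)
}
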