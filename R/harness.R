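# Packaged experiments: validation scenarios from serial imaging studies,
# the overlapping-stent comparison, and the one-at-a-time sensitivity scan.

#' Validation scenarios from serial imaging studies
#'
#' The three single-stent scenarios used for model validation, defined by
#' the post-procedural lumen diameters reported in serial angiography /
#' intravascular-ultrasound studies, together with the study-reported final
#' lumen diameters (mean +/- SD) used as the acceptance window.
#'
#' @return A tibble with columns `scenario`, `initial_ld_mm`,
#'   `study_final_ld_mm`, `study_final_ld_sd`.
#' @export
validation_scenarios <- function() {
  tibble::tibble(
    scenario = c("kimura", "hoffmann", "chamie"),
    initial_ld_mm = c(2.9, 3.19, 2.39),
    study_final_ld_mm = c(2.2, 2.12, 1.28),
    study_final_ld_sd = c(0.6, 0.82, 0.74))
}

#' Run the validation suite
#'
#' Runs `n` replicates of each validation scenario (single stent, 20 struts,
#' default wall thickness) and checks that the replicate-mean final lumen
#' diameter lies within one study standard deviation of the study mean.
#'
#' @param base_seed Seed for the first replicate of each scenario.
#' @param n Replicates per scenario (default 10).
#' @param scenarios Optional subset of scenario names.
#' @return A `validation_report`: list with the per-scenario `report` tibble
#'   and the underlying `replicate_summary` objects in `results`.
#' @export
validation_suite <- function(base_seed = 1L, n = 10L,
                             scenarios = validation_scenarios()$scenario) {
  sc <- validation_scenarios()
  sc <- sc[sc$scenario %in% scenarios, ]
  results <- lapply(seq_len(nrow(sc)), function(i) {
    cfg <- vessel_config(lumen_diameter_mm = sc$initial_ld_mm[i],
                         seed = base_seed)
    run_replicates(cfg, n = n, base_seed = base_seed + (i - 1L) * 1000L)
  })
  names(results) <- sc$scenario
  report <- dplyr::bind_cols(sc, dplyr::bind_rows(lapply(results, function(r) {
    s <- r$summary
    tibble::tibble(
      model_final_ld_mm = s$mean[s$metric == "final_lumen_diameter_mm"],
      model_final_ld_sd = s$sd[s$metric == "final_lumen_diameter_mm"],
      model_stab_day = s$mean[s$metric == "stabilization_day"],
      model_stab_sd = s$sd[s$metric == "stabilization_day"],
      n = s$n[1])
  })))
  report$within_one_sd <-
    abs(report$model_final_ld_mm - report$study_final_ld_mm) <=
    report$study_final_ld_sd
  out <- list(report = report, results = results)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf(
      "  %-9s init %.2f mm: model %.2f+/-%.2f mm (study %.2f+/-%.2f) stab %.0f+/-%.0f d %s\n",
      r$scenario[i], r$initial_ld_mm[i], r$model_final_ld_mm[i],
      r$model_final_ld_sd[i], r$study_final_ld_mm[i],
      r$study_final_ld_sd[i], r$model_stab_day[i], r$model_stab_sd[i],
      if (r$within_one_sd[i]) "PASS" else "FAIL"))
  }
  invisible(x)
}

#' Overlapping-stent experiment
#'
#' Runs the 2.9 mm scenario with two overlapping stents and compares against
#' the single-stent case: the expected pattern is a smaller final lumen
#' diameter, a longer time to stabilization, and higher peak local cytokine
#' concentrations.
#'
#' @param base_seed Seed for the first replicate.
#' @param n Replicates per arm (default 10).
#' @param arrangement Strut arrangement of the second stent.
#' @param single Optionally, a pre-computed single-stent
#'   [run_replicates()] result to compare against (avoids re-running it).
#' @return An `overlap_report`: list with the comparison tibble `report` and
#'   both `replicate_summary` objects.
#' @export
overlap_experiment <- function(base_seed = 1L, n = 10L,
                               arrangement = c("staggered", "aligned"),
                               single = NULL) {
  arrangement <- match.arg(arrangement)
  if (is.null(single)) {
    single <- run_replicates(vessel_config(2.9, seed = base_seed),
                             n = n, base_seed = base_seed)
  }
  overlap <- run_replicates(
    vessel_config(2.9, stent_count = 2L, arrangement = arrangement,
                  seed = base_seed),
    n = n, base_seed = base_seed + 5000L)
  g <- function(r, metric) {
    s <- r$summary
    c(s$mean[s$metric == metric], s$sd[s$metric == metric])
  }
  ld_s <- g(single, "final_lumen_diameter_mm")
  ld_o <- g(overlap, "final_lumen_diameter_mm")
  st_s <- g(single, "stabilization_day")
  st_o <- g(overlap, "stabilization_day")
  report <- tibble::tibble(
    metric = c("final_lumen_diameter_mm", "stabilization_day",
               "peak_tgfb_ngml", "peak_tnfa_ngml"),
    single = c(ld_s[1], st_s[1], max(single$runs$peak_tgfb_ngml),
               max(single$runs$peak_tnfa_ngml)),
    overlap = c(ld_o[1], st_o[1], max(overlap$runs$peak_tgfb_ngml),
                max(overlap$runs$peak_tnfa_ngml)))
  report$delta <- report$overlap - report$single
  report$relative_pct <- 100 * report$delta / report$single
  out <- list(report = report, single = single, overlap = overlap,
              arrangement = arrangement)
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> (%s arrangement)\n", x$arrangement))
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-26s single %6.2f  overlap %6.2f  (%+.1f%%)\n",
                r$metric[i], r$single[i], r$overlap[i], r$relative_pct[i]))
  }
  invisible(x)
}

#' One-at-a-time parameter sensitivity scan
#'
#' Perturbs a single registered configuration parameter by the given
#' relative deltas, runs replicates for each perturbation, and reports the
#' effect on final lumen diameter and stabilization day together with a
#' Welch t-test against the unperturbed baseline. After the perturbation
#' batches a default-configuration batch is re-run to confirm all changes
#' were reversed.
#'
#' @param parameter Name of a numeric scalar field of [vessel_config()].
#' @param deltas Relative perturbations (default +/-10% and +/-50%).
#' @param base_seed Seed for the first replicate.
#' @param n Replicates per setting.
#' @param config Baseline configuration (default: the 2.9 mm scenario).
#' @param alpha Significance level for the Welch test (default 0.01).
#' @return A tibble with one row per setting (including the baseline and the
#'   restoration check), with means, SDs, and t-test p-values.
#' @export
sensitivity_scan <- function(parameter, deltas = c(-0.5, -0.1, 0.1, 0.5),
                             base_seed = 1L, n = 10L,
                             config = vessel_config(2.9, seed = 1L),
                             alpha = 0.01) {
  if (!parameter %in% names(config) ||
      !is.numeric(config[[parameter]]) || length(config[[parameter]]) != 1L) {
    stop("unknown or non-scalar parameter: ", parameter, call. = FALSE)
  }
  run_batch <- function(cfg, seed_off) {
    run_replicates(cfg, n = n, base_seed = base_seed + seed_off)
  }
  base <- run_batch(config, 0L)
  rows <- list(scan_row("baseline", config[[parameter]], base, base, alpha))
  for (i in seq_along(deltas)) {
    cfg <- config
    cfg[[parameter]] <- config[[parameter]] * (1 + deltas[i])
    pert <- run_batch(cfg, i * 100L)
    rows[[length(rows) + 1L]] <- scan_row(sprintf("%+.0f%%", 100 * deltas[i]),
                                          cfg[[parameter]], pert, base, alpha)
  }
  restore <- run_batch(config, 0L)
  rows[[length(rows) + 1L]] <- scan_row("restored", config[[parameter]],
                                        restore, base, alpha)
  out <- dplyr::bind_rows(rows)
  out$parameter <- parameter
  out
}

scan_row <- function(label, value, batch, base, alpha) {
  ld <- batch$runs$final_lumen_diameter_mm[batch$runs$converged]
  ld0 <- base$runs$final_lumen_diameter_mm[base$runs$converged]
  p <- if (identical(ld, ld0) || stats::sd(ld) + stats::sd(ld0) == 0) {
    1
  } else {
    stats::t.test(ld, ld0)$p.value
  }
  s <- batch$summary
  tibble::tibble(
    setting = label, value = value,
    final_ld_mm = s$mean[s$metric == "final_lumen_diameter_mm"],
    final_ld_sd = s$sd[s$metric == "final_lumen_diameter_mm"],
    stab_day = s$mean[s$metric == "stabilization_day"],
    p_value = p,
    significant = p < alpha)
}
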