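# broom-style tidiers for simulation results

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single simulation run
#'
#' Returns the per-step time series as a tibble (one row per 6-h step).
#'
#' @param x A `stent_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stent_run
#' @export
tidy.stent_run <- function(x, ...) {
  x$series
}

#' One-row summary of a simulation run
#'
#' @param x A `stent_run`.
#' @param ... Unused.
#' @return A one-row tibble with the scalar outcomes.
#' @method glance stent_run
#' @export
glance.stent_run <- function(x, ...) {
  tibble::tibble(
    initial_lumen_diameter_mm = x$config$lumen_diameter_mm,
    final_lumen_diameter_mm = x$final_lumen_diameter_mm,
    percent_area_change = x$percent_area_change_final,
    stabilization_day = x$stabilization_day,
    restenosis = x$restenosis,
    occluded = x$occluded,
    peak_tgfb_ngml = x$peak_tgfb_ngml,
    peak_tnfa_ngml = x$peak_tnfa_ngml,
    days_simulated = x$days_simulated,
    converged = x$converged,
    seed = x$seed)
}

#' Tidy a replicate batch
#'
#' @param x A `replicate_summary` from [run_replicates()].
#' @param ... Unused.
#' @return The per-run tibble (one row per replicate).
#' @method tidy replicate_summary
#' @export
tidy.replicate_summary <- function(x, ...) {
  x$runs
}

#' One-row summary of a replicate batch
#'
#' @param x A `replicate_summary`.
#' @param ... Unused.
#' @return A one-row tibble with means and SDs across replicates.
#' @method glance replicate_summary
#' @export
glance.replicate_summary <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    initial_lumen_diameter_mm = x$config$lumen_diameter_mm,
    final_ld_mean = s$mean[s$metric == "final_lumen_diameter_mm"],
    final_ld_sd = s$sd[s$metric == "final_lumen_diameter_mm"],
    stab_day_mean = s$mean[s$metric == "stabilization_day"],
    stab_day_sd = s$sd[s$metric == "stabilization_day"],
    area_change_mean = s$mean[s$metric == "percent_area_change"],
    area_change_sd = s$sd[s$metric == "percent_area_change"],
    restenosis_fraction = mean(x$runs$restenosis[x$runs$converged]),
    n = s$n[1])
}
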