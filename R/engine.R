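# Simulation engine: per-step orchestration, stopping rule, replicates.

#' Advance the simulation one 6-hour step
#'
#' Applies, in order: platelet step, TGF-beta release, leukocyte
#' recruitment, leukocyte step, TNF-alpha release, cytokine diffusion and
#' decay, SMC step, EC/frontier step. The caller records metrics afterwards.
#'
#' @param state A `sim_state`.
#' @return The advanced state (one 6-h step later).
#' @export
sim_step <- function(state) {
  state$step <- state$step + 1L
  # per-step caches: the tissue mask and injury map are constant from the
  # end of the previous EC step until the SMC/EC steps below change them
  state$.tis <- NULL
  state$.injmap <- NULL
  state$.injadj <- NULL
  state$.tg_local <- NULL
  state$.tis <- tissue_mask(state)
  state$.injmap <- injury_map(state)
  state$.injadj <- injury_adj(state)

  state <- step_platelets(state)
  state <- release_tgfb(state)
  state$.tg_local <- tg_local_field(state)
  state <- maybe_recruit_leukocytes(state)
  state <- step_leukocytes(state)
  state <- release_tnfa(state)
  state <- diffuse_and_decay(state)
  n <- state$frame$n
  tgl <- boxsum3(count_field(state$tg$pos, n))
  tnl <- boxsum3(count_field(state$tn$pos, n))
  state <- step_smc(state, tgl, tnl)
  state$.tis <- NULL                      # the SMC step moved tissue
  state <- step_ec(state, tgl, tnl)
  state$.tis <- NULL
  state$.injmap <- NULL
  state$.injadj <- NULL
  state$.tg_local <- NULL
  if (state$tg_emitted > 0) state$last_emit <- state$step
  attr(state, "fields") <- list(tg = tgl, tn = tnl)
  state
}

#' Run one simulation to lumen-diameter stabilization
#'
#' Iterates [sim_step()] until TGF-beta release has ceased for a full
#' simulated day, marks the last day of release as the stabilization day,
#' then continues for a 60-day confirmation window during which the minimum
#' lumen diameter must stay within one patch (0.05 mm); late drift or
#' resumed release restarts the window. Terminates early (with
#' `occluded = TRUE`) when the neointima fills the lumen, and gives up at a
#' hard cap of `max_days` (400) simulated days.
#'
#' @param config A [vessel_config()].
#' @param seed Optional RNG seed overriding `config$seed`.
#' @return A `stent_run` object: a list with `final_lumen_diameter_mm`,
#'   `stabilization_day`, `percent_area_change_final`, `peak_tgfb_ngml`,
#'   `peak_tnfa_ngml`, `occluded`, `converged`, `restenosis`, and the
#'   per-step `series` tibble.
#' @examples
#' \donttest{
#' run <- run_simulation(vessel_config(2.9, seed = 1))
#' run$final_lumen_diameter_mm
#' }
#' @export
run_simulation <- function(config, seed = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  set.seed(cfg$seed)
  state <- build_initial_state(cfg)

  spd <- cfg$steps_per_day
  max_steps <- cfg$max_days * spd
  confirm_steps <- cfg$confirm_days * spd
  rec0 <- record_step(state)
  series <- matrix(NA_real_, max_steps + 1L, length(rec0),
                   dimnames = list(NULL, names(rec0)))
  series[1L, ] <- rec0

  stabilized <- FALSE
  confirm_from <- NA_integer_
  ld_ref <- NA_real_
  drift_restarts <- 0L
  converged <- FALSE

  while (state$step < max_steps) {
    state <- sim_step(state)
    f <- attr(state, "fields")
    series[state$step + 1L, ] <- record_step(state, f$tg, f$tn)
    if (state$occluded) break

    if (state$tg_emitted > 0 && stabilized) {
      stabilized <- FALSE   # release resumed: not stable after all
    }
    if (!stabilized && state$step - state$last_emit >= spd) {
      stabilized <- TRUE
      confirm_from <- state$step
      ld_ref <- min_lumen_diameter(state)
    } else if (stabilized) {
      if (abs(min_lumen_diameter(state) - ld_ref) > cfg$patch_mm + 1e-9) {
        drift_restarts <- drift_restarts + 1L
        confirm_from <- state$step
        ld_ref <- min_lumen_diameter(state)
      } else if (state$step - confirm_from >= confirm_steps) {
        converged <- TRUE
        break
      }
    }
  }
  if (state$occluded) converged <- TRUE

  series <- tibble::as_tibble(series[seq_len(state$step + 1L), , drop = FALSE])
  final_d <- if (state$occluded) 0 else min_lumen_diameter(state)
  pac <- percent_area_change(cfg$lumen_diameter_mm,
                             min(final_d, cfg$lumen_diameter_mm))
  out <- list(
    config = cfg,
    seed = cfg$seed,
    final_lumen_diameter_mm = final_d,
    stabilization_day = if (state$occluded) {
      round(state$step / spd)
    } else {
      round(state$last_emit / spd)
    },
    percent_area_change_final = pac,
    restenosis = classify_restenosis(pac),
    peak_tgfb_ngml = max(series$tgfb_max_local_ngml),
    peak_tnfa_ngml = max(series$tnfa_max_local_ngml),
    peak_tgfb_serum_ngml = max(series$tgfb_serum_ngml),
    peak_tnfa_serum_ngml = max(series$tnfa_serum_ngml),
    occluded = state$occluded,
    converged = converged,
    drift_restarts = drift_restarts,
    days_simulated = state$step / spd,
    series = series)
  class(out) <- "stent_run"
  out
}

#' @export
print.stent_run <- function(x, ...) {
  cat("<stent_run>\n")
  cat(sprintf("  initial LD %.2f mm -> final %.2f mm (%.1f%% area change%s)\n",
              x$config$lumen_diameter_mm, x$final_lumen_diameter_mm,
              x$percent_area_change_final,
              if (x$occluded) ", occluded" else ""))
  cat(sprintf("  stabilization day %d; peak local TGF-b %.1f / TNF-a %.1f ng/ml\n",
              x$stabilization_day, x$peak_tgfb_ngml, x$peak_tnfa_ngml))
  if (!x$converged) cat("  WARNING: run did not converge within the day cap\n")
  invisible(x)
}

#' Run independent replicate simulations
#'
#' Runs `n` independent simulations (seeds `base_seed`, `base_seed + 1`,
#' ...) and summarises the final lumen diameter, stabilization day and
#' percent area change as mean +/- SD. Ten runs per scenario are sufficient
#' for stable reporting. Non-convergent runs are excluded with a warning.
#'
#' @param config A [vessel_config()].
#' @param n Number of replicates (default 10).
#' @param base_seed Seed of the first replicate; replicate i uses
#'   `base_seed + i - 1`.
#' @return A `replicate_summary`: list with a per-run tibble `runs`, the
#'   summary tibble `summary`, and the run objects in `details`.
#' @export
run_replicates <- function(config, n = 10L, base_seed = config$seed) {
  stopifnot(n >= 1)
  details <- lapply(seq_len(n), function(i) {
    run_simulation(config, seed = base_seed + i - 1L)
  })
  ok <- vapply(details, `[[`, logical(1), "converged")
  if (any(!ok)) {
    warning(sum(!ok), " non-convergent run(s) excluded from the summary")
  }
  runs <- tibble::tibble(
    replicate = seq_len(n),
    seed = base_seed + seq_len(n) - 1L,
    final_lumen_diameter_mm = vapply(details, `[[`, numeric(1),
                                     "final_lumen_diameter_mm"),
    stabilization_day = vapply(details, function(d)
      as.numeric(d$stabilization_day), numeric(1)),
    percent_area_change = vapply(details, `[[`, numeric(1),
                                 "percent_area_change_final"),
    peak_tgfb_ngml = vapply(details, `[[`, numeric(1), "peak_tgfb_ngml"),
    peak_tnfa_ngml = vapply(details, `[[`, numeric(1), "peak_tnfa_ngml"),
    occluded = vapply(details, `[[`, logical(1), "occluded"),
    restenosis = vapply(details, `[[`, logical(1), "restenosis"),
    converged = ok)
  use <- runs[runs$converged, ]
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  summary <- tibble::tibble(
    metric = c("final_lumen_diameter_mm", "stabilization_day",
               "percent_area_change"),
    mean = c(mean(use$final_lumen_diameter_mm), mean(use$stabilization_day),
             mean(use$percent_area_change)),
    sd = c(sd0(use$final_lumen_diameter_mm), sd0(use$stabilization_day),
           sd0(use$percent_area_change)),
    n = nrow(use))
  out <- list(config = config, runs = runs, summary = summary,
              details = details)
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %d runs, initial LD %.2f mm\n",
              nrow(x$runs), x$config$lumen_diameter_mm))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-26s %.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
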