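# Measurement protocols: minimum lumen diameter from the EC-defined
# boundary, percent lumen-area change, restenosis classification, and the
# per-step time series.

#' Minimum lumen diameter (mm)
#'
#' Casts diameters through the vessel axis at evenly spaced angles (half the
#' angular-bin resolution, 180 by default) and measures, for each, the
#' distance between the innermost points of the EC-defined lumen boundary on
#' opposite sides. Returns the minimum — the worst-case lumen obstruction —
#' in mm, or 0 for an occluded lumen.
#'
#' @param state A `sim_state`.
#' @return Length in mm.
#' @export
min_lumen_diameter <- function(state) {
  if (state$occluded) return(0)
  fr <- state$fr
  if (all(is.na(fr))) stop("no lumen boundary found and no occlusion flag")
  nb <- state$frame$nb
  half <- nb %/% 2L
  d <- fr[seq_len(half)] + fr[seq_len(half) + half]
  min(d, na.rm = TRUE) * state$cfg$patch_mm
}

#' Percent change in lumen cross-sectional area
#'
#' 100 x (A0 - A) / A0 with A = pi (d/2)^2 computed on the initial and the
#' current minimum lumen diameter. A current diameter exceeding the initial
#' one clamps to 0% with a warning (the stent prevents outward growth).
#'
#' @param initial_d_mm Initial (post-procedural) lumen diameter, mm.
#' @param current_d_mm Current minimum lumen diameter, mm.
#' @return Percent area change in `[0, 100]`.
#' @examples
#' percent_area_change(2.9, 2.13)  # 46.06
#' @export
percent_area_change <- function(initial_d_mm, current_d_mm) {
  if (any(current_d_mm < 0) || initial_d_mm <= 0) {
    stop("diameters must be non-negative, initial positive", call. = FALSE)
  }
  over <- current_d_mm > initial_d_mm
  if (any(over)) {
    warning("current diameter exceeds initial; clamping area change to 0")
    current_d_mm[over] <- initial_d_mm
  }
  100 * (1 - (current_d_mm / initial_d_mm)^2)
}

#' Classify clinically defined restenosis
#'
#' Restenosis is a loss of strictly more than 50% of the post-procedural
#' lumen cross-sectional area.
#'
#' @param pct_area_change Percent lumen-area change in `[0, 100]`.
#' @return Logical.
#' @examples
#' classify_restenosis(45.52)  # FALSE
#' classify_restenosis(77.67)  # TRUE
#' @export
classify_restenosis <- function(pct_area_change) {
  stopifnot(all(pct_area_change >= -5), all(pct_area_change <= 100))
  pct_area_change > 50
}

#' One time-series record for the current step
#'
#' Assembles the per-step record (day, minimum lumen diameter, percent area
#' change, cell censuses, cytokine maxima and serum levels) as a named
#' numeric vector; [run_simulation()] stacks these into the `series` tibble.
#'
#' @param state A `sim_state`.
#' @param tg_local,tn_local Optional precomputed local (9-patch) count
#'   matrices; recomputed from the state when omitted.
#' @return Named numeric vector.
#' @export
record_step <- function(state, tg_local = NULL, tn_local = NULL) {
  n <- state$frame$n
  cfg <- state$cfg
  if (is.null(tg_local)) tg_local <- boxsum3(count_field(state$tg$pos, n))
  if (is.null(tn_local)) tn_local <- boxsum3(count_field(state$tn$pos, n))
  cpq <- conc_per_quantum(cfg)
  d <- min_lumen_diameter(state)
  c(step = state$step,
    day = state$step / cfg$steps_per_day,
    min_lumen_diameter_mm = d,
    percent_area_change = percent_area_change(cfg$lumen_diameter_mm,
                                              min(d, cfg$lumen_diameter_mm)),
    smc = sum(state$S_int) + sum(state$S_med) + sum(state$S_adv) +
      sum(state$S_mig),
    ec = ec_count(state),
    monocytes = sum(state$leuk$kind == 1L),
    neutrophils = sum(state$leuk$kind == 2L),
    macrophages = sum(state$leuk$kind >= 3L),
    platelets_activated = sum(state$platelets$active),
    tgfb_max_local_ngml = max(tg_local) * cpq,
    tnfa_max_local_ngml = max(tn_local) * cpq,
    tgfb_serum_ngml = serum_concentration(length(state$tg$pos), cfg),
    tnfa_serum_ngml = serum_concentration(length(state$tn$pos), cfg),
    tgfb_emitted = state$tg_emitted,
    tnfa_emitted = state$tn_emitted)
}
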