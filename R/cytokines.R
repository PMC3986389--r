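# Cytokine fields: release, diffusion, decay, and concentration measurement.
#
# Both species (TGF-beta, TNF-alpha) are represented as discrete quanta of
# fixed mass (`quantum_pg`) living on lattice patches. Concentrations are
# measured over a patch's local environment (itself plus its 8 neighbours)
# using the volume V = C x AP, where C is the patch thickness constant and
# AP the neighbourhood area.

# 3x3 box sum with zero padding (the local-environment aggregation),
# computed separably: a vertical then a horizontal 3-point sum
boxsum3 <- function(M) {
  n <- nrow(M)
  m <- ncol(M)
  P <- matrix(0, n + 2, m)
  P[2:(n + 1), ] <- M
  V <- P[1:n, ] + P[2:(n + 1), ] + P[3:(n + 2), ]
  Q <- matrix(0, n, m + 2)
  Q[, 2:(m + 1)] <- V
  Q[, 1:m] + Q[, 2:(m + 1)] + Q[, 3:(m + 2)]
}

# per-patch count matrix from a vector of patch indices
count_field <- function(pos, n) {
  matrix(tabulate(pos, nbins = n * n), n, n)
}

# ng/ml contributed by one quantum in a full 9-patch local environment
conc_per_quantum <- function(cfg) {
  # pg / mm^3 is numerically ng/ml
  cfg$quantum_pg / (cfg$patch_thickness_C_mm * 9 * cfg$patch_mm^2)
}

# quanta emitted per cell per step at the nominal release rate
quanta_per_cell_step <- function(cfg) {
  cfg$release_pg_per_10h * cfg$step_hours / 10 / cfg$quantum_pg
}

# cytokine thresholds expressed as local quantum counts
threshold_quanta <- function(cfg, which = c("tgfb", "tnfa")) {
  which <- match.arg(which)
  th <- if (which == "tgfb") cfg$tgfb_threshold_ngml else cfg$tnfa_threshold_ngml
  round(th / conc_per_quantum(cfg), 6)
}

#' Local cytokine concentration (ng/ml)
#'
#' Counts cytokine quanta on a patch of interest and its 8 adjacent patches,
#' then divides by the local-environment volume V = C x AP (AP = area of the
#' 9 patches). Edge patches use their truncated neighbourhood with a
#' correspondingly reduced AP.
#'
#' @param field Square integer matrix of per-patch quantum counts.
#' @param patch Optional patch index (column-major) or `c(row, col)`; when
#'   omitted the full concentration matrix is returned.
#' @param cfg A [vessel_config()] (defaults supply the calibration constants).
#' @return Concentration(s) in ng/ml.
#' @examples
#' f <- matrix(0L, 9, 9); f[5, 5] <- 54L
#' cfg <- vessel_config(2.9)
#' local_concentration(f, c(5, 5), cfg)  # 3 ng/ml: the SMC trigger level
#' @export
local_concentration <- function(field, patch = NULL, cfg = vessel_config(2.9)) {
  n <- nrow(field)
  counts <- boxsum3(field)
  nn <- boxsum3(matrix(1, n, n))  # neighbourhood size (truncated at edges)
  conc <- counts * cfg$quantum_pg /
    (cfg$patch_thickness_C_mm * nn * cfg$patch_mm^2)
  if (is.null(patch)) return(conc)
  if (length(patch) == 2L) conc[patch[1], patch[2]] else conc[patch]
}

#' Serum (grid-wide) cytokine concentration (ng/ml)
#'
#' Total cytokine mass on the grid divided by the reference serum volume
#' (the full grid area times the patch thickness constant C). The serum
#' level does not drive any agent behaviour; it is a physiology checkpoint
#' that should remain within 0-10 ng/ml during valid runs.
#'
#' @param n_quanta Total number of quanta on the grid (or a count matrix).
#' @param cfg A [vessel_config()].
#' @return Concentration in ng/ml.
#' @export
serum_concentration <- function(n_quanta, cfg = vessel_config(2.9)) {
  if (is.matrix(n_quanta)) n_quanta <- sum(n_quanta)
  vol_mm3 <- cfg$patch_thickness_C_mm * (cfg$grid_n * cfg$patch_mm)^2
  n_quanta * cfg$quantum_pg / vol_mm3
}

#' Hoop-stress modulation of TGF-beta release
#'
#' Circumferential (hoop) wall stress under the thin-wall Laplace
#' approximation is proportional to the lumen radius over the wall
#' thickness. The release-rate multiplier is normalised to 1 at the default
#' 1:1 radius-to-thickness geometry, so narrowing of the lumen at fixed wall
#' thickness proportionally reduces TGF-beta release.
#'
#' @param lumen_radius_mm Current lumen radius (mm, positive).
#' @param wall_thickness_mm Wall thickness (mm, positive).
#' @param exponent Sensitivity of release to the stress ratio; 1 gives the
#'   plain Laplace ratio. The engine uses the configured `hoop_exponent`,
#'   a calibration constant making the growth endpoint scale with vessel
#'   size.
#' @return Dimensionless multiplier (r / t)^exponent.
#' @examples
#' hoop_stress_factor(1.45, 1.45)  # 1
#' hoop_stress_factor(1.16, 1.45)  # 0.8 after a 20% radius loss
#' @export
hoop_stress_factor <- function(lumen_radius_mm, wall_thickness_mm,
                               exponent = 1) {
  stopifnot(lumen_radius_mm > 0, wall_thickness_mm > 0)
  (lumen_radius_mm / wall_thickness_mm)^exponent
}

# Per-angular-bin hoop-stress release modulation. The wall unloads as the
# neointima thickens: release saturates at the post-procedural stress and
# falls steeply once the local lumen radius drops below `hoop_knee` of its
# initial value (the saturating power-law calibration of the stress-release
# coupling). Returns a per-patch multiplier matrix.
state_hoop_matrix <- function(state) {
  cfg <- state$cfg
  t_mm <- cfg$wall_thickness_mm
  rel <- hoop_stress_factor(pmax(state$fr, 0.5) * cfg$patch_mm, t_mm) /
    hoop_stress_factor(state$r0 * cfg$patch_mm, t_mm)
  hb <- pmin(1, (rel / cfg$hoop_knee)^cfg$hoop_exponent)
  hb[is.na(hb)] <- 1
  matrix(hb[state$frame$bin], state$frame$n, state$frame$n)
}

# injury map: unhealed strut patches plus frontier patches of angular bins
# whose EC cover is missing or still damaged
injury_map <- function(state) {
  if (!is.null(state$.injmap)) return(state$.injmap)
  n <- state$frame$n
  inj <- matrix(FALSE, n, n)
  for (i in seq_along(state$strut_info)) {
    if (!state$strut_healed[i]) inj[state$strut_info[[i]]$patches] <- TRUE
  }
  gap <- which(!state$ec_healthy & !is.na(state$frontier_idx))
  inj[state$frontier_idx[gap]] <- TRUE
  inj
}

# 3x3 dilation of the injury map, cached within a step by the engine
injury_adj <- function(state) {
  if (!is.null(state$.injadj)) return(state$.injadj)
  boxsum3(injury_map(state)) > 0
}

# multiplier matrix: `injury_factor` on patches in/adjacent to an unhealed
# strut (the deeper procedural injury), 1 elsewhere
strut_injury_mult <- function(state) {
  n <- state$frame$n
  sm <- matrix(0L, n, n)
  for (i in seq_along(state$strut_info)) {
    if (!state$strut_healed[i]) sm[state$strut_info[[i]]$patches] <- 1L
  }
  1 + (state$cfg$injury_factor - 1) * (boxsum3(sm) > 0)
}

#' Release TGF-beta quanta
#'
#' Activated platelets, SMCs and ECs emit TGF-beta at 0.02 pg per 10 hours
#' per cell (one 0.012 pg quantum per cell per 6-h step on average, Poisson
#' distributed), multiplied by the strut injury factor and the live
#' hoop-stress factor. SMCs and ECs release only while they sit in or
#' adjacent to injured territory; on fully re-endothelialised, uninjured
#' ground their trigger is off and release ceases.
#'
#' @param state A `sim_state`.
#' @return The state with new quanta appended and emission bookkeeping
#'   updated.
#' @export
release_tgfb <- function(state) {
  cfg <- state$cfg
  n <- state$frame$n
  inj_adj <- injury_adj(state)

  # degranulation is transient: an activated platelet releases only during
  # its first `platelet_release_d` days in the thrombus
  fresh <- state$platelets$active &
    (state$step - state$platelets$act_step) <=
      state$cfg$platelet_release_d * state$cfg$steps_per_day
  fresh[is.na(fresh)] <- FALSE
  plat <- count_field(state$platelets$pos[fresh], n)
  smc <- state$S_int + state$S_med + state$S_adv + state$S_mig
  ecf <- matrix(0L, n, n)
  epatch <- unique(state$frontier_idx[state$ec_present &
                                        !is.na(state$frontier_idx)])
  ecf[epatch] <- 1L
  # only cells at the wound surface are signalling-active: deeper cells
  # are quiescent, so per patch at most `surface_release_cap` SMC/EC emit.
  # Cells in injured territory release at `wound_release_factor` times the
  # basal rate; the deeper strut injuries amplify further.
  tissue <- tissue_mask(state)
  surface <- tissue & (boxsum3(!tissue) > 0)
  cells <- pmin(smc + ecf, cfg$surface_release_cap) * (inj_adj & surface)
  lambda <- (cells * cfg$wound_release_factor * strut_injury_mult(state) +
               pmin(plat, cfg$surface_release_cap)) *
    cfg$release_scale * quanta_per_cell_step(cfg) * state_hoop_matrix(state)
  act <- which(lambda > 0)
  if (length(act) == 0) {
    state$tg_emitted <- 0L
    return(state)
  }
  k <- stats::rpois(length(act), lambda[act])
  tot <- sum(k)
  if (tot > 0) {
    state$tg$pos <- c(state$tg$pos, rep.int(act, k))
    state$tg$death <- c(state$tg$death,
                        rep.int(state$step + cfg$cytokine_life_steps, tot))
  }
  state$tg_emitted <- tot
  state$tg_total_emitted <- state$tg_total_emitted + tot
  state$.tg_local <- NULL
  state
}

# local (9-patch) TGF-beta counts for the current field, cached per phase
tg_local_field <- function(state) {
  if (!is.null(state$.tg_local)) return(state$.tg_local)
  boxsum3(count_field(state$tg$pos, state$frame$n))
}

#' Release TNF-alpha quanta
#'
#' Monocytes, neutrophils and macrophages emit TNF-alpha at the same
#' 0.02 pg / 10 h / cell rate, triggered by the presence of local TGF-beta
#' (any nonzero count in the cell's 9-patch environment).
#'
#' @param state A `sim_state`.
#' @return Updated state.
#' @export
release_tnfa <- function(state) {
  cfg <- state$cfg
  n <- state$frame$n
  if (length(state$leuk$kind) == 0) {
    state$tn_emitted <- 0L
    return(state)
  }
  tg_local <- tg_local_field(state)
  pos <- leuk_patch(state)
  on <- tg_local[pos] > 0
  if (!any(on)) {
    state$tn_emitted <- 0L
    return(state)
  }
  k <- stats::rpois(sum(on), cfg$release_scale * quanta_per_cell_step(cfg))
  tot <- sum(k)
  if (tot > 0) {
    state$tn$pos <- c(state$tn$pos, rep.int(pos[on], k))
    state$tn$death <- c(state$tn$death,
                        rep.int(state$step + cfg$cytokine_life_steps, tot))
  }
  state$tn_emitted <- tot
  state$tn_total_emitted <- state$tn_total_emitted + tot
  state
}

#' Diffuse and decay cytokine quanta
#'
#' Each quantum performs one unbiased single-patch random-walk step (8
#' directions) restricted to wall tissue and lumen-adjacent patches; a move
#' onto a disallowed patch is rejected and the quantum stays. Quanta expire
#' after `cytokine_life_steps` steps (24 h by default). Mass is conserved up
#' to this decay.
#'
#' @param state A `sim_state`.
#' @return Updated state.
#' @export
diffuse_and_decay <- function(state) {
  n <- state$frame$n
  allowed <- boxsum3(tissue_mask(state)) > 0
  state$tg <- walk_quanta(state$tg, allowed, n, state$step)
  state$tn <- walk_quanta(state$tn, allowed, n, state$step)
  state$tg_decayed <- state$tg_decayed + attr(state$tg, "n_decayed")
  state$tn_decayed <- state$tn_decayed + attr(state$tn, "n_decayed")
  state
}

walk_quanta <- function(q, allowed, n, step) {
  m <- length(q$pos)
  if (m > 0) {
    off <- c(-1L, 1L, -n, n, -n - 1L, -n + 1L, n - 1L, n + 1L)
    cand <- q$pos + sample(off, m, replace = TRUE)
    ok <- cand >= 1L & cand <= n * n
    ok[ok] <- allowed[cand[ok]]
    q$pos[ok] <- cand[ok]
  }
  keep <- q$death > step
  out <- list(pos = q$pos[keep], death = q$death[keep])
  attr(out, "n_decayed") <- sum(!keep)
  out
}

# solid-tissue mask: the initial wall annulus, every patch holding SMCs,
# plaque, and struts
tissue_mask <- function(state) {
  if (!is.null(state$.tis)) return(state$.tis)
  state$wall0 | state$strut | state$plaque |
    (state$S_int + state$S_med + state$S_adv + state$S_mig) > 0L
}
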