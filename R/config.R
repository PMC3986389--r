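#' Build a vessel/stent scenario configuration
#'
#' Assembles every parameter needed to initialise and run a simulation of the
#' vascular response to angioplasty plus bare-metal stent deployment: the
#' post-procedural vessel geometry, the stent layout, and the biological rate
#' constants governing the cellular agents and cytokine fields.
#'
#' The lattice is fixed at 150 x 150 patches, one patch side representing
#' 0.05 mm, and one time step representing 6 hours. The post-procedural lumen
#' is assumed circular; struts are evenly spaced around its boundary. When
#' `wall_thickness_mm` is not given it defaults to the lumen radius (a 1:1
#' lumen-radius to wall-thickness ratio). Exactly one of `struts_per_stent`
#' and `strut_spacing_mm` may be set; with neither, 20 struts per stent are
#' used. With a spacing, the strut count is the lumen circumference divided by
#' the spacing, rounded to the nearest integer.
#'
#' Biological defaults follow the model's parameter table: TGF-beta and
#' TNF-alpha release at 0.02 pg / 10 hours / cell, SMC TGF-beta sensitivity
#' 3 ng/ml, SMC/EC TNF-alpha sensitivity 4 ng/ml with apoptosis capped at 15%
#' of the local population per exposure, SMC population doubling every 30 h,
#' SMC migration 20 um/h, leukocyte migration 1 um/min, lifespans of 5-10 days
#' (platelets), 3 days (monocytes), 45 days (macrophages) and 5 days
#' (neutrophils), and at most 15 SMC agents per patch.
#'
#' @param lumen_diameter_mm Post-procedural lumen diameter (mm). Required.
#' @param wall_thickness_mm Vessel wall thickness (mm); `NULL` uses the
#'   default, equal to the lumen radius.
#' @param stent_count Number of (concentric, overlapping) stents, 1 or 2.
#' @param struts_per_stent Number of struts per stent; `NULL` to derive from
#'   `strut_spacing_mm` or fall back to the default of 20.
#' @param strut_spacing_mm Arc spacing between adjacent struts (mm); mutually
#'   exclusive with `struts_per_stent`.
#' @param strut_size_mm Side length of the square strut cross-section (mm).
#' @param arrangement Strut arrangement for two stents: `"staggered"` (inner
#'   struts midway between adjacent outer struts) or `"aligned"`.
#' @param stent_length_mm Stent length (mm); recorded as scenario metadata
#'   only, the model simulates a single cross-section.
#' @param plaque_box Plaque bounding box `c(x1, x2, y1, y2)` in lattice
#'   coordinates, or `NULL` for the default bottom-left arc. The plaque is
#'   clipped to the band between the intimal and medial layers so that it
#'   neither protrudes into the lumen nor overlaps a strut.
#' @param seed Integer RNG seed stored with the scenario.
#' @param ... Overrides for the advanced parameters listed in
#'   [default_parameters()] (rate constants, calibration constants, initial
#'   densities, stopping-rule settings).
#'
#' @return An object of class `vessel_config`: a named list of validated
#'   parameters.
#' @examples
#' cfg <- vessel_config(lumen_diameter_mm = 2.9)
#' cfg$wall_thickness_mm   # defaults to the lumen radius, 1.45
#' cfg$struts_per_stent    # defaults to 20
#' @export
vessel_config <- function(lumen_diameter_mm,
                          wall_thickness_mm = NULL,
                          stent_count = 1L,
                          struts_per_stent = NULL,
                          strut_spacing_mm = NULL,
                          strut_size_mm = 0.1,
                          arrangement = c("staggered", "aligned"),
                          stent_length_mm = 15,
                          plaque_box = NULL,
                          seed = 1L,
                          ...) {
  arrangement <- match.arg(arrangement)
  if (!is.numeric(lumen_diameter_mm) || length(lumen_diameter_mm) != 1L ||
      lumen_diameter_mm <= 0) {
    stop("`lumen_diameter_mm` must be a single positive number", call. = FALSE)
  }
  if (!stent_count %in% c(1L, 2L)) {
    stop("`stent_count` must be 1 or 2", call. = FALSE)
  }
  if (!is.null(struts_per_stent) && !is.null(strut_spacing_mm)) {
    stop("set at most one of `struts_per_stent` and `strut_spacing_mm`",
         call. = FALSE)
  }
  wall_thickness_mm <- default_wall_thickness(lumen_diameter_mm,
                                              wall_thickness_mm)
  p <- default_parameters()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots

  n_struts <- if (!is.null(struts_per_stent)) {
    as.integer(struts_per_stent)
  } else if (!is.null(strut_spacing_mm)) {
    strut_count_from_spacing(lumen_diameter_mm, strut_spacing_mm)
  } else {
    20L
  }
  if (n_struts < 1L) stop("need at least one strut per stent", call. = FALSE)

  cfg <- c(list(
    lumen_diameter_mm = lumen_diameter_mm,
    wall_thickness_mm = wall_thickness_mm,
    stent_count = as.integer(stent_count),
    struts_per_stent = n_struts,
    strut_size_mm = strut_size_mm,
    arrangement = arrangement,
    stent_length_mm = stent_length_mm,
    plaque_box = plaque_box,
    seed = as.integer(seed)
  ), p)
  class(cfg) <- "vessel_config"
  validate_config(cfg)
  cfg
}

#' Advanced model parameters and their defaults
#'
#' Returns the full list of rate constants, unit conversions, calibration
#' constants and engine settings that [vessel_config()] accepts as overrides.
#' Values marked "Table-derived" are direct unit conversions of published cell
#' biology measurements; the remainder are model calibration constants frozen
#' in the default configuration.
#'
#' @return Named list of parameter defaults.
#' @details
#' Lattice and clock: `grid_n` (150), `patch_mm` (0.05), `step_hours` (6),
#' `steps_per_day` (4), `n_bins` (angular resolution of the lumen boundary,
#' 360), `diameter_rays` (number of centre rays used for the minimum-diameter
#' scan, 180).
#'
#' Cytokines: `release_pg_per_10h` (0.02), `quantum_pg` (0.003; a cell
#' releasing at the nominal rate emits 0.012 pg = 4 quanta per 6-h step),
#' `patch_thickness_C_mm` (the constant C in the local measurement volume
#' V = C x AP; the default makes one local quantum 1/18 ng/ml, so the
#' proliferation and apoptosis thresholds sit at 54 and 72 local quanta),
#' `cytokine_life_steps` (4, a 24-h quantum lifetime), thresholds
#' `tgfb_threshold_ngml` (3), `tnfa_threshold_ngml` (4),
#' `recruit_threshold_quanta` (1, the femtomolar-scale recruitment trigger),
#' `serum_cap_ngml` (10), `wound_release_factor` (cells in injured
#' territory release at this multiple of the basal rate), `injury_factor`
#' (additional release multiplier at strut injuries), `surface_release_cap`
#' (at most this many SMC/EC per patch are signalling-active; deeper cells
#' are quiescent), `hoop_knee`/`hoop_exponent` (the saturating power-law
#' coupling of hoop stress to TGF-beta release: full rate while the local
#' lumen radius exceeds `hoop_knee` of its initial value, then falling as
#' the ratio to the knee raised to `hoop_exponent`), `platelet_release_d`
#' (days an activated platelet degranulates).
#'
#' Cells: `smc_doubling_h` (30), `smc_migration_um_h` (20),
#' `leukocyte_um_min` (1), `apoptosis_cap_frac` (0.15), `smc_per_patch` (15),
#' lifespans in days (`platelet_life_d` = c(5, 10), `monocyte_life_d` = 3,
#' `macrophage_life_d` = 45, `neutrophil_life_d` = 5).
#'
#' Initial state: `intima_frac`/`media_frac` (wall layer fractions),
#' `intimal_smc_per_patch` (sparse intimal seeding, 1 SMC per 3 patches),
#' `media_density`/`adventitia_density` (SMCs per patch), `denuded_frac`
#' (fraction of the EC ring injured at t = 0), `plaque_arc_deg`,
#' `plaque_radial_patches`, `n_platelets` (circulating latent pool).
#'
#' Calibration/engine: `recruit_rate` (leukocytes spawned per triggering
#' step), `mac_strut_frac` (fraction of new macrophages residing at struts),
#' `chemotaxis_bias`, `p_ec_heal` (per-step EC recovery probability where
#' TGF-beta is detectable), `p_ec_base` (baseline EC recovery),
#' `mac_strut_residence_d` (days a foreign-body macrophage stays at its
#' strut before rejoining the wandering population),
#' `max_days` (hard cap, 400), `confirm_days` (60-day post-stabilisation
#' confirmation window), `release_scale` (global release-rate multiplier,
#' 1 = the published rate).
#' @export
default_parameters <- function() {
  list(
    # lattice and clock
    grid_n = 150L,
    patch_mm = 0.05,
    step_hours = 6,
    steps_per_day = 4L,
    n_bins = 360L,
    diameter_rays = 180L,
    # cytokine measurement and release (Table-derived)
    release_pg_per_10h = 0.02,
    quantum_pg = 0.003,
    patch_thickness_C_mm = 2.4,  # with the 0.003 pg quantum: 1 local quantum = 1/18 ng/ml
    cytokine_life_steps = 4L,
    tgfb_threshold_ngml = 3,
    tnfa_threshold_ngml = 4,
    recruit_threshold_quanta = 1L,
    serum_cap_ngml = 10,
    injury_factor = 1.22,
    hoop_exponent = 12,
    hoop_knee = 0.72,
    wound_release_factor = 1.132,
    release_scale = 1,
    surface_release_cap = 1L,
    # cell rates (Table-derived)
    smc_doubling_h = 30,
    smc_migration_um_h = 20,
    leukocyte_um_min = 1,
    apoptosis_cap_frac = 0.15,
    smc_per_patch = 15L,
    platelet_life_d = c(5, 10),
    platelet_release_d = 1.5,
    monocyte_life_d = 3,
    macrophage_life_d = 45,
    neutrophil_life_d = 5,
    # initial state
    intima_frac = 0.1,
    media_frac = 0.6,
    intimal_smc_per_patch = 1 / 3,
    media_density = 5L,
    adventitia_density = 5L,
    denuded_frac = 1,
    plaque_arc_deg = 30,
    plaque_radial_patches = 4L,
    n_platelets = 90L,
    # calibration and engine settings
    recruit_rate = 3,
    mac_strut_frac = 0.85,
    mac_strut_residence_d = 15,
    chemotaxis_bias = 0.8,
    p_ec_heal = 0.021,
    p_ec_base = 0.01,
    max_days = 400L,
    confirm_days = 60L
  )
}

validate_config <- function(cfg) {
  half_grid_mm <- (cfg$grid_n / 2 - 1) * cfg$patch_mm
  outer_mm <- cfg$lumen_diameter_mm / 2 + cfg$wall_thickness_mm
  if (outer_mm > half_grid_mm) {
    stop(sprintf(
      "vessel does not fit the %dx%d grid: lumen radius + wall = %.2f mm > %.2f mm",
      cfg$grid_n, cfg$grid_n, outer_mm, half_grid_mm), call. = FALSE)
  }
  stopifnot(cfg$strut_size_mm > 0, cfg$wall_thickness_mm > 0)
  invisible(cfg)
}

#' @export
print.vessel_config <- function(x, ...) {
  cat("<vessel_config>\n")
  cat(sprintf("  lumen diameter : %.2f mm (radius %.1f patches)\n",
              x$lumen_diameter_mm, mm_to_units(x$lumen_diameter_mm / 2)))
  cat(sprintf("  wall thickness : %.2f mm\n", x$wall_thickness_mm))
  cat(sprintf("  stents         : %d x %d struts (%.2f mm, %s)\n",
              x$stent_count, x$struts_per_stent, x$strut_size_mm,
              x$arrangement))
  cat(sprintf("  seed           : %d\n", x$seed))
  invisible(x)
}
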