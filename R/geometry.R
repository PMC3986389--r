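#' Unit conversions between millimetres and lattice units
#'
#' One lattice distance unit (one patch side) represents 0.05 mm in vivo.
#'
#' @param length_mm Length in millimetres (non-negative).
#' @param units Length in lattice units (non-negative).
#' @param patch_mm Patch side length in mm.
#' @return The converted length.
#' @examples
#' mm_to_units(2.9)   # 58 lattice units
#' units_to_mm(1)     # 0.05 mm
#' @export
mm_to_units <- function(length_mm, patch_mm = 0.05) {
  if (any(length_mm < 0)) stop("length must be non-negative", call. = FALSE)
  length_mm / patch_mm
}

#' @rdname mm_to_units
#' @export
units_to_mm <- function(units, patch_mm = 0.05) {
  if (any(units < 0)) stop("length must be non-negative", call. = FALSE)
  units * patch_mm
}

#' Default vessel wall thickness
#'
#' Imaging studies rarely report the outer vessel diameter, so the default
#' wall thickness equals the post-procedural lumen radius (a 1:1
#' radius-to-wall ratio typical of coronary arteries). An explicit value
#' passes through unchanged.
#'
#' @param lumen_diameter_mm Post-procedural lumen diameter (mm, positive).
#' @param wall_thickness_mm Optional explicit thickness (mm).
#' @return Wall thickness in mm.
#' @examples
#' default_wall_thickness(2.9)        # 1.45
#' default_wall_thickness(2.9, 1.2)   # explicit override: 1.2
#' @export
default_wall_thickness <- function(lumen_diameter_mm, wall_thickness_mm = NULL) {
  if (lumen_diameter_mm <= 0) stop("lumen diameter must be positive", call. = FALSE)
  if (is.null(wall_thickness_mm)) lumen_diameter_mm / 2 else wall_thickness_mm
}

#' Number of struts implied by an inter-strut spacing
#'
#' Divides the post-stenting lumen circumference by the requested arc spacing
#' and rounds to the nearest integer. A spacing wider than the circumference
#' clamps to a single strut with a warning.
#'
#' @param lumen_diameter_mm Post-procedural lumen diameter (mm).
#' @param spacing_mm Arc spacing between adjacent struts (mm, positive).
#' @return Integer strut count (>= 1).
#' @examples
#' strut_count_from_spacing(2.9, 0.4556)  # 20
#' @export
strut_count_from_spacing <- function(lumen_diameter_mm, spacing_mm) {
  if (spacing_mm <= 0) stop("spacing must be positive", call. = FALSE)
  n <- round(pi * lumen_diameter_mm / spacing_mm)
  if (n < 1) {
    warning("spacing exceeds the lumen circumference; using a single strut")
    n <- 1
  }
  as.integer(n)
}

#' Polar strut layout for one or two stents
#'
#' Struts of a stent are evenly spaced in angle around the post-stenting
#' lumen boundary. With two (overlapping) stents the second ring sits
#' radially adjacent, inside the first; its struts share the outer angles
#' (`"aligned"`) or are offset by half the angular pitch (`"staggered"`,
#' each inner strut midway between two adjacent outer struts).
#'
#' @param config A [vessel_config()].
#' @return A `strut_layout`: tibble with one row per strut (columns `stent`,
#'   `angle` in radians, `radius_units`, `side_units`).
#' @examples
#' layout <- build_strut_layout(vessel_config(2.9))
#' nrow(layout)  # 20
#' @export
build_strut_layout <- function(config) {
  n <- config$struts_per_stent
  side <- mm_to_units(config$strut_size_mm, config$patch_mm)
  r0 <- mm_to_units(config$lumen_diameter_mm / 2, config$patch_mm)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  out <- tibble::tibble(stent = 1L, angle = ang, radius_units = r0,
                        side_units = side)
  if (config$stent_count == 2L) {
    ang2 <- if (config$arrangement == "staggered") ang + pi / n else ang
    out <- dplyr::bind_rows(out, tibble::tibble(
      stent = 2L, angle = ang2 %% (2 * pi),
      radius_units = r0 - side, side_units = side))
  }
  class(out) <- c("strut_layout", class(out))
  out
}

# Precomputed lattice frame: distances, angles, angular-bin rays, and the
# one-patch-inward neighbour map used for SMC migration and crowding.
# Memoised per (grid size, bin count): the frame is pure geometry.
.frame_cache <- new.env(parent = emptyenv())

lattice_frame <- function(cfg) {
  key <- paste(cfg$grid_n, cfg$n_bins, sep = "_")
  hit <- .frame_cache[[key]]
  if (!is.null(hit)) return(hit)
  frame <- lattice_frame_build(cfg)
  .frame_cache[[key]] <- frame
  frame
}

lattice_frame_build <- function(cfg) {
  n <- cfg$grid_n
  cx <- (n + 1) / 2
  xs <- rep(seq_len(n), each = n)   # column (x)
  ys <- rep(seq_len(n), times = n)  # row (y)
  dx <- xs - cx
  dy <- ys - cx
  D <- sqrt(dx^2 + dy^2)
  TH <- atan2(dy, dx) %% (2 * pi)
  nb <- cfg$n_bins
  bin <- pmin(floor(TH / (2 * pi) * nb) + 1L, nb)

  # one-patch step toward the vessel axis (8-neighbourhood)
  sx <- ifelse(D > 0, round(-dx / pmax(abs(dx), abs(dy), 1e-9)), 0)
  sy <- ifelse(D > 0, round(-dy / pmax(abs(dx), abs(dy), 1e-9)), 0)
  inward1 <- as.integer((xs + sx - 1) * n + (ys + sy))

  # the three lumen-ward-most neighbours of every patch (for crowding
  # displacement: surplus spreads laterally instead of forming radial spikes)
  offx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  offy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  N <- n * n
  inward3 <- matrix(NA_integer_, N, 3)
  nbD <- matrix(Inf, N, 8)
  nbI <- matrix(NA_integer_, N, 8)
  for (k in 1:8) {
    nx <- xs + offx[k]
    ny <- ys + offy[k]
    okk <- nx >= 1 & nx <= n & ny >= 1 & ny <= n
    id <- ifelse(okk, (nx - 1L) * n + ny, NA_integer_)
    nbI[, k] <- id
    nbD[okk, k] <- D[id[okk]]
  }
  ordk <- t(apply(nbD, 1, order))[, 1:3]
  for (j in 1:3) {
    inward3[, j] <- nbI[cbind(seq_len(N), ordk[, j])]
  }

  rmax <- n / 2 - 2
  keep <- which(D >= 1 & D <= rmax)
  ord <- keep[order(D[keep])]
  rays <- split(ord, bin[ord])          # each ray sorted by increasing D
  rays <- rays[as.character(seq_len(nb))]

  list(n = n, cx = cx, D = D, TH = TH, bin = bin, inward1 = inward1,
       inward3 = inward3, rays = rays, nb = nb,
       Dm = matrix(D, n, n), binm = matrix(bin, n, n))
}

# Innermost tissue patch per angular bin. Returns list(idx, r); bins whose
# ray holds no tissue (should not happen for a valid annulus) get NA.
scan_frontier <- function(frame, tissue) {
  idx <- unname(vapply(frame$rays, function(v) {
    j <- match(TRUE, tissue[v])
    if (is.na(j)) NA_integer_ else v[j]
  }, integer(1)))
  r <- ifelse(is.na(idx), NA_real_, frame$D[idx])
  list(idx = idx, r = r)
}

#' Construct the initial post-intervention simulation state
#'
#' Builds the cross-section immediately after angioplasty and stenting:
#' concentric annuli around the vessel axis (lumen; intima with a single-cell
#' EC monolayer and sparse SMCs; SMC-filled media and adventitia), plaque
#' agents between the intimal and medial layers, stent struts embedded at the
#' lumen boundary, circulating latent platelets in the lumen, and the injury
#' map created by the procedure (the denuded EC ring, with struts as deeper
#' injuries).
#'
#' @param config A [vessel_config()].
#' @return A `sim_state` list holding the lattice frame, agent registries,
#'   cytokine fields, injury map, and clock (day 0).
#' @export
build_initial_state <- function(config) {
  cfg <- config
  frame <- lattice_frame(cfg)
  n <- frame$n
  r0 <- mm_to_units(cfg$lumen_diameter_mm / 2, cfg$patch_mm)
  w <- mm_to_units(cfg$wall_thickness_mm, cfg$patch_mm)
  if (r0 + w > n / 2 - 2) stop("vessel does not fit the grid", call. = FALSE)

  ti <- max(1, cfg$intima_frac * w)
  tm <- cfg$media_frac * w
  D <- frame$D
  intima <- D >= r0 & D < r0 + ti
  media <- D >= r0 + ti & D < r0 + ti + tm
  advent <- D >= r0 + ti + tm & D < r0 + w
  wall0 <- D >= r0 & D < r0 + w

  zero <- matrix(0L, n, n)
  S_int <- S_med <- S_adv <- S_mig <- zero
  S_int[intima] <- stats::rbinom(sum(intima), 1L, cfg$intimal_smc_per_patch)
  S_med[media] <- cfg$media_density
  S_adv[advent] <- cfg$adventitia_density

  # struts: 2x2-ish blocks of patches nearest each strut centre
  layout <- build_strut_layout(cfg)
  strut <- matrix(FALSE, n, n)
  strut_info <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    # struts are pressed into the wall: the exterior stent sits flush with
    # the lumen boundary, an interior (second) stent radially adjacent
    r <- layout$radius_units[i] +
      layout$side_units[i] / 2 * (if (layout$stent[i] == 1L) 1 else -1)
    a <- layout$angle[i]
    sxc <- frame$cx + r * cos(a)
    syc <- frame$cx + r * sin(a)
    k <- max(2L, ceiling(layout$side_units[i]))
    cols <- round(sxc - 0.5) + seq_len(k) - floor(k / 2)
    rows <- round(syc - 0.5) + seq_len(k) - floor(k / 2)
    idx <- as.integer(outer(rows, (cols - 1) * n, `+`))
    idx <- idx[idx >= 1 & idx <= n * n]
    strut[idx] <- TRUE
    strut_info[[i]] <- list(
      patches = idx,
      bins = unique(frame$bin[idx]),
      inner_r = min(D[idx]),
      stent = layout$stent[i])
  }

  # plaque: default bottom-left arc between intima and media, clipped so it
  # neither protrudes into the lumen nor overlaps a strut
  plaque <- matrix(FALSE, n, n)
  band <- D >= r0 + ti & D < r0 + ti + cfg$plaque_radial_patches
  if (is.null(cfg$plaque_box)) {
    half <- cfg$plaque_arc_deg / 2 * pi / 180
    ctr <- 225 * pi / 180
    dang <- abs(((frame$TH - ctr + pi) %% (2 * pi)) - pi)
    sel <- band & dang <= half
  } else {
    b <- cfg$plaque_box
    xs <- rep(seq_len(n), each = n)
    ys <- rep(seq_len(n), times = n)
    sel <- band & xs >= b[1] & xs <= b[2] & ys >= b[3] & ys <= b[4]
  }
  plaque[sel & !strut] <- TRUE

  # struts are solid metal: no SMC occupies a strut patch
  S_int[strut] <- 0L
  S_med[strut] <- 0L
  S_adv[strut] <- 0L

  tissue <- wall0 | strut | plaque
  fro <- scan_frontier(frame, tissue)

  # EC monolayer on the lumen-facing frontier; struts crush the ECs they
  # cover, and a `denuded_frac` fraction of the remaining ring is injured
  nb <- frame$nb
  strut_bins <- unlist(lapply(strut_info, function(s)
    if (s$stent == 1L) s$bins else integer(0)))
  ec_present <- rep(TRUE, nb)
  ec_present[strut_bins] <- FALSE
  ec_healthy <- ec_present & stats::runif(nb) > cfg$denuded_frac

  # circulating latent platelet pool
  lumen_idx <- which(D < r0 - 1)
  np <- cfg$n_platelets
  platelets <- list(
    pos = sample(lumen_idx, np, replace = TRUE),
    active = rep(FALSE, np),
    act_step = rep(NA_integer_, np),
    death = sample(seq(cfg$platelet_life_d[1] * cfg$steps_per_day,
                       cfg$platelet_life_d[2] * cfg$steps_per_day), np,
                   replace = TRUE))

  # latent TGF-beta seeded at the procedural injury sites
  inj0 <- which(strut)
  tg <- list(pos = inj0, death = rep(cfg$cytokine_life_steps, length(inj0)))

  state <- list(
    cfg = cfg, frame = frame,
    r0 = r0, w = w, ti = ti,
    S_int = S_int, S_med = S_med, S_adv = S_adv, S_mig = S_mig,
    strut = strut, strut_info = strut_info,
    strut_healed = rep(FALSE, length(strut_info)),
    plaque = plaque, wall0 = wall0,
    ec_present = ec_present, ec_healthy = ec_healthy,
    frontier_idx = fro$idx, fr = fro$r,
    platelets = platelets,
    leuk = list(kind = integer(0), x = numeric(0), y = numeric(0),
                death = integer(0), fixed = logical(0),
                strut = integer(0), until = integer(0)),
    tg = tg,
    tn = list(pos = integer(0), death = integer(0)),
    tg_emitted = 0L, tn_emitted = 0L,
    tg_total_emitted = 0, tn_total_emitted = 0,
    tg_decayed = 0, tn_decayed = 0,
    step = 0L, last_emit = 0L, occluded = FALSE)
  class(state) <- "sim_state"
  state
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state>\n")
  cat(sprintf("  day %.2f (step %d)%s\n", x$step / x$cfg$steps_per_day,
              x$step, if (x$occluded) " [occluded]" else ""))
  cat(sprintf("  SMC %d | EC %d | leukocytes %d | TGF-b quanta %d | TNF-a quanta %d\n",
              sum(x$S_int) + sum(x$S_med) + sum(x$S_adv) + sum(x$S_mig),
              ec_count(x), length(x$leuk$kind),
              length(x$tg$pos), length(x$tn$pos)))
  cat(sprintf("  min lumen diameter %.2f mm\n", min_lumen_diameter(x)))
  invisible(x)
}

# number of distinct frontier patches currently carrying an EC
ec_count <- function(state) {
  length(unique(state$frontier_idx[state$ec_present &
                                     !is.na(state$frontier_idx)]))
}
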