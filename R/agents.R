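# Cellular agent rules: platelets, leukocytes, SMCs, ECs.
#
# Leukocyte kinds: 1 = monocyte, 2 = neutrophil, 3 = macrophage riding the
# wound frontier, 4 = macrophage resident at a stent strut (foreign-body
# response). Kinds 2 (once attached) and 4 are immobile.

leuk_patch <- function(state) {
  n <- state$frame$n
  x <- pmin(pmax(round(state$leuk$x), 1L), n)
  y <- pmin(pmax(round(state$leuk$y), 1L), n)
  as.integer((x - 1L) * n + y)
}

current_lumen_idx <- function(state) {
  which(!tissue_mask(state) & state$frame$D < state$r0 - 0.5)
}

#' Advance the platelet population one step
#'
#' Latent platelets random-walk one patch within the lumen; a latent
#' platelet whose local environment (its patch plus 8 neighbours) contains an
#' injury site or an activated platelet becomes activated and stops moving,
#' joining the thrombus. Platelets past their lifespan (drawn uniformly from
#' 5-10 days at creation) are removed and replaced by a fresh circulating
#' latent platelet, keeping the circulating pool at its nominal size.
#'
#' @param state A `sim_state`.
#' @return Updated state.
#' @export
step_platelets <- function(state) {
  cfg <- state$cfg
  n <- state$frame$n
  p <- state$platelets
  lumen <- current_lumen_idx(state)
  if (length(lumen) == 0) return(state)

  # lifespan turnover: dead platelets (latent or thrombus-bound) are
  # replaced by new circulating latent platelets
  dead <- p$death <= state$step
  if (any(dead)) {
    k <- sum(dead)
    p$pos[dead] <- sample(lumen, k, replace = TRUE)
    p$active[dead] <- FALSE
    p$act_step[dead] <- NA_integer_
    spd <- cfg$steps_per_day
    p$death[dead] <- state$step +
      sample(seq(cfg$platelet_life_d[1] * spd, cfg$platelet_life_d[2] * spd),
             k, replace = TRUE)
  }

  # unbiased random walk for latent platelets, rejected at tissue
  lat <- which(!p$active)
  if (length(lat) > 0) {
    off <- c(-1L, 1L, -n, n, -n - 1L, -n + 1L, n - 1L, n + 1L)
    cand <- p$pos[lat] + sample(off, length(lat), replace = TRUE)
    ok <- cand >= 1L & cand <= n * n
    ok[ok] <- !tissue_mask(state)[cand[ok]]
    p$pos[lat[ok]] <- cand[ok]
  }

  # contact activation by injury sites or the growing thrombus; once the
  # wound is re-endothelialised the exposed surface is gone, so a residual
  # thrombus no longer recruits and simply decays with platelet turnover
  inj <- injury_map(state)
  near_inj <- injury_adj(state)
  act_src <- inj
  live_thrombus <- p$pos[p$active]
  live_thrombus <- live_thrombus[near_inj[live_thrombus]]
  act_src[live_thrombus] <- TRUE
  near <- boxsum3(act_src) > 0
  turn <- !p$active & near[p$pos]
  p$active[turn] <- TRUE
  p$act_step[turn] <- state$step

  state$platelets <- p
  state
}

#' Recruit circulating leukocytes
#'
#' While the local TGF-beta concentration anywhere on the intimal (wound)
#' boundary exceeds the femtomolar-scale recruitment threshold, circulating
#' monocytes and neutrophils appear in the lumen at `recruit_rate` of each
#' per step.
#'
#' @param state A `sim_state`.
#' @return Updated state.
#' @export
maybe_recruit_leukocytes <- function(state) {
  cfg <- state$cfg
  n <- state$frame$n
  if (length(state$tg$pos) == 0) return(state)
  tg_local <- tg_local_field(state)
  fidx <- state$frontier_idx[!is.na(state$frontier_idx)]
  if (!any(tg_local[fidx] >= cfg$recruit_threshold_quanta)) return(state)

  # recruitment scales with the remaining wound burden, so inflammation
  # subsides as re-endothelialisation proceeds
  inj_frac <- (sum(!state$ec_healthy) + 2 * sum(!state$strut_healed)) /
    state$frame$nb
  rate <- cfg$recruit_rate * min(1, inj_frac)
  k <- floor(rate) + (stats::runif(1) < rate - floor(rate))
  if (k <= 0) return(state)
  lumen <- current_lumen_idx(state)
  if (length(lumen) == 0) return(state)
  spawn <- function(kind, life_d) {
    pos <- sample(lumen, k, replace = TRUE)
    list(kind = rep(kind, k),
         x = ((pos - 1L) %/% n) + 1 + stats::runif(k, -0.4, 0.4),
         y = ((pos - 1L) %% n) + 1 + stats::runif(k, -0.4, 0.4),
         death = rep(state$step + round(life_d * cfg$steps_per_day), k),
         fixed = rep(FALSE, k),
         strut = rep(NA_integer_, k),
         until = rep(NA_integer_, k))
  }
  new <- mapply(c, spawn(1L, cfg$monocyte_life_d),
                spawn(2L, cfg$neutrophil_life_d), SIMPLIFY = FALSE)
  state$leuk <- mapply(c, state$leuk, new, SIMPLIFY = FALSE)
  state
}

#' Advance monocytes, neutrophils and macrophages one step
#'
#' Mobile leukocytes move 1 um/min (360 um = 7.2 patches per 6-h step) as a
#' biased random walk toward the wounded wall. A neutrophil that meets an
#' activated platelet attaches to the thrombus and stops. A monocyte that
#' crosses the thrombus and reaches wall tissue matures into a macrophage; a
#' fraction `mac_strut_frac` of new macrophages take up residence at the
#' nearest unhealed stent strut (foreign-body response), the rest patrol the
#' wound frontier. Agents past their lifespan are removed.
#'
#' @param state A `sim_state`.
#' @return Updated state.
#' @export
step_leukocytes <- function(state) {
  cfg <- state$cfg
  n <- state$frame$n
  L <- state$leuk
  if (length(L$kind) == 0) return(state)

  keep <- L$death > state$step
  L <- lapply(L, `[`, keep)
  m <- length(L$kind)
  if (m == 0) { state$leuk <- L; return(state) }

  cx <- state$frame$cx
  speed <- cfg$leukocyte_um_min * 60 * cfg$step_hours / (cfg$patch_mm * 1000)
  mob <- which(!L$fixed & L$kind %in% c(1L, 2L))
  if (length(mob) > 0) {
    dx <- L$x[mob] - cx
    dy <- L$y[mob] - cx
    r <- pmax(sqrt(dx^2 + dy^2), 1e-6)
    ang_out <- atan2(dy, dx)
    rnd <- stats::runif(length(mob)) > cfg$chemotaxis_bias
    ang <- ifelse(rnd, stats::runif(length(mob), 0, 2 * pi), ang_out)
    nx <- L$x[mob] + speed * cos(ang)
    ny <- L$y[mob] + speed * sin(ang)
    # clamp at the lumen boundary of the agent's angular bin
    nr <- sqrt((nx - cx)^2 + (ny - cx)^2)
    nang <- atan2(ny - cx, nx - cx) %% (2 * pi)
    bins <- pmin(floor(nang / (2 * pi) * state$frame$nb) + 1L, state$frame$nb)
    fb <- state$fr[bins]
    fb[is.na(fb)] <- state$r0
    hit <- nr >= fb - 0.5
    sc <- ifelse(hit, (fb - 0.6) / nr, 1)
    L$x[mob] <- cx + (nx - cx) * sc
    L$y[mob] <- cx + (ny - cx) * sc
    attr(L, "hit_idx") <- mob[hit]
  }

  pos <- {
    x <- pmin(pmax(round(L$x), 1L), n)
    y <- pmin(pmax(round(L$y), 1L), n)
    as.integer((x - 1L) * n + y)
  }

  # neutrophil attachment to the thrombus
  plat_act <- count_field(state$platelets$pos[state$platelets$active], n)
  near_thrombus <- boxsum3(plat_act) > 0
  att <- L$kind == 2L & !L$fixed & near_thrombus[pos]
  L$fixed[att] <- TRUE

  # monocyte maturation on reaching the wall
  hit_idx <- attr(L, "hit_idx")
  mat <- intersect(hit_idx, which(L$kind == 1L))
  if (length(mat) > 0) {
    L$kind[mat] <- 3L
    L$death[mat] <- state$step + cfg$macrophage_life_d * cfg$steps_per_day
    to_strut <- mat[stats::runif(length(mat)) < cfg$mac_strut_frac]
    open <- which(!state$strut_healed)
    if (length(to_strut) > 0 && length(open) > 0) {
      ang_m <- atan2(L$y[to_strut] - cx, L$x[to_strut] - cx) %% (2 * pi)
      strut_ang <- vapply(state$strut_info[open], function(s) {
        p1 <- s$patches[1]
        state$frame$TH[p1]
      }, numeric(1))
      for (j in seq_along(to_strut)) {
        d <- abs(((strut_ang - ang_m[j] + pi) %% (2 * pi)) - pi)
        s <- state$strut_info[[open[which.min(d)]]]
        p1 <- s$patches[which.min(state$frame$D[s$patches])]
        L$x[to_strut[j]] <- ((p1 - 1L) %/% n) + 1
        L$y[to_strut[j]] <- ((p1 - 1L) %% n) + 1
        L$kind[to_strut[j]] <- 4L
        L$fixed[to_strut[j]] <- TRUE
        L$strut[to_strut[j]] <- open[which.min(d)]
        L$until[to_strut[j]] <- state$step +
          round(cfg$mac_strut_residence_d * cfg$steps_per_day)
      }
    }
  }

  # foreign-body macrophages rotate: after their residence period at a
  # strut they rejoin the wandering tissue population
  rot <- which(L$kind == 4L & !is.na(L$until) & L$until <= state$step)
  if (length(rot) > 0) {
    L$kind[rot] <- 3L
    L$fixed[rot] <- FALSE
    L$strut[rot] <- NA_integer_
    L$until[rot] <- NA_integer_
  }

  # tissue macrophages wander through the wall (a slow random walk through
  # dense tissue), dispersing away from the wound edge over time
  pat <- which(L$kind == 3L)
  if (length(pat) > 0) {
    tis <- tissue_mask(state)
    ang <- stats::runif(length(pat), 0, 2 * pi)
    step_len <- stats::runif(length(pat), 0, 2)
    nx <- L$x[pat] + step_len * cos(ang)
    ny <- L$y[pat] + step_len * sin(ang)
    px <- pmin(pmax(round(nx), 1L), n)
    py <- pmin(pmax(round(ny), 1L), n)
    okp <- tis[as.integer((px - 1L) * n + py)]
    L$x[pat[okp]] <- nx[okp]
    L$y[pat[okp]] <- ny[okp]
  }
  attr(L, "hit_idx") <- NULL
  state$leuk <- L
  state
}

#' Advance the SMC populations one step
#'
#' (a) Proliferation: an SMC on a patch whose local TGF-beta is at or above
#' the 3 ng/ml threshold divides with per-step probability
#' 2^(6/30) - 1 (population doubling every 30 h); injured intimal SMCs
#' produce two daughters per division. Daughters of medial divisions enter a
#' migrating pool. (b) Apoptosis: where local TNF-alpha is at or above
#' 4 ng/ml, SMCs die, capped at 15% of the local population per exposure
#' step. (c) Migration: migrating medial SMCs move lumen-ward at 20 um/h
#' (2.4 patches per step) and become intimal on reaching the wound frontier.
#' (d) Crowding: a patch holds at most 15 SMCs; the surplus is pushed one
#' patch lumen-ward (this is how the neointima advances). (e) Adventitial
#' SMCs never migrate inward; their surplus is lost to contact inhibition.
#'
#' @param state A `sim_state`.
#' @param tgfb_local,tnfa_local Local (9-patch) quantum-count matrices for
#'   the two cytokines, measured after diffusion this step.
#' @return Updated state.
#' @export
step_smc <- function(state, tgfb_local, tnfa_local) {
  cfg <- state$cfg
  n <- state$frame$n
  p_div <- 2^(cfg$step_hours / cfg$smc_doubling_h) - 1
  elig <- tgfb_local >= threshold_quanta(cfg, "tgfb")
  inj_adj <- injury_adj(state)
  # contact inhibition: intimal/neointimal SMCs proliferate only at the free
  # (lumen-facing) surface; deeper cells are quiescent
  tissue <- tissue_mask(state)
  at_surface <- boxsum3(!tissue) > 0

  divide <- function(S, gate = elig) {
    idx <- which(S > 0L & gate)
    if (length(idx) == 0) return(list(idx = integer(0), k = integer(0)))
    list(idx = idx, k = stats::rbinom(length(idx), S[idx], p_div))
  }
  d_int <- divide(state$S_int, elig & at_surface)
  if (length(d_int$idx) > 0) {
    two <- inj_adj[d_int$idx]
    state$S_int[d_int$idx] <- state$S_int[d_int$idx] +
      d_int$k * (1L + as.integer(two))
  }
  # medial proliferation is confined to the injured territory (strut
  # penetration); its daughters join the lumen-ward migrating pool
  d_med <- divide(state$S_med, elig & inj_adj)
  if (length(d_med$idx) > 0) {
    state$S_mig[d_med$idx] <- state$S_mig[d_med$idx] + d_med$k
  }
  d_mig <- divide(state$S_mig, elig & at_surface)
  if (length(d_mig$idx) > 0) {
    state$S_mig[d_mig$idx] <- state$S_mig[d_mig$idx] + d_mig$k
  }
  d_adv <- divide(state$S_adv, elig & inj_adj)
  if (length(d_adv$idx) > 0) {
    state$S_adv[d_adv$idx] <- pmin(state$S_adv[d_adv$idx] + d_adv$k,
                                   cfg$smc_per_patch)
  }

  # apoptosis under TNF-alpha, capped at 15% of the local population
  tot <- state$S_int + state$S_med + state$S_adv + state$S_mig
  apo <- which(tot > 0L & tnfa_local >= threshold_quanta(cfg, "tnfa"))
  if (length(apo) > 0) {
    n9 <- boxsum3(tot)
    cap <- floor(cfg$apoptosis_cap_frac * n9[apo])
    kills <- pmin(stats::rbinom(length(apo), tot[apo], cfg$apoptosis_cap_frac),
                  cap)
    for (f in c("S_int", "S_mig", "S_med", "S_adv")) {
      take <- pmin(state[[f]][apo], kills)
      state[[f]][apo] <- state[[f]][apo] - take
      kills <- kills - take
      if (all(kills == 0L)) break
    }
  }

  # lumen-ward migration of proliferating medial SMCs (2.4 patches/step)
  mig_idx <- which(state$S_mig > 0L)
  if (length(mig_idx) > 0) {
    counts <- state$S_mig[mig_idx]
    state$S_mig[mig_idx] <- 0L
    speed <- cfg$smc_migration_um_h * cfg$step_hours / (cfg$patch_mm * 1000)
    base <- floor(speed)
    frac <- speed - base
    src <- rep.int(mig_idx, counts)
    dest <- src
    for (s in seq_len(base)) {
      nxt <- state$frame$inward1[dest]
      blocked <- state$strut[nxt]
      dest[!blocked] <- nxt[!blocked]
    }
    extra <- stats::runif(length(dest)) < frac
    nxt <- state$frame$inward1[dest[extra]]
    ok2 <- !state$strut[nxt]
    dest[extra][ok2] <- nxt[ok2]
    # arrivals at (or past) the wound frontier become intimal SMCs
    b <- state$frame$bin[dest]
    fb <- state$fr[b]
    fb[is.na(fb)] <- 0
    at_front <- state$frame$D[dest] <= fb + 0.5
    over <- state$frame$D[dest] < fb - 0.5      # overshot into the lumen
    fix <- over & !is.na(state$frontier_idx[b])
    dest[fix] <- state$frontier_idx[b[fix]]
    arr_int <- tabulate(dest[at_front | fix], nbins = n * n)
    arr_mig <- tabulate(dest[!(at_front | fix)], nbins = n * n)
    state$S_int <- state$S_int + matrix(arr_int, n, n)
    state$S_mig <- state$S_mig + matrix(arr_mig, n, n)
  }

  state <- resolve_crowding(state)
  state
}

# Push per-patch SMC surplus (over the 15-agent cap) one patch lumen-ward.
# Surplus cells seek free capacity among the three most lumen-ward
# neighbours (least-occupied first), so displaced tissue spreads laterally
# along the ring instead of spiking radially. Adventitial SMCs never move;
# their surplus is lost to contact inhibition.
resolve_crowding <- function(state) {
  cfg <- state$cfg
  n <- state$frame$n
  cap <- cfg$smc_per_patch
  iw3 <- state$frame$inward3
  for (iter in 1:40) {
    tot <- state$S_int + state$S_med + state$S_adv + state$S_mig
    over <- which(tot > cap)
    if (length(over) == 0) break
    surplus <- tot[over] - cap
    moved <- integer(length(over))
    for (f in c("S_mig", "S_int", "S_med")) {
      take <- pmin(state[[f]][over], surplus)
      state[[f]][over] <- state[[f]][over] - take
      moved <- moved + take
      surplus <- surplus - take
      if (all(surplus == 0L)) break
    }
    if (any(surplus > 0L)) {
      state$S_adv[over] <- state$S_adv[over] - surplus   # contact-inhibited
    }
    for (j in seq_along(over)) {
      m <- moved[j]
      if (m == 0L) next
      cand <- iw3[over[j], ]
      cand <- cand[!is.na(cand)]
      cand <- cand[!state$strut[cand]]     # struts are impenetrable
      if (length(cand) == 0L) {
        nbr <- over[j] + c(-1L, 1L, -n, n, -n - 1L, -n + 1L, n - 1L, n + 1L)
        nbr <- nbr[nbr >= 1L & nbr <= n * n]
        cand <- nbr[!state$strut[nbr]]
      }
      while (m > 0L) {
        occ <- tot[cand]
        pick <- cand[which.min(occ)]
        room <- max(cap - tot[pick], 1L)
        put <- min(m, room)
        state$S_int[pick] <- state$S_int[pick] + put
        tot[pick] <- tot[pick] + put
        m <- m - put
      }
    }
  }
  state
}

#' Re-seat the endothelial monolayer and update injury flags
#'
#' ECs reside on the lumen-facing frontier of the tissue mass and move with
#' it. Frontier gaps re-endothelialise stochastically (faster where local
#' TGF-beta is above the proliferation threshold); damaged ECs recover the
#' same way, clearing the injury flag of their patch. ECs exposed to local
#' TNF-alpha at or above 4 ng/ml die (15% cap), re-opening injuries. A strut
#' becomes a healed, embedded foreign body once the frontier has advanced
#' covered by a restored EC monolayer stops acting as an injury. A
#' fully occluded lumen raises the occlusion flag.
#'
#' @inheritParams step_smc
#' @return Updated state.
#' @export
step_ec <- function(state, tgfb_local, tnfa_local) {
  cfg <- state$cfg
  fro <- scan_frontier(state$frame, tissue_mask(state))
  state$frontier_idx <- fro$idx
  state$fr <- fro$r

  half <- state$frame$nb %/% 2L
  pair_d <- fro$r[seq_len(half)] + fro$r[seq_len(half) + half]
  if (any(!is.na(pair_d)) && min(pair_d, na.rm = TRUE) <= 2) {
    state$occluded <- TRUE   # neointima has closed the lumen
    return(state)
  }

  fidx <- fro$idx
  okbin <- !is.na(fidx)
  tg <- tn <- rep(0, state$frame$nb)
  tg[okbin] <- tgfb_local[fidx[okbin]]
  tn[okbin] <- tnfa_local[fidx[okbin]]

  # TNF-alpha-driven EC death (apoptosis cap as per-EC probability)
  die <- state$ec_present & tn >= threshold_quanta(cfg, "tnfa") &
    stats::runif(state$frame$nb) < cfg$apoptosis_cap_frac
  state$ec_present[die] <- FALSE
  state$ec_healthy[die] <- FALSE

  # re-endothelialisation: spawn into gaps / recovery of damaged ECs.
  # Healing proceeds wherever wound signalling (any local TGF-beta) is
  # detectable, with a small baseline elsewhere.
  p_fix <- cfg$p_ec_base + cfg$p_ec_heal * (tg > 0)
  gap <- !state$ec_present & okbin
  fill <- gap & stats::runif(state$frame$nb) < p_fix
  state$ec_present[fill] <- TRUE
  state$ec_healthy[fill] <- TRUE
  hurt <- state$ec_present & !state$ec_healthy
  mend <- hurt & stats::runif(state$frame$nb) < p_fix
  state$ec_healthy[mend] <- TRUE

  # strut endothelialisation: a strut stops acting as an injury once a
  # restored EC monolayer covers its whole angular extent (whether or not
  # neointima has buried it more deeply)
  occupied <- unique(state$leuk$strut[state$leuk$kind == 4L])
  for (i in seq_along(state$strut_info)) {
    if (state$strut_healed[i]) next
    if (!(i %in% occupied) &&
        all(state$ec_healthy[state$strut_info[[i]]$bins])) {
      state$strut_healed[i] <- TRUE
    }
  }
  state
}
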