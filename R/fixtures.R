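# Deterministic micro-fixtures: small vessels with hand-placed agents and
# forced cytokine fields, so that every behavioural rule can be unit-tested
# through the production code paths without running a full simulation.

# a small vessel that fits a 40x40 grid (lumen radius 8, wall 8 patches)
micro_config <- function(seed = 42L, ...) {
  vessel_config(lumen_diameter_mm = 0.8, wall_thickness_mm = 0.4,
                seed = seed, grid_n = 40L, n_bins = 72L,
                diameter_rays = 36L, n_platelets = 20L,
                struts_per_stent = 4L, ...)
}

# force `k` quanta of a cytokine onto a patch
force_quanta <- function(state, field = c("tg", "tn"), patch, k,
                         life = 1000L) {
  field <- match.arg(field)
  state[[field]]$pos <- c(state[[field]]$pos, rep.int(as.integer(patch), k))
  state[[field]]$death <- c(state[[field]]$death,
                            rep.int(state$step + life, k))
  state
}

#' Construct a named deterministic micro-fixture
#'
#' Returns a reproducible micro-state (a small vessel on a 40x40 grid) with
#' hand-placed agents or forced cytokine fields, plus the bookkeeping needed
#' to assert the rule under test. Registered fixtures: `"empty"` (no mobile
#' agents, no cytokines), `"platelet_activation"` (a latent platelet beside
#' an injured strut), `"neutrophil_attachment"` (a neutrophil one patch from
#' an activated platelet), `"monocyte_maturation"` (a monocyte at the wall),
#' `"crowding"` (a patch overfilled with 16 SMCs), `"threshold"` (forced
#' local TGF-beta one quantum below / exactly at the proliferation
#' threshold), `"apoptosis_cap"` (20 SMCs under threshold TNF-alpha),
#' `"ec_tracking"`
#' (an SMC bulge one patch lumen-ward of the frontier), and
#' `"strut_immobility"` (the plain initial state, for asserting struts and
#' plaque never change).
#'
#' @param name Fixture name (see above).
#' @param seed RNG seed used while building the underlying state.
#' @return A list with the `state` and a fixture-specific `info` list
#'   (key patches, expected values).
#' @export
make_fixture <- function(name, seed = 42L) {
  set.seed(seed)
  cfg <- micro_config(seed)
  state <- build_initial_state(cfg)
  n <- state$frame$n
  at <- function(x, y) as.integer((x - 1L) * n + y)
  ctr <- state$frame$cx

  switch(
    name,
    empty = {
      state$platelets <- list(pos = integer(0), active = logical(0),
                              act_step = integer(0), death = integer(0))
      state$tg <- list(pos = integer(0), death = integer(0))
      state$ec_healthy <- rep(TRUE, state$frame$nb)
      state$strut_healed[] <- TRUE
      list(state = state, info = list())
    },
    platelet_activation = {
      strut1 <- state$strut_info[[1]]
      p_strut <- strut1$patches[which.min(state$frame$D[strut1$patches])]
      inward <- state$frame$inward1[p_strut]  # lumen patch at the strut
      far <- at(round(ctr), round(ctr))  # vessel axis: far from any injury
      state$platelets <- list(pos = c(inward, far),
                              active = c(FALSE, FALSE),
                              act_step = c(NA_integer_, NA_integer_),
                              death = c(10000L, 10000L))
      list(state = state, info = list(near = 1L, far = 2L))
    },
    neutrophil_attachment = {
      strut1 <- state$strut_info[[1]]
      p_strut <- strut1$patches[which.min(state$frame$D[strut1$patches])]
      pp <- state$frame$inward1[p_strut]
      state$platelets <- list(pos = pp, active = TRUE, act_step = 0L,
                              death = 10000L)
      nx <- ((state$frame$inward1[pp] - 1L) %/% n) + 1
      ny <- ((state$frame$inward1[pp] - 1L) %% n) + 1
      state$leuk <- list(kind = 2L, x = as.numeric(nx), y = as.numeric(ny),
                         death = 10000L, fixed = FALSE,
                         strut = NA_integer_, until = NA_integer_)
      list(state = state, info = list())
    },
    monocyte_maturation = {
      b <- 1L  # angular bin whose frontier the monocyte is about to hit
      fidx <- state$frontier_idx[b]
      fx <- ((fidx - 1L) %/% n) + 1
      fy <- ((fidx - 1L) %% n) + 1
      # place the monocyte just inside the lumen on the same ray
      r <- state$fr[b]
      sc <- (r - 1.2) / r
      state$leuk <- list(kind = 1L, x = ctr + (fx - ctr) * sc,
                         y = ctr + (fy - ctr) * sc,
                         death = 10000L, fixed = FALSE,
                         strut = NA_integer_, until = NA_integer_)
      state$platelets$active[] <- FALSE
      list(state = state, info = list(bin = b))
    },
    crowding = {
      med <- which(state$S_med > 0L)
      patch <- med[which.max(state$frame$D[med])]
      state$S_med[patch] <- 16L
      list(state = state, info = list(patch = patch,
                                      inward = state$frame$inward1[patch]))
    },
    threshold = {
      # an uninjured, fully healed vessel with a lone intimal SMC colony at
      # the lumen surface, so only the TGF-beta gate controls division
      state$ec_healthy <- rep(TRUE, state$frame$nb)
      state$strut_healed[] <- TRUE
      state$platelets$active[] <- FALSE
      state$tg <- list(pos = integer(0), death = integer(0))
      # a bin well away from any strut (struts sit at bins 1/19/37/55)
      patch <- state$frontier_idx[10L]
      state$S_med[] <- 0L
      state$S_adv[] <- 0L
      state$S_int[] <- 0L
      state$S_int[patch] <- 10L
      th <- ceiling(threshold_quanta(state$cfg, "tgfb"))
      below <- force_quanta(state, "tg", patch, th - 1L)
      at_th <- force_quanta(state, "tg", patch, th)
      list(state = state, below = below, at_threshold = at_th,
           info = list(patch = patch))
    },
    apoptosis_cap = {
      med <- which(state$S_med > 0L)
      patch <- med[which.max(state$frame$D[med])]
      state$S_med[] <- 0L
      state$S_adv[] <- 0L
      state$S_int[] <- 0L
      state$S_med[patch] <- 15L
      state$S_int[patch] <- 5L
      state <- force_quanta(state, "tn", patch,
                            ceiling(threshold_quanta(state$cfg, "tnfa")))
      list(state = state, info = list(patch = patch, n = 20L, max_kill = 3L))
    },
    ec_tracking = {
      fidx <- state$frontier_idx[10L]
      bulge <- state$frame$inward1[fidx]
      state$S_int[bulge] <- 3L
      # the one-patch-inward neighbour can fall into an adjacent angular
      # bin; expectations are phrased for the bulge's own bin
      list(state = state, info = list(bin = state$frame$bin[bulge],
                                      bulge = bulge, old_front = fidx))
    },
    strut_immobility = {
      list(state = state,
           info = list(strut = which(state$strut),
                       plaque = which(state$plaque)))
    },
    stop("unknown fixture: ", name, call. = FALSE)
  )
}
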