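# Behavioural rules exercised through deterministic micro-fixtures; every
# rule is driven through the production code paths.

test_that("latent platelets activate on contact with injury, not in mid-lumen", {
  fx <- make_fixture("platelet_activation")
  hits_near <- 0L
  hits_far <- 0L
  for (rep in 1:50) {
    set.seed(rep)
    st2 <- fx$state
    for (k in 1:40) st2 <- step_platelets(st2)
    hits_near <- hits_near + st2$platelets$active[fx$info$near]
    st3 <- fx$state
    for (k in 1:3) st3 <- step_platelets(st3)
    hits_far <- hits_far + st3$platelets$active[fx$info$far]
  }
  # a latent platelet wandering beside the injured strut meets the wound
  # within a few steps; one at the vessel axis cannot reach it
  expect_gte(hits_near, 48L)
  expect_equal(hits_far, 0L)
})

test_that("platelet lifespans are drawn from 5-10 days (20-40 steps)", {
  cfg <- vessel_config(2.9, seed = 2)
  set.seed(2)
  st <- build_initial_state(cfg)
  expect_true(all(st$platelets$death >= 20 & st$platelets$death <= 40))
  # the circulating pool keeps its nominal size through turnover
  set.seed(3)
  for (i in 1:30) st <- sim_step(st)
  expect_equal(length(st$platelets$pos), cfg$n_platelets)
})

test_that("no TGF-beta means no leukocyte recruitment", {
  fx <- make_fixture("empty")
  st <- fx$state
  set.seed(1)
  st2 <- maybe_recruit_leukocytes(st)
  expect_equal(length(st2$leuk$kind), 0L)
})

test_that("above-threshold intimal TGF-beta recruits monocytes and neutrophils", {
  fx <- make_fixture("strut_immobility")
  st <- fx$state
  st <- restenosim:::force_quanta(st, "tg", st$frontier_idx[1L], 3L)
  set.seed(4)
  st2 <- maybe_recruit_leukocytes(st)
  expect_gte(sum(st2$leuk$kind == 1L), 1L)
  expect_gte(sum(st2$leuk$kind == 2L), 1L)
  # spawn count is the configured rate per triggering step (full wound)
  total <- 0L
  for (rep in 1:10) {
    set.seed(rep)
    total <- total + sum(maybe_recruit_leukocytes(st)$leuk$kind == 1L)
  }
  expect_equal(total, 10L * floor(st$cfg$recruit_rate))
})

test_that("neutrophils meeting activated platelets attach to the thrombus", {
  fx <- make_fixture("neutrophil_attachment")
  set.seed(5)
  st <- step_leukocytes(fx$state)
  expect_true(st$leuk$fixed[1])
  # attached: immobile thereafter
  x0 <- st$leuk$x[1]
  set.seed(6)
  st2 <- step_leukocytes(st)
  expect_equal(st2$leuk$x[1], x0)
})

test_that("monocytes crossing the thrombus mature into macrophages", {
  fx <- make_fixture("monocyte_maturation")
  set.seed(7)
  st <- fx$state
  for (i in 1:4) st <- step_leukocytes(st)
  expect_true(all(st$leuk$kind %in% c(3L, 4L)))
  # macrophage lifespan is 45 days = 180 steps from maturation
  expect_lte(max(st$leuk$death), st$step + 180L + 4L)
})

test_that("leukocyte step displacement is 7.2 lattice units", {
  cfg <- vessel_config(2.9)
  expect_equal(cfg$leukocyte_um_min * 60 * cfg$step_hours /
                 (cfg$patch_mm * 1000), 7.2)
})

test_that("SMC division requires local TGF-beta at or above 3 ng/ml", {
  fx <- make_fixture("threshold")
  n <- fx$state$frame$n
  run_once <- function(st) {
    tgl <- restenosim:::boxsum3(restenosim:::count_field(st$tg$pos, n))
    tnl <- matrix(0, n, n)
    st2 <- step_smc(st, tgl, tnl)
    sum(st2$S_int) - sum(st$S_int)
  }
  # 5 local quanta = 2.5 ng/ml: below threshold, never divides
  set.seed(11)
  gains_below <- replicate(100, run_once(fx$below))
  expect_true(all(gains_below == 0))
  # 6 local quanta = 3.0 ng/ml: divides at the 30-h doubling rate
  set.seed(12)
  gains_at <- replicate(400, run_once(fx$at_threshold))
  p <- 2^(6 / 30) - 1
  expect_gt(mean(gains_at), 0)
  # mean gain ~ 10 * p (one daughter per division, colony is uninjured)
  se <- sqrt(10 * p * (1 + p)) / sqrt(400)
  expect_lt(abs(mean(gains_at) - 10 * p), 5 * se)
})

test_that("population growth under saturating TGF-beta recovers the 30-hour doubling law", {
  # oracle: closed-form geometric growth (1+p)^k on an isolated colony
  fx <- make_fixture("threshold")
  st0 <- fx$at_threshold
  st0 <- restenosim:::force_quanta(st0, "tg", fx$info$patch, 60L)  # saturate
  n <- st0$frame$n
  st0$S_int[fx$info$patch] <- 1L
  tgl <- restenosim:::boxsum3(restenosim:::count_field(st0$tg$pos, n))
  tnl <- matrix(0, n, n)
  p <- 2^(6 / 30) - 1
  set.seed(13)
  finals <- replicate(600, {
    st <- st0
    for (k in 1:5) st <- step_smc(st, tgl, tnl)
    sum(st$S_int) + sum(st$S_mig)
  })
  # five steps = 30 h: the population should double on average
  expect_lt(abs(mean(finals) - 2), 4 * stats::sd(finals) / sqrt(600))
})

test_that("TNF-alpha apoptosis kills at most 15% of the local population per event", {
  fx <- make_fixture("apoptosis_cap")
  st <- fx$state
  n <- st$frame$n
  tnl <- restenosim:::boxsum3(restenosim:::count_field(st$tn$pos, n))
  tgl <- matrix(0, n, n)
  expect_equal(local_concentration(restenosim:::count_field(st$tn$pos, n),
                                   fx$info$patch, st$cfg), 4.0)
  # the fixture patch is overfull (20 cells), so crowding will displace the
  # surplus; deaths are read from the grid-wide census, which crowding
  # conserves
  before <- sum(st$S_med) + sum(st$S_int)
  set.seed(14)
  for (rep in 1:100) {
    st2 <- step_smc(st, tgl, tnl)
    killed <- before - (sum(st2$S_med) + sum(st2$S_int))
    expect_lte(killed, fx$info$max_kill)   # floor(0.15 * 20) = 3
    expect_gte(killed, 0)
  }
})

test_that("with zero TGF-beta the SMC population is non-increasing", {
  fx <- make_fixture("strut_immobility")
  st <- fx$state
  st$cfg$release_scale <- 0
  st$tg <- list(pos = integer(0), death = integer(0))  # no latent seed
  set.seed(15)
  tot0 <- sum(st$S_int) + sum(st$S_med) + sum(st$S_adv) + sum(st$S_mig)
  for (i in 1:12) {
    st <- sim_step(st)
    tot <- sum(st$S_int) + sum(st$S_med) + sum(st$S_adv) + sum(st$S_mig)
    expect_lte(tot, tot0)
    expect_equal(length(st$leuk$kind), 0L)  # and nothing is recruited
  }
})

test_that("an overfilled patch sheds its surplus one patch lumen-ward", {
  fx <- make_fixture("crowding")
  st <- restenosim:::resolve_crowding(fx$state)
  tot <- st$S_int + st$S_med + st$S_adv + st$S_mig
  expect_lte(tot[fx$info$patch], 15L)
  expect_equal(sum(tot), sum(fx$state$S_int + fx$state$S_med +
                               fx$state$S_adv + fx$state$S_mig))
  moved_to <- which(tot != (fx$state$S_int + fx$state$S_med +
                              fx$state$S_adv + fx$state$S_mig)[seq_along(tot)] &
                      seq_along(tot) != fx$info$patch)
  expect_true(all(st$frame$D[moved_to] < st$frame$D[fx$info$patch]))
})

test_that("the 15-SMC patch cap holds after every step of a live simulation", {
  fx <- make_fixture("strut_immobility")
  st <- fx$state
  set.seed(16)
  for (i in 1:24) {
    st <- sim_step(st)
    tot <- st$S_int + st$S_med + st$S_adv + st$S_mig
    expect_lte(max(tot), st$cfg$smc_per_patch)
  }
})

test_that("struts and plaque never move, appear, or disappear", {
  fx <- make_fixture("strut_immobility")
  st <- fx$state
  set.seed(17)
  for (i in 1:20) st <- sim_step(st)
  expect_identical(which(st$strut), fx$info$strut)
  expect_identical(which(st$plaque), fx$info$plaque)
})

test_that("the EC ring tracks the advancing SMC frontier", {
  fx <- make_fixture("ec_tracking")
  st <- fx$state
  tg0 <- matrix(0, st$frame$n, st$frame$n)
  st2 <- step_ec(st, tg0, tg0)
  expect_equal(st2$frontier_idx[fx$info$bin], fx$info$bulge)
  expect_lt(st2$fr[fx$info$bin], st$fr[fx$info$bin])
  # with no SMC movement and no TNF-alpha, EC positions are a fixed point
  st3 <- step_ec(st2, tg0, tg0)
  expect_identical(st3$frontier_idx, st2$frontier_idx)
})

test_that("adventitial SMCs never migrate inward", {
  cfg <- vessel_config(2.9, seed = 18)
  set.seed(18)
  st <- build_initial_state(cfg)
  adv_zone <- st$frame$D >= st$r0 + st$ti + st$cfg$media_frac * st$w
  set.seed(19)
  for (i in 1:16) st <- sim_step(st)
  expect_true(all(st$S_adv[!adv_zone] == 0L))
})

test_that("all step operators are no-ops on an empty micro-state", {
  fx <- make_fixture("empty")
  st <- fx$state
  set.seed(20)
  st2 <- sim_step(st)
  expect_equal(sum(st2$S_int), sum(st$S_int))
  expect_equal(length(st2$leuk$kind), 0L)
  expect_equal(length(st2$tn$pos), 0L)
  expect_equal(st2$tg_emitted, 0L)
})
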