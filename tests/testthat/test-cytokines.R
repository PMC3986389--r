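cfg <- vessel_config(2.9)

test_that("local concentration implements the V = C x AP protocol", {
  f <- matrix(0L, 11, 11)
  expect_equal(local_concentration(f, c(6, 6), cfg), 0)
  # one quantum anywhere in the 9-patch window contributes 1/18 ng/ml
  f[6, 6] <- 1L
  expect_equal(local_concentration(f, c(6, 6), cfg), 1 / 18)
  expect_equal(local_concentration(f, c(7, 7), cfg), 1 / 18)
  expect_equal(local_concentration(f, c(6, 8), cfg), 0)  # outside the window
  # 54 local quanta sit exactly at the 3 ng/ml SMC proliferation trigger
  f[6, 6] <- 54L
  expect_equal(local_concentration(f, c(6, 6), cfg), 3.0)
  expect_equal(restenosim:::threshold_quanta(cfg, "tgfb"), 54)
  expect_equal(restenosim:::threshold_quanta(cfg, "tnfa"), 72)
  expect_equal(cfg$tgfb_threshold_ngml, 3)
})

test_that("uniform fields give the analytic concentration on interior patches", {
  f <- matrix(3L, 15, 15)
  conc <- local_concentration(f, cfg = cfg)
  inner <- conc[3:13, 3:13]
  expect_true(all(abs(inner - 27 * cfg$quantum_pg /
                        (cfg$patch_thickness_C_mm * 9 * cfg$patch_mm^2)) <
                    1e-12))
  # edge patches use the truncated neighbourhood and reduced volume:
  # the uniform concentration is the same there
  expect_equal(conc[1, 1], inner[1, 1])
})

test_that("serum concentration is linear in total mass and zero when empty", {
  expect_equal(serum_concentration(0, cfg), 0)
  s1 <- serum_concentration(1000, cfg)
  expect_equal(serum_concentration(2000, cfg), 2 * s1)
  # the physiological window comfortably holds typical loads
  expect_lt(serum_concentration(5000, cfg), 10)
})

test_that("hoop-stress factor is r/t, normalised at the 1:1 geometry", {
  expect_equal(hoop_stress_factor(1.45, 1.45), 1)
  expect_equal(hoop_stress_factor(1, 1), 1)
  expect_equal(hoop_stress_factor(0.8 * 1.45, 1.45), 0.8)
  # monotone increasing in the lumen radius at fixed thickness
  r <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(hoop_stress_factor(r, 1.45)) > 0))
  expect_error(hoop_stress_factor(-1, 1))
})

test_that("cytokine mass is conserved up to decay", {
  fx <- make_fixture("strut_immobility")
  st <- fx$state
  set.seed(42)
  for (i in 1:12) st <- sim_step(st)
  expect_equal(st$tg_total_emitted + length(fx$state$tg$pos),
               length(st$tg$pos) + st$tg_decayed)
  expect_equal(st$tn_total_emitted, length(st$tn$pos) + st$tn_decayed)
})

test_that("quanta expire after their lifetime", {
  fx <- make_fixture("empty")
  st <- fx$state
  patch <- which(st$wall0)[1]
  st <- restenosim:::force_quanta(st, "tg", patch, 10L,
                                  life = st$cfg$cytokine_life_steps)
  set.seed(1)
  for (i in seq_len(st$cfg$cytokine_life_steps)) {
    st <- sim_step(st)
  }
  expect_equal(length(st$tg$pos), 0L)
  expect_equal(st$tg_decayed, 10)
})

test_that("diffusion is an unbiased single-patch random walk", {
  # oracle: exact enumeration over the 8 equiprobable moves gives a mean
  # squared displacement of (4*1 + 4*2)/8 = 1.5 per step
  n <- 21L
  allowed <- matrix(TRUE, n, n)
  start <- as.integer((10L) * n + 11L)  # centre patch (11, 11)
  set.seed(7)
  reps <- 20000L
  q <- list(pos = rep.int(start, reps), death = rep.int(100L, reps))
  q2 <- restenosim:::walk_quanta(q, allowed, n, step = 0L)
  dx <- ((q2$pos - 1L) %/% n) - ((start - 1L) %/% n)
  dy <- ((q2$pos - 1L) %% n) - ((start - 1L) %% n)
  expect_true(all(abs(dx) <= 1 & abs(dy) <= 1))
  expect_gt(sum(abs(dx) + abs(dy)), 0)     # it does move
  msd <- mean(dx^2 + dy^2)
  expect_lt(abs(msd - 1.5), 0.02)
  expect_lt(abs(mean(dx)), 0.02)           # unbiased
  expect_lt(abs(mean(dy)), 0.02)
})

test_that("rejected moves keep quanta on allowed ground", {
  n <- 9L
  allowed <- matrix(FALSE, n, n)
  allowed[5, 5] <- TRUE                    # a single allowed patch
  start <- as.integer(4L * n + 5L)
  q <- list(pos = rep.int(start, 500L), death = rep.int(100L, 500L))
  set.seed(8)
  q2 <- restenosim:::walk_quanta(q, allowed, n, step = 0L)
  expect_true(all(q2$pos == start))
})

test_that("raising the injury factor never lowers early TGF-beta release", {
  emitted_after <- function(factor) {
    cfg <- restenosim:::micro_config(seed = 21, injury_factor = factor)
    set.seed(21)
    st <- build_initial_state(cfg)
    for (i in 1:8) st <- sim_step(st)
    st$tg_total_emitted
  }
  expect_gte(emitted_after(3), emitted_after(1))
})
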