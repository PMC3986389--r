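test_that("mm/lattice-unit conversions follow the 0.05 mm patch scale", {
  expect_equal(mm_to_units(0.05), 1.0)
  expect_equal(mm_to_units(0), 0)
  expect_equal(mm_to_units(2.9), 58.0)
  expect_error(mm_to_units(-1), "non-negative")
  # round trip
  for (x in c(0.05, 1.45, 2.9, 3.19)) {
    expect_equal(units_to_mm(mm_to_units(x)), x, tolerance = 1e-12)
  }
})

test_that("default wall thickness equals the lumen radius unless overridden", {
  expect_equal(default_wall_thickness(2.9), 1.45)
  expect_equal(default_wall_thickness(2.0), 1.0)
  expect_equal(default_wall_thickness(3.19), 1.595)
  expect_equal(default_wall_thickness(2.9, 1.2), 1.2)
  expect_error(default_wall_thickness(0), "positive")
})

test_that("strut count from spacing divides the circumference and rounds", {
  expect_equal(strut_count_from_spacing(2.9, 0.4556), 20L)
  expect_equal(strut_count_from_spacing(2.9, pi * 2.9), 1L)
  expect_warning(n <- strut_count_from_spacing(2.9, 50), "single strut")
  expect_equal(n, 1L)
  expect_error(strut_count_from_spacing(2.9, 0), "positive")
  # default when no spacing is given
  expect_equal(vessel_config(2.9)$struts_per_stent, 20L)
})

test_that("strut layouts are evenly spaced; staggered offsets by half a pitch", {
  lay <- build_strut_layout(vessel_config(2.9))
  expect_equal(nrow(lay), 20L)
  pitches <- diff(c(lay$angle, 2 * pi))
  expect_true(all(abs(pitches - 2 * pi / 20) < 1e-12))
  expect_equal(sum(pitches), 2 * pi)
  expect_equal(unique(lay$side_units), 2.0)  # default 0.1 mm strut

  ali <- build_strut_layout(vessel_config(2.9, stent_count = 2L,
                                          arrangement = "aligned"))
  expect_equal(ali$angle[ali$stent == 1L], ali$angle[ali$stent == 2L])

  sta <- build_strut_layout(vessel_config(2.9, stent_count = 2L,
                                          arrangement = "staggered"))
  off <- (sta$angle[sta$stent == 2L] - sta$angle[sta$stent == 1L]) %% (2 * pi)
  expect_true(all(abs(off - pi / 20) < 1e-12))  # 9 degrees for N = 20
})

test_that("config validation rejects impossible geometry and bad input", {
  expect_error(vessel_config(-1), "positive")
  expect_error(vessel_config(2.9, stent_count = 3), "1 or 2")
  expect_error(vessel_config(2.9, struts_per_stent = 10, strut_spacing_mm = 1),
               "at most one")
  expect_error(vessel_config(6.5), "fit")
  expect_error(vessel_config(2.9, not_a_param = 1), "unknown")
})

test_that("the initial state realises the configured cross-section", {
  cfg <- vessel_config(2.9, seed = 7)
  set.seed(7)
  st <- build_initial_state(cfg)

  expect_equal(st$frame$n^2, 22500L)
  expect_equal(st$r0, 29)              # lumen radius in patches
  expect_equal(st$r0 + st$w, 58)       # outer wall radius
  # minimum lumen diameter within one patch of the configured diameter
  expect_lt(abs(min_lumen_diameter(st) - 2.9), 0.05 + 1e-9)

  # EC monolayer: every non-strut angular bin has an EC on its frontier
  strut_bins <- unique(unlist(lapply(st$strut_info, `[[`, "bins")))
  free_bins <- setdiff(seq_len(st$frame$nb), strut_bins)
  expect_true(all(st$ec_present[free_bins]))
  # the procedure denuded the ring: no EC is healthy at day 0
  expect_false(any(st$ec_healthy))

  # plaque sits in the bottom-left quadrant, in the wall, clear of struts
  pq <- which(st$plaque)
  expect_gt(length(pq), 0)
  expect_true(all(st$frame$D[pq] >= st$r0))
  th <- st$frame$TH[pq]
  expect_true(all(th > pi & th < 1.5 * pi))
  expect_false(any(st$plaque & st$strut))

  # wall layers populated by SMCs, lumen free of them
  smc <- st$S_int + st$S_med + st$S_adv + st$S_mig
  expect_true(all(smc[st$frame$D < st$r0 - 1] == 0))
  expect_true(all(st$S_med[st$frame$Dm >= st$r0 + st$ti &
                             st$frame$Dm < st$r0 + st$ti + 1] > 0))
})

test_that("a second stent adds a radially adjacent ring of struts", {
  cfg <- vessel_config(2.9, stent_count = 2L, seed = 1)
  set.seed(1)
  st <- build_initial_state(cfg)
  stents <- vapply(st$strut_info, `[[`, integer(1), "stent")
  expect_equal(sum(stents == 1L), 20L)
  expect_equal(sum(stents == 2L), 20L)
  r1 <- vapply(st$strut_info[stents == 1L], `[[`, numeric(1), "inner_r")
  r2 <- vapply(st$strut_info[stents == 2L], `[[`, numeric(1), "inner_r")
  expect_gt(mean(r1), mean(r2))  # interior stent sits inside the exterior
})

test_that("repositioning the plaque around the circumference leaves replicate outcomes unchanged", {
  # micro-vessel replicates with the plaque at two different angular
  # positions; the cross-section is circular, so outcomes must agree
  run_loss <- function(box) {
    cfg <- restenosim:::micro_config(seed = 11, max_days = 25L,
                                     confirm_days = 2L)
    if (!is.null(box)) cfg$plaque_box <- box
    res <- suppressWarnings(run_replicates(cfg, n = 10L, base_seed = 11L))
    res$runs$percent_area_change
  }
  # default: bottom-left; alternative: a box in the top-right quadrant
  a <- run_loss(NULL)
  b <- run_loss(c(24, 40, 24, 40))
  tt <- t.test(a, b)
  expect_gt(tt$p.value, 0.01)
})
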