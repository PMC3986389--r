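test_that("equal config and seed give bit-identical runs", {
  cfg <- restenosim:::micro_config(seed = 31, max_days = 12L,
                                   confirm_days = 2L)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$final_lumen_diameter_mm, b$final_lumen_diameter_mm)
  c2 <- run_simulation(cfg, seed = 32)
  expect_false(identical(a$series, c2$series))
})

test_that("the day counter advances a quarter day per step", {
  cfg <- restenosim:::micro_config(seed = 33, max_days = 3L,
                                   confirm_days = 1L)
  run <- run_simulation(cfg)
  expect_equal(run$series$day, run$series$step / 4)
  expect_equal(nrow(run$series), run$series$step[nrow(run$series)] + 1)
})

test_that("the null model (no cytokine release) stabilizes immediately", {
  cfg <- restenosim:::micro_config(seed = 34, release_scale = 0,
                                   max_days = 70L)
  run <- run_simulation(cfg)
  expect_equal(run$stabilization_day, 0)
  expect_equal(run$final_lumen_diameter_mm,
               run$series$min_lumen_diameter_mm[1])
  expect_equal(run$percent_area_change_final,
               run$series$percent_area_change[1])
  expect_lt(run$percent_area_change_final, 5)
  expect_true(run$converged)
  # post-stabilization confirmation: the recorded tail is static
  tail_d <- utils::tail(run$series$min_lumen_diameter_mm,
                        cfg$confirm_days * 4)
  expect_true(all(abs(tail_d - tail_d[1]) <= 0.05 + 1e-9))
})

test_that("final diameter never exceeds the initial diameter", {
  cfg <- restenosim:::micro_config(seed = 35, max_days = 20L,
                                   confirm_days = 2L)
  for (s in 35:37) {
    run <- run_simulation(cfg, seed = s)
    expect_lte(run$final_lumen_diameter_mm, cfg$lumen_diameter_mm + 1e-9)
    expect_gte(run$final_lumen_diameter_mm, 0)
  }
})

test_that("replicates summarise mean and SD; n = 1 degenerates to the run", {
  # quiescent configuration so every micro-run converges quickly
  cfg <- restenosim:::micro_config(seed = 38, max_days = 10L,
                                   confirm_days = 1L, release_scale = 0)
  one <- run_replicates(cfg, n = 1L, base_seed = 38L)
  expect_equal(one$summary$sd, c(0, 0, 0))
  single <- run_simulation(cfg, seed = 38L)
  expect_equal(one$summary$mean[1], single$final_lumen_diameter_mm)

  three <- run_replicates(cfg, n = 3L, base_seed = 40L)
  expect_equal(nrow(three$runs), 3L)
  expect_equal(three$runs$seed, 40:42)
  expect_equal(three$summary$mean[1],
               mean(three$runs$final_lumen_diameter_mm))
})

test_that("tidiers expose runs and summaries as tibbles", {
  cfg <- restenosim:::micro_config(seed = 43, max_days = 8L,
                                   confirm_days = 1L, release_scale = 0)
  run <- run_simulation(cfg)
  expect_s3_class(tidy(run), "tbl_df")
  g <- glance(run)
  expect_equal(nrow(g), 1L)
  expect_equal(g$final_lumen_diameter_mm, run$final_lumen_diameter_mm)

  reps <- run_replicates(cfg, n = 2L, base_seed = 43L)
  expect_s3_class(tidy(reps), "tbl_df")
  expect_equal(nrow(tidy(reps)), 2L)
  expect_equal(glance(reps)$n, 2)
})

test_that("plot methods return ggplot objects", {
  cfg <- restenosim:::micro_config(seed = 44, max_days = 6L,
                                   confirm_days = 1L)
  run <- run_simulation(cfg)
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(autoplot(run, type = "populations"), "ggplot")
  expect_s3_class(autoplot(run, type = "cytokines"), "ggplot")
  set.seed(44)
  st <- build_initial_state(cfg)
  expect_s3_class(plot_cross_section(st), "ggplot")
})
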