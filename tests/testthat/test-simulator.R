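test_that("equilibrate is deterministic and conserves the closed system", {
  p <- default_parameters()
  a <- equilibrate(p, seed = 12)
  b <- equilibrate(p, seed = 12)
  expect_identical(a, b)
  total <- a$surface + a$ee + a$endo_transit + a$exo_transit
  expect_lte(total, 252L)  # rounding of four means can add ~1 per class
  expect_gte(total, 248L)  # mobile census is 250 up to rounding
  expect_gte(min(a$surface, a$ee, a$endo_transit, a$exo_transit), 0L)
})

test_that("trials are bit-reproducible under a fixed seed", {
  p <- default_parameters(t_end = 2)
  init <- equilibrate(p, seed = 12)
  pr <- make_profile("EP1", p)
  a <- run_trial(p, pr, seed = 5, init = init)
  b <- run_trial(p, pr, seed = 5, init = init)
  expect_identical(a, b)
  c2 <- run_trial(p, pr, seed = 6, init = init)
  expect_false(identical(a$series, c2$series))
})

test_that("ensemble seeds are distinct and counter-derived", {
  s <- ensemble_seeds(42L, 100)
  expect_identical(length(unique(s)), 100L)
  expect_identical(ensemble_seeds(42L, 100), s)
  expect_false(any(ensemble_seeds(43L, 100) == s))
  expect_true(all(s > 0 & s < 2^31))
})

test_that("run_ensemble reuses one equilibration and returns all trials", {
  p <- default_parameters(t_end = 1)
  init <- equilibrate(p, seed = 3)
  ens <- run_ensemble(p, NULL, n_reps = 3, base_seed = 3, init = init)
  expect_identical(length(ens$trials), 3L)
  expect_identical(ens$profile, "none")
  expect_identical(ens$seeds, ensemble_seeds(3L, 3))
  # single-trial ensemble is valid
  e1 <- run_ensemble(p, NULL, n_reps = 1, base_seed = 9, init = init)
  expect_identical(length(e1$trials), 1L)
})

test_that("reference engine runs full trials with the same contract", {
  p <- default_parameters(t_start = -1, t_end = 0.5)
  init <- equilibrate(p, seed = 8)
  tr <- run_trial(p, NULL, seed = 2, init = init, engine = "R")
  expect_s3_class(tr, "endosim_trial")
  expect_named(tr$series, c("t_min", "N_syn", "D_Rab5", "N_EE_Rab5"))
  expect_identical(nrow(tr$series), 90L)  # 1.5 min at 1-s cadence
  expect_true(all(tr$series$D_Rab5 >= 0 & tr$series$D_Rab5 <= 1))
  expect_true(all(tr$series$N_syn > 0))
  tr2 <- run_trial(p, NULL, seed = 2, init = init, engine = "R")
  expect_identical(tr, tr2)
})

test_that("no-stimulus trials stay at baseline and never sort", {
  p <- default_parameters()
  init <- equilibrate(p, seed = 21)
  trials <- lapply(ensemble_seeds(21L, 6), run_trial, p = p,
                   profile = NULL, init = init)
  # basal Rab5 fraction stays orders of magnitude below the threshold
  expect_true(all(vapply(trials, function(tr) max(tr$series$D_Rab5),
                         numeric(1)) < 0.05))
  expect_true(all(is.na(vapply(trials, `[[`, numeric(1), "t_sort"))))
  # stationarity: per-trial means of two disjoint windows agree within
  # 3 cross-trial standard errors
  early <- vapply(trials, window_mean, numeric(1), var = "N_syn",
                  t0 = -10, t1 = 0)
  late <- vapply(trials, window_mean, numeric(1), var = "N_syn",
                 t0 = 40, t1 = 50)
  d <- late - early
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("compiled engine matches the reference path statistically", {
  # same dynamics, different event sampling (binomial batching vs
  # per-site Bernoulli): compare endocytosis event counts over 1 min
  p <- default_parameters()
  set.seed(14)
  st0 <- init_state(p)
  k <- rep(30, 600)  # elevated rate, 1 simulated minute
  ev_cpp <- replicate(10, {
    out <- endosim:::run_engine(st0, NULL, k, p, 600)
    out$n_endo_events
  })
  # count scissions in the R path directly via the unrolled kernels
  ev_R <- replicate(6, {
    st <- st0
    events <- 0L
    for (i in seq_len(600)) {
      pre <- length(st$endo_arr)
      st$t <- st$t + p$dt
      st <- expire_rab5(st, st$t)
      st <- fuse_endocytic(st, p, st$t)
      st <- fuse_exocytic(st, st$t)
      n_before <- length(st$endo_arr)
      st <- scission(st, p, st$t)
      events <- events + (length(st$endo_arr) - n_before)
      st <- release_buds(st, p, st$t)
      st <- nucleate_pits(st, 30, p, st$t)
      st <- nucleate_buds(st, p, st$t)
      st$surf <- diffuse(st$surf, p$d_s, p)
      st$ee <- diffuse(st$ee, p$d_EE, p)
    }
    events
  })
  # Welch t-test on event counts: means agree
  expect_gt(t.test(ev_cpp, ev_R)$p.value, 0.01)
})

test_that("binomial batching equals per-site Bernoulli counts in law", {
  p <- default_parameters()
  pr <- endosim:::rate_to_prob(20, p$dt)
  set.seed(88)
  bern <- replicate(3000, sum(runif(2500) < pr))
  batch <- rbinom(3000, 2500, pr)
  expect_gt(suppressWarnings(ks.test(bern, batch))$p.value, 0.001)
})

test_that("EPm depresses transiently, never sorts, and mostly recovers", {
  # the strict 3-SE recovery criterion is part of the acceptance suite;
  # here we check the mechanics: no ignition, a real transient, and
  # recovery to within a few percent of baseline
  p <- default_parameters()
  init <- equilibrate(p, seed = 33)
  epm <- make_profile("EPm", p)
  trials <- lapply(ensemble_seeds(33L, 8), run_trial, p = p,
                   profile = epm, init = init)
  expect_true(all(is.na(vapply(trials, `[[`, numeric(1), "t_sort"))))
  late <- vapply(trials, window_mean, numeric(1), var = "N_syn",
                 t0 = 40, t1 = 50)
  dep <- vapply(trials, window_mean, numeric(1), var = "N_syn",
                t0 = 5, t1 = 15)
  expect_lt(mean(dep), 0.9)   # the mild stimulus does depress transiently
  expect_gt(mean(late), mean(dep) + 0.2)  # and most of it recovers
  expect_gt(mean(late), 0.9)
})

test_that("CLI run/analyze round trip on a tiny configuration", {
  out_dir <- withr::local_tempdir()
  cfg <- withr::local_tempfile(fileext = ".json")
  write_params(default_parameters(t_start = -1, t_end = 0.5), cfg)
  suppressMessages(endosim_main(c(
    "run", "--profile", "none", "--reps", "2", "--seed", "4",
    "--config", cfg, "--out", out_dir)))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "trial_002.csv")))
  report <- withr::local_tempfile(fileext = ".json")
  endosim_main(c("analyze", "--in", out_dir, "--report", report))
  rep <- jsonlite::fromJSON(report)
  expect_equal(rep$n, 2L)
  expect_equal(rep$occurrence, 0)
})
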