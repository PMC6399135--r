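test_that("diffusion conserves receptors and is a no-op at d = 0", {
  p <- tiny_params()
  set.seed(2)
  occ <- endosim:::scatter_counts(60, 100)
  expect_identical(diffuse(occ, 0, p), occ)
  for (i in 1:20) {
    occ2 <- diffuse(occ, p$d_s, p)
    expect_identical(sum(occ2), sum(occ))
    occ <- occ2
  }
})

test_that("random walk reproduces the 2D diffusion law (MSD = 4dt)", {
  p <- default_parameters()
  L <- p$lattice_side
  centre <- (L / 2) * L + L / 2 + 1  # site (25, 25), column-major
  occ <- integer(L^2)
  n <- 400L
  occ[centre] <- n
  set.seed(31)
  nbr <- endosim:::neighbor_index(L)
  steps <- 200L
  for (i in seq_len(steps)) occ <- diffuse(occ, p$d_s, p, nbr)
  # squared displacement from the start site (toroidal minimum image)
  s <- which(occ > 0L)
  drow <- (s - 1) %% L - (centre - 1) %% L
  dcol <- (s - 1) %/% L - (centre - 1) %/% L
  wrap <- function(d) ifelse(d > L / 2, d - L, ifelse(d < -L / 2, d + L, d))
  r2 <- (wrap(drow)^2 + wrap(dcol)^2) * p$lattice_spacing^2
  msd <- sum(occ[s] * r2) / n
  expected <- 4 * p$d_s * steps * p$dt  # um^2
  se <- sqrt(sum(occ[s] * (r2 - msd)^2) / n) / sqrt(n)
  expect_lt(abs(msd - expected), 3 * se)
})

test_that("pit nucleation: none at rate 0; per-site probability oracle", {
  p <- default_parameters()
  st <- endosim:::new_state(p)
  set.seed(5)
  expect_identical(nucleate_pits(st, 0, p, t = 0)$pit_t, st$pit_t)
  # per-site per-step probability 1 - exp(-1.2/60 * 0.1) ~ 0.0019980
  expect_equal(endosim:::rate_to_prob(1.2, 0.1), 1 - exp(-0.002))
  expect_equal(endosim:::rate_to_prob(1.0, 0.1), 0.0016653, tolerance = 1e-4)
  # chi-squared of per-step pit counts against Binomial(2500, p)
  n_steps <- 3000L
  counts <- integer(n_steps)
  for (i in seq_len(n_steps)) {
    counts[i] <- sum(is.finite(nucleate_pits(st, 1.2, p, t = 0)$pit_t))
  }
  pr <- endosim:::rate_to_prob(1.2, p$dt)
  breaks <- c(-1, 1:9, Inf)
  obs <- table(cut(counts, breaks))
  expected <- diff(pbinom(breaks, 2500, pr))
  expect_gt(suppressWarnings(
    chisq.test(as.vector(obs), p = expected / sum(expected))$p.value),
    0.001)
  # new pits carry scission times inside t + tau_pit_range
  set.seed(6)
  st2 <- nucleate_pits(st, 400, p, t = 100)
  lags <- st2$pit_t[is.finite(st2$pit_t)] - 100
  expect_true(all(lags >= p$tau_pit_range[1] & lags <= p$tau_pit_range[2]))
})

test_that("scission takes the whole site occupancy, empty pits included", {
  p <- tiny_params()
  st <- scripted_state(p, surf_sites = c(4, 4, 4))
  st$pit_t[4] <- 1       # due
  st$pit_t[9] <- 1       # due, empty site
  st$pit_t[2] <- 99      # not due
  set.seed(3)
  st2 <- scission(st, p, t = 1)
  expect_identical(st2$surf[4], 0L)
  expect_identical(length(st2$endo_arr), 2L)
  expect_setequal(st2$endo_cargo, c(3L, 0L))     # cargo-0 vesicle traffics
  expect_identical(st2$pit_t[2], 99)
  expect_true(all(st2$endo_arr > 1))
  expect_identical(scission(st2, p, t = 1.5)$endo_cargo, st2$endo_cargo)
})

test_that("endocytic fusion adds cargo and recruits a single Rab5", {
  p <- tiny_params()
  st <- scripted_state(p)
  st$endo_arr <- c(1, 1)
  st$endo_cargo <- c(2L, 1L)
  set.seed(11)
  st2 <- fuse_endocytic(st, p, t = 1)
  set.seed(11)
  sites <- c(sample.int(100, 1), sample.int(100, 1))  # replay the rule
  expect_identical(sum(st2$ee), 3L)
  expect_identical(st2$ee[sites[1]] + st2$ee[sites[2]],
                   if (sites[1] == sites[2]) 6L else 3L)
  expect_identical(sum(is.finite(st2$rab5_exp)),
                   length(unique(sites)))           # one Rab5 per site
  expect_identical(length(st2$endo_arr), 0L)
  # D was 0 at the first fusion: tau_Rab5(0) = 0, expiry at placement time
  expect_equal(st2$rab5_exp[sites[1]], 1)
  st3 <- expire_rab5(st2, t = 1)
  expect_false(is.finite(st3$rab5_exp[sites[1]]))
  expect_identical(st3$ee, st2$ee)                  # receptors unaffected
})

test_that("Rab5 lifetimes are frozen at recruitment (pre-placement D)", {
  p <- tiny_params()
  st <- scripted_state(p)
  st$rab5_exp[1:10] <- 1e9   # D = 0.1 before the new arrival
  st$endo_arr <- 5
  st$endo_cargo <- 0L
  set.seed(20)
  repeat {
    st2 <- fuse_endocytic(st, p, t = 5)
    new_site <- which(is.finite(st2$rab5_exp) & !is.finite(st$rab5_exp))
    if (length(new_site)) break               # landed on a Rab5-free site
  }
  scale <- endosim:::tau_rab5_seconds_per_unit(p)
  expect_equal(st2$rab5_exp[new_site], 5 + tau_rab5(0.1, p) * scale)
  # existing Rab5 expiry kept on re-fusion
  st$endo_arr <- 5
  set.seed(21)
  st3 <- fuse_endocytic(st, p, t = 5)
  expect_identical(st3$rab5_exp[1:10], st$rab5_exp[1:10])
})

test_that("buds nucleate only on Rab5-free sites but release regardless", {
  p <- tiny_params()
  st <- scripted_state(p, ee_sites = c(1, 1, 2))
  st$rab5_exp[] <- 1e12                 # all sites Rab5-positive
  set.seed(8)
  expect_identical(nucleate_buds(st, p, t = 0)$bud_t, st$bud_t)
  # a bud whose site acquires Rab5 during the lag still releases
  st$bud_t[1] <- 3
  st2 <- release_buds(st, p, t = 3)
  expect_identical(st2$ee[1], 0L)
  expect_identical(st2$exo_cargo, 2L)
  expect_identical(st2$bud_t[1], Inf)
})

test_that("exocytic fusion deposits cargo on the surface", {
  p <- tiny_params()
  st <- scripted_state(p)
  st$exo_arr <- c(2, 2)
  st$exo_cargo <- c(0L, 4L)
  set.seed(13)
  st2 <- fuse_exocytic(st, t = 2)
  expect_identical(sum(st2$surf), 4L)   # cargo-0 fusion changes nothing
  expect_identical(length(st2$exo_arr), 0L)
})

test_that("every kernel conserves receptors through full steps", {
  p <- tiny_params()
  set.seed(17)
  st <- init_state(p)
  total <- census(st, p)[["total"]]
  sw <- new_switch(p)
  for (i in 1:150) {
    out <- step_once(st, sw, k_endo_now = 30, p)
    st <- out$st
    sw <- out$sw
    expect_conserved(st, p, total)
  }
  # something actually happened
  expect_gt(length(st$endo_arr) + length(st$exo_arr) +
              sum(is.finite(st$pit_t)), 0)
})
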