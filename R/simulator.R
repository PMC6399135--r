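#' @useDynLib endosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

engine_pars <- function(p) {
  out <- p[c("lattice_side", "S_im", "dt", "lattice_spacing", "d_s", "d_EE",
             "k_exo", "tau_pit_range", "tau_bud_range",
             "tau_endo_mean", "tau_endo_sd", "tau_exo_mean", "tau_exo_sd",
             "a", "b", "C", "K", "tau_s")]
  out$tau_rab5_scale <- tau_rab5_seconds_per_unit(p)
  out
}

disabled_switch <- function() {
  structure(list(h = 2, t_exc = NA_real_, T_above = 0,
                 sorted = FALSE, t_sort = NA_real_),
            class = "endosim_switch")
}

run_engine <- function(st, sw, k_endo_min, p, n_steps,
                       record_every = 10L, enable_switch = TRUE,
                       audit = TRUE) {
  if (is.null(sw)) {
    sw <- disabled_switch()
    enable_switch <- FALSE
  }
  sim_engine_cpp(unclass(st), unclass(sw), k_endo_min, engine_pars(p),
                 as.integer(n_steps), as.integer(record_every),
                 enable_switch, audit)
}

run_engine_R <- function(st, sw, k_endo_min, p, n_steps,
                         record_every = 10L, audit = TRUE) {
  # reference path: same phase order, per-site Bernoulli nucleation
  nbr <- neighbor_index(p$lattice_side)
  n_rec <- n_steps %/% record_every
  rec <- matrix(NA_real_, n_rec, 9,
                dimnames = list(NULL, c("t", "postsyn", "ee_total", "n_rab5",
                                        "n_ee_rab5", "endo_transit",
                                        "exo_transit", "sorted_tally",
                                        "p_sort")))
  total0 <- census(st, p)[["total"]]
  ri <- 0L
  for (i in seq_len(n_steps)) {
    out <- step_once(st, sw, k_endo_min[i], p, nbr)
    st <- out$st
    sw <- out$sw
    if (i %% record_every == 0L) {
      ri <- ri + 1L
      cen <- census(st, p)
      if (audit && cen[["total"]] != total0) {
        stop("receptor conservation violated in R engine")
      }
      rec[ri, ] <- c(st$t, cen[["surface_mobile"]] + p$S_im, cen[["ee"]],
                     sum(is.finite(st$rab5_exp)), ee_rab5_count(st),
                     cen[["in_transit_endo"]], cen[["in_transit_exo"]],
                     st$sorted_tally,
                     if (is.null(sw)) 0 else p_sort(sw, p))
    }
  }
  list(state = st, sw = sw, records = rec,
       n_sorted = if (!is.null(sw) && sw$sorted) NA else 0L)
}

#' Equilibrate the basal recycling dynamics
#'
#' Runs the stimulus-free dynamics (sorting disabled) from the nominal
#' initial condition (`n_surface_init` surface / `n_ee_init` EE
#' receptors) until the compartment counts are stationary, then averages
#' each compartment over a further 5 simulated minutes. Stationarity is
#' declared when the mean surface and EE counts of two successive 5-min
#' windows agree within 2% of the total mobile receptor census (the
#' individual compartments hold only tens of receptors, so a relative
#' criterion on a compartment mean would never be met under their
#' Poisson-scale fluctuations; see the vignette).
#'
#' @param p an `endosim_params`.
#' @param seed integer seed for the equilibration RNG stream.
#' @param max_minutes simulated-time limit before giving up (default
#'   120).
#' @return an object of class `endosim_init`: rounded mean counts
#'   `surface`, `ee`, `endo_transit`, `exo_transit` plus the simulated
#'   time used.
#' @export
equilibrate <- function(p, seed = 1L, max_minutes = 120) {
  validate_params(p)
  set.seed(seed)
  st <- init_state(p)
  chunk_steps <- as.integer(5 * 60 / p$dt)
  k_basal <- rep(p$k0, chunk_steps)
  prev <- NULL
  minutes <- 0
  converged <- FALSE
  while (minutes < max_minutes) {
    out <- run_engine(st, NULL, k_basal, p, chunk_steps,
                      record_every = 10L, audit = TRUE)
    st <- out$state
    minutes <- minutes + 5
    rec <- out$records
    cur <- c(surface = mean(rec[, "postsyn"]) - p$S_im,
             ee = mean(rec[, "ee_total"]))
    tol <- 0.02 * (p$n_surface_init + p$n_ee_init)
    if (!is.null(prev) && all(abs(cur - prev) <= tol)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged) {
    stop("equilibration did not reach stationarity within ", max_minutes,
         " simulated minutes")
  }
  out <- run_engine(st, NULL, k_basal, p, chunk_steps,
                    record_every = 10L, audit = TRUE)
  rec <- out$records
  structure(list(
    surface = as.integer(round(mean(rec[, "postsyn"]) - p$S_im)),
    ee = as.integer(round(mean(rec[, "ee_total"]))),
    endo_transit = as.integer(round(mean(rec[, "endo_transit"]))),
    exo_transit = as.integer(round(mean(rec[, "exo_transit"]))),
    minutes = minutes + 5, seed = seed
  ), class = "endosim_init")
}

#' @export
print.endosim_init <- function(x, ...) {
  cat(sprintf(
    "<endosim_init> surface %d, EE %d, endo transit %d, exo transit %d (%g sim min)\n",
    x$surface, x$ee, x$endo_transit, x$exo_transit, x$minutes))
  invisible(x)
}

step_grid_k_endo <- function(p, profile) {
  t0 <- p$t_start * 60
  n_steps <- as.integer(round((p$t_end - p$t_start) * 60 / p$dt))
  tmin <- (t0 + seq_len(n_steps) * p$dt) / 60
  k <- rep(p$k0, n_steps)
  if (!is.null(profile)) k <- k + k_ep(profile, tmin)
  list(k = k, n_steps = n_steps)
}

#' Run a single trial
#'
#' Simulates one trial from `t_start` to `t_end` minutes at step `dt`,
#' with the stimulus starting at t = 0 and sampling recorded every
#' second. The per-trial threshold `h` is drawn from its Gaussian at the
#' start of the trial. `N_syn` and `N_EE_Rab5` are normalized by the
#' baseline postsynaptic count, the mean over `[t_start, 0)`.
#'
#' @param p an `endosim_params`.
#' @param profile an `endosim_profile`, or `NULL` for a stimulus-free
#'   trial.
#' @param seed integer seed; the trial is a deterministic function of
#'   `(p, profile, seed)`.
#' @param init an `endosim_init` from [equilibrate()], or `NULL` to
#'   equilibrate on the fly (seed `seed`).
#' @param engine `"cpp"` (default) or `"R"` (slow reference path, for
#'   validation on short windows).
#' @param record_every recording cadence in steps (default one second).
#' @return an `endosim_trial`: list with `series` (data.frame `t_min`,
#'   `N_syn`, `D_Rab5`, `N_EE_Rab5`), `t_sort` (minutes or `NA`),
#'   `t_exc`, `n_sorted`, `h`, `baseline` (receptor count), `seed`,
#'   `profile` label.
#' @export
run_trial <- function(p, profile, seed, init = NULL,
                      engine = c("cpp", "R"), record_every = NULL) {
  validate_params(p)
  engine <- match.arg(engine)
  if (is.null(init)) init <- equilibrate(p, seed = seed)
  if (is.null(record_every)) record_every <- max(1L, as.integer(1 / p$dt))
  set.seed(seed)
  sw <- new_switch(p)
  st <- init_state(p, n_surface = init$surface, n_ee = init$ee,
                   n_endo = init$endo_transit, n_exo = init$exo_transit)
  grid <- step_grid_k_endo(p, profile)
  out <- if (engine == "cpp") {
    run_engine(st, sw, grid$k, p, grid$n_steps,
               record_every = record_every, audit = TRUE)
  } else {
    run_engine_R(st, sw, grid$k, p, grid$n_steps,
                 record_every = record_every, audit = TRUE)
  }
  rec <- out$records
  t_min <- rec[, "t"] / 60
  base_idx <- t_min < 0
  if (!any(base_idx)) stop("no baseline samples: t_start must be < 0")
  baseline <- mean(rec[base_idx, "postsyn"])
  sw_out <- out$sw
  structure(list(
    series = data.frame(
      t_min = t_min,
      N_syn = rec[, "postsyn"] / baseline,
      D_Rab5 = rec[, "n_rab5"] / p$lattice_side^2,
      N_EE_Rab5 = rec[, "n_ee_rab5"] / baseline
    ),
    t_sort = if (is.na(sw_out$t_sort)) NA_real_ else sw_out$t_sort / 60,
    t_exc = if (is.na(sw_out$t_exc)) NA_real_ else sw_out$t_exc / 60,
    n_sorted = if (engine == "cpp") out$n_sorted else
      out$state$sorted_tally,
    h = sw_out$h,
    baseline = baseline,
    seed = seed,
    profile = if (is.null(profile)) "none" else profile$label
  ), class = "endosim_trial")
}

#' @export
print.endosim_trial <- function(x, ...) {
  cat(sprintf(
    "<endosim_trial %s seed %d> baseline %.1f receptors, t_sort %s, h %.3f\n",
    x$profile, x$seed, x$baseline,
    if (is.na(x$t_sort)) "none" else sprintf("%.2f min", x$t_sort), x$h))
  invisible(x)
}

#' Per-trial seeds of an ensemble
#'
#' Counter-based derivation: seed_i = (base_seed + i * 1000003) mod
#' (2^31 - 1), i = 1..n. Trials can therefore be run in any order, or in
#' parallel, without changing results; all seeds are distinct for any
#' realistic repetition count.
#'
#' @param base_seed integer base seed.
#' @param n number of trials.
#' @return integer vector of `n` seeds.
#' @export
ensemble_seeds <- function(base_seed, n) {
  as.integer((as.double(base_seed) + seq_len(n) * 1000003) %% 2147483647)
}

#' Run a repetition ensemble
#'
#' Runs `n_reps` independent trials of one profile; each trial's seed is
#' derived from `base_seed` with [ensemble_seeds()]. One shared
#' equilibration (seed `base_seed`) provides the initial counts for
#' every trial unless `init` is supplied.
#'
#' @param p an `endosim_params`.
#' @param profile an `endosim_profile` or `NULL`.
#' @param n_reps number of repetitions (default 100).
#' @param base_seed integer base seed.
#' @param init optional shared `endosim_init`.
#' @param progress print a dot per completed trial.
#' @return an `endosim_ensemble`: list of trials plus metadata.
#' @export
run_ensemble <- function(p, profile, n_reps = 100L, base_seed = 1L,
                         init = NULL, progress = FALSE) {
  stopifnot(n_reps >= 1)
  if (is.null(init)) init <- equilibrate(p, seed = base_seed)
  seeds <- ensemble_seeds(base_seed, n_reps)
  trials <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    trials[[i]] <- run_trial(p, profile, seeds[i], init = init)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(
    trials = trials,
    profile = if (is.null(profile)) "none" else profile$label,
    params = p,
    base_seed = base_seed,
    seeds = seeds,
    init = init
  ), class = "endosim_ensemble")
}

#' @export
print.endosim_ensemble <- function(x, ...) {
  ts <- t_sorts(x)
  cat(sprintf(
    "<endosim_ensemble %s> %d trials, sorting occurrence %.0f%%\n",
    x$profile, length(x$trials), 100 * mean(!is.na(ts))))
  invisible(x)
}

#' Sorting times of an ensemble
#'
#' @param ens an `endosim_ensemble`.
#' @return numeric vector of per-trial sorting times in minutes (`NA`
#'   for trials without a sorting event).
#' @export
t_sorts <- function(ens) {
  vapply(ens$trials, function(tr) tr$t_sort, numeric(1))
}
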