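#' Per-step trafficking kernels (reference implementation)
#'
#' Pure-R kernels for one integration step of the trafficking dynamics.
#' They define the model's semantics; the compiled engine used by
#' [run_trial()] implements the same rules with binomial event batching
#' (statistically equivalent, asserted in the test suite). All kernels
#' conserve the total receptor count exactly.
#'
#' Rate-to-probability conversion uses the exact Poisson-clock form
#' `1 - exp(-k * dt)`, not `k * dt`, so stimulated rates remain valid.
#'
#' @name trafficking_kernels
NULL

rate_to_prob <- function(k_per_min, dt_s) {
  1 - exp(-k_per_min / 60 * dt_s)
}

neighbor_index <- function(L) {
  # 4-neighbour index table (toroidal) for an L x L column-major lattice
  s <- 0:(L * L - 1)
  row <- s %% L
  col <- s %/% L
  cbind(
    up    = ((row + L - 1) %% L) + col * L + 1,
    down  = ((row + 1) %% L) + col * L + 1,
    left  = row + ((col + L - 1) %% L) * L + 1,
    right = row + ((col + 1) %% L) * L + 1
  )
}

#' Lateral diffusion on a lattice
#'
#' Each receptor independently hops to each of its four toroidal
#' neighbours with per-direction probability `q = d * dt /
#' lattice_spacing^2`, else stays. Occupancy is unbounded; the move is
#' synchronous (all hops computed from the pre-step occupancy).
#'
#' @param occ integer occupancy vector (length `lattice_side^2`).
#' @param d diffusion coefficient, um^2 s^-1.
#' @param p an `endosim_params`.
#' @param nbr optional precomputed [neighbor_index()] table.
#' @return the post-step occupancy vector (same total).
#' @export
diffuse <- function(occ, d, p, nbr = neighbor_index(p$lattice_side)) {
  q <- hop_probability(p, d)
  if (q == 0) return(occ)
  occupied <- which(occ > 0L)
  if (!length(occupied)) return(occ)
  new_occ <- occ
  for (s in occupied) {
    n <- occ[s]
    u <- stats::runif(n)
    dir <- findInterval(u, c(q, 2 * q, 3 * q, 4 * q)) + 1L  # 1..4 hop, 5 stay
    moved <- dir <= 4L
    if (any(moved)) {
      dest <- nbr[s, dir[moved]]
      new_occ[s] <- new_occ[s] - sum(moved)
      for (d2 in dest) new_occ[d2] <- new_occ[d2] + 1L
    }
  }
  new_occ
}

#' Nucleate clathrin-coated pits
#'
#' Each pit-free surface site independently forms a pit with probability
#' `1 - exp(-k_endo * dt)`; a new pit is assigned a scission time
#' `t + tau_pit`, `tau_pit ~ Uniform(tau_pit_range)` (seconds). At most
#' one pending pit per site.
#'
#' @param st an `endosim_state`.
#' @param k_endo_now current total endocytosis rate `k0 + k_ep(t)`,
#'   min^-1.
#' @param p an `endosim_params`.
#' @param t current time, seconds.
#' @return the updated state.
#' @export
nucleate_pits <- function(st, k_endo_now, p, t) {
  stopifnot(k_endo_now >= 0)
  if (k_endo_now == 0) return(st)
  pr <- rate_to_prob(k_endo_now, p$dt)
  free <- which(st$pit_t == Inf)
  hit <- free[stats::runif(length(free)) < pr]
  if (length(hit)) {
    st$pit_t[hit] <- t +
      stats::runif(length(hit), p$tau_pit_range[1], p$tau_pit_range[2])
  }
  st
}

#' Pit scission
#'
#' Every pit whose scission time has passed is removed; the site's entire
#' current occupancy (possibly zero: empty vesicles still traffic) becomes
#' the cargo of an endocytic vesicle scheduled to arrive at the EE after
#' `tau_endo ~ N(tau_endo_mean, tau_endo_sd)` minutes (truncated below at
#' one time step).
#'
#' @inheritParams nucleate_pits
#' @return the updated state.
#' @export
scission <- function(st, p, t) {
  due <- which(st$pit_t <= t)
  if (!length(due)) return(st)
  for (s in due) {
    cargo <- st$surf[s]
    st$surf[s] <- 0L
    st$pit_t[s] <- Inf
    tau <- max(stats::rnorm(1, p$tau_endo_mean, p$tau_endo_sd) * 60, p$dt)
    st$endo_arr <- c(st$endo_arr, t + tau)
    st$endo_cargo <- c(st$endo_cargo, cargo)
  }
  st
}

#' Endocytic vesicle fusion and Rab5 recruitment
#'
#' Every endocytic vesicle whose arrival time has passed fuses at a
#' uniformly random EE site: its cargo is added there and Rab5 is
#' recruited to the site with expiry `t + tau_Rab5(D)`, where `D` is the
#' Rab5-positive fraction evaluated just before this vesicle's own Rab5
#' is placed (vesicles fusing within one step see each other
#' sequentially). The lifetime is frozen at recruitment. If the site
#' already carries Rab5, the existing expiry is kept (single-Rab5 rule).
#'
#' @inheritParams nucleate_pits
#' @return the updated state.
#' @export
fuse_endocytic <- function(st, p, t) {
  due <- which(st$endo_arr <= t)
  if (!length(due)) return(st)
  L2 <- length(st$ee)
  for (i in due) {
    s <- sample.int(L2, 1)
    st$ee[s] <- st$ee[s] + st$endo_cargo[i]
    if (!is.finite(st$rab5_exp[s])) {
      D <- mean(is.finite(st$rab5_exp))
      st$rab5_exp[s] <- t + tau_rab5(D, p) * tau_rab5_seconds_per_unit(p)
    }
  }
  st$endo_arr <- st$endo_arr[-due]
  st$endo_cargo <- st$endo_cargo[-due]
  st
}

#' Rab5 expiry
#'
#' Removes every Rab5 whose expiry time has passed. Receptors at those
#' sites are unaffected (receptor residence is independent of Rab5).
#'
#' @inheritParams nucleate_pits
#' @return the updated state.
#' @export
expire_rab5 <- function(st, t) {
  gone <- is.finite(st$rab5_exp) & st$rab5_exp <= t
  st$rab5_exp[gone] <- -Inf
  st
}

#' Nucleate exocytic buds
#'
#' Each Rab5-free, bud-free EE site buds with probability
#' `1 - exp(-k_exo * dt)`; release time `t + tau_bud`,
#' `tau_bud ~ Uniform(tau_bud_range)` (seconds). The Rab5-free gate is
#' checked at nucleation only: a bud whose site later acquires Rab5 still
#' releases.
#'
#' @inheritParams nucleate_pits
#' @return the updated state.
#' @export
nucleate_buds <- function(st, p, t) {
  pr <- rate_to_prob(p$k_exo, p$dt)
  free <- which(st$bud_t == Inf & !is.finite(st$rab5_exp))
  hit <- free[stats::runif(length(free)) < pr]
  if (length(hit)) {
    st$bud_t[hit] <- t +
      stats::runif(length(hit), p$tau_bud_range[1], p$tau_bud_range[2])
  }
  st
}

#' Bud release
#'
#' Mirror of [scission()]: due buds take their site's entire current
#' occupancy as cargo and become exocytic vesicles arriving at the
#' surface after `tau_exo ~ N(tau_exo_mean, tau_exo_sd)` minutes
#' (truncated below at one time step).
#'
#' @inheritParams nucleate_pits
#' @return the updated state.
#' @export
release_buds <- function(st, p, t) {
  due <- which(st$bud_t <= t)
  if (!length(due)) return(st)
  for (s in due) {
    cargo <- st$ee[s]
    st$ee[s] <- 0L
    st$bud_t[s] <- Inf
    tau <- max(stats::rnorm(1, p$tau_exo_mean, p$tau_exo_sd) * 60, p$dt)
    st$exo_arr <- c(st$exo_arr, t + tau)
    st$exo_cargo <- c(st$exo_cargo, cargo)
  }
  st
}

#' Exocytic vesicle fusion
#'
#' Due exocytic vesicles deposit their cargo at a uniformly random
#' surface site, where it joins the mobile pool.
#'
#' @inheritParams nucleate_pits
#' @return the updated state.
#' @export
fuse_exocytic <- function(st, t) {
  due <- which(st$exo_arr <= t)
  if (!length(due)) return(st)
  L2 <- length(st$surf)
  for (i in due) {
    s <- sample.int(L2, 1)
    st$surf[s] <- st$surf[s] + st$exo_cargo[i]
  }
  st$exo_arr <- st$exo_arr[-due]
  st$exo_cargo <- st$exo_cargo[-due]
  st
}

#' One full integration step (reference path)
#'
#' Advances the state by `dt` using the fixed phase order:
#' (1) Rab5 expiry, (2) vesicle fusion (endocytic then exocytic),
#' (3) pit scission and bud release, (4) nucleation (pits then buds),
#' (5) diffusion (surface then EE), (6) switch update and sorting draw.
#' The order is fixed for reproducibility.
#'
#' @param st an `endosim_state`.
#' @param sw an `endosim_switch` or `NULL` to disable sorting.
#' @param k_endo_now total endocytosis rate at this step, min^-1.
#' @param p an `endosim_params`.
#' @param nbr optional precomputed neighbour table.
#' @return list `(st, sw)` with time advanced by `dt`.
#' @export
step_once <- function(st, sw, k_endo_now, p,
                      nbr = neighbor_index(p$lattice_side)) {
  t <- st$t + p$dt
  st$t <- t
  st <- expire_rab5(st, t)
  st <- fuse_endocytic(st, p, t)
  st <- fuse_exocytic(st, t)
  st <- scission(st, p, t)
  st <- release_buds(st, p, t)
  st <- nucleate_pits(st, k_endo_now, p, t)
  st <- nucleate_buds(st, p, t)
  st$surf <- diffuse(st$surf, p$d_s, p, nbr)
  st$ee <- diffuse(st$ee, p$d_EE, p, nbr)
  if (!is.null(sw) && !sw$sorted) {
    sw <- update_switch(sw, d_rab5(st), t, p$dt)
    res <- maybe_sort(sw, st, p, t)
    sw <- res$sw
    st <- res$st
  }
  list(st = st, sw = sw)
}
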