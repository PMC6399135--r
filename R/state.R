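#' Simulation state
#'
#' The state of one trial: two occupancy lattices (surface and early
#' endosome), per-site pending timed events (pit scission, bud release,
#' Rab5 expiry), the queues of in-transit vesicles, and the absorbing
#' late-endosome tally. Sites are stored column-major as flat vectors of
#' length `lattice_side^2`. Pending-event vectors hold the absolute event
#' time in seconds, with `Inf` (pits, buds) or `-Inf` (Rab5) meaning
#' "none". A site is Rab5-positive iff its `rab5_exp` entry is finite;
#' expiry is executed at the first step whose time is >= the entry.
#'
#' @name endosim_state
NULL

new_state <- function(p) {
  L2 <- p$lattice_side^2
  structure(list(
    surf      = integer(L2),
    ee        = integer(L2),
    pit_t     = rep(Inf, L2),
    bud_t     = rep(Inf, L2),
    rab5_exp  = rep(-Inf, L2),
    endo_arr  = numeric(0),  # arrival times, seconds
    endo_cargo = integer(0),
    exo_arr   = numeric(0),
    exo_cargo = integer(0),
    sorted_tally = 0L,
    t = p$t_start * 60       # current time, seconds
  ), class = "endosim_state")
}

scatter_counts <- function(n, L2) {
  # place n receptors uniformly at random over L2 sites -> occupancy vector
  if (n == 0) return(integer(L2))
  tabulate(sample.int(L2, n, replace = TRUE), nbins = L2)
}

#' Initialize a simulation state
#'
#' Places `n_surface` receptors uniformly at random on the surface lattice
#' and `n_ee` on the EE lattice, with empty vesicle queues, no pending
#' pits or buds, and no Rab5. Optionally seeds the vesicle queues with
#' `n_endo` / `n_exo` in-transit receptors (one receptor per vesicle,
#' arrival times uniform over one mean transit time) so that a trial can
#' start from equilibrated compartment counts; the 10-minute pre-stimulus
#' window then relaxes the transient introduced by this approximation.
#'
#' Uses the R random number generator; call `set.seed()` first for
#' reproducible placements.
#'
#' @param p an `endosim_params` object.
#' @param n_surface,n_ee,n_endo,n_exo receptor counts per compartment;
#'   default to `p$n_surface_init`, `p$n_ee_init`, 0, 0.
#' @return an `endosim_state`.
#' @export
init_state <- function(p, n_surface = p$n_surface_init, n_ee = p$n_ee_init,
                       n_endo = 0L, n_exo = 0L) {
  validate_params(p)
  st <- new_state(p)
  L2 <- p$lattice_side^2
  st$surf <- scatter_counts(n_surface, L2)
  st$ee <- scatter_counts(n_ee, L2)
  t0 <- st$t
  if (n_endo > 0) {
    st$endo_arr <- t0 + stats::runif(n_endo, 0, p$tau_endo_mean * 60)
    st$endo_cargo <- rep(1L, n_endo)
  }
  if (n_exo > 0) {
    st$exo_arr <- t0 + stats::runif(n_exo, 0, p$tau_exo_mean * 60)
    st$exo_cargo <- rep(1L, n_exo)
  }
  st
}

#' Receptor census
#'
#' Exact integer bookkeeping of every receptor's location class. The
#' total is invariant over a trial (the late-endosome tally is an
#' absorbing sink inside the closed system).
#'
#' @param st an `endosim_state`.
#' @param p an `endosim_params` (for the immobile count).
#' @return a named integer vector with components `surface_mobile`,
#'   `surface_immobile`, `ee`, `in_transit_endo`, `in_transit_exo`,
#'   `sorted_to_LE`, `total`.
#' @export
census <- function(st, p) {
  out <- c(
    surface_mobile  = sum(st$surf),
    surface_immobile = as.integer(p$S_im),
    ee              = sum(st$ee),
    in_transit_endo = sum(st$endo_cargo),
    in_transit_exo  = sum(st$exo_cargo),
    sorted_to_LE    = as.integer(st$sorted_tally)
  )
  c(out, total = sum(out))
}

#' Fraction of Rab5-positive EE sites
#'
#' @param st an `endosim_state`.
#' @return `D_Rab5`, the number of Rab5-bearing EE sites divided by the
#'   number of sites; always in \[0, 1\].
#' @export
d_rab5 <- function(st) {
  mean(is.finite(st$rab5_exp))
}

#' Receptors co-resident with Rab5
#'
#' Raw count of EE receptors sitting on Rab5-positive sites (the vacuolar
#' portion); the pool removed to the late endosome at a sorting event.
#'
#' @param st an `endosim_state`.
#' @return integer count.
#' @export
ee_rab5_count <- function(st) {
  sum(st$ee[is.finite(st$rab5_exp)])
}

#' Snapshot a state as a site table
#'
#' Columnar debugging snapshot: one row per lattice site with surface and
#' EE occupancy and the Rab5 flag.
#'
#' @param st an `endosim_state`.
#' @return a `data.frame` with columns `site`, `surf`, `ee`, `rab5`.
#' @export
state_snapshot <- function(st) {
  data.frame(
    site = seq_along(st$surf),
    surf = st$surf,
    ee = st$ee,
    rab5 = is.finite(st$rab5_exp)
  )
}
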