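#' Rab5 lifetime
#'
#' State-dependent residence time of a newly recruited Rab5 molecule:
#' `tau_Rab5(D) = K * D * (C - D) / (1 + exp(-(D - a)/b))`,
#' where `D` is the current fraction of Rab5-positive EE sites. The
#' numerator is autocatalytic growth with a limiting factor (zero at both
#' `D = 0` and `D = C`); the sigmoidal denominator suppresses lifetimes
#' below the ignition point `a`, shaping the rise. The lifetime is
#' returned in the unit carried by `K` (`p$tau_rab5_unit`; see
#' [default_parameters()] for why the default is hours) and is frozen at
#' recruitment: later changes of `D` do not affect Rab5 already on the
#' lattice.
#'
#' @param D fraction of Rab5-positive sites (vectorized), in `[0, C]`.
#' @param p an `endosim_params`.
#' @return lifetime(s), in `p$tau_rab5_unit`.
#' @examples
#' p <- default_parameters()
#' tau_rab5(0.4, p)  # ~5.6 (zero at D = 0 and at D = C)
#' @export
tau_rab5 <- function(D, p) {
  if (any(D < 0 | D > p$C)) {
    stop("D must lie in [0, C] = [0, ", p$C, "]")
  }
  p$K * D * (p$C - D) / (1 + exp(-(D - p$a) / p$b))
}

tau_rab5_seconds_per_unit <- function(p) {
  switch(p$tau_rab5_unit, hour = 3600, min = 60,
         stop("unsupported tau_rab5_unit"))
}

#' Sorting switch
#'
#' Per-trial soft threshold for the commitment of the Rab5-positive EE
#' portion to the late endosome. The threshold `h` is drawn once per
#' trial; `t_exc` is the first time `D_Rab5 >= h`; `T_above` accumulates
#' the time spent at or above `h` after `t_exc` (time below the threshold
#' is excluded, freezing the sorting probability during dips).
#'
#' @param h threshold in (0, 1); if `NULL`, drawn from
#'   `N(h_mean, h_sd)` truncated to (0, 1) using the current RNG state.
#' @param p an `endosim_params`.
#' @return an `endosim_switch`: list with `h`, `t_exc` (seconds, `NA`
#'   until crossing), `T_above` (seconds), `sorted`, `t_sort`.
#' @export
new_switch <- function(p, h = NULL) {
  if (is.null(h)) h <- draw_threshold(p)
  structure(list(h = h, t_exc = NA_real_, T_above = 0,
                 sorted = FALSE, t_sort = NA_real_),
            class = "endosim_switch")
}

draw_threshold <- function(p) {
  for (i in 1:100) {
    h <- stats::rnorm(1, p$h_mean, p$h_sd)
    if (h > 0 && h < 1) return(h)
  }
  min(max(h, p$dt / 60), 1 - 1e-9)  # pathological sd: clamp
}

#' Advance the sorting switch by one time step
#'
#' Sets `t_exc` at the first step with `D_now >= h`; on subsequent steps
#' with `D_now >= h` adds `dt` to `T_above`.
#'
#' @param sw an `endosim_switch`.
#' @param D_now current fraction of Rab5-positive sites.
#' @param t current time, seconds.
#' @param dt time step, seconds.
#' @return the updated switch.
#' @export
update_switch <- function(sw, D_now, t, dt) {
  if (D_now >= sw$h) {
    if (is.na(sw$t_exc)) {
      sw$t_exc <- t
    } else {
      sw$T_above <- sw$T_above + dt
    }
  }
  sw
}

#' Sorting probability
#'
#' `p_sort = 0` before the threshold crossing and
#' `1 - min(exp(-T_above / tau_s), 1)` after it; monotone non-decreasing
#' along any trajectory because `T_above` never decreases.
#'
#' @param sw an `endosim_switch`.
#' @param p an `endosim_params` (`tau_s` in minutes).
#' @return probability in `[0, 1]`.
#' @export
p_sort <- function(sw, p) {
  if (is.na(sw$t_exc)) return(0)
  1 - min(exp(-(sw$T_above / 60) / p$tau_s), 1)
}

#' Attempt the sorting event
#'
#' Draws one uniform number per call (one per time step in the
#' simulator); if it falls below `p_sort`, all receptors currently on
#' Rab5-positive EE sites are transferred to the late-endosome tally,
#' the Rab5 of those sites is cleared, and the switch is marked sorted.
#' At most one sorting event occurs per trial.
#'
#' @param sw an `endosim_switch` with `sw$sorted == FALSE`.
#' @param st an `endosim_state`.
#' @param p an `endosim_params`.
#' @param t current time, seconds.
#' @return list `(sw, st, n_sorted)`; `n_sorted` is 0 when no event
#'   fired.
#' @export
maybe_sort <- function(sw, st, p, t) {
  stopifnot(!sw$sorted)
  n_sorted <- 0L
  ps <- p_sort(sw, p)
  if (ps > 0 && stats::runif(1) < ps) {
    pos <- is.finite(st$rab5_exp)
    n_sorted <- sum(st$ee[pos])
    st$ee[pos] <- 0L
    st$rab5_exp[pos] <- -Inf
    st$sorted_tally <- st$sorted_tally + n_sorted
    sw$sorted <- TRUE
    sw$t_sort <- t
  }
  list(sw = sw, st = st, n_sorted = n_sorted)
}
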