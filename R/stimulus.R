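#' Endocytosis profiles
#'
#' LTD-inducing stimulation is abstracted as a time-dependent addition
#' `k_ep(t)` to the basal pit-nucleation rate. Each profile is a
#' piecewise concave pulse: a Gaussian rise on `[0, t_peak - 3)`, a
#' plateau of height `A` on `[t_peak - 3, t_peak + 3)`, and an
#' exponential decay from `t_peak + 3` on; `k_ep` is continuous at both
#' junctions and zero for `t < 0`. The five LTD-inducing profiles
#' EP1..EP5 share a common time integral (the magnitude of the stimulus)
#' but stagger their peak times to model different speeds of LTD
#' expression; the mild profile EPm has EP3's timing with a much smaller
#' integral.
#'
#' @name endocytosis_profile
NULL

profile_shape_integral <- function(t_peak, sigma, tau_decay) {
  # integral of the unit-amplitude pulse over [0, Inf):
  # truncated half-Gaussian rise + 6-min plateau + exponential tail
  rise <- sigma * sqrt(2 * pi) * (stats::pnorm((t_peak - 3) / sigma) - 0.5)
  rise + 6 + tau_decay
}

#' Build an endocytosis profile
#'
#' @param label one of `"EP1"`..`"EP5"`, `"EPm"`.
#' @param p an `endosim_params`; supplies the peak times
#'   (`ep_t_peaks`), the common target integral (`ep_target_integral`),
#'   the decay constant (`ep_tau_decay`) and the EPm integral fraction
#'   (`epm_fraction`).
#' @param t_peak,sigma_rise,tau_decay,target_integral optional overrides
#'   for a custom profile (then `label` is only a tag). `sigma_rise`
#'   defaults to `(t_peak - 3) / 2` so the rise spans the pre-plateau
#'   support.
#' @return an object of class `endosim_profile` with fields `label`,
#'   `t_peak`, `A` (plateau amplitude, min^-1), `sigma_rise`,
#'   `tau_decay`, `target_integral` (all times in minutes).
#' @examples
#' p <- default_parameters()
#' ep1 <- make_profile("EP1", p)
#' k_ep(ep1, ep1$t_peak)  # plateau amplitude
#' @export
make_profile <- function(label, p = default_parameters(),
                         t_peak = NULL, sigma_rise = NULL,
                         tau_decay = NULL, target_integral = NULL) {
  known <- c(paste0("EP", 1:5), "EPm")
  if (is.null(t_peak)) {
    if (!label %in% known) {
      stop("unknown profile label: ", label,
           " (expected EP1..EP5, EPm, or explicit t_peak)")
    }
    t_peak <- if (label == "EPm") p$ep_t_peaks[3] else
      p$ep_t_peaks[match(label, known)]
  }
  if (t_peak <= 3) stop("degenerate profile: t_peak must exceed 3 min")
  if (is.null(sigma_rise)) sigma_rise <- (t_peak - 3) / 2
  if (is.null(tau_decay)) tau_decay <- p$ep_tau_decay
  if (is.null(target_integral)) {
    target_integral <- if (identical(label, "EPm")) {
      p$ep_target_integral * p$epm_fraction
    } else {
      p$ep_target_integral
    }
  }
  A <- solve_amplitude(t_peak, sigma_rise, tau_decay, target_integral)
  structure(list(label = label, t_peak = t_peak, A = A,
                 sigma_rise = sigma_rise, tau_decay = tau_decay,
                 target_integral = target_integral),
            class = "endosim_profile")
}

#' Solve the plateau amplitude for a target integral
#'
#' The pulse is linear in its amplitude, so the amplitude giving a
#' prescribed time integral is exact:
#' `A = target / (sigma * sqrt(2*pi) * (Phi((t_peak-3)/sigma) - 1/2) + 6 + tau_decay)`.
#'
#' @param t_peak peak time, minutes (> 3).
#' @param sigma_rise Gaussian rise width, minutes.
#' @param tau_decay exponential decay constant, minutes.
#' @param target_integral desired integral of `k_ep` over the stimulation
#'   support, min^-1 x min (> 0).
#' @return plateau amplitude `A`, min^-1.
#' @export
solve_amplitude <- function(t_peak, sigma_rise, tau_decay, target_integral) {
  if (t_peak <= 3) stop("degenerate profile: t_peak must exceed 3 min")
  stopifnot(target_integral > 0, sigma_rise > 0, tau_decay > 0)
  target_integral / profile_shape_integral(t_peak, sigma_rise, tau_decay)
}

#' Evaluate a profile
#'
#' @param profile an `endosim_profile`.
#' @param t time(s) in minutes (vectorized); stimulation starts at 0.
#' @return stimulus-driven endocytosis rate `k_ep(t)`, min^-1.
#' @export
k_ep <- function(profile, t) {
  tp <- profile$t_peak
  A <- profile$A
  s <- profile$sigma_rise
  out <- numeric(length(t))
  rise <- t >= 0 & t < tp - 3
  out[rise] <- A * exp(-((t[rise] - (tp - 3))^2) / (2 * s^2))
  plateau <- t >= tp - 3 & t < tp + 3
  out[plateau] <- A
  decay <- t >= tp + 3
  out[decay] <- A * exp(-(t[decay] - (tp + 3)) / profile$tau_decay)
  out
}

#' Numerical integral of a profile
#'
#' Quadrature check of the closed form used by [solve_amplitude()].
#'
#' @param profile an `endosim_profile`.
#' @param upper upper integration limit, minutes.
#' @return integral of `k_ep` over `[0, upper]`.
#' @export
profile_integral <- function(profile, upper = 200) {
  stats::integrate(function(t) k_ep(profile, t), 0, upper,
                   subdivisions = 2000L, rel.tol = 1e-8)$value
}

#' @export
print.endosim_profile <- function(x, ...) {
  cat(sprintf(
    "<endosim_profile %s> t_peak %g min, A %.3f /min, sigma %g, decay %g, integral %g\n",
    x$label, x$t_peak, x$A, x$sigma_rise, x$tau_decay, x$target_integral))
  invisible(x)
}
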