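#' Model parameters
#'
#' Container for every constant of the trafficking model plus the
#' simulator-level choices (lattice spacing, time step, recording window)
#' that the model leaves open. Time-like fields carry explicit units in
#' their names or documentation: rates are per minute, the integration
#' step `dt` is in seconds, delay distributions are in the unit stated
#' below.
#'
#' @details Fields (defaults in parentheses):
#' \describe{
#'   \item{lattice_side}{sites per lattice edge (50); both the surface and
#'     the early-endosome (EE) compartment are `lattice_side^2` grids.}
#'   \item{S_im}{immobile postsynaptic receptor count (40); added to the
#'     mobile surface population when the postsynaptic number is read out.}
#'   \item{k0}{basal per-site clathrin-pit nucleation rate, min^-1 (1.2).}
#'   \item{tau_pit_range}{pit maturation lag, seconds, Uniform (c(1, 2)).}
#'   \item{tau_endo_mean, tau_endo_sd}{endocytic vesicle transit time,
#'     minutes, Gaussian (4, 1), truncated below at one time step.}
#'   \item{a, b, C, K}{constants of the Rab5-lifetime curve
#'     `tau_Rab5(D) = K * D * (C - D) / (1 + exp(-(D - a)/b))`
#'     (0.2, 0.02, 1.1, 20); `K` carries the unit given by
#'     `tau_rab5_unit`.}
#'   \item{tau_rab5_unit}{time unit carried by `K`, `"min"` (default) or
#'     `"hour"`. With minutes, Rab5 ignition is a near-critical cascade
#'     reachable only when endocytosis approaches the flux cap set by
#'     the pit lag, which is what makes sorting probabilistic and the
#'     post-sorting early endosome able to relax back to recycling; see
#'     the vignette for the full analysis.}
#'   \item{d_EE, d_s}{diffusion coefficients on the EE and surface
#'     lattices, um^2 s^-1 (0.05, 0.05).}
#'   \item{k_exo}{per-site budding rate of Rab5-free EE sites, min^-1 (1).}
#'   \item{tau_bud_range}{bud maturation lag, seconds, Uniform
#'     (c(1.5, 2.5)).}
#'   \item{tau_exo_mean, tau_exo_sd}{exocytic vesicle transit time,
#'     minutes, Gaussian (2, 0.5), truncated below at one time step.}
#'   \item{h_mean, h_sd}{sorting-threshold distribution, dimensionless
#'     Gaussian (0.4, 0.02), truncated to (0, 1); one draw per trial.}
#'   \item{tau_s}{softness of the sorting threshold, minutes (0.38).}
#'   \item{dt}{integration time step, seconds (0.1).}
#'   \item{lattice_spacing}{site edge length, um (0.2). Not fixed by the
#'     model; chosen so the per-direction hop probability
#'     `d * dt / lattice_spacing^2` is well below the stability bound.}
#'   \item{n_surface_init, n_ee_init}{pre-equilibration receptor counts on
#'     the surface and the EE (150, 100).}
#'   \item{t_start, t_end}{recording window in minutes (-10, 50); the
#'     stimulus always starts at t = 0.}
#'   \item{ep_t_peaks}{peak times (minutes) of the five LTD-inducing
#'     endocytosis profiles EP1..EP5 (5, 8.5, 12, 15.5, 19).}
#'   \item{ep_tau_decay}{decay constant of the profile tail, minutes (4).}
#'   \item{ep_target_integral}{common time integral of EP1..EP5,
#'     min^-1 x min (25500); calibrated so that every profile ignites
#'     the Rab5 switch in most repetitions while the focused profiles'
#'     mean LTD falls in the 20--35% band. The large value reflects the
#'     near-critical ignition flux of the Rab5 lifetime curve; see the
#'     package vignette.}
#'   \item{epm_fraction}{integral of the mild profile EPm relative to the
#'     LTD-inducing integral (0.25).}
#' }
#'
#' @param ... named fields overriding the defaults.
#' @return A validated object of class `endosim_params`.
#' @seealso [validate_params()], [write_params()], [read_params()]
#' @examples
#' p <- default_parameters()
#' p$k0
#' q <- default_parameters(d_s = 0.02)
#' @export
default_parameters <- function(...) {
  p <- list(
    lattice_side    = 50L,
    S_im            = 40L,
    k0              = 1.2,
    tau_pit_range   = c(1, 2),
    tau_endo_mean   = 4,
    tau_endo_sd     = 1,
    a               = 0.2,
    b               = 0.02,
    C               = 1.1,
    K               = 20,
    tau_rab5_unit   = "min",
    d_EE            = 0.05,
    d_s             = 0.05,
    k_exo           = 1.0,
    tau_bud_range   = c(1.5, 2.5),
    tau_exo_mean    = 2,
    tau_exo_sd      = 0.5,
    h_mean          = 0.4,
    h_sd            = 0.02,
    tau_s           = 0.38,
    dt              = 0.1,
    lattice_spacing = 0.2,
    n_surface_init  = 150L,
    n_ee_init       = 100L,
    t_start         = -10,
    t_end           = 50,
    ep_t_peaks      = c(5, 8.5, 12, 15.5, 19),
    ep_tau_decay    = 4,
    ep_target_integral = 25500,
    epm_fraction    = 0.25
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(p))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    }
    p[names(override)] <- override
  }
  class(p) <- "endosim_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks positivity of rates, delays and diffusion coefficients, the
#' shape constraints of the Rab5-lifetime curve (`0 < a < C`, `b > 0`),
#' the threshold distribution (`0 < h_mean < 1`, `h_sd >= 0`), the
#' ordering of the uniform delay intervals, and the lattice-diffusion
#' stability bound: the per-direction hop probability
#' `d * dt / lattice_spacing^2` must not exceed 0.25 for either lattice.
#'
#' @param p an `endosim_params` object (or plain named list with the same
#'   fields).
#' @return `p` (classed, unchanged) if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_params <- function(p) {
  if (!inherits(p, "endosim_params")) {
    stopifnot(is.list(p))
    class(p) <- "endosim_params"
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  pos <- function(field) {
    x <- p[[field]]
    chk(num1(x) && x > 0, paste0(field, " must be a positive number"))
  }
  for (f in c("k0", "k_exo", "d_EE", "d_s", "tau_endo_mean", "tau_exo_mean",
              "tau_s", "dt", "lattice_spacing", "K", "C",
              "ep_tau_decay", "ep_target_integral", "epm_fraction")) {
    pos(f)
  }
  chk(num1(p$b) && p$b > 0, "b must be positive")
  chk(num1(p$a) && p$a > 0 && p$a < p$C, "a must satisfy 0 < a < C")
  chk(num1(p$h_mean) && p$h_mean > 0 && p$h_mean < 1,
      "h_mean must lie in (0, 1)")
  chk(num1(p$h_sd) && p$h_sd >= 0, "h_sd must be non-negative")
  chk(num1(p$tau_endo_sd) && p$tau_endo_sd >= 0,
      "tau_endo_sd must be non-negative")
  chk(num1(p$tau_exo_sd) && p$tau_exo_sd >= 0,
      "tau_exo_sd must be non-negative")
  for (f in c("tau_pit_range", "tau_bud_range")) {
    r <- p[[f]]
    chk(is.numeric(r) && length(r) == 2L && all(is.finite(r)) &&
          r[1] > 0 && r[1] < r[2],
        paste0(f, " must be c(lower, upper) with 0 < lower < upper"))
  }
  chk(num1(p$lattice_side) && p$lattice_side >= 2 &&
        p$lattice_side == as.integer(p$lattice_side),
      "lattice_side must be an integer >= 2")
  chk(num1(p$S_im) && p$S_im >= 0 && p$S_im == as.integer(p$S_im),
      "S_im must be a non-negative integer")
  for (f in c("n_surface_init", "n_ee_init")) {
    x <- p[[f]]
    chk(num1(x) && x >= 0 && x == as.integer(x),
        paste0(f, " must be a non-negative integer"))
  }
  chk(num1(p$t_start) && num1(p$t_end) && p$t_start < 0 && p$t_end > 0,
      "recording window must satisfy t_start < 0 < t_end")
  chk(is.numeric(p$ep_t_peaks) && length(p$ep_t_peaks) == 5L &&
        all(p$ep_t_peaks > 3) && !is.unsorted(p$ep_t_peaks, strictly = TRUE),
      "ep_t_peaks must be five increasing peak times, each > 3 min")
  chk(p$tau_rab5_unit %in% c("hour", "min"),
      "tau_rab5_unit must be \"hour\" or \"min\"")
  chk(num1(p$epm_fraction) && p$epm_fraction < 1,
      "epm_fraction must lie in (0, 1)")

  # lattice random-walk stability: per-direction hop probability <= 1/4
  for (f in c("d_s", "d_EE")) {
    q <- p[[f]] * p$dt / p$lattice_spacing^2
    chk(q <= 0.25, sprintf(
      "hop probability exceeds 0.25 for %s (%.4g = %s*dt/lattice_spacing^2)",
      f, q, f))
  }
  p
}

#' Per-direction lattice hop probability
#'
#' `d * dt / lattice_spacing^2` for a diffusion coefficient `d` under the
#' parameter set `p`; must be at most 0.25 for the split random walk to
#' reproduce 2D diffusion.
#'
#' @param p an `endosim_params` object.
#' @param d diffusion coefficient, um^2 s^-1.
#' @return the per-direction hop probability per time step.
#' @export
hop_probability <- function(p, d) {
  d * p$dt / p$lattice_spacing^2
}

#' @export
print.endosim_params <- function(x, ...) {
  cat("<endosim_params>\n")
  cat(sprintf("  lattice: %d x %d sites, spacing %g um, dt %g s\n",
              x$lattice_side, x$lattice_side, x$lattice_spacing, x$dt))
  cat(sprintf("  rates:   k0 %g /min, k_exo %g /min\n", x$k0, x$k_exo))
  cat(sprintf("  Rab5:    a %g, b %g, C %g, K %g %s\n",
              x$a, x$b, x$C, x$K, x$tau_rab5_unit))
  cat(sprintf("  switch:  h ~ N(%g, %g), tau_s %g min\n",
              x$h_mean, x$h_sd, x$tau_s))
  cat(sprintf("  window:  %g..%g min; init %d surface / %d EE (+%d immobile)\n",
              x$t_start, x$t_end, x$n_surface_init, x$n_ee_init, x$S_im))
  invisible(x)
}

#' Read and write parameter files
#'
#' Parameters serialize to JSON with keys equal to the field names; a
#' read/write round trip reproduces every field exactly.
#'
#' @param p an `endosim_params` object.
#' @param path file path of the JSON configuration.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a validated `endosim_params`.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  x <- unclass(p)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  int_fields <- c("lattice_side", "S_im", "n_surface_init", "n_ee_init")
  for (f in names(x)) {
    # whole-number doubles come back as integers; restore declared types
    if (is.numeric(x[[f]])) {
      x[[f]] <- if (f %in% int_fields) as.integer(x[[f]]) else
        as.numeric(x[[f]])
    }
  }
  do.call(default_parameters, x)
}
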