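#' Windowed mean of a recorded variable
#'
#' Arithmetic mean of a trial's samples with `t0 <= t < t1` (all analysis
#' windows are half-open). Works on an `endosim_trial` or directly on its
#' `series` data frame.
#'
#' @param trial an `endosim_trial` or a data.frame with a `t_min` column.
#' @param var variable name (`"N_syn"`, `"D_Rab5"`, `"N_EE_Rab5"`).
#' @param t0,t1 window bounds in minutes.
#' @return the per-trial mean.
#' @export
window_mean <- function(trial, var, t0, t1) {
  ser <- if (inherits(trial, "endosim_trial")) trial$series else trial
  sel <- ser$t_min >= t0 & ser$t_min < t1
  if (!any(sel)) stop("empty window [", t0, ", ", t1, ")")
  mean(ser[[var]][sel])
}

ensemble_window_means <- function(ens, var, t0, t1) {
  vapply(ens$trials, window_mean, numeric(1), var = var, t0 = t0, t1 = t1)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return `sd(values) / mean(values)`.
#' @export
cv <- function(values) {
  if (length(values) < 2) stop("cv needs at least two values")
  m <- mean(values)
  if (m == 0) stop("cv undefined for zero mean")
  stats::sd(values) / m
}

#' Windowed ensemble statistic
#'
#' Per-trial window means of one variable plus their ensemble mean, SD
#' and CV.
#'
#' @param ens an `endosim_ensemble`.
#' @param var variable name.
#' @param t0,t1 window in minutes.
#' @return list `(window, per_trial, mean, sd, cv)`.
#' @export
window_stat <- function(ens, var, t0, t1) {
  v <- ensemble_window_means(ens, var, t0, t1)
  list(window = c(t0, t1), per_trial = v, mean = mean(v),
       sd = stats::sd(v), cv = cv(v))
}

#' LTD amounts of an ensemble
#'
#' Per-trial LTD amount: mean `N_syn` over the baseline window
#' `[t_start, 0)` minus mean `N_syn` over the depression window (default
#' the maintenance window `[40, 50)`). Restricted to trials with a
#' sorting event, since late-endosomal sorting is required for LTD
#' maintenance.
#'
#' @param ens an `endosim_ensemble`.
#' @param window depression window in minutes (default `c(40, 50)`).
#' @param sorted_only restrict to sorted trials (default `TRUE`).
#' @return list `(per_trial, mean, cv, n, window)`; amounts are
#'   fractions of baseline (multiply by 100 for percent).
#' @export
ltd_amounts <- function(ens, window = c(40, 50), sorted_only = TRUE) {
  keep <- if (sorted_only) !is.na(t_sorts(ens)) else
    rep(TRUE, length(ens$trials))
  if (!any(keep)) stop("no sorted trials in ensemble")
  trials <- ens$trials[keep]
  amount <- vapply(trials, function(tr) {
    base <- window_mean(tr, "N_syn", tr$series$t_min[1], 0)
    base - window_mean(tr, "N_syn", window[1], window[2])
  }, numeric(1))
  list(per_trial = amount, mean = mean(amount),
       cv = if (length(amount) >= 2 && mean(amount) != 0) cv(amount)
            else NA_real_,
       n = length(amount), window = window)
}

#' Sorting occurrence
#'
#' Fraction of trials in which the EE-to-LE sorting event fired.
#'
#' @param ens an `endosim_ensemble`.
#' @return fraction in `[0, 1]`.
#' @export
sorting_occurrence <- function(ens) {
  mean(!is.na(t_sorts(ens)))
}

sorting_windows <- function() {
  list(early = c(6, 13), intermediate = c(13, 20), late = c(20, 27))
}

#' Histogram of sorting times
#'
#' Counts and frequency ratios of sorting times in the early `[6, 13)`,
#' intermediate `[13, 20)` and late `[20, 27)` windows (half-open;
#' sorting times outside all three windows are counted in the ratio
#' denominator but in no window).
#'
#' @param x a numeric vector of sorting times (minutes), an
#'   `endosim_ensemble`, or a list of ensembles to pool.
#' @return an `endosim_sorting_histogram`: list with `counts`, `ratios`,
#'   `n_sorted`.
#' @export
sorting_histogram <- function(x) {
  ts <- pooled_t_sorts(x)
  ts <- ts[!is.na(ts)]
  if (!length(ts)) stop("no sorted trials")
  w <- sorting_windows()
  counts <- vapply(w, function(b) sum(ts >= b[1] & ts < b[2]), numeric(1))
  structure(list(counts = counts, ratios = counts / length(ts),
                 n_sorted = length(ts)),
            class = "endosim_sorting_histogram")
}

pooled_t_sorts <- function(x) {
  if (is.numeric(x)) return(x)
  if (inherits(x, "endosim_ensemble")) return(t_sorts(x))
  if (is.list(x)) return(unlist(lapply(x, pooled_t_sorts), use.names = FALSE))
  stop("expected sorting times, an ensemble, or a list of ensembles")
}

#' @export
print.endosim_sorting_histogram <- function(x, ...) {
  cat("<sorting histogram>", x$n_sorted, "sorted trials\n")
  print(round(rbind(counts = x$counts, ratios = x$ratios), 3))
  invisible(x)
}

#' Low-variability control data set
#'
#' Synthetic comparison set for the sorting-time histogram: within each
#' ensemble the sorted times are shrunk toward their ensemble mean
#' (`t' = mean + shrink * (t - mean)`), preserving every ensemble's mean
#' sorting time while reducing its variance. With the default shrink the
#' pooled histogram spreads the mass across the three windows (each
#' profile's trials collapse near its own mean), whereas the original
#' stochastic set concentrates occurrence at intermediate times.
#'
#' @param ensembles a list of `endosim_ensemble` objects (or numeric
#'   vectors of sorting times).
#' @param shrink SD shrink factor in `[0, 1]` (default 0.1; 1 reproduces
#'   the original set, 0 collapses each ensemble onto its mean).
#' @return an `endosim_sorting_histogram` of the shrunken pooled set,
#'   with the shrunken times attached as attribute `"t_sort"`.
#' @export
low_variability_control <- function(ensembles, shrink = 0.1) {
  stopifnot(shrink >= 0, shrink <= 1)
  if (inherits(ensembles, "endosim_ensemble") || is.numeric(ensembles)) {
    ensembles <- list(ensembles)
  }
  shrunk <- unlist(lapply(ensembles, function(e) {
    ts <- pooled_t_sorts(e)
    ts <- ts[!is.na(ts)]
    mean(ts) + shrink * (ts - mean(ts))
  }), use.names = FALSE)
  out <- sorting_histogram(shrunk)
  attr(out, "t_sort") <- shrunk
  out
}

#' Ensemble report
#'
#' Summary statistics of a set of ensembles, one per endocytosis
#' profile: sorting occurrence, mean/CV of LTD amounts in the
#' maintenance window, mean sorting times, and the pooled timing
#' histogram.
#'
#' @param ensembles named list of `endosim_ensemble` objects.
#' @return a list suitable for JSON serialization.
#' @export
ensemble_report <- function(ensembles) {
  per <- lapply(ensembles, function(e) {
    ts <- t_sorts(e)
    ltd <- if (any(!is.na(ts))) ltd_amounts(e) else NULL
    list(
      profile = e$profile,
      n = length(e$trials),
      occurrence = sorting_occurrence(e),
      mean_t_sort = mean(ts, na.rm = TRUE),
      sd_t_sort = stats::sd(ts[!is.na(ts)]),
      ltd_mean = if (is.null(ltd)) NA_real_ else ltd$mean,
      ltd_cv = if (is.null(ltd)) NA_real_ else ltd$cv
    )
  })
  list(profiles = per,
       pooled_histogram = unclass(sorting_histogram(ensembles)))
}
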