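## Trace metrics: the quantities the disease models are read through —
## onset (first-passage) times of plaque accumulation, dominance of the
## non-amyloidogenic over the amyloidogenic cleavage products, calcium
## homeostasis and its loss, oscillation diagnostics, and CAST depletion.
## All metrics are pure functions of a trajectory or ensemble.

#' First-passage time of a place to a token threshold
#'
#' Earliest recorded time at which the count reaches or exceeds the
#' threshold; \code{Inf} if never. On grid-recorded trajectories the result
#' is resolved to the grid (the first grid point at/after the true
#' crossing).
#'
#' @param traj an \code{spn_trajectory}.
#' @param place place id.
#' @param threshold positive integer.
#' @return non-negative numeric, possibly \code{Inf}.
#' @export
first_passage_time <- function(traj, place, threshold = 1L) {
  if (!place %in% rownames(traj$markings)) stop("unknown place: ", place)
  if (threshold < 1) stop("threshold must be >= 1")
  i <- which(traj$markings[place, ] >= threshold)[1L]
  if (is.na(i)) Inf else traj$times[i]
}

fpt_matrix <- function(ens, place, threshold) {
  if (!place %in% ens$places) stop("unknown place: ", place)
  vapply(ens$runs, function(r) {
    i <- which(r[place, ] >= threshold)[1L]
    if (is.na(i)) Inf else ens$grid[i]
  }, numeric(1))
}

#' Ensemble onset time of accumulation
#'
#' Operationalizes "accumulation starts" as the ensemble of per-run
#' first-passage times to a token threshold (default 1: the first token
#' appears).
#'
#' @param ens an \code{spn_ensemble}.
#' @param place place id.
#' @param threshold positive integer.
#' @return an \code{onset_result}: per-run times (\code{Inf} when never
#'   reached), mean and median over the finite times (\code{NA} when no run
#'   reached the threshold), and the fraction of runs that reached it.
#' @export
onset_time <- function(ens, place, threshold = 1L) {
  if (threshold < 1) stop("threshold must be >= 1")
  times <- fpt_matrix(ens, place, threshold)
  fin <- times[is.finite(times)]
  structure(list(place = place, threshold = as.integer(threshold),
                 times = times,
                 mean = if (length(fin)) mean(fin) else NA_real_,
                 median = if (length(fin)) stats::median(fin) else NA_real_,
                 fraction_reached = mean(is.finite(times)),
                 n_runs = ens$n_runs, t_end = ens$t_end),
            class = "onset_result")
}

#' @export
#' @method print onset_result
print.onset_result <- function(x, ...) {
  cat(sprintf(
    "Onset of %s >= %d: mean %.2f, median %.2f, reached in %.0f%% of %d runs\n",
    x$place, x$threshold, x$mean, x$median, 100 * x$fraction_reached,
    x$n_runs))
  invisible(x)
}

#' Dominance ratio of two species over a time window
#'
#' Ratio of the time-averaged ensemble mean of \code{place_a} to that of
#' \code{place_b} over \code{window}. A value above 1 means \code{place_a}
#' dominates. When \code{place_b} has zero mean everywhere in the window
#' the ratio is \code{Inf} and carries attribute \code{undefined = TRUE}.
#'
#' @param ens an \code{spn_ensemble}.
#' @param place_a,place_b place ids.
#' @param window length-2 numeric within \code{[0, t_end]}.
#' @return numeric scalar (possibly \code{Inf}).
#' @export
dominance_ratio <- function(ens, place_a, place_b,
                            window = c(0, ens$t_end)) {
  for (p in c(place_a, place_b))
    if (!p %in% ens$places) stop("unknown place: ", p)
  if (length(window) != 2L || window[1] < 0 || window[2] > ens$t_end ||
      window[1] >= window[2])
    stop("window must be an increasing pair within [0, t_end]")
  w <- ens$grid >= window[1] & ens$grid <= window[2]
  a <- mean(ens$mean[place_a, w])
  b <- mean(ens$mean[place_b, w])
  if (b == 0) {
    out <- Inf
    attr(out, "undefined") <- TRUE
    return(out)
  }
  a / b
}

#' Calcium homeostasis report
#'
#' Homeostasis holds while the ensemble mean of the external pool stays
#' above the internal one at every grid time. If violated, the first grid
#' time with \code{mean(in) >= mean(out)} is reported as the dysregulation
#' onset (a package-defined operationalization: the sources describe the
#' event only visually on averaged traces).
#'
#' @param ens an \code{spn_ensemble}.
#' @param in_place internal (e.g. cytosolic) pool.
#' @param out_place external pool.
#' @param store_place optional storage pool, reported for context.
#' @return a \code{homeostasis_report}: \code{homeostatic} flag,
#'   \code{crossover_time} (\code{NA} when none), and window means.
#' @export
homeostasis_report <- function(ens, in_place = "Ca_In",
                               out_place = "Ca_Out",
                               store_place = NULL) {
  for (p in c(in_place, out_place, store_place))
    if (!p %in% ens$places) stop("unknown place: ", p)
  m_in <- ens$mean[in_place, ]
  m_out <- ens$mean[out_place, ]
  cross <- which(m_in >= m_out)[1L]
  structure(list(in_place = in_place, out_place = out_place,
                 store_place = store_place,
                 homeostatic = is.na(cross),
                 crossover_time = if (is.na(cross)) NA_real_
                                  else ens$grid[cross],
                 mean_in = mean(m_in), mean_out = mean(m_out),
                 mean_store = if (is.null(store_place)) NA_real_
                              else mean(ens$mean[store_place, ]),
                 t_end = ens$t_end),
            class = "homeostasis_report")
}

#' @export
#' @method print homeostasis_report
print.homeostasis_report <- function(x, ...) {
  if (x$homeostatic)
    cat(sprintf("Homeostatic: mean(%s) = %.2f stays below mean(%s) = %.2f over [0, %g]\n",
                x$in_place, x$mean_in, x$out_place, x$mean_out, x$t_end))
  else
    cat(sprintf("Dysregulated: mean(%s) reaches mean(%s) at t = %g\n",
                x$in_place, x$out_place, x$crossover_time))
  invisible(x)
}

#' Oscillation diagnostics for one place
#'
#' Computed per run on the grid samples after \code{burn_in}, then averaged
#' over runs: number of crossings of the run's own post-burn-in mean,
#' coefficient of variation, and the dominant period (grid lag of the
#' highest local autocorrelation maximum whose value exceeds the white-noise
#' floor \code{2/sqrt(n)}; \code{NA} when no such peak exists).
#'
#' @param ens an \code{spn_ensemble}.
#' @param place place id.
#' @param burn_in initial time span to discard (must be < t_end).
#' @return an \code{oscillation_metrics} list.
#' @export
oscillation_metrics <- function(ens, place, burn_in = 10) {
  if (!place %in% ens$places) stop("unknown place: ", place)
  if (burn_in >= ens$t_end) stop("burn_in must be below t_end")
  keep <- ens$grid >= burn_in
  dt <- stats::median(diff(ens$grid))
  per_run <- lapply(ens$runs, function(r) {
    x <- r[place, keep]
    mu <- mean(x)
    cross <- sum(diff(sign(x - mu)) != 0 & !(x[-length(x)] == mu))
    cv <- if (mu > 0) stats::sd(x) / mu else 0
    period <- NA_real_
    if (stats::sd(x) > 0) {
      ac <- stats::acf(x, lag.max = min(length(x) - 1L, 200L),
                       plot = FALSE)$acf[-1L]
      floor_ <- 2 / sqrt(length(x))
      is_peak <- which(diff(sign(diff(c(-Inf, ac, -Inf)))) < 0)
      is_peak <- is_peak[ac[is_peak] > floor_]
      if (length(is_peak)) period <- is_peak[which.max(ac[is_peak])] * dt
    }
    c(cross = cross, cv = cv, period = period)
  })
  m <- do.call(rbind, per_run)
  periods <- m[, "period"]
  structure(list(place = place, burn_in = burn_in,
                 n_mean_crossings = mean(m[, "cross"]),
                 coefficient_of_variation = mean(m[, "cv"]),
                 dominant_period = if (all(is.na(periods))) NA_real_
                                   else mean(periods, na.rm = TRUE)),
            class = "oscillation_metrics")
}

#' @export
#' @method print oscillation_metrics
print.oscillation_metrics <- function(x, ...) {
  cat(sprintf(
    "Oscillation of %s (burn-in %g): %.1f mean-crossings, CV %.2f, period %s\n",
    x$place, x$burn_in, x$n_mean_crossings, x$coefficient_of_variation,
    if (is.na(x$dominant_period)) "none" else sprintf("%.2f", x$dominant_period)))
  invisible(x)
}

#' Depletion fraction of a degraded species
#'
#' Per grid time: ensemble mean of the degraded pool divided by the summed
#' means of the degraded plus conserved pools (0 where the total is 0).
#' Used to track CAST depletion: degraded fragments against all CAST forms.
#' The result carries attribute \code{non_decreasing}, TRUE when the series
#' never decreases beyond Monte-Carlo tolerance (expected whenever the net
#' has no synthesis source for the degraded species' pool).
#'
#' @param ens an \code{spn_ensemble}.
#' @param degraded_place id of the degraded form.
#' @param conserved_places ids of the remaining forms of the same pool.
#' @param tol slack for the monotonicity flag.
#' @return numeric vector over \code{ens$grid} in [0, 1].
#' @export
depletion_fraction <- function(ens, degraded_place, conserved_places,
                               tol = 1e-8) {
  for (p in c(degraded_place, conserved_places))
    if (!p %in% ens$places) stop("unknown place: ", p)
  d <- ens$mean[degraded_place, ]
  tot <- d + colSums(ens$mean[conserved_places, , drop = FALSE])
  f <- ifelse(tot > 0, d / tot, 0)
  attr(f, "non_decreasing") <- all(diff(f) >= -tol)
  names(f) <- NULL
  f
}

#' Export metric rows as a flat summary table
#'
#' @param model model name.
#' @param metric metric name.
#' @param places places involved (collapsed with "/").
#' @param value numeric value.
#' @param ens the ensemble the metric was computed from (for n_runs, seed).
#' @return one-row data frame with columns model, metric, places, value,
#'   n_runs, seed.
#' @export
metric_row <- function(model, metric, places, value, ens) {
  data.frame(model = model, metric = metric,
             places = paste(places, collapse = "/"),
             value = value, n_runs = ens$n_runs, seed = ens$base_seed,
             stringsAsFactors = FALSE)
}
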