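## Stochastic simulation of an SPN as an exponential-race jump process.
## Each enabled transition i carries an exponentially distributed delay with
## hazard equal to its propensity; the race winner fires, delays are
## resampled (memorylessness makes this exact), and the chain continues to
## t_end or deadlock.

KIND_CODE <- c(standard = 0L, inhibitor = 1L, read = 2L, equal = 3L)

## flatten a net into the index arrays the C++ kernel consumes
compile_spn <- function(net) {
  pid <- net$places$id
  tid <- net$transitions$id
  pidx <- stats::setNames(seq_along(pid) - 1L, pid)
  a <- net$arcs
  pre_ptr <- integer(length(tid) + 1L)
  pre_place <- pre_w <- pre_kind <- integer(0)
  d_ptr <- integer(length(tid) + 1L)
  d_place <- d_delta <- integer(0)
  for (i in seq_along(tid)) {
    t <- tid[i]
    ain <- a[a$target == t, , drop = FALSE]
    pre_ptr[i + 1L] <- pre_ptr[i] + nrow(ain)
    pre_place <- c(pre_place, unname(pidx[ain$source]))
    pre_w <- c(pre_w, ain$weight)
    pre_kind <- c(pre_kind, unname(KIND_CODE[ain$kind]))
    d <- firing_delta(net, t)
    nz <- which(d != 0L)
    d_ptr[i + 1L] <- d_ptr[i] + length(nz)
    d_place <- c(d_place, nz - 1L)
    d_delta <- c(d_delta, unname(d[nz]))
  }
  cap <- net$places$capacity
  cap[is.na(cap)] <- -1L
  list(nP = length(pid), pid = pid, tid = tid,
       pre_ptr = pre_ptr, pre_place = pre_place,
       pre_w = as.integer(pre_w), pre_kind = pre_kind,
       d_ptr = d_ptr, d_place = d_place, d_delta = as.integer(d_delta),
       cap = as.integer(cap))
}

check_rates <- function(net, rates) {
  missing <- setdiff(net$transitions$id, names(rates))
  if (length(missing))
    stop("rates missing for transitions: ", paste(missing, collapse = ", "))
  r <- rates[net$transitions$id]
  if (any(!is.finite(r)) || any(r < 0))
    stop("rates must be finite and >= 0 (0 = permanently disabled)")
  r
}

#' Propensity (instantaneous firing hazard) of a transition
#'
#' Zero when the transition is disabled. When enabled:
#' under \code{"constant_hazard"} semantics the hazard is the bare rate
#' \code{mu}; under \code{"mass_action"} it is \code{mu} times the product,
#' over standard input arcs, of \code{choose(m[p], w)} (the number of ways to
#' pick the consumed tokens). Read, inhibitor and equal arcs gate enabling
#' but never scale the propensity.
#'
#' @inheritParams is_enabled
#' @param rates named vector of firing rates, one per transition.
#' @param semantics \code{"constant_hazard"} or \code{"mass_action"}.
#' @return non-negative numeric scalar.
#' @export
propensity <- function(net, m, t, rates,
                       semantics = c("constant_hazard", "mass_action")) {
  semantics <- match.arg(semantics)
  if (!t %in% net$transitions$id) stop("unknown transition: ", t)
  rates <- check_rates(net, rates)
  if (!is_enabled(net, m, t)) return(0)
  a <- unname(rates[t])
  if (semantics == "mass_action") {
    ain <- arcs_into(net, t)
    std <- ain[ain$kind == "standard", , drop = FALSE]
    for (i in seq_len(nrow(std)))
      a <- a * choose(m[[std$source[i]]], std$weight[i])
  }
  a
}

#' Simulate an SPN
#'
#' Exact jump-process sampling: at each state the total propensity is the sum
#' over transitions, the waiting time is exponential with that total, and the
#' firing transition is chosen with probability proportional to its
#' propensity. Stops at \code{t_end} or at deadlock (no enabled transition).
#' With \code{nsim > 1} returns a seeded ensemble with per-place mean and
#' variance on a common resampling grid; run \code{i} uses seed
#' \code{seed + i}.
#'
#' @param object an \code{spn}.
#' @param nsim number of runs.
#' @param seed integer base seed; identical inputs and seed give an
#'   identical event sequence.
#' @param marking initial marking (defaults to all-zero).
#' @param rates named vector of transition rates.
#' @param t_end simulation horizon in model unit time.
#' @param semantics hazard semantics, see \code{\link{propensity}}.
#' @param record \code{"events"} stores every jump (exact trajectory);
#'   \code{"grid"} stores the right-continuous marking on a regular grid.
#'   Ensembles always record on the grid.
#' @param grid_dt grid spacing for \code{record = "grid"}.
#' @param max_events abort threshold for runaway simulations.
#' @param ... unused.
#' @return an \code{spn_trajectory} (\code{nsim = 1}) or
#'   \code{spn_ensemble} (\code{nsim > 1}).
#' @examples
#' src <- spn("X", "make", data.frame(source = "make", target = "X"))
#' tr <- simulate(src, seed = 1, rates = c(make = 1), t_end = 10)
#' tail(tr$markings["X", ], 1)  # Poisson(10) sample
#' @export
simulate.spn <- function(object, nsim = 1, seed = NULL, marking = NULL,
                         rates, t_end = 10,
                         semantics = c("constant_hazard", "mass_action"),
                         record = c("events", "grid"), grid_dt = 0.5,
                         max_events = 5e7, ...) {
  semantics <- match.arg(semantics)
  record <- match.arg(record)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive")
  if (grid_dt <= 0) stop("grid_dt must be positive")
  if (nsim > 1)
    return(spn_ensemble(object, marking = marking, rates = rates,
                        t_end = t_end, semantics = semantics,
                        grid_dt = grid_dt, n_runs = nsim,
                        base_seed = if (is.null(seed)) 0L else seed,
                        max_events = max_events))
  if (is.null(marking)) marking <- spn_marking(object)
  marking <- spn_marking(object, marking[marking != 0])
  r <- check_rates(object, rates)
  cc <- compile_spn(object)
  if (!is.null(seed)) set.seed(seed)
  grid <- if (record == "grid") make_grid(t_end, grid_dt) else numeric(0)
  res <- ssa_run_cpp(cc$nP, cc$pre_ptr, cc$pre_place, cc$pre_w, cc$pre_kind,
                     cc$d_ptr, cc$d_place, cc$d_delta, cc$cap,
                     unname(marking), unname(r), t_end,
                     if (semantics == "mass_action") 1L else 0L,
                     record == "events", grid, max_events)
  if (record == "events") {
    mk <- res$states
    rownames(mk) <- cc$pid
    traj <- list(times = res$times,
                 markings = mk,
                 fired = c(NA_character_, cc$tid[res$fired[-1L]]),
                 t_end = t_end, final_time = t_end,
                 final_marking = stats::setNames(res$final_marking, cc$pid),
                 deadlock = res$deadlock, deadlock_time = res$deadlock_time,
                 semantics = semantics, record = "events", net_name = object$name)
  } else {
    mk <- res$grid_states
    rownames(mk) <- cc$pid
    traj <- list(times = grid, markings = mk, fired = NULL,
                 t_end = t_end, final_time = t_end,
                 final_marking = stats::setNames(res$final_marking, cc$pid),
                 deadlock = res$deadlock, deadlock_time = res$deadlock_time,
                 semantics = semantics, record = "grid", net_name = object$name)
  }
  class(traj) <- "spn_trajectory"
  traj
}

make_grid <- function(t_end, grid_dt) {
  g <- seq(0, t_end, by = grid_dt)
  if (g[length(g)] < t_end) g <- c(g, t_end)
  g
}

#' Seeded ensemble of SPN runs
#'
#' Runs \code{n_runs} independent simulations with per-run seed
#' \code{base_seed + i} and summarises per-place mean and variance on a
#' common time grid (right-continuous step resampling).
#'
#' @inheritParams simulate.spn
#' @param net an \code{spn}.
#' @param n_runs number of runs (>= 1).
#' @param base_seed integer; run \code{i} uses seed \code{base_seed + i}.
#' @return an object of class \code{spn_ensemble} with elements
#'   \code{runs} (list of place-by-time count matrices), \code{grid},
#'   \code{mean} and \code{var} (place-by-time summaries), and bookkeeping.
#' @export
spn_ensemble <- function(net, marking = NULL, rates, t_end = 10,
                         semantics = c("constant_hazard", "mass_action"),
                         grid_dt = 0.5, n_runs = 100, base_seed = 0,
                         max_events = 5e7) {
  semantics <- match.arg(semantics)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (is.null(marking)) marking <- spn_marking(net)
  marking <- spn_marking(net, marking[marking != 0])
  r <- check_rates(net, rates)
  cc <- compile_spn(net)
  grid <- make_grid(t_end, grid_dt)
  runs <- vector("list", n_runs)
  deadlocks <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(base_seed + i)
    res <- ssa_run_cpp(cc$nP, cc$pre_ptr, cc$pre_place, cc$pre_w, cc$pre_kind,
                       cc$d_ptr, cc$d_place, cc$d_delta, cc$cap,
                       unname(marking), unname(r), t_end,
                       if (semantics == "mass_action") 1L else 0L,
                       FALSE, grid, max_events)
    mk <- res$grid_states
    rownames(mk) <- cc$pid
    runs[[i]] <- mk
    deadlocks[i] <- res$deadlock
  }
  nP <- cc$nP; nG <- length(grid)
  s1 <- matrix(0, nP, nG); s2 <- matrix(0, nP, nG)
  for (i in seq_len(n_runs)) {
    s1 <- s1 + runs[[i]]
    s2 <- s2 + runs[[i]]^2
  }
  mu <- s1 / n_runs
  vv <- if (n_runs > 1) (s2 - n_runs * mu^2) / (n_runs - 1) else s2 * 0
  dimnames(mu) <- dimnames(vv) <- list(cc$pid, NULL)
  structure(list(runs = runs, grid = grid, mean = mu, var = vv,
                 n_runs = n_runs, base_seed = base_seed,
                 semantics = semantics, t_end = t_end,
                 deadlocks = deadlocks, net_name = net$name,
                 places = cc$pid),
            class = "spn_ensemble")
}

#' @export
#' @method print spn_trajectory
print.spn_trajectory <- function(x, ...) {
  cat(sprintf("SPN trajectory of '%s': %s recording, t_end = %g%s\n",
              x$net_name, x$record, x$t_end,
              if (x$deadlock) sprintf(", deadlocked at t = %g", x$deadlock_time)
              else ""))
  if (x$record == "events")
    cat(sprintf("  %d events\n", length(x$times) - 1L))
  invisible(x)
}

#' @export
#' @method print spn_ensemble
print.spn_ensemble <- function(x, ...) {
  cat(sprintf(
    "SPN ensemble of '%s': %d runs, base seed %d, %s semantics, t_end = %g\n",
    x$net_name, x$n_runs, x$base_seed, x$semantics, x$t_end))
  if (any(x$deadlocks))
    cat(sprintf("  %d run(s) deadlocked\n", sum(x$deadlocks)))
  invisible(x)
}

#' @export
#' @method summary spn_ensemble
summary.spn_ensemble <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$grid[length(object$grid)]
  idx <- vapply(times, function(t) which.min(abs(object$grid - t)), 1L)
  out <- data.frame(place = rep(object$places, length(idx)),
                    time = rep(object$grid[idx], each = length(object$places)),
                    mean = as.vector(object$mean[, idx]),
                    var = as.vector(object$var[, idx]))
  rownames(out) <- NULL
  out
}

#' Plot ensemble mean traces
#'
#' @param x an \code{spn_ensemble}.
#' @param places places to draw (default: the six with the largest final
#'   mean).
#' @param ... passed to \code{matplot}.
#' @export
plot.spn_ensemble <- function(x, places = NULL, ...) {
  if (is.null(places)) {
    fin <- x$mean[, ncol(x$mean)]
    places <- names(sort(fin, decreasing = TRUE))[seq_len(min(6, length(fin)))]
  }
  y <- t(x$mean[places, , drop = FALSE])
  graphics::matplot(x$grid, y, type = "l", lty = 1,
                    xlab = "time", ylab = "mean token count", ...)
  graphics::legend("topleft", legend = places, col = seq_along(places),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.spn_trajectory <- function(x, places = NULL, ...) {
  if (is.null(places)) {
    fin <- x$markings[, ncol(x$markings)]
    places <- names(sort(fin, decreasing = TRUE))[seq_len(min(6, length(fin)))]
  }
  y <- t(x$markings[places, , drop = FALSE])
  graphics::matplot(x$times, y, type = "s", lty = 1,
                    xlab = "time", ylab = "token count", ...)
  graphics::legend("topleft", legend = places, col = seq_along(places),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
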