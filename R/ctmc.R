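## Brute-force validation of the SSA engine: the marking process of an SPN
## is a homogeneous continuous-time Markov chain on the reachability graph,
## with edge rates given by the propensities. For small (or truncated) state
## spaces the master equation can be solved directly and compared with
## ensemble statistics.

#' Build the (truncated) reachability graph of an SPN
#'
#' Breadth-first exploration from the initial marking. Successor markings
#' with any count above \code{cap} are not expanded: their probability flow
#' is redirected to a single absorbing overflow pseudo-state and
#' \code{truncated} is set, so truncation mass is tracked rather than
#' silently dropped.
#'
#' @inheritParams propensity
#' @param m0 initial marking.
#' @param cap per-place token cap for exploration.
#' @param max_states hard limit; exploration beyond it aborts with a
#'   diagnostic.
#' @return an object of class \code{spn_stategraph}: \code{states} (matrix,
#'   one marking per row, row 1 = initial), \code{edges} (data frame with
#'   \code{from}, \code{to}, \code{transition}, \code{rate}; \code{to = 0}
#'   denotes the overflow state), \code{truncated} flag.
#' @export
reachability_graph <- function(net, m0, rates,
                               semantics = c("constant_hazard", "mass_action"),
                               cap = 8L, max_states = 2e5) {
  semantics <- match.arg(semantics)
  rates <- check_rates(net, rates)
  m0 <- spn_marking(net, m0[m0 != 0])
  if (any(m0 > cap))
    stop("initial marking already exceeds the exploration cap")
  tid <- net$transitions$id
  key <- function(m) paste(m, collapse = ",")
  index <- new.env(hash = TRUE, parent = emptyenv())
  states <- list(m0)
  assign(key(m0), 1L, envir = index)
  ef <- integer(0); et <- integer(0); etr <- character(0); er <- numeric(0)
  queue <- 1L
  while (length(queue)) {
    s <- queue[1L]; queue <- queue[-1L]
    m <- states[[s]]
    for (t in tid) {
      a <- propensity(net, m, t, rates, semantics)
      if (a <= 0) next
      m2 <- m + firing_delta(net, t)
      if (any(m2 > cap)) {
        ef <- c(ef, s); et <- c(et, 0L); etr <- c(etr, t); er <- c(er, a)
        next
      }
      k2 <- key(m2)
      j <- index[[k2]]
      if (is.null(j)) {
        states[[length(states) + 1L]] <- m2
        j <- length(states)
        if (j > max_states)
          stop("reachability_graph: state count exceeded max_states (",
               max_states, ")")
        assign(k2, j, envir = index)
        queue <- c(queue, j)
      }
      ef <- c(ef, s); et <- c(et, j); etr <- c(etr, t); er <- c(er, a)
    }
  }
  st <- do.call(rbind, states)
  colnames(st) <- net$places$id
  structure(list(states = st,
                 edges = data.frame(from = ef, to = et, transition = etr,
                                    rate = er, stringsAsFactors = FALSE),
                 truncated = any(et == 0L),
                 semantics = semantics, net_name = net$name),
            class = "spn_stategraph")
}

#' @export
#' @method print spn_stategraph
print.spn_stategraph <- function(x, ...) {
  cat(sprintf("State graph of '%s': %d states, %d edges%s\n",
              x$net_name, nrow(x$states), nrow(x$edges),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

## sparse generator over explored states + one overflow column when truncated
stategraph_Q <- function(g) {
  n <- nrow(g$states)
  e <- g$edges
  over <- e$to == 0L
  n_all <- n + as.integer(any(over))
  to <- ifelse(over, n + 1L, e$to)
  Q <- Matrix::sparseMatrix(i = e$from, j = to, x = e$rate,
                            dims = c(n_all, n_all))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  Q
}

#' Transient distribution by uniformization
#'
#' Solves the master equation \code{dp/dt = p Q} by uniformization: the
#' chain is subordinated to a Poisson process of rate \code{q >= max exit
#' rate}, giving \code{p(t) = sum_k Pois(k; q t) p0 P^k} with
#' \code{P = I + Q/q}. The series is truncated when the remaining Poisson
#' tail is below \code{tol}; long horizons are squared down recursively so
#' the Poisson weights never underflow.
#'
#' @param g an \code{spn_stategraph}.
#' @param t non-negative time.
#' @param tol truncation tolerance for the Poisson tail.
#' @return numeric probability vector over the explored states, with
#'   attribute \code{truncation_mass} (probability absorbed by the overflow
#'   state; 0 when the graph is not truncated). The vector plus the
#'   truncation mass sums to 1 within \code{tol}.
#' @export
transient_distribution <- function(g, t, tol = 1e-9) {
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  Q <- stategraph_Q(g)
  n_all <- nrow(Q)
  p0 <- numeric(n_all); p0[1L] <- 1
  p <- uniformize(p0, Q, t, tol)
  n <- nrow(g$states)
  out <- p[seq_len(n)]
  attr(out, "truncation_mass") <- if (n_all > n) p[n_all] else 0
  out
}

uniformize <- function(p0, Q, t, tol) {
  if (t == 0) return(p0)
  q <- max(-Matrix::diag(Q)) * 1.02 + 1e-12
  if (q * t < 1e-300) return(p0)
  if (q * t > 400) {  # halve the horizon to keep exp(-q t) representable
    half <- uniformize(p0, Q, t / 2, tol / 2)
    return(uniformize(half, Q, t / 2, tol / 2))
  }
  P <- Matrix::Diagonal(nrow(Q)) + Q / q
  w <- exp(-q * t)
  acc <- w * p0
  v <- p0
  k <- 0L
  wsum <- w
  while (1 - wsum > tol) {
    k <- k + 1L
    v <- as.numeric(v %*% P)
    w <- w * q * t / k
    acc <- acc + w * v
    wsum <- wsum + w
    if (k > 1e6) stop("uniformization failed to converge")
  }
  ## assign the (tiny) remaining tail to the current vector
  acc + (1 - wsum) * v
}

#' Stationary distribution of an irreducible state graph
#'
#' Solves the global balance equations \code{pi Q = 0}, \code{sum(pi) = 1}.
#' Errors when the chain is reducible (not strongly connected) or
#' truncated.
#'
#' @param g an \code{spn_stategraph}.
#' @return numeric probability vector over states.
#' @export
stationary_distribution <- function(g) {
  if (g$truncated)
    stop("stationary distribution undefined on a truncated graph")
  n <- nrow(g$states)
  if (!is_strongly_connected(n, g$edges))
    stop("chain is reducible: state graph is not strongly connected")
  Q <- as.matrix(stategraph_Q(g))
  A <- rbind(t(Q)[-1L, , drop = FALSE], rep(1, n))
  b <- c(numeric(n - 1L), 1)
  pi <- solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

is_strongly_connected <- function(n, edges) {
  if (n == 1L) return(TRUE)
  fwd <- split(edges$to, edges$from)
  bwd <- split(edges$from, edges$to)
  reach <- function(adj) {
    seen <- logical(n); seen[1L] <- TRUE; stack <- 1L
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (j in adj[[as.character(s)]]) {
        if (j >= 1L && !seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
      }
    }
    all(seen)
  }
  reach(fwd) && reach(bwd)
}
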