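## Synthetic nets with known behaviour. These are first-class model bundles:
## every engine feature is testable against a closed form (Poisson source,
## birth-death queue, two-state toggle) or against the CTMC oracle on small
## random conservative nets, with no external data.

new_bundle <- function(name, net, marking, rates,
                       semantics = "constant_hazard",
                       params = list(), notes = character()) {
  rates <- check_rates(net, rates)
  structure(list(name = name, net = net,
                 marking = spn_marking(net, marking[marking != 0]),
                 rates = rates, semantics = semantics,
                 params = params, notes = notes),
            class = "spn_model")
}

#' @export
#' @method print spn_model
print.spn_model <- function(x, ...) {
  cat(sprintf("SPN model bundle '%s' (%s semantics)\n", x$name, x$semantics))
  print(x$net)
  cat(sprintf("  initial tokens: %d over %d marked places\n",
              sum(x$marking), sum(x$marking > 0)))
  invisible(x)
}

#' Simulate a model bundle
#'
#' Convenience dispatch of \code{\link{simulate.spn}} using the bundle's net,
#' default marking, rates and recommended hazard semantics.
#'
#' @param object an \code{spn_model} bundle.
#' @param nsim,seed,t_end,record,grid_dt,... see \code{\link{simulate.spn}}.
#' @export
simulate.spn_model <- function(object, nsim = 1, seed = NULL, t_end = 10,
                               record = "events", grid_dt = 0.5, ...) {
  simulate.spn(object$net, nsim = nsim, seed = seed,
               marking = object$marking, rates = object$rates,
               t_end = t_end, semantics = object$semantics,
               record = record, grid_dt = grid_dt, ...)
}

#' Build a synthetic fixture net
#'
#' @param kind one of \code{"poisson_source"} (a single source transition
#'   filling one place: counts are Poisson), \code{"birth_death"} (constant
#'   birth and death hazards: an M/M/1 queue with geometric stationary law
#'   under a capacity), \code{"toggle"} (one token alternating between two
#'   places), \code{"enzyme_substrate"} (E + S <-> ES -> E + P),
#'   \code{"receptor_ligand"} (receptor opening, ligand activation, complex
#'   formation), or \code{"random_bounded"} (seeded random conservative net:
#'   every transition consumes and produces the same total weight, so total
#'   token count is conserved and bounded).
#' @param ... kind-specific parameters, see Details.
#' @details Parameters and defaults: \code{poisson_source(mu = 1)};
#'   \code{birth_death(lambda = 1, mu = 2, cap = 10)};
#'   \code{toggle(mu1 = 1, mu2 = 3)};
#'   \code{enzyme_substrate(k_bind = 1, k_unbind = 0.5, k_cat = 1, e0 = 2,
#'   s0 = 5)} (rates are package defaults);
#'   \code{receptor_ligand(d1 = 1, d2 = 1)};
#'   \code{random_bounded(seed, n_places = 4, n_transitions = 4,
#'   max_weight = 2, p_inhibitor = 0.1, p_read = 0.1, total_tokens = 6)}.
#' @return an \code{spn_model} bundle.
#' @export
spn_fixture <- function(kind = c("poisson_source", "birth_death", "toggle",
                                 "enzyme_substrate", "receptor_ligand",
                                 "random_bounded"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         poisson_source = fixture_poisson(...),
         birth_death = fixture_birth_death(...),
         toggle = fixture_toggle(...),
         enzyme_substrate = fixture_enzyme(...),
         receptor_ligand = fixture_receptor_ligand(...),
         random_bounded = fixture_random(...))
}

fixture_poisson <- function(mu = 1) {
  stopifnot(mu > 0)
  net <- spn("X", "src", data.frame(source = "src", target = "X"),
             name = "poisson_source")
  new_bundle("poisson_source", net, c(X = 0), c(src = mu),
             params = list(mu = mu))
}

fixture_birth_death <- function(lambda = 1, mu = 2, cap = 10L) {
  stopifnot(lambda > 0, mu > 0, is.na(cap) || cap >= 1)
  net <- spn(data.frame(id = "N", label = "population",
                        capacity = if (is.na(cap)) NA_integer_ else as.integer(cap)),
             c("birth", "death"),
             data.frame(source = c("birth", "N"), target = c("N", "death")),
             name = "birth_death")
  new_bundle("birth_death", net, c(N = 0),
             c(birth = lambda, death = mu),
             params = list(lambda = lambda, mu = mu, cap = cap))
}

fixture_toggle <- function(mu1 = 1, mu2 = 3) {
  stopifnot(mu1 > 0, mu2 > 0)
  net <- spn(c("A", "B"), c("fwd", "rev"),
             data.frame(source = c("A", "fwd", "B", "rev"),
                        target = c("fwd", "B", "rev", "A")),
             name = "toggle")
  new_bundle("toggle", net, c(A = 1), c(fwd = mu1, rev = mu2),
             params = list(mu1 = mu1, mu2 = mu2))
}

fixture_enzyme <- function(k_bind = 1, k_unbind = 0.5, k_cat = 1,
                           e0 = 2L, s0 = 5L) {
  net <- spn(c("E", "S", "ES", "P"), c("bind", "unbind", "cat"),
             data.frame(
               source = c("E", "S", "bind", "ES", "unbind", "unbind",
                          "ES", "cat", "cat"),
               target = c("bind", "bind", "ES", "unbind", "E", "S",
                          "cat", "E", "P")),
             name = "enzyme_substrate")
  new_bundle("enzyme_substrate", net, c(E = e0, S = s0),
             c(bind = k_bind, unbind = k_unbind, cat = k_cat),
             params = list(k_bind = k_bind, k_unbind = k_unbind,
                           k_cat = k_cat, e0 = e0, s0 = s0))
}

fixture_receptor_ligand <- function(d1 = 1, d2 = 1) {
  net <- spn(c("Receptor", "Open_R", "Ligand", "Active_L", "RL_Complex"),
             c("Opening", "Activation", "Binding"),
             data.frame(
               source = c("Receptor", "Opening", "Ligand", "Activation",
                          "Open_R", "Active_L", "Binding"),
               target = c("Opening", "Open_R", "Activation", "Active_L",
                          "Binding", "Binding", "RL_Complex")),
             name = "receptor_ligand")
  new_bundle("receptor_ligand", net, c(Receptor = 1, Ligand = 1),
             c(Opening = d1, Activation = d1, Binding = d2),
             params = list(d1 = d1, d2 = d2))
}

fixture_random <- function(seed, n_places = 4L, n_transitions = 4L,
                           max_weight = 2L, p_inhibitor = 0.1,
                           p_read = 0.1, total_tokens = 6L) {
  stopifnot(!missing(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pid <- paste0("P", seq_len(n_places))
  tid <- paste0("T", seq_len(n_transitions))
  arcs <- NULL
  for (t in tid) {
    w_tot <- sample.int(max_weight, 1L)
    split_w <- function(w) {
      if (w == 1L || stats::runif(1) < 0.5) {
        data.frame(p = sample(pid, 1L), w = w)
      } else {
        data.frame(p = sample(pid, 2L), w = c(1L, w - 1L))
      }
    }
    din <- split_w(w_tot); dout <- split_w(w_tot)
    arcs <- rbind(arcs,
                  data.frame(source = din$p, target = t, kind = "standard",
                             weight = din$w),
                  data.frame(source = t, target = dout$p, kind = "standard",
                             weight = dout$w))
    if (stats::runif(1) < p_inhibitor) {
      cand <- setdiff(pid, din$p)
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      arcs <- rbind(arcs, data.frame(source = p, target = t,
                                     kind = "inhibitor",
                                     weight = sample.int(3L, 1L)))
    }
    if (stats::runif(1) < p_read) {
      cand <- setdiff(pid, arcs$source[arcs$target == t & arcs$kind != "standard"])
      if (length(cand)) {
        p <- if (length(cand) == 1L) cand else sample(cand, 1L)
        arcs <- rbind(arcs, data.frame(source = p, target = t, kind = "read",
                                       weight = 1L))
      }
    }
  }
  ## merge duplicate standard arcs on the same pair by summing weights
  key <- paste(arcs$source, arcs$target, arcs$kind)
  if (anyDuplicated(key)) {
    arcs <- do.call(rbind, lapply(split(arcs, key), function(d) {
      d$weight[1L] <- sum(d$weight); d[1L, ]
    }))
    rownames(arcs) <- NULL
  }
  net <- spn(pid, tid, arcs, name = sprintf("random_bounded_%d", seed))
  m0 <- stats::setNames(as.vector(stats::rmultinom(1, total_tokens,
                                                   rep(1, n_places))), pid)
  rates <- stats::setNames(round(stats::runif(n_transitions, 0.2, 2), 2), tid)
  new_bundle(sprintf("random_bounded_%d", seed), net, m0, rates,
             params = list(seed = seed, total_tokens = total_tokens))
}

#' Closed-form reference behaviour of a fixture
#'
#' @param bundle a fixture bundle from \code{\link{spn_fixture}} of kind
#'   \code{poisson_source}, \code{birth_death} or \code{toggle}.
#' @return a list with (where defined) \code{mean(place, t)},
#'   \code{var(place, t)}, \code{pmf(k, t)} and \code{stationary} (named
#'   probability vector). All refer to constant-hazard semantics, under
#'   which these fixtures are textbook Markov chains.
#' @export
fixture_expectation <- function(bundle) {
  p <- bundle$params
  switch(bundle$name,
         poisson_source = list(
           mean = function(place = "X", t) p$mu * t,
           var = function(place = "X", t) p$mu * t,
           pmf = function(k, t) stats::dpois(k, p$mu * t)),
         birth_death = {
           rho <- p$lambda / p$mu
           ks <- 0:p$cap
           pi <- rho^ks / sum(rho^ks)
           list(stationary = stats::setNames(pi, ks),
                ratio = rho,
                mean = function(place = "N", t = Inf) sum(ks * pi))
         },
         toggle = {
           st <- c(A = p$mu2 / (p$mu1 + p$mu2), B = p$mu1 / (p$mu1 + p$mu2))
           list(stationary = st,
                mean = function(place, t = Inf) unname(st[place]))
         },
         stop("no closed form for fixture kind: ", bundle$name))
}
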