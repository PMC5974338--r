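## Small builders and independent oracles used across the suite.

## one place feeding one transition through a single arc of a given kind,
## with a token sink so firing is observable
single_arc_net <- function(kind, weight) {
  spn(c("P", "Q"), "T",
      data.frame(source = c("P", "T"), target = c("T", "Q"),
                 kind = c(kind, "standard"), weight = c(weight, 1L)),
      check = FALSE)
}

## independent enabling rule, straight from the arc-kind definitions
enabling_oracle <- function(kind, tokens, weight) {
  switch(kind,
         standard = tokens >= weight,
         read = tokens >= weight,
         inhibitor = tokens < weight,
         equal = tokens == weight)
}

## ensemble-free Monte-Carlo standard error of a mean
mc_se <- function(v, n) sqrt(v / n)

## mean and variance of one place at a grid time, from an ensemble
ens_at <- function(ens, place, t) {
  i <- which.min(abs(ens$grid - t))
  c(mean = unname(ens$mean[place, i]), var = unname(ens$var[place, i]))
}

## oracle mean of each place at time t from a state graph
oracle_means <- function(g, t) {
  p <- transient_distribution(g, t)
  as.numeric(p %*% g$states)
}

## hand-built trajectory / ensemble objects for metric unit tests
fake_trajectory <- function(times, counts, place = "X") {
  structure(list(times = times,
                 markings = matrix(counts, nrow = 1,
                                   dimnames = list(place, NULL)),
                 t_end = max(times), record = "grid",
                 deadlock = FALSE, net_name = "fake"),
            class = "spn_trajectory")
}

fake_ensemble <- function(grid, runs_list) {
  ## runs_list: list of place-by-time matrices with rownames
  places <- rownames(runs_list[[1]])
  s1 <- Reduce(`+`, runs_list)
  mu <- s1 / length(runs_list)
  s2 <- Reduce(`+`, lapply(runs_list, function(r) r^2))
  vv <- if (length(runs_list) > 1)
    (s2 - length(runs_list) * mu^2) / (length(runs_list) - 1)
  else s2 * 0
  structure(list(runs = runs_list, grid = grid, mean = mu, var = vv,
                 n_runs = length(runs_list), base_seed = 0,
                 semantics = "constant_hazard", t_end = max(grid),
                 deadlocks = rep(FALSE, length(runs_list)),
                 net_name = "fake", places = places),
            class = "spn_ensemble")
}
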