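test_that("first-passage times read trajectories correctly", {
  tr <- fake_trajectory(c(0, 1, 2), c(0, 0, 1))
  expect_identical(first_passage_time(tr, "X", 1), 2)
  flat <- fake_trajectory(c(0, 1, 2), c(0, 0, 0))
  expect_identical(first_passage_time(flat, "X", 1), Inf)
  expect_error(first_passage_time(tr, "Y", 1), "unknown place")
  expect_error(first_passage_time(tr, "X", 0), "threshold")

  ## exponential first arrival: ensemble mean ~ 1/mu
  fx <- spn_fixture("poisson_source", mu = 0.1)
  ens <- simulate(fx, nsim = 200, seed = 4, t_end = 120, record = "grid")
  ot <- onset_time(ens, "X", 1)
  se <- sd(ot$times[is.finite(ot$times)]) / sqrt(sum(is.finite(ot$times)))
  expect_lt(abs(ot$mean - 10), 3 * se + 0.5)  # + grid resolution slack
})

test_that("onset aggregation handles single runs and never-reached runs", {
  g <- c(0, 1, 2)
  r1 <- matrix(c(0, 0, 2), 1, dimnames = list("X", NULL))
  e1 <- fake_ensemble(g, list(r1))
  o1 <- onset_time(e1, "X", 1)
  expect_identical(o1$mean, 2)
  expect_identical(o1$fraction_reached, 1)

  r0 <- matrix(0, 1, 3, dimnames = list("X", NULL))
  e0 <- fake_ensemble(g, list(r0, r0))
  o0 <- onset_time(e0, "X", 1)
  expect_identical(o0$fraction_reached, 0)
  expect_true(is.na(o0$mean))

  ## threshold monotonicity: higher threshold, no earlier passage
  fx <- spn_fixture("poisson_source", mu = 1)
  ens <- simulate(fx, nsim = 30, seed = 6, t_end = 20, record = "grid")
  t1 <- onset_time(ens, "X", 1)$times
  t3 <- onset_time(ens, "X", 3)$times
  expect_true(all(t3 >= t1))
})

test_that("dominance ratio is a windowed mean ratio with sentinel handling", {
  g <- seq(0, 10, 0.5)
  ra <- matrix(rep(c(4, 2), each = length(g)), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), NULL))
  e <- fake_ensemble(g, list(ra))
  expect_identical(dominance_ratio(e, "A", "A"), 1)
  expect_identical(dominance_ratio(e, "A", "B"), 2)
  ## reciprocal identity
  expect_equal(dominance_ratio(e, "A", "B") * dominance_ratio(e, "B", "A"), 1)
  ## empty denominator flags an undefined infinite ratio
  rz <- ra; rz["B", ] <- 0
  ez <- fake_ensemble(g, list(rz))
  d <- dominance_ratio(ez, "A", "B")
  expect_true(is.infinite(d))
  expect_true(attr(d, "undefined"))
  expect_error(dominance_ratio(e, "A", "B", c(5, 2)), "window")

  ## two independent sources at 0.5 and 0.3: ratio of means -> 5/3
  net <- spn(c("A", "B"), c("sa", "sb"),
             data.frame(source = c("sa", "sb"), target = c("A", "B")))
  ens <- spn_ensemble(net, rates = c(sa = 0.5, sb = 0.3), t_end = 60,
                      n_runs = 300, base_seed = 8)
  expect_equal(dominance_ratio(ens, "A", "B", c(10, 60)), 5 / 3,
               tolerance = 0.05)
})

test_that("homeostasis report detects ordering and crossover times", {
  g <- seq(0, 10, 1)
  mk <- function(inn, out) {
    m <- rbind(inn, out)
    rownames(m) <- c("Ca_In", "Ca_Out")
    m
  }
  ## constant in = 1 below out = 5: homeostatic
  e <- fake_ensemble(g, list(mk(rep(1, 11), rep(5, 11))))
  h <- homeostasis_report(e, "Ca_In", "Ca_Out")
  expect_true(h$homeostatic)
  expect_true(is.na(h$crossover_time))
  ## ramp crossing at t = 7
  inn <- 0:10; out <- rep(6.5, 11)
  h2 <- homeostasis_report(fake_ensemble(g, list(mk(inn, out))),
                           "Ca_In", "Ca_Out")
  expect_false(h2$homeostatic)
  expect_identical(h2$crossover_time, 7)
  ## the calcium channel model alone is homeostatic over the full horizon
  ca <- ad_model("calcium_channel")
  ens <- simulate(ca, nsim = 40, seed = 1, t_end = 200, record = "grid")
  expect_true(homeostasis_report(ens, "Ca_In", "Ca_Out")$homeostatic)
})

test_that("oscillation metrics find square-wave periods and flat traces", {
  g <- seq(0, 40, 0.5)
  flat <- matrix(3, 1, length(g), dimnames = list("X", NULL))
  ef <- fake_ensemble(g, list(flat))
  om <- oscillation_metrics(ef, "X", burn_in = 5)
  expect_identical(om$n_mean_crossings, 0)
  expect_identical(om$coefficient_of_variation, 0)
  expect_true(is.na(om$dominant_period))

  ## deterministic square wave of period 4
  sq <- matrix(ifelse(g %% 4 < 2, 0, 2), 1, dimnames = list("X", NULL))
  es <- fake_ensemble(g, list(sq))
  os <- oscillation_metrics(es, "X", burn_in = 5)
  expect_equal(os$dominant_period, 4, tolerance = 0.5)
  expect_gt(os$n_mean_crossings, 5)

  ## a toggling place alternates, so crossings are forced
  tg <- spn_fixture("toggle")
  ens <- simulate(tg, nsim = 5, seed = 3, t_end = 30, record = "grid")
  expect_gt(oscillation_metrics(ens, "A", 5)$n_mean_crossings, 0)
})

test_that("depletion fraction is a share in [0, 1] with a monotonicity flag", {
  g <- 0:4
  mk <- function(d, c1) {
    m <- rbind(d, c1); rownames(m) <- c("dCT", "CT"); m
  }
  ez <- fake_ensemble(g, list(mk(rep(0, 5), rep(3, 5))))
  f0 <- depletion_fraction(ez, "dCT", "CT")
  expect_identical(as.numeric(f0), rep(0, 5))
  ## full degradation at the end
  ef <- fake_ensemble(g, list(mk(c(0, 1, 2, 3, 4), c(4, 3, 2, 1, 0))))
  ff <- depletion_fraction(ef, "dCT", "CT")
  expect_identical(ff[5], 1)
  expect_true(attr(ff, "non_decreasing"))

  ## crosstalk: degraded CAST share grows between t = 20 and t = 200
  ct <- ad_model("crosstalk")
  ens <- simulate(ct, nsim = 50, seed = 1, t_end = 200, record = "grid")
  cast <- c("mCT", "cCT", "iCT", "CT", "mC", "cC")
  f <- depletion_fraction(ens, "dCT", cast)
  i20 <- which(ens$grid == 20); i200 <- length(ens$grid)
  expect_gt(f[i200], f[i20])
  expect_true(attr(f, "non_decreasing"))
})

test_that("metrics are pure functions of the ensemble", {
  fx <- spn_fixture("poisson_source")
  ens <- simulate(fx, nsim = 20, seed = 5, t_end = 10, record = "grid")
  expect_identical(onset_time(ens, "X", 2), onset_time(ens, "X", 2))
  expect_identical(dominance_ratio(ens, "X", "X"),
                   dominance_ratio(ens, "X", "X"))
})
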