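## Published transition-rate tables, transcribed once and asserted
## table-driven against the shipped bundles.

calcium_rates <- c(
  t1 = 1, t2 = 1, t3 = 1, t4 = 1, t5 = 1, t6 = 1, t7 = 1, t8 = 1, t9 = 1,
  t10 = 0.65, t11 = 1, t12 = 1, t13 = 1, t14 = 1, t15 = 1, t16 = 1,
  t17 = 1, t18 = 1, t19 = 1, t20 = 1, t21 = 1, t22 = 1, t23 = 1, t24 = 1,
  t25 = 1, t26 = 1, t27 = 1, t28 = 1, t29 = 1, t30 = 1, t31 = 1,
  Energy = 1)

## Calpain-CAST table as printed (c4 = 0.02, c5 = 0.5); the shipped bundle
## swaps c4/c5 to the narrative-consistent assignment
calpain_rates_printed <- c(
  c1 = 0.5, c2 = 0.1, c3 = 1, c4 = 0.02, c5 = 0.5, c6 = 0.5, c7 = 0.3,
  c8 = 0.5, c9 = 1, c10 = 1, c11 = 1, c12 = 1, c13 = 1, c14 = 0.5)

app_rates <- c(a = 0.5, a1 = 0.5, b = 0.3, b1 = 0.3, g1 = 0.5, g2 = 0.5,
               g_a = 0.5, g_b = 0.3, p1 = 0.005, p2 = 0.02)

crosstalk_extra <- c(c4 = 0.5, c5 = 0.02, c6 = 1, c12 = 0.5,
                     k1 = 0.5, k2 = 0.6, k3 = 1, k4 = 0.6, k5 = 0.01,
                     k6 = 0.04, b2 = 0.3)

test_that("every published rate appears verbatim in its bundle", {
  ca <- ad_model("calcium_channel")
  expect_identical(length(ca$rates), 32L)
  expect_equal(ca$rates[names(calcium_rates)], calcium_rates)

  cc <- ad_model("calpain_cast")
  expect_equal(cc$rates[names(calcium_rates)], calcium_rates)
  ## corrected assignment by default ...
  swapped <- calpain_rates_printed
  swapped[c("c4", "c5")] <- calpain_rates_printed[c("c5", "c4")]
  expect_equal(cc$rates[names(swapped)], swapped)
  ## ... and the raw printed values remain available
  raw <- ad_model("calpain_cast", raw_table_rates = TRUE)
  expect_equal(raw$rates[names(calpain_rates_printed)],
               calpain_rates_printed)

  ap <- ad_model("app_processing")
  expect_identical(length(ap$rates), 10L)
  expect_equal(ap$rates[names(app_rates)], app_rates)
  expect_identical(unname(ap$rates["p1"]), 0.005)
  expect_identical(unname(ap$rates["p2"]), 0.02)

  ct <- ad_model("crosstalk")
  expect_equal(ct$rates[names(calcium_rates)], calcium_rates)
  expect_equal(ct$rates[names(app_rates)], app_rates)
  expect_equal(ct$rates[names(crosstalk_extra)], crosstalk_extra)
  expect_identical(unname(ct$rates["t10"]), 0.65)
  expect_identical(unname(ct$rates["k5"]), 0.01)
})

test_that("shared calcium transitions carry identical rates in every bundle", {
  ts <- names(calcium_rates)
  ca <- ad_model("calcium_channel")$rates[ts]
  for (nm in c("calpain_cast", "crosstalk"))
    expect_equal(ad_model(nm)$rates[ts], ca)
})

test_that("the catalogue matches the shipped encodings", {
  cat <- list_models()
  expect_true("crosstalk" %in% cat$name)
  expect_identical(cat$rates[cat$name == "calcium_channel"], 32L)
  expect_identical(cat$rates[cat$name == "app_processing"], 10L)
  for (i in seq_len(nrow(cat))) {
    b <- ad_model(cat$name[i])
    expect_identical(nrow(b$net$transitions), cat$transitions[i])
    expect_identical(nrow(b$net$places), cat$places[i])
  }
})

test_that("model structure encodes the documented couplings", {
  ct <- ad_model("crosstalk")
  a <- ct$net$arcs
  ## NCX stoichiometry: 3 Na in per 1 Ca out
  expect_true(any(a$source == "t26" & a$target == "Na_In" & a$weight == 3))
  expect_true(any(a$source == "Ca_In" & a$target == "t26" & a$weight == 1))
  ## Calpain-gated second BACE cleavage (read arc from CLP)
  expect_true(any(a$source == "CLP" & a$target == "b2" & a$kind == "read"))
  expect_true(any(a$source == "b2" & a$target == "sAPPb"))
  ## amyloid-beta inhibits the Energy transition
  expect_true(any(a$source == "Amyloidbeta" & a$target == "Energy" &
                    a$kind == "inhibitor"))
  ## oligomer pores feed calcium influx (k3 joins Oligomer with Ca_In)
  expect_true(any(a$source == "Oligomer" & a$target == "k3" &
                    a$kind == "read"))
  expect_true(any(a$source == "k3" & a$target == "Ca_In"))
  ## PKC -> alpha-secretase via k1; P35 chain c13/k2/k4/k5/k6 present
  expect_true(any(a$source == "PKC" & a$target == "k1" & a$kind == "read"))
  for (t in c("c13", "k2", "k4", "k5", "k6"))
    expect_true(t %in% ct$net$transitions$id)
  ## aggregation stoichiometry is configurable
  m <- ad_model("app_processing", n_oligo = 3, n_plaq = 2)
  expect_true(any(m$net$arcs$source == "Amyloidbeta" &
                    m$net$arcs$target == "p1" & m$net$arcs$weight == 3))
  expect_true(any(m$net$arcs$source == "Oligomer" &
                    m$net$arcs$target == "p2" & m$net$arcs$weight == 2))
})

test_that("interventions replace rates without touching the original bundle", {
  base <- ad_model("crosstalk")
  iv <- apply_intervention(base, c(c2 = 0.05, c5 = 0.005))
  expect_identical(unname(iv$rates[c("c2", "c5")]), c(0.05, 0.005))
  expect_identical(unname(base$rates[c("c2", "c5")]), c(0.1, 0.02))
  expect_identical(apply_intervention(base, numeric(0))$rates, base$rates)
  expect_error(apply_intervention(base, c(zz = 1)), "unknown transitions")
  expect_error(apply_intervention(base, c(c2 = -1)), ">= 0")
  ## shipped presets name the perturbed transitions
  ivs <- ad_interventions()
  expect_identical(unname(ivs$mild), c(0.05, 0.005))
  expect_identical(names(ivs$mild), c("c2", "c5"))
  expect_identical(unname(ivs$c2_block), 0)
})

test_that("bundles document provenance for every element", {
  for (nm in ad_models()) {
    b <- ad_model(nm)
    expect_true(all(c("element", "provenance") %in% names(b$notes)))
    expect_identical(nrow(b$notes),
                     nrow(b$net$places) + nrow(b$net$transitions) +
                       nrow(b$net$arcs))
    expect_true(all(b$notes$provenance %in%
                      c("stated", "inferred", "calibrated")))
  }
})

test_that("unknown model names are rejected", {
  expect_error(ad_model("tau_pathology"))
})

test_that("calcium model stays bounded and the crosstalk CAST-degradation mean is non-decreasing", {
  ca <- ad_model("calcium_channel")
  ens <- simulate(ca, nsim = 30, seed = 11, t_end = 200, record = "grid")
  expect_lt(max(ens$mean), 200)  # counts bounded at the calibration cap
  expect_true(all(vapply(ens$runs, max, 1) < 400))

  ct <- ad_model("crosstalk")
  ens2 <- simulate(ct, nsim = 50, seed = 11, t_end = 200, record = "grid")
  dct <- ens2$mean["dCT", ]
  expect_true(all(diff(dct) >= -1e-9))
})
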