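test_that("validate_spn reports structural violations by name", {
  ## inhibitor arc running transition -> place is illegal
  bad <- spn(c("P"), c("T"),
             data.frame(source = "T", target = "P", kind = "inhibitor",
                        weight = 1L), check = FALSE)
  v <- validate_spn(bad)
  expect_length(v, 1L)
  expect_match(v, "inhibitor")
  expect_match(v, "T")

  ## dangling endpoint
  bad2 <- spn("P", "T",
              data.frame(source = "ghost", target = "T"), check = FALSE)
  v2 <- validate_spn(bad2)
  expect_true(any(grepl("ghost", v2)))

  ## duplicate (source, target, kind) triple
  bad3 <- spn("P", "T",
              data.frame(source = c("P", "P"), target = c("T", "T")),
              check = FALSE)
  expect_true(any(grepl("duplicate arcs", validate_spn(bad3))))

  ## place/transition namespace collision
  bad4 <- spn("X", "X", data.frame(source = "X", target = "X"),
              check = FALSE)
  expect_true(any(grepl("both a place and a transition",
                        validate_spn(bad4))))

  ## the receptor-ligand binding net is well formed
  expect_length(validate_spn(spn_fixture("receptor_ligand")$net), 0L)
  ## every shipped disease model passes validation
  for (nm in ad_models())
    expect_length(validate_spn(ad_model(nm)$net), 0L)
})

test_that("enabling matches the arc-kind truth table for all kinds x tokens x weights", {
  for (kind in c("standard", "inhibitor", "read", "equal")) {
    for (w in 1:3) {
      net <- single_arc_net(kind, w)
      for (tok in 0:4) {
        m <- spn_marking(net, c(P = tok))
        expect_identical(is_enabled(net, m, "T"),
                         enabling_oracle(kind, tok, w),
                         info = sprintf("%s w=%d tok=%d", kind, w, tok))
      }
    }
  }
})

test_that("firing consumes only standard input arcs and respects weights", {
  ## standard arc weight 3 empties a 3-token pre-place
  net <- single_arc_net("standard", 3L)
  m2 <- fire(net, spn_marking(net, c(P = 3)), "T")
  expect_identical(unname(m2[c("P", "Q")]), c(0L, 1L))

  ## read / inhibitor / equal arcs leave the pre-place untouched
  for (kind in c("read", "equal")) {
    net <- single_arc_net(kind, 5L)
    m2 <- fire(net, spn_marking(net, c(P = 5)), "T")
    expect_identical(unname(m2["P"]), 5L)
    expect_identical(unname(m2["Q"]), 1L)
  }
  net <- single_arc_net("inhibitor", 2L)
  m2 <- fire(net, spn_marking(net, c(P = 1)), "T")
  expect_identical(unname(m2["P"]), 1L)

  ## firing a disabled transition errors
  net <- single_arc_net("standard", 2L)
  expect_error(fire(net, spn_marking(net, c(P = 1)), "T"), "not enabled")

  ## receptor-ligand complex formation moves both reactants into the complex
  rl <- spn_fixture("receptor_ligand")
  m <- spn_marking(rl$net, c(Open_R = 1, Active_L = 1))
  m2 <- fire(rl$net, m, "Binding")
  expect_identical(unname(m2[c("Open_R", "Active_L", "RL_Complex")]),
                   c(0L, 0L, 1L))
})

test_that("fire never produces a negative count on random nets", {
  for (s in 1:10) {
    fx <- spn_fixture("random_bounded", seed = s)
    m <- fx$marking
    for (step in 1:50) {
      en <- Filter(function(t) is_enabled(fx$net, m, t),
                   fx$net$transitions$id)
      if (!length(en)) break
      m <- fire(fx$net, m, en[[1L + step %% length(en)]])
      expect_true(all(m >= 0))
    }
  }
})

test_that("incidence matrix sums standard weights and ignores gating arcs", {
  rl <- spn_fixture("receptor_ligand")
  C <- incidence_matrix(rl$net)
  expect_identical(C[c("Open_R", "Active_L", "RL_Complex"), "Binding"],
                   c(Open_R = -1L, Active_L = -1L, RL_Complex = 1L))

  ## read-only inputs contribute zero columns
  net <- single_arc_net("read", 1L)
  expect_identical(incidence_matrix(net)["P", "T"], 0L)

  ## a source transition with a weight-2 output gives a single +2 entry
  src <- spn("X", "s",
             data.frame(source = "s", target = "X", weight = 2L))
  expect_identical(incidence_matrix(src)["X", "s"], 2L)
})

test_that("p_invariants returns conserved weightings (toggle, enzyme, source)", {
  tg <- spn_fixture("toggle")
  Y <- p_invariants(tg$net)
  expect_identical(nrow(Y), 1L)
  expect_identical(unname(Y[1, c("A", "B")]), c(1L, 1L))

  ## pure source net has none
  src <- spn("X", "s", data.frame(source = "s", target = "X"))
  expect_identical(nrow(p_invariants(src)), 0L)

  ## enzyme-substrate: enzyme pool (E + ES) and mass (S + ES + P)
  ez <- spn_fixture("enzyme_substrate")
  Y <- p_invariants(ez$net)
  C <- incidence_matrix(ez$net)
  expect_true(all(Y %*% C == 0))
  key <- apply(Y[, c("E", "S", "ES", "P")], 1, paste, collapse = ",")
  expect_true("1,0,1,0" %in% key)  # E + ES
  expect_true("0,1,1,1" %in% key)  # S + ES + P
})

test_that("p_invariants agrees with brute-force enumeration on small random nets", {
  for (s in c(3, 11, 27)) {
    fx <- spn_fixture("random_bounded", seed = s)
    C <- incidence_matrix(fx$net)
    Y <- p_invariants(fx$net)
    if (nrow(Y)) expect_true(all(Y %*% C == 0))
    ## enumerate all non-negative vectors up to weight 3 in the kernel
    nP <- nrow(C)
    grid <- as.matrix(expand.grid(rep(list(0:3), nP)))
    ker <- grid[rowSums(grid) > 0 & rowSums(abs(grid %*% C)) == 0, ,
                drop = FALSE]
    if (nrow(ker)) {
      ## every minimal-support brute-force solution must appear in the
      ## generating set (up to integer scaling)
      supp <- ker != 0
      minimal <- vapply(seq_len(nrow(ker)), function(i) {
        !any(vapply(seq_len(nrow(ker)), function(j) {
          j != i && all(supp[j, ] <= supp[i, ]) && any(supp[i, ] & !supp[j, ])
        }, TRUE))
      }, TRUE)
      kmin <- ker[minimal, , drop = FALSE]
      norm <- function(v) { g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), abs(v[v != 0])); paste(v / g, collapse = ",") }
      got <- apply(Y, 1, norm)
      want <- unique(apply(kmin, 1, norm))
      expect_true(all(want %in% got),
                  info = sprintf("seed %d: missing invariants", s))
    } else {
      expect_identical(nrow(Y), 0L)
    }
  }
})

test_that("conserved weighted token sums hold along simulated trajectories", {
  for (s in c(5, 9)) {
    fx <- spn_fixture("random_bounded", seed = s)
    Y <- p_invariants(fx$net)
    if (!nrow(Y)) next
    tr <- simulate(fx$net, seed = s, marking = fx$marking,
                   rates = fx$rates, t_end = 20)
    tot <- Y %*% tr$markings
    expect_true(all(tot == tot[, 1]))
  }
})

test_that("marking construction checks names, signs and capacities", {
  net <- spn(data.frame(id = "P", capacity = 2L), "T",
             data.frame(source = "P", target = "T"))
  expect_error(spn_marking(net, c(Z = 1)), "unknown places")
  expect_error(spn_marking(net, c(P = -1)), "negative")
  expect_error(spn_marking(net, c(P = 3)), "capacity")
  expect_identical(unname(spn_marking(net, c(P = 2))["P"]), 2L)
})
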