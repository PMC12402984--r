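test_that("alphabet reduction handles all four hypothesis cases", {
  b <- toy_basis()

  # null: identity
  red0 <- reduce_alphabet(b, resub_config("W", "Y", Is = 0))
  expect_identical(red0$basis$pi, b$pi)
  expect_identical(red0$basis$r, b$r)

  # expansion discarding W (retain Y): frequencies renormalize
  red3 <- reduce_alphabet(b, resub_config("W", "Y", Is = 3))
  expect_equal(unname(red3$basis$pi), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(red3$index_map, c(1L, 3L))

  # expansion discarding Y (retain W)
  red2 <- reduce_alphabet(b, resub_config("W", "Y", Is = 2))
  expect_equal(unname(red2$basis$pi), c(0.6, 0.1) / 0.7, tolerance = 1e-12)
  expect_equal(red2$basis$r["x", "W"], 1)

  # refinement: merged state at equilibrium between sub-states
  red1 <- reduce_alphabet(b, resub_config("W", "Y", Is = 1))
  expect_equal(unname(red1$basis$pi), c(0.6, 0.4), tolerance = 1e-12)
  expect_equal(red1$merged_label, "W/Y")
  expect_equal(red1$basis$r["x", "W/Y"], (1 * 0.1 + 2 * 0.3) / 0.4)

  expect_error(resub_config("W", "W", Is = 1), "differ")
})

test_that("refinement merging is the frequency-weighted average on 20 states", {
  b <- random_basis(20, seed = 21)
  cfg <- resub_config("W", "Y", Is = 1)
  red <- reduce_alphabet(b, cfg)
  expect_equal(sum(red$basis$pi), 1, tolerance = 1e-12)
  expect_equal(red$basis$r, t(red$basis$r))
  iW <- which(aa_alphabet() == "W")
  iY <- which(aa_alphabet() == "Y")
  others <- setdiff(seq_len(20), c(iW, iY))
  manual <- (b$r[iW, others] * b$pi[iW] + b$r[iY, others] * b$pi[iY]) /
    (b$pi[iW] + b$pi[iY])
  got <- red$basis$r["W/Y", setdiff(colnames(red$basis$r), "W/Y")]
  expect_equal(unname(got), unname(manual), tolerance = 1e-12)
})

test_that("saltation matrices follow the refinement and expansion forms", {
  b <- toy_basis()

  # expansion, worked example: [[0.9, 0.1, 0], [0, 0.25, 0.75]]
  Xi3 <- saltation_matrix(b, resub_config("W", "Y", Is = 3, nu = 0.25))
  expect_equal(unname(Xi3),
               matrix(c(0.9, 0.1, 0, 0, 0.25, 0.75), 2, 3, byrow = TRUE),
               tolerance = 1e-12)

  # 20-state refinement with gamma1 = W, gamma0 = Y
  b20 <- random_basis(20, seed = 3)
  Xi <- saltation_matrix(b20, resub_config("W", "Y", Is = 1, nu = 0.4))
  piW <- b20$pi[["W"]]
  piY <- b20$pi[["Y"]]
  expect_equal(unname(Xi["A", "W"]), unname(piW))
  expect_equal(unname(Xi["A", "Y"]), unname(piY))
  expect_equal(unname(Xi["A", "A"]), unname(1 - piW - piY))
  expect_equal(unname(Xi["W/Y", "Y"]), 0.4)
  expect_equal(unname(Xi["W/Y", "W"]), 0.6)
  expect_equal(sum(Xi["C", c("C", "W", "Y")]), 1)

  # nu = 0 expansion: retained row is one-hot; others still leak
  Xi0 <- saltation_matrix(b, resub_config("W", "Y", Is = 3, nu = 0))
  expect_equal(unname(Xi0[2, ]), c(0, 0, 1))
  expect_equal(unname(Xi0[1, 2]), 0.1)

  expect_error(saltation_matrix(b, resub_config("W", "Y", Is = 0)),
               "undefined")
})

test_that("saltation rows are stochastic for random frequencies and nu", {
  set.seed(8)
  for (rep in 1:20) {
    m <- sample(3:8, 1)
    b <- random_basis(m)
    st <- as.character(b$states)
    cherry <- sample(st, 2)
    cfg <- resub_config(cherry[1], cherry[2], Is = sample(1:3, 1),
                        nu = runif(1))
    Xi <- saltation_matrix(b, cfg)
    expect_equal(unname(rowSums(Xi)), rep(1, m - 1), tolerance = 1e-12)
    expect_true(all(Xi >= 0 & Xi <= 1))
    i0 <- match(cfg$gamma0, st)
    ridx <- which(reduce_alphabet(b, cfg)$index_map == match(cfg$gamma1, st))
    expect_equal(unname(Xi[ridx, i0]), cfg$nu, tolerance = 1e-12)
  }
})

test_that("epoch transition matrices compose the three factors", {
  b <- toy_basis()
  cfg <- resub_config("W", "Y", Is = 3, te = 0.5, nu = 0.25)

  # worked example at tau2 = tau1 = 0.5
  P <- epoch_transition_matrix(b, cfg, 0.5, 0.5)
  expect_equal(unname(P),
               matrix(c(0.635, 0.110, 0.255, 0.512, 0.142, 0.345),
                      2, 3, byrow = TRUE), tolerance = 2e-3)
  expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)

  # zero distances collapse onto the saltation matrix
  expect_equal(unname(epoch_transition_matrix(b, cfg, 0, 0)),
               unname(saltation_matrix(b, cfg)), tolerance = 1e-12)

  # null case collapses to a single-epoch matrix over the total distance
  cfg0 <- resub_config("W", "Y", Is = 0)
  Qn <- normalize_rate_matrix(build_rate_matrix(b))
  expect_equal(unname(epoch_transition_matrix(b, cfg0, 0.3, 0.2)),
               unname(transition_matrix(Qn, 0.5)), tolerance = 1e-12)

  expect_error(epoch_transition_matrix(b, cfg, -1, 0.2), ">= 0")
})

test_that("epoch matrix equals the brute-force sum over boundary states", {
  set.seed(12)
  for (Is in 1:3) {
    b <- random_basis(5)
    st <- as.character(b$states)
    cfg <- resub_config(st[2], st[4], Is = Is, te = 0.3, nu = runif(1))
    tau2 <- runif(1, 0, 1)
    tau1 <- runif(1, 0, 1)
    P <- epoch_transition_matrix(b, cfg, tau2, tau1)
    red <- reduce_alphabet(b, cfg)
    P2 <- transition_matrix(normalize_rate_matrix(build_rate_matrix(red$basis)),
                            tau2)
    P1 <- transition_matrix(normalize_rate_matrix(build_rate_matrix(b)), tau1)
    Xi <- saltation_matrix(b, cfg)
    brute <- matrix(0, nrow(P2), ncol(P1))
    for (i in seq_len(nrow(P2))) {
      for (j in seq_len(ncol(P1))) {
        acc <- 0
        for (k in seq_len(ncol(P2))) {
          for (l in seq_len(nrow(P1))) {
            acc <- acc + P2[i, k] * Xi[k, l] * P1[l, j]
          }
        }
        brute[i, j] <- acc
      }
    }
    expect_equal(unname(P), brute, tolerance = 1e-12)
  }
})

test_that("long young-epoch branches converge on the full equilibrium", {
  b <- toy_basis()
  cfg <- resub_config("W", "Y", Is = 1, te = 1, nu = 0.7)
  P <- epoch_transition_matrix(b, cfg, 0.4, 60)
  for (i in seq_len(nrow(P))) {
    expect_equal(unname(P[i, ]), unname(b$pi), tolerance = 1e-8)
  }
})

test_that("root frequencies switch to the reduced simplex above the boundary", {
  b <- toy_basis()
  expect_identical(root_frequencies(b, resub_config("W", "Y", 0), 10), b$pi)
  f3 <- root_frequencies(b, resub_config("W", "Y", 3, te = 0.5), 1)
  expect_equal(unname(f3), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # boundary above the root: whole tree in the young epoch
  f1 <- root_frequencies(b, resub_config("W", "Y", 1, te = 2), 1)
  expect_identical(f1, b$pi)
})
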