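test_that("rate matrix construction follows Q = r diag(pi) with zero-sum rows", {
  b <- toy_basis()
  Q <- build_rate_matrix(b)
  # off-diagonals of the x row: r(x,W) pi_W = 0.1, r(x,Y) pi_Y = 0.6
  expect_equal(Q["x", "W"], 0.1)
  expect_equal(Q["x", "Y"], 0.6)
  expect_equal(Q["x", "x"], -0.7)
  expect_equal(unname(rowSums(Q)), rep(0, 3), tolerance = 1e-12)

  # uniform basis: full symmetry
  bu <- substitution_basis(matrix(2, 4, 4), rep(0.25, 4), letters[1:4])
  Qu <- build_rate_matrix(bu)
  off <- Qu[upper.tri(Qu) | lower.tri(Qu)]
  expect_true(all(abs(off - off[1]) < 1e-15))
  expect_true(all(abs(diag(Qu) - diag(Qu)[1]) < 1e-15))

  # random basis rows sum to zero
  br <- random_basis(4, seed = 11)
  expect_equal(unname(rowSums(build_rate_matrix(br))), rep(0, 4),
               tolerance = 1e-10)
})

test_that("basis validation names the offending entry", {
  r <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  expect_error(substitution_basis(r, c(0.5, 0.1, 0.3), c("x", "W", "Y")),
               "sum to 1")
  r2 <- r
  r2[1, 2] <- 9
  expect_error(substitution_basis(r2, c(0.6, 0.1, 0.3), c("x", "W", "Y")),
               "symmetric")
  expect_error(substitution_basis(r, c(0.7, -0.1, 0.4), c("x", "W", "Y")),
               "positive")
})

test_that("normalization reproduces the worked example and is idempotent", {
  b <- toy_basis()
  Qn <- normalize_rate_matrix(build_rate_matrix(b))
  printed <- matrix(c(-0.686, 0.098, 0.588,
                      0.588, -1.470, 0.882,
                      1.180, 0.294, -1.470), 3, 3, byrow = TRUE)
  expect_equal(unclass(Qn), printed, tolerance = 5e-3,
               ignore_attr = TRUE)
  expect_equal(-sum(b$pi * diag(Qn)), 1, tolerance = 1e-10)
  Qn2 <- normalize_rate_matrix(Qn)
  expect_equal(unclass(Qn2), unclass(Qn), tolerance = 1e-12,
               ignore_attr = TRUE)

  # reduced 2-state toy
  red <- reduce_alphabet(b, resub_config("W", "Y", Is = 3))
  Qr <- normalize_rate_matrix(build_rate_matrix(red$basis))
  expect_equal(unclass(Qr),
               matrix(c(-0.75, 0.75, 1.50, -1.50), 2, 2, byrow = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)

  Z <- build_rate_matrix(substitution_basis(matrix(0, 3, 3),
                                            c(0.6, 0.1, 0.3),
                                            c("x", "W", "Y")))
  expect_error(normalize_rate_matrix(Z), "degenerate")
})

test_that("transition probabilities match the worked example and limits", {
  b <- toy_basis()
  Qn <- normalize_rate_matrix(build_rate_matrix(b))
  P <- transition_matrix(Qn, 0.5)
  printed <- matrix(c(0.772, 0.042, 0.186,
                      0.253, 0.502, 0.246,
                      0.372, 0.082, 0.546), 3, 3, byrow = TRUE)
  expect_equal(unclass(P), printed, tolerance = 2e-3, ignore_attr = TRUE)

  expect_equal(unname(transition_matrix(Qn, 0)), diag(3))
  # stationary limit
  Pinf <- transition_matrix(Qn, 50)
  for (i in 1:3) expect_equal(unname(Pinf[i, ]), unname(b$pi),
                              tolerance = 1e-6)
  expect_error(transition_matrix(Qn, -0.1), ">= 0")
})

test_that("transition matrices satisfy the Markov properties on random bases", {
  for (seed in 1:3) {
    b <- random_basis(sample(3:6, 1), seed = seed)
    Qn <- normalize_rate_matrix(build_rate_matrix(b))
    for (tau in c(0, 0.1, 1, 10)) {
      P <- transition_matrix(Qn, tau)
      expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
      expect_true(all(P >= 0 & P <= 1 + 1e-12))
      # detailed balance: pi_i P_ij = pi_j P_ji
      flux <- b$pi * P
      expect_equal(flux, t(flux), tolerance = 1e-9)
    }
    # Chapman-Kolmogorov
    expect_equal(transition_matrix(Qn, 0.3) %*% transition_matrix(Qn, 0.7),
                 transition_matrix(Qn, 1.0), tolerance = 1e-9)
    # agreement with the dense Pade exponential
    expect_equal(unname(transition_matrix(Qn, 0.8)),
                 unname(as.matrix(Matrix::expm(Matrix::Matrix(unclass(Qn) * 0.8)))),
                 tolerance = 1e-9)
  }
})

test_that("discrete gamma categories average one and match quadrature", {
  expect_equal(discrete_gamma_rates(2.3, 1)$rates, 1)
  r4 <- discrete_gamma_rates(1e7, 4)$rates   # vanishing-variance limit
  expect_true(all(abs(r4 - 1) < 1e-3))

  sm <- discrete_gamma_rates(0.5, 4)
  expect_equal(mean(sm$rates), 1, tolerance = 1e-12)
  expect_true(all(diff(sm$rates) >= 0))
  # quadrature oracle for the category means
  q <- qgamma((0:4) / 4, shape = 0.5, rate = 0.5)
  oracle <- vapply(1:4, function(i) {
    4 * integrate(function(x) x * dgamma(x, 0.5, 0.5), q[i], q[i + 1],
                  rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(sm$rates, oracle, tolerance = 1e-6)
  # independent library discretization agrees
  expect_equal(sm$rates,
               as.numeric(phangorn::discrete.gamma(0.5, 4)),
               tolerance = 1e-8)
  expect_error(discrete_gamma_rates(-1, 4), "positive")
})

test_that("PAML-style rate files round-trip into a basis", {
  b <- random_basis(20, seed = 5)
  path <- withr::local_tempfile(fileext = ".dat")
  lines <- character(0)
  for (i in 2:20) {
    lines <- c(lines, paste(format(b$r[i, 1:(i - 1)], digits = 10),
                            collapse = " "))
  }
  lines <- c(lines, "", paste(format(b$pi, digits = 10), collapse = " "))
  writeLines(lines, path)
  b2 <- read_paml_rates(path)
  expect_equal(b2$r, b$r, tolerance = 1e-8)
  expect_equal(b2$pi, b$pi, tolerance = 1e-8)
})
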