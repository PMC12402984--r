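test_that("branch distances split correctly at the epoch boundary", {
  expect_equal(split_branch_at_boundary(1, 0, 0.5, 1),
               c(tau2 = 0.5, tau1 = 0.5))
  expect_equal(split_branch_at_boundary(0.4, 0, 0.5, 1),
               c(tau2 = 0, tau1 = 0.4))
  expect_equal(split_branch_at_boundary(1, 0, 0.5, 2),
               c(tau2 = 1, tau1 = 1))
  # branch wholly above the boundary sits in the old epoch
  expect_equal(split_branch_at_boundary(1, 0.6, 0.5, 1),
               c(tau2 = 0.4, tau1 = 0))
  # conservation under arbitrary placements
  set.seed(4)
  for (i in 1:20) {
    hp <- runif(1, 0.5, 2)
    hc <- runif(1, 0, hp - 0.01)
    te <- runif(1, -0.2, 2.5)
    rate <- runif(1, 0.1, 3)
    tau <- split_branch_at_boundary(hp, hc, te, rate)
    expect_equal(sum(tau), rate * (hp - hc), tolerance = 1e-12)
    expect_true(all(tau >= 0))
  }
  expect_error(split_branch_at_boundary(0.2, 0.5, 0.3, 1), "exceed")
})

test_that("one-taxon site likelihoods equal pi %*% P and sum to one", {
  b <- toy_basis()
  tt <- tree_one_taxon(origin = 1)
  cfg <- resub_config("W", "Y", Is = 0)
  Qn <- normalize_rate_matrix(build_rate_matrix(b))
  expected <- as.numeric(b$pi %*% transition_matrix(Qn, 1))
  liks <- vapply(seq_along(b$states), function(s) {
    aln <- pattern_alignment(as.character(b$states)[s], "A", b$states)
    exp(tree_log_likelihood(tt, aln, b, cfg))
  }, numeric(1))
  expect_equal(liks, expected, tolerance = 1e-12)
  expect_equal(sum(liks), 1, tolerance = 1e-12)
})

test_that("epoch-aware pruning equals exhaustive enumeration on toy trees", {
  b <- toy_basis()
  trees <- list(tree_one_taxon(), tree_two_taxon(), tree_three_taxon())
  for (tt in trees) {
    pats <- all_patterns(b$states, tt$ntip)
    for (Is in 0:3) {
      for (te in c(0.2, 0.6, 1.5)) {
        cfg <- resub_config("W", "Y", Is = Is, te = te, nu = 0.35)
        orc <- oracle_pattern_lik(tt, b, cfg)
        total <- 0
        for (p in seq_len(nrow(pats))) {
          aln <- pattern_alignment(pats[p, ], tt$labels, b$states)
          lik <- exp(tree_log_likelihood(tt, aln, b, cfg))
          expect_equal(lik, orc(pats[p, ]), tolerance = 1e-10)
          total <- total + lik
        }
        expect_equal(total, 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("pruning with rate heterogeneity matches the enumeration oracle", {
  b <- toy_basis()
  tt <- tree_two_taxon()
  sm <- discrete_gamma_rates(0.6, 4)
  cfg <- resub_config("W", "Y", Is = 1, te = 0.7, nu = 0.5)
  orc <- oracle_pattern_lik(tt, b, cfg, rates = sm$rates)
  pats <- all_patterns(b$states, 2)
  for (p in seq_len(nrow(pats))) {
    aln <- pattern_alignment(pats[p, ], tt$labels, b$states)
    expect_equal(exp(tree_log_likelihood(tt, aln, b, cfg, sm)),
                 orc(pats[p, ]), tolerance = 1e-10)
  }
})

test_that("null-model likelihood matches standard pruning and ignores te, nu", {
  set.seed(7)
  tt <- simulate_bd_tree(n = 5)
  b <- random_basis(20, seed = 9)
  cfg0 <- resub_config("W", "Y", Is = 0)
  sm <- discrete_gamma_rates(0.7, 4)
  clock <- clock_model(0.8)
  aln <- simulate_alignment(tt, b, cfg0, sm, clock, L = 40)
  ll <- tree_log_likelihood(tt, aln, b, cfg0, sm, clock)

  phy <- tt_to_phylo(tt)
  phy$edge.length <- phy$edge.length * 0.8
  pd <- phangorn::phyDat(unclass(aln), type = "USER",
                         levels = aa_alphabet())
  fit <- phangorn::pml(phy, pd, bf = b$pi, Q = b$r[lower.tri(b$r)],
                       k = 4, shape = 0.7)
  expect_equal(ll, fit$logLik, tolerance = 1e-8)

  # invariance of the null likelihood to te and nu
  for (te in c(0.1, 1, 5)) {
    cfg <- resub_config("W", "Y", Is = 0, te = te, nu = runif(1))
    expect_equal(tree_log_likelihood(tt, aln, b, cfg, sm, clock), ll,
                 tolerance = 1e-12)
  }
})

test_that("gap and ambiguity columns marginalize over compatible states", {
  b <- random_basis(20, seed = 14)
  tt <- tree_two_taxon()
  cfg <- resub_config("W", "Y", Is = 2, te = 0.6, nu = 0.2)
  # a fully gapped column contributes probability 1
  aln_gap <- aa_alignment(c(A = "-", B = "X"), states = b$states)
  expect_equal(tree_log_likelihood(tt, aln_gap, b, cfg), 0,
               tolerance = 1e-10)
  # B = {D, N}: likelihood is the sum over the two resolutions
  aln_b <- aa_alignment(c(A = "B", B = "A"), states = b$states)
  l_sum <- sum(vapply(c("D", "N"), function(s) {
    exp(tree_log_likelihood(tt, aa_alignment(c(A = s, B = "A"),
                                             states = b$states), b, cfg))
  }, numeric(1)))
  expect_equal(exp(tree_log_likelihood(tt, aln_b, b, cfg)), l_sum,
               tolerance = 1e-12)
})

test_that("likelihood is continuous in te except at node heights", {
  b <- toy_basis()
  tt <- tree_two_taxon(root = 0.5, origin = 1)
  aln <- aa_alignment(c(A = "W", B = "W"), states = b$states)
  ll_at <- function(te) {
    tree_log_likelihood(tt, aln, b,
                        resub_config("W", "Y", Is = 1, te = te, nu = 0.8))
  }
  # smooth away from node heights
  expect_lt(abs(ll_at(0.300001) - ll_at(0.3)), 1e-4)
  # discontinuity when the boundary crosses the two-taxon root
  jump <- abs(ll_at(0.500001) - ll_at(0.499999))
  expect_gt(jump, 0.01)
})

test_that("taxa and alphabet mismatches raise descriptive errors", {
  b <- toy_basis()
  tt <- tree_two_taxon()
  aln <- aa_alignment(c(A = "x", C = "W"), states = b$states)
  expect_error(tree_log_likelihood(tt, aln, b, resub_config("W", "Y", 0)),
               "taxa mismatch")
  aln2 <- aa_alignment(c(A = "A", B = "C"), states = aa_alphabet())
  expect_error(tree_log_likelihood(tt, aln2, b, resub_config("W", "Y", 0)),
               "alphabet")
})
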