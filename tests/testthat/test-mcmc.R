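test_that("model support and classification follow the Bayes factor rule", {
  tr <- tibble::tibble(Sample = 1:100, Is = rep(0L, 100))
  s <- model_support(tr, burnin = 0)
  expect_equal(unname(s[1:4]), c(1, 0, 0, 0))
  tr2 <- tibble::tibble(Sample = 1:100,
                        Is = rep(c(0L, 1L, 2L, 3L), c(10, 30, 40, 20)))
  expect_equal(unname(model_support(tr2, burnin = 0)[1:4]),
               c(0.1, 0.3, 0.4, 0.2))
  expect_error(model_support(tibble::tibble(Sample = integer(0),
                                            Is = integer(0))), "empty")

  expect_equal(classify_support(0.95, 1), "resub")
  expect_equal(classify_support(10 / 11, 1), "?")   # BF exactly 10
  expect_equal(classify_support(0.5, 1), "?")
  expect_equal(classify_support(0.05, 1), "no resub")
  expect_equal(classify_support(1, 1), "resub")
  # prior odds divide out
  expect_equal(classify_support(0.95, 19), "?")
})

test_that("the ESS estimator matches sampling and closed-form oracles", {
  set.seed(61)
  x <- rnorm(10000)
  expect_lt(abs(effective_sample_size(x) - 10000) / 10000, 0.15)

  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), 10000))
  target <- 10000 * (1 - phi) / (1 + phi)
  expect_lt(abs(effective_sample_size(ar) - target) / target, 0.25)

  # duplicating every sample halves the information rate
  dup <- rep(rnorm(3000), each = 2)
  expect_lt(effective_sample_size(dup), 6000 * 0.7)

  expect_warning(e0 <- effective_sample_size(rep(1, 100)), "constant")
  expect_equal(e0, 0)
  expect_error(effective_sample_size(1:5), "short")
  # cross-check against an independent implementation
  expect_lt(abs(effective_sample_size(ar) -
                  as.numeric(coda::effectiveSize(ar))) / target, 0.3)
})

test_that("cross-bracing prior evaluates the exponential at the height gaps", {
  h <- c(root = 4.4, luca = 4.2, laca = 3.3)
  expect_equal(cross_brace_log_prior(h, h), 2 * log(100))
  h2 <- h
  h2["root"] <- 4.41
  expect_equal(cross_brace_log_prior(h, h2, 0.01),
               (log(100) - 1) + log(100), tolerance = 1e-9)
  # monotone decrease in the root gap
  gaps <- seq(0, 0.05, by = 0.01)
  vals <- vapply(gaps, function(g) {
    hh <- h
    hh["root"] <- h[["root"]] + g
    cross_brace_log_prior(hh, h)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(cross_brace_log_prior(h, h[1:2]), "equal length")
})

test_that("calibration densities use the real-space lognormal translation", {
  lp <- resubr:::lognormal_params(4.25, 0.0094)
  # mean and sd of the lognormal recover M and S
  M <- exp(lp$meanlog + lp$sdlog^2 / 2)
  S2 <- (exp(lp$sdlog^2) - 1) * exp(2 * lp$meanlog + lp$sdlog^2)
  expect_equal(M, 4.25, tolerance = 1e-9)
  expect_equal(sqrt(S2), 0.0094, tolerance = 1e-6)
  # the density integrates to 1 over a window around the sharp mode
  expect_equal(integrate(function(x) dlnorm(x, lp$meanlog, lp$sdlog),
                         4.1, 4.4, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  expect_gt(dlnorm(4.25, lp$meanlog, lp$sdlog), 0)
  # the boundary prior at its mode is 1 / (2 delta)
  expect_equal(resubr:::te_log_prior(4, 4, 0.05), log(1 / (2 * 0.05)),
               tolerance = 1e-9)
})

test_that("the joint log prior sums its component densities", {
  set.seed(15)
  tree <- simulate_bd_tree(n = 5)
  pri <- prior_spec()
  a <- root_height(tree)
  base <- resub_log_prior(tree, te = a, nu = 0.5, Is = 0, priors = pri)
  expect_true(is.finite(base))
  # at te = anchor the boundary term sits at the Laplace mode
  away <- resub_log_prior(tree, te = a + 0.1, nu = 0.5, Is = 0, priors = pri)
  expect_equal(base - away, 0.1 / pri$delta, tolerance = 1e-9)
  # support violations reject rather than error
  expect_identical(resub_log_prior(tree, a, nu = 1.5, Is = 0, pri), -Inf)
  expect_identical(resub_log_prior(tree, a, nu = 0.5, Is = 7, pri), -Inf)
  # optional components add their densities
  with_shape <- resub_log_prior(tree, a, 0.5, 0, pri, shape = 2)
  expect_equal(with_shape - base, dexp(2, 1, log = TRUE), tolerance = 1e-12)
})

test_that("relaxed-clock multipliers are mean-one lognormal draws", {
  set.seed(16)
  tree <- simulate_bd_tree(n = 40)
  strict <- draw_branch_rates(tree, clock_model(1, "strict"))
  expect_true(all(strict$rate_mult == 1))
  relaxed <- draw_branch_rates(tree, clock_model(1, "lognormal", sdlog = 0.4))
  expect_true(all(relaxed$rate_mult > 0))
  expect_gt(sd(relaxed$rate_mult), 0)
  set.seed(17)
  many <- replicate(200, {
    mean(draw_branch_rates(tree, clock_model(1, "lognormal", 0.4))$rate_mult)
  })
  expect_lt(abs(mean(many) - 1), 0.01)
})

test_that("fixed seeds reproduce traces and two chains agree on support", {
  b <- toy_basis()
  set.seed(88)
  tt <- simulate_bd_tree(n = 8)
  cfg <- resub_config("W", "Y", Is = 2, te = 0.6 * root_height(tt), nu = 0.7)
  aln <- simulate_alignment(tt, b, cfg, L = 120)
  ctl <- mcmc_control(n_iter = 3000, thin = 5, k = 1)
  r1 <- resub_mcmc(aln, b, c("W", "Y"), tree = tt, control = ctl, seed = 19)
  r2 <- resub_mcmc(aln, b, c("W", "Y"), tree = tt, control = ctl, seed = 19)
  expect_identical(r1$trace, r2$trace)

  fit2 <- resub_mcmc_chains(aln, b, c("W", "Y"), tree = tt, control = ctl,
                            seed = 19, chains = 2)
  p1 <- model_support(fit2$chains[[1]])[["p_resub"]]
  p2 <- model_support(fit2$chains[[2]])[["p_resub"]]
  expect_lt(abs(p1 - p2), 0.05)
  expect_true(all(c("te", "tree_length") %in% names(fit2$ess)))

  td <- tidy(r1)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "ess") %in%
                    names(td)))
  g <- glance(r1)
  expect_equal(g$p_Is0 + g$p_resub, 1, tolerance = 1e-12)
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("prior-only chains recover the main prior marginals", {
  b <- toy_basis()
  aln <- aa_alignment(stats::setNames(rep("x", 6), paste0("t", 1:6)),
                      states = b$states)
  pri <- prior_spec(delta = 0.05)
  ctl <- mcmc_control(n_iter = 60000, thin = 10, likelihood = FALSE,
                      estimate_shape = TRUE, estimate_clock = TRUE)
  run <- resub_mcmc(aln, b, c("W", "Y"), priors = pri, control = ctl,
                    seed = 23)
  tr <- resubr:::burned_trace(run)
  thin <- seq(1, nrow(tr), 4)
  # boundary offset ~ Laplace(0, delta)
  d <- (tr$te - tr$anchor_height)[thin]
  expect_gt(suppressWarnings(
    ks.test(d, function(q) laplace_cdf(q, 0, 0.05)))$p.value, 0.001)
  # nu ~ U(0,1)
  expect_gt(ks.test(tr$nu[thin] + runif(length(thin), 0, 1e-12),
                    punif)$p.value, 0.001)
  # shape ~ Exp(1), clock ~ lognormal
  expect_gt(suppressWarnings(ks.test(tr$shape[thin], pexp, 1))$p.value,
            0.001)
  expect_gt(suppressWarnings(
    ks.test(tr$clock_rate[thin], plnorm, pri$clock_meanlog,
            pri$clock_sdlog))$p.value, 0.001)
})

test_that("frequency and exchangeability sampling stays in support", {
  b <- toy_basis()
  set.seed(41)
  tt <- simulate_bd_tree(n = 6)
  aln <- simulate_alignment(tt, b, resub_config("W", "Y", 0), L = 60)
  ctl <- mcmc_control(n_iter = 2000, thin = 10, estimate_pi = TRUE,
                      estimate_r = TRUE, is_fixed = 0L, k = 1,
                      trace_pi = TRUE)
  run <- resub_mcmc(aln, b, c("W", "Y"), tree = tt, control = ctl, seed = 4)
  pi_cols <- grep("^pi_", names(run$trace), value = TRUE)
  expect_length(pi_cols, 3)
  sums <- rowSums(run$trace[, pi_cols])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(run$trace[, pi_cols] > 0))
  st <- run$final_state
  expect_equal(st$r, t(st$r))
  expect_true(all(st$r[upper.tri(st$r)] > 0))
})
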