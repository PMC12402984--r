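#' Prior specification for resub inference
#'
#' Collects every prior density used by [resub_mcmc()]:
#'
#' * boundary prior: `te - t_anchor ~ Laplace(0, delta)`, truncated to
#'   non-negative ages, where the anchor is the height of a named node
#'   (the cherry bifurcation), the root, or a fixed age;
#' * a conditioned birth-death tree prior with birth rate `lambda`,
#'   reproduction number `r0 = lambda / mu`, and sampling fraction `rho`;
#' * optional lognormal node-age calibrations given as real-space mean `M`
#'   and standard deviation `S` (units Ga in dated analyses);
#' * a uniform prior on the saltation fraction `nu`;
#' * a probability vector over the model indicator `Is` in `0:3`
#'   (uniform by default);
#' * flat Dirichlet on frequencies `pi`, iid exponentials on
#'   exchangeabilities `r`, exponential on the gamma site shape, lognormal
#'   on the clock rate;
#' * an exponential cross-bracing mean (used by [cross_brace_log_prior()]
#'   when two co-estimated trees are linked).
#'
#' @param delta Scale of the Laplace boundary prior (time units).
#' @param anchor One of `list(type = "root")`,
#'   `list(type = "mrca", taxa = c(...))`, or
#'   `list(type = "fixed", age = a)`.
#' @param is_prior Probability vector over `Is = 0:3`.
#' @param bd List with `lambda`, `r0`, `rho`.
#' @param calibrations List of `list(name =, taxa =, M =, S =)` lognormal
#'   age calibrations on clades.
#' @param cross_brace_mean Mean of the exponential cross-bracing prior.
#' @param shape_mean Mean of the exponential prior on the gamma site shape.
#' @param clock_meanlog,clock_sdlog Lognormal prior on the strict clock rate.
#' @param r_rate Rate of the iid exponential priors on exchangeabilities.
#' @return A list of class `"prior_spec"`.
#' @export
prior_spec <- function(delta = 0.05,
                       anchor = list(type = "root"),
                       is_prior = rep(0.25, 4),
                       bd = list(lambda = 2, r0 = 2, rho = 1),
                       calibrations = list(),
                       cross_brace_mean = 0.01,
                       shape_mean = 1,
                       clock_meanlog = 0, clock_sdlog = 0.5,
                       r_rate = 1) {
  if (length(is_prior) != 4 || any(is_prior < 0) ||
      abs(sum(is_prior) - 1) > 1e-9) {
    stop("is_prior must be 4 non-negative probabilities summing to 1")
  }
  if (delta <= 0) stop("delta must be positive")
  stopifnot(bd$lambda > 0, bd$r0 > 0, bd$rho > 0, bd$rho <= 1)
  structure(list(delta = delta, anchor = anchor, is_prior = is_prior,
                 bd = bd, calibrations = calibrations,
                 cross_brace_mean = cross_brace_mean,
                 shape_mean = shape_mean,
                 clock_meanlog = clock_meanlog, clock_sdlog = clock_sdlog,
                 r_rate = r_rate),
            class = "prior_spec")
}

# ---- Laplace boundary prior -------------------------------------------------

dlaplace <- function(x, location = 0, scale = 1, log = FALSE) {
  ld <- -abs(x - location) / scale - base::log(2 * scale)
  if (log) ld else exp(ld)
}

plaplace <- function(q, location = 0, scale = 1) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

rlaplace <- function(n, location = 0, scale = 1) {
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

anchor_height <- function(tree, anchor) {
  switch(anchor$type,
         root = root_height(tree),
         mrca = mrca_height(tree, anchor$taxa),
         fixed = anchor$age,
         # deterministic mid-tree anchor: the internal node whose age is
         # closest to frac * root height in the current tree
         depth_frac = tree$heights[node_near_depth(tree, anchor$frac)],
         stop("unknown anchor type '", anchor$type, "'"))
}

# Laplace(anchor, delta) truncated to te >= 0.
te_log_prior <- function(te, anchor_h, delta) {
  if (te < 0) return(-Inf)
  z <- 1 - plaplace(0, location = anchor_h, scale = delta)
  dlaplace(te, anchor_h, delta, log = TRUE) - log(z)
}

rte_prior <- function(n, anchor_h, delta) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rlaplace(1, anchor_h, delta)
      if (x >= 0) break
    }
    out[i] <- x
  }
  out
}

# ---- Conditioned birth-death tree prior ------------------------------------

# rho-sampled birth-death conditioned on the number of sampled extant tips:
# the n-1 speciation times are iid with the density below (the sampling
# transformation lambda* = rho lambda, mu* = mu - lambda(1 - rho) preserves
# the reconstructed-tree distribution), and the ranked labelled topology is
# uniform.
bd_transformed <- function(bd) {
  mu <- bd$lambda / bd$r0
  list(lam = bd$rho * bd$lambda,
       mu = mu - bd$lambda * (1 - bd$rho),
       r = bd$lambda - mu)
}

bd_node_log_density <- function(s, bd) {
  p <- bd_transformed(bd)
  if (p$r <= 0) stop("birth-death prior requires r0 > 1 (supercritical)")
  log(p$lam) + 2 * log(p$r) - p$r * s - 2 * log(p$lam - p$mu * exp(-p$r * s))
}

bd_node_cdf <- function(s, bd) {
  p <- bd_transformed(bd)
  p$lam * (1 - exp(-p$r * s)) / (p$lam - p$mu * exp(-p$r * s))
}

bd_node_quantile <- function(q, bd) {
  p <- bd_transformed(bd)
  u <- p$lam * (1 - q) / (p$lam - q * p$mu)
  -log(u) / p$r
}

tree_bd_log_prior <- function(tree, bd) {
  internal <- (tree$ntip + 1L):length(tree$parent)
  sum(bd_node_log_density(tree$heights[internal], bd))
}

# ---- Calibrations -----------------------------------------------------------

# Real-space mean M and sd S -> meanlog/sdlog of the lognormal.
lognormal_params <- function(M, S) {
  sdlog2 <- log(1 + (S / M)^2)
  list(meanlog = log(M) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

calibration_log_prior <- function(tree, calibrations) {
  if (length(calibrations) == 0) return(0)
  sum(vapply(calibrations, function(cal) {
    lp <- lognormal_params(cal$M, cal$S)
    stats::dlnorm(mrca_height(tree, cal$taxa), lp$meanlog, lp$sdlog, log = TRUE)
  }, numeric(1)))
}

#' Divergence-date calibrations for deep nodes of the tree of life
#'
#' Lognormal age priors (real-space mean `M` and standard deviation `S`,
#' units Ga) for the root and the last universal (LUCA), archaeal (LACA),
#' bacterial (LBCA), mitochondrial (LMCA), and eukaryotic (LECA) common
#' ancestors, for use in dated analyses. Taxon sets must be attached by the
#' caller before the calibrations can be evaluated on a tree.
#'
#' @return A tibble with columns `name`, `M`, `S`.
#' @export
default_calibrations <- function() {
  tibble::tibble(
    name = c("Root", "LUCA", "LACA", "LBCA", "LMCA", "LECA"),
    M = c(4.49, 4.25, 3.35, 3.25, 1.43, 1.32),
    S = c(0.00375, 0.0094, 0.0114, 0.0142, 0.0589, 0.0443))
}

#' Joint log prior density of a model state
#'
#' Sums every prior term that applies to the supplied components: the
#' conditioned birth-death tree density, node-age calibrations, the
#' truncated Laplace boundary prior, the uniform saltation prior, the
#' model-indicator mass, and (when given) the gamma-shape, clock-rate and
#' exchangeability priors. States outside the support return `-Inf`
#' rather than raising an error, so samplers can treat them as rejections.
#'
#' @param tree A [time_tree()].
#' @param te Boundary age.
#' @param nu Saltation fraction.
#' @param Is Model indicator in `0:3`.
#' @param priors A [prior_spec()].
#' @param shape,clock_rate,r Optional further components; `r` is an
#'   exchangeability matrix whose upper triangle carries iid exponential
#'   priors.
#' @return Log prior density (scalar; `-Inf` outside the support).
#' @export
resub_log_prior <- function(tree, te, nu, Is, priors = prior_spec(),
                            shape = NULL, clock_rate = NULL, r = NULL) {
  if (!Is %in% 0:3 || nu < 0 || nu > 1) return(-Inf)
  lp <- log(priors$is_prior[Is + 1])
  anchor_h <- anchor_height(tree, priors$anchor)
  lp <- lp + te_log_prior(te, anchor_h, priors$delta)
  lp <- lp + tree_bd_log_prior(tree, priors$bd)
  lp <- lp + calibration_log_prior(tree, priors$calibrations)
  if (!is.null(shape)) {
    lp <- lp + stats::dexp(shape, 1 / priors$shape_mean, log = TRUE)
  }
  if (!is.null(clock_rate)) {
    lp <- lp + stats::dlnorm(clock_rate, priors$clock_meanlog,
                             priors$clock_sdlog, log = TRUE)
  }
  if (!is.null(r)) {
    lp <- lp + sum(stats::dexp(r[upper.tri(r)], priors$r_rate, log = TRUE))
  }
  unname(lp)
}

#' Cross-bracing prior linking two co-estimated trees
#'
#' Exponential(mean) log density evaluated at the absolute difference of
#' the two root heights, plus the same density at the mean absolute
#' difference across the braced node pairs. Used to hold equivalent nodes
#' of two co-estimated phylogenies at around the same age.
#'
#' @param heights_a,heights_b Matched numeric vectors of node ages; the
#'   element named `"root"` (or the first element) is the tree root, the
#'   rest are the braced node pairs.
#' @param mean Mean of the exponential prior (same time units as the
#'   heights).
#' @return Log prior density (a scalar).
#' @export
cross_brace_log_prior <- function(heights_a, heights_b, mean = 0.01) {
  if (length(heights_a) != length(heights_b)) {
    stop("braced node lists must have equal length")
  }
  ri <- if (!is.null(names(heights_a)) && "root" %in% names(heights_a)) {
    which(names(heights_a) == "root")[1]
  } else 1L
  rate <- 1 / mean
  lp <- stats::dexp(abs(heights_a[ri] - heights_b[ri]), rate, log = TRUE)
  if (length(heights_a) > 1) {
    d <- mean(abs(heights_a[-ri] - heights_b[-ri]))
    lp <- lp + stats::dexp(d, rate, log = TRUE)
  } else {
    lp <- lp + stats::dexp(0, rate, log = TRUE)
  }
  unname(lp)
}
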