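#' Control settings for resub MCMC
#'
#' @param n_iter Total Metropolis-Hastings iterations.
#' @param thin Record every `thin`-th state.
#' @param burnin Fraction of the trace discarded by summaries.
#' @param estimate_tree Sample node heights (and topology unless
#'   `estimate_topology = FALSE`).
#' @param estimate_topology Sample the topology by narrow exchange moves.
#' @param estimate_clock,estimate_pi,estimate_r,estimate_shape Sample the
#'   strict clock rate, frequencies, exchangeabilities, gamma shape.
#' @param is_fixed Fix the model indicator to this value (`NULL` to
#'   average over `0:3`).
#' @param k Gamma site-rate categories.
#' @param likelihood Evaluate the sequence likelihood (`FALSE` gives a
#'   prior-only chain, used for prior-recovery checks).
#' @param trace_pi,trace_r Include frequency / exchangeability columns in
#'   the trace.
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 10000L, thin = 10L, burnin = 0.1,
                         estimate_tree = TRUE, estimate_topology = TRUE,
                         estimate_clock = FALSE,
                         estimate_pi = FALSE, estimate_r = FALSE,
                         estimate_shape = FALSE, is_fixed = NULL,
                         k = 4L, likelihood = TRUE,
                         trace_pi = FALSE, trace_r = FALSE) {
  structure(as.list(environment()), class = "mcmc_control")
}

reflect01 <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

# Fast likelihood evaluator with the pattern compression and leaf partials
# precomputed once per data set.
make_loglik <- function(aln, tree0, states, cherry, k, priors) {
  aln <- aln[tree0$labels, , drop = FALSE]
  pc <- pattern_compress(aln)
  cube <- leaf_partials(pc$patterns, alphabet(states))
  force(k)
  # the eigensystems depend only on (pi, r, Is); cache them so chains that
  # hold the basis fixed pay the decompositions once per hypothesis
  cache <- new.env(parent = emptyenv())
  cache$pi <- NULL
  cache$sm_shape <- NULL
  function(st) {
    te <- state_te(st, priors)
    config <- resub_config(cherry[1], cherry[2], Is = st$Is,
                           te = max(te, 0), nu = st$nu)
    if (!identical(cache$pi, st$pi) || !identical(cache$r, st$r)) {
      cache$pi <- st$pi
      cache$r <- st$r
      cache$basis <- substitution_basis(st$r, st$pi, states)
      cache$pins <- vector("list", 4L)
    }
    key <- st$Is + 1L
    if (is.null(cache$pins[[key]])) {
      cache$pins[[key]] <- pruning_inputs(st$tree, cache$basis, config)
    }
    pin <- cache$pins[[key]]
    # the saltation matrix depends on nu, which moves every few steps
    if (st$Is > 0L) pin$Xi <- saltation_matrix(cache$basis, config)
    if (!identical(cache$sm_shape, st$shape)) {
      cache$sm_shape <- st$shape
      cache$sm <- discrete_gamma_rates(st$shape, k)
    }
    sm <- cache$sm
    tr <- st$tree
    epoch_pruning_cpp(
      children = tr$children, heights = tr$heights,
      order = postorder_internal(tr), root = tr$root,
      has_origin = !is.na(tr$origin_height),
      origin_height = if (is.na(tr$origin_height)) -1 else tr$origin_height,
      branch_rate = st$clock_rate * tr$rate_mult,
      te = te, is0 = st$Is == 0L,
      U = pin$eig$U, Ui = pin$eig$Ui, ev = pin$eig$values,
      Ur = pin$eigr$U, Uir = pin$eigr$Ui, evr = pin$eigr$values,
      Xi = pin$Xi, rf_full = pin$rf_full, rf_red = pin$rf_red,
      leaf_part = cube, cat_rates = sm$rates,
      weights = pc$weights)$loglik
  }
}

# The boundary age is held in the state as the offset d = te - t_anchor,
# so tree moves carry te along with the anchor node; te itself is derived.
state_te <- function(st, priors) {
  anchor_height(st$tree, priors$anchor) + st$te_off
}

state_log_prior <- function(st, priors, control) {
  lp <- log(priors$is_prior[st$Is + 1])
  if (!is.finite(lp)) return(-Inf)
  if (st$nu < 0 || st$nu > 1) return(-Inf)
  anchor_h <- anchor_height(st$tree, priors$anchor)
  lp <- lp + te_log_prior(anchor_h + st$te_off, anchor_h, priors$delta)
  lp <- lp + tree_bd_log_prior(st$tree, priors$bd)
  lp <- lp + calibration_log_prior(st$tree, priors$calibrations)
  if (control$estimate_shape) {
    lp <- lp + stats::dexp(st$shape, 1 / priors$shape_mean, log = TRUE)
  }
  if (control$estimate_clock) {
    lp <- lp + stats::dlnorm(st$clock_rate, priors$clock_meanlog,
                             priors$clock_sdlog, log = TRUE)
  }
  if (control$estimate_pi && any(st$pi <= 0)) return(-Inf)
  if (control$estimate_r) {
    lp <- lp + sum(stats::dexp(st$r[upper.tri(st$r)], priors$r_rate,
                               log = TRUE))
  }
  lp
}

# ---- operators --------------------------------------------------------------
# Each operator maps a state to list(st = proposal, lhr = log Hastings
# ratio, lik = does the likelihood change) or NULL for an immediate reject.

mcmc_operators <- function(priors, control, m) {
  ops <- list()
  add <- function(name, weight, fn) {
    ops[[length(ops) + 1]] <<- list(name = name, weight = weight, fn = fn)
  }
  w_te <- 2 * priors$delta
  add("te_walk", 2, function(st) {
    st$te_off <- st$te_off + stats::runif(1, -w_te, w_te)
    list(st = st, lhr = 0, lik = st$Is != 0L)
  })
  add("te_prior", 1, function(st) {
    a <- anchor_height(st$tree, priors$anchor)
    old <- st$te_off
    st$te_off <- rte_prior(1, a, priors$delta) - a
    # anchor unchanged within the move, so the truncation normalizer cancels
    list(st = st, lhr = (abs(st$te_off) - abs(old)) / priors$delta,
         lik = st$Is != 0L)
  })
  add("nu_walk", 2, function(st) {
    st$nu <- reflect01(st$nu + stats::runif(1, -0.35, 0.35))
    list(st = st, lhr = 0, lik = st$Is != 0L)
  })
  add("nu_prior", 1, function(st) {
    st$nu <- stats::runif(1)
    list(st = st, lhr = 0, lik = st$Is != 0L)
  })
  if (is.null(control$is_fixed)) {
    support <- which(priors$is_prior > 0) - 1L
    add("is_resample", 3, function(st) {
      st$Is <- sample(support, 1L)
      list(st = st, lhr = 0, lik = TRUE)
    })
    add("is_joint", 2, function(st) {
      a <- anchor_height(st$tree, priors$anchor)
      old <- st$te_off
      st$Is <- sample(support, 1L)
      st$te_off <- rte_prior(1, a, priors$delta) - a
      st$nu <- stats::runif(1)
      list(st = st, lhr = (abs(st$te_off) - abs(old)) / priors$delta,
           lik = TRUE)
    })
  }
  if (control$estimate_shape) {
    add("shape_scale", 1, function(st) {
      s <- exp(stats::runif(1, -0.5, 0.5))
      st$shape <- st$shape * s
      list(st = st, lhr = log(s), lik = TRUE)
    })
    add("shape_prior", 1.5, function(st) {
      old <- st$shape
      st$shape <- stats::rexp(1, 1 / priors$shape_mean)
      list(st = st,
           lhr = stats::dexp(old, 1 / priors$shape_mean, log = TRUE) -
             stats::dexp(st$shape, 1 / priors$shape_mean, log = TRUE),
           lik = TRUE)
    })
  }
  if (control$estimate_clock) {
    add("clock_scale", 2, function(st) {
      s <- exp(stats::runif(1, -0.3, 0.3))
      st$clock_rate <- st$clock_rate * s
      list(st = st, lhr = log(s), lik = TRUE)
    })
    add("clock_prior", 1.5, function(st) {
      old <- st$clock_rate
      st$clock_rate <- stats::rlnorm(1, priors$clock_meanlog,
                                     priors$clock_sdlog)
      list(st = st,
           lhr = stats::dlnorm(old, priors$clock_meanlog, priors$clock_sdlog,
                               log = TRUE) -
             stats::dlnorm(st$clock_rate, priors$clock_meanlog,
                           priors$clock_sdlog, log = TRUE),
           lik = TRUE)
    })
  }
  if (control$estimate_pi) {
    add("pi_exchange", 2, function(st) {
      ij <- sample.int(m, 2L)
      d <- stats::runif(1, -0.05, 0.05)
      st$pi[ij[1]] <- st$pi[ij[1]] + d
      st$pi[ij[2]] <- st$pi[ij[2]] - d
      if (any(st$pi[ij] <= 1e-8)) return(NULL)
      list(st = st, lhr = 0, lik = TRUE)
    })
  }
  if (control$estimate_r) {
    add("r_scale", 3, function(st) {
      i <- sample.int(m - 1L, 1L)
      j <- sample((i + 1L):m, 1L)
      s <- exp(stats::runif(1, -0.7, 0.7))
      st$r[i, j] <- st$r[j, i] <- st$r[i, j] * s
      list(st = st, lhr = log(s), lik = TRUE)
    })
  }
  if (control$estimate_tree) {
    # rank-preserving independence redraw of all node ages from the
    # birth-death prior: new sorted ages are assigned to the internal nodes
    # in their current rank order, so the topology stays valid; the Hastings
    # ratio cancels the tree-prior term and the move mixes heights freely
    if (!control$likelihood) add("heights_prior", 3, function(st) {
      tr <- st$tree
      if (any(tr$heights[seq_len(tr$ntip)] > 0)) return(NULL)
      internal <- (tr$ntip + 1L):length(tr$parent)
      if (length(internal) < 1) return(NULL)
      old <- tr$heights[internal]
      new <- sort(bd_node_quantile(stats::runif(length(internal)),
                                   priors$bd))
      tr$heights[internal] <- new[rank(old, ties.method = "first")]
      if (!is.na(tr$origin_height) &&
          tr$heights[tr$root] >= tr$origin_height) return(NULL)
      st$tree <- tr
      list(st = st,
           lhr = sum(bd_node_log_density(old, priors$bd)) -
             sum(bd_node_log_density(tr$heights[internal], priors$bd)),
           lik = TRUE)
    })
    add("height_slide", 4, function(st) {
      tr <- st$tree
      cand <- setdiff((tr$ntip + 1L):length(tr$parent), tr$root)
      if (length(cand) == 0) return(NULL)
      v <- if (length(cand) == 1L) cand else sample(cand, 1L)
      lo <- max(tr$heights[tr$children[[v]]])
      hi <- tr$heights[tr$parent[v]]
      tr$heights[v] <- stats::runif(1, lo, hi)
      st$tree <- tr
      list(st = st, lhr = 0, lik = TRUE)
    })
    add("root_scale", 2, function(st) {
      tr <- st$tree
      mc <- max(tr$heights[tr$children[[tr$root]]])
      s <- exp(stats::runif(1, -0.8, 0.8))
      h <- mc + (tr$heights[tr$root] - mc) * s
      if (!is.na(tr$origin_height) && h >= tr$origin_height) return(NULL)
      tr$heights[tr$root] <- h
      st$tree <- tr
      list(st = st, lhr = log(s), lik = TRUE)
    })
    add("tree_scale", 1, function(st) {
      tr <- st$tree
      if (any(tr$heights[seq_len(tr$ntip)] > 0)) return(NULL)
      internal <- (tr$ntip + 1L):length(tr$parent)
      s <- exp(stats::runif(1, -0.35, 0.35))
      tr$heights[internal] <- tr$heights[internal] * s
      if (!is.na(tr$origin_height) &&
          tr$heights[tr$root] >= tr$origin_height) return(NULL)
      st$tree <- tr
      list(st = st, lhr = length(internal) * log(s), lik = TRUE)
    })
    if (control$estimate_topology) add("narrow_exchange", 3, function(st) {
      tr <- st$tree
      cand <- setdiff((tr$ntip + 1L):length(tr$parent), tr$root)
      if (length(cand) == 0) return(NULL)
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      g <- tr$parent[p]
      a <- setdiff(tr$children[[g]], p)
      u <- sample(tr$children[[p]], 1L)
      if (tr$heights[a] >= tr$heights[p]) return(NULL)
      # swap u and a
      tr$parent[u] <- g
      tr$parent[a] <- p
      tr$children[[g]] <- c(setdiff(tr$children[[g]], a), u)
      tr$children[[p]] <- c(setdiff(tr$children[[p]], u), a)
      st$tree <- tr
      list(st = st, lhr = 0, lik = TRUE)
    })
  }
  ops
}

#' Metropolis-Hastings sampler for resub models
#'
#' Samples the posterior over the model indicator `Is`, boundary age `te`,
#' saltation fraction `nu`, tree (node heights and topology under the
#' conditioned birth-death prior), and optionally the clock rate,
#' frequencies, exchangeabilities, and gamma shape. Model averaging over
#' the four alphabet hypotheses uses a pseudo-prior construction: `te` and
#' `nu` remain in the state under `Is = 0`, where the likelihood ignores
#' them, so no reversible-jump dimension matching is needed.
#'
#' @param aln An [aa_alignment()].
#' @param basis Initial/fixed [substitution_basis()].
#' @param cherry Length-2 character vector, e.g. `c("W", "Y")`.
#' @param tree Initial [time_tree()] (fixed when
#'   `control$estimate_tree = FALSE`); `NULL` draws one from the
#'   birth-death prior using the alignment's taxa.
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()].
#' @param init Optional named list of initial values (`te`, `nu`, `Is`,
#'   `shape`, `clock_rate`).
#' @param seed Optional integer seed (fixed seed gives an identical trace).
#' @param chain_id Chain identifier recorded in the trace.
#' @return An object of class `"resub_mcmc"`: list with `trace` (a tibble),
#'   `acceptance` (per-operator counts), `final_state`, and the settings.
#' @export
resub_mcmc <- function(aln, basis, cherry, tree = NULL,
                       priors = prior_spec(), control = mcmc_control(),
                       init = list(), seed = NULL, chain_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) {
    tree <- simulate_bd_tree(priors$bd$lambda, priors$bd$r0, priors$bd$rho,
                             n = nrow(aln))
    tree$labels <- rownames(aln)
  }
  m <- length(basis$states)
  anchor_h <- anchor_height(tree, priors$anchor)
  st <- list(tree = tree, clock_rate = init$clock_rate %||% 1,
             pi = basis$pi, r = basis$r,
             shape = init$shape %||% 1,
             Is = init$Is %||% control$is_fixed %||%
               (which(priors$is_prior > 0)[1] - 1L),
             te_off = (init$te %||% rte_prior(1, anchor_h, priors$delta)) -
               anchor_h,
             nu = init$nu %||% stats::runif(1))
  if (!is.null(control$is_fixed)) st$Is <- as.integer(control$is_fixed)
  loglik <- if (control$likelihood) {
    make_loglik(aln, tree, as.character(basis$states), cherry, control$k,
                priors)
  } else {
    function(st) 0
  }
  ops <- mcmc_operators(priors, control, m)
  wts <- vapply(ops, function(o) o$weight, numeric(1))
  n_prop <- n_acc <- integer(length(ops))
  ll <- loglik(st)
  lp <- state_log_prior(st, priors, control)
  if (!is.finite(lp + ll)) stop("initial state has zero posterior density")
  n_rec <- floor(control$n_iter / control$thin)
  base_cols <- c("Sample", "posterior", "likelihood", "prior", "Is", "te",
                 "nu", "shape", "clock_rate", "root_height", "tree_length",
                 "anchor_height")
  extra <- character(0)
  if (control$trace_pi) extra <- c(extra, paste0("pi_", basis$states))
  if (control$trace_r) {
    idx <- which(upper.tri(st$r), arr.ind = TRUE)
    extra <- c(extra, paste0("r_", basis$states[idx[, 1]], "_",
                             basis$states[idx[, 2]]))
  }
  rec <- matrix(NA_real_, n_rec, length(base_cols) + length(extra),
                dimnames = list(NULL, c(base_cols, extra)))
  row <- 0L
  for (iter in seq_len(control$n_iter)) {
    oi <- sample.int(length(ops), 1L, prob = wts)
    n_prop[oi] <- n_prop[oi] + 1L
    prop <- ops[[oi]]$fn(st)
    if (!is.null(prop)) {
      lp2 <- state_log_prior(prop$st, priors, control)
      if (is.finite(lp2)) {
        ll2 <- if (prop$lik) loglik(prop$st) else ll
        if (log(stats::runif(1)) < (lp2 + ll2) - (lp + ll) + prop$lhr) {
          st <- prop$st
          lp <- lp2
          ll <- ll2
          n_acc[oi] <- n_acc[oi] + 1L
        }
      }
    }
    if (iter %% control$thin == 0L) {
      row <- row + 1L
      vals <- c(iter, lp + ll, ll, lp, st$Is, state_te(st, priors),
                st$nu, st$shape,
                st$clock_rate, root_height(st$tree), tree_length(st$tree),
                anchor_height(st$tree, priors$anchor))
      if (control$trace_pi) vals <- c(vals, st$pi)
      if (control$trace_r) vals <- c(vals, st$r[upper.tri(st$r)])
      rec[row, ] <- vals
    }
  }
  acc <- tibble::tibble(
    operator = vapply(ops, function(o) o$name, character(1)),
    proposed = n_prop, accepted = n_acc,
    rate = ifelse(n_prop > 0, n_acc / n_prop, NA_real_))
  probe <- acc$proposed > 50 & acc$accepted == 0
  if (any(probe)) {
    warning("operator(s) with zero acceptance: ",
            paste(acc$operator[probe], collapse = ", "),
            " - consider retuning")
  }
  trace <- tibble::as_tibble(rec[seq_len(row), , drop = FALSE])
  trace$chain <- chain_id
  structure(list(trace = trace, acceptance = acc, final_state = st,
                 priors = priors, control = control, cherry = cherry,
                 seed = seed),
            class = "resub_mcmc")
}

#' @export
print.resub_mcmc <- function(x, ...) {
  cat("<resub_mcmc>", nrow(x$trace), "recorded states; p(Is > 0) =",
      format(model_support(x)[["p_resub"]], digits = 3), "\n")
  invisible(x)
}

#' Run independent chains and combine them
#'
#' The convergence protocol runs two independent chains per configuration
#' and reports parameters with a combined effective sample size over 200.
#'
#' @inheritParams resub_mcmc
#' @param chains Number of independent chains.
#' @return A list of class `"resub_chains"` with elements `chains`,
#'   combined `trace`, and per-parameter combined `ess`.
#' @export
resub_mcmc_chains <- function(aln, basis, cherry, tree = NULL,
                              priors = prior_spec(),
                              control = mcmc_control(), init = list(),
                              seed = 1L, chains = 2L) {
  runs <- lapply(seq_len(chains), function(i) {
    resub_mcmc(aln, basis, cherry, tree, priors, control, init,
               seed = seed + (i - 1L) * 1000L, chain_id = i)
  })
  traces <- lapply(runs, function(r) burned_trace(r))
  combined <- dplyr::bind_rows(traces)
  pars <- c("te", "nu", "shape", "clock_rate", "root_height", "tree_length",
            "likelihood")
  ess <- vapply(pars, function(p) {
    sum(vapply(traces, function(tr) effective_sample_size(tr[[p]]),
               numeric(1)))
  }, numeric(1))
  structure(list(chains = runs, trace = combined, ess = ess),
            class = "resub_chains")
}

burned_trace <- function(x, burnin = NULL) {
  if (inherits(x, "resub_mcmc")) {
    burnin <- burnin %||% x$control$burnin
    tr <- x$trace
  } else if (inherits(x, "resub_chains")) {
    return(x$trace)
  } else {
    tr <- x
    burnin <- burnin %||% 0.1
  }
  if (nrow(tr) == 0) stop("empty trace")
  tr[tr$Sample > burnin * max(tr$Sample), , drop = FALSE]
}

#' Posterior support for the four alphabet hypotheses
#'
#' Post-burn-in empirical frequencies of the model indicator.
#'
#' @param x A `resub_mcmc` object, `resub_chains` object, or trace tibble
#'   with an `Is` column.
#' @param burnin Burn-in fraction (defaults to the run's setting).
#' @return Named numeric vector `p_Is0..p_Is3` plus `p_resub = p(Is > 0)`.
#' @export
model_support <- function(x, burnin = NULL) {
  tr <- burned_trace(x, burnin)
  if (nrow(tr) == 0) stop("no post-burn-in samples in trace")
  counts <- tabulate(tr$Is + 1L, 4L)
  p <- counts / sum(counts)
  c(p_Is0 = p[1], p_Is1 = p[2], p_Is2 = p[3], p_Is3 = p[4],
    p_resub = sum(p[-1]))
}

#' Classify resub support through a Bayes factor
#'
#' The Bayes factor is the posterior odds of `Is > 0` divided by the prior
#' odds. Support is called "resub" when BF exceeds 10, "no resub" when BF
#' is below 1/10, and "?" otherwise (strict inequalities; with equal prior
#' odds the 10 threshold corresponds to posterior support 10/11).
#'
#' @param p_resub Posterior probability of `Is > 0`.
#' @param prior_odds Prior odds of `Is > 0` versus `Is = 0` (1 when the
#'   two alternatives are equal a priori).
#' @return One of `"resub"`, `"no resub"`, `"?"`.
#' @export
classify_support <- function(p_resub, prior_odds = 1) {
  if (p_resub < 0 || p_resub > 1) stop("p_resub must lie in [0, 1]")
  post_odds <- if (p_resub == 1) Inf else p_resub / (1 - p_resub)
  bf <- post_odds / prior_odds
  if (bf > 10) "resub" else if (bf < 1 / 10) "no resub" else "?"
}

#' Effective sample size by initial monotone sequence autocorrelation
#'
#' Geyer-style estimator: the integrated autocorrelation time is built
#' from consecutive pairs of autocorrelations, truncated at the first
#' non-positive pair and forced monotone non-increasing; ESS = n / tau.
#' Chains are combined by summing their per-chain ESS.
#'
#' @param x Numeric series (length >= 10).
#' @return Effective sample size; 0 (with a warning) for a constant series.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("series too short for an ESS estimate (need >= 10)")
  if (stats::var(x) == 0) {
    warning("constant series: ESS is 0")
    return(0)
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  n_pair <- floor((lag_max + 1) / 2)
  gam <- numeric(n_pair)
  for (mm in seq_len(n_pair)) {
    gam[mm] <- rho[2 * mm - 1] + ifelse(2 * mm <= lag_max + 1, rho[2 * mm], 0)
  }
  keep <- which(gam <= 0)
  if (length(keep)) gam <- gam[seq_len(keep[1] - 1)]
  if (length(gam) == 0) return(n)
  gam <- cummin(gam)
  tau <- max(-1 + 2 * sum(gam), 1 / n)
  min(n, n / tau)
}

#' Write a BEAST-style tab-separated trace log
#'
#' @param x A `resub_mcmc` object.
#' @param path Output file.
#' @param header_comment Reproducibility block written as `#` comments
#'   (seed and settings are always recorded).
#' @export
write_trace <- function(x, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ", utils::packageName() %||% "resubr", " trace"),
    paste0("# seed: ", x$seed %||% "none"),
    paste0("# cherry: ", paste(x$cherry, collapse = "")),
    paste0("# n_iter: ", x$control$n_iter, " thin: ", x$control$thin),
    if (!is.null(header_comment)) paste0("# ", header_comment)), con)
  utils::write.table(x$trace, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
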