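#' BLOSUM62 utilities
#'
#' `read_blosum()` parses an NCBI-format substitution score matrix (the
#' packaged BLOSUM62 by default); `blosum_pair_scores()` looks up the score
#' of each amino acid pair; `blosum_cherry_score()` returns their mean —
#' the statistic used to compare the exchangeability profile of the aaRS
#' cherries against the "false" cross-class cherries.
#'
#' @param path Matrix file (NCBI text layout, `#` comments allowed).
#' @return `read_blosum()`: an integer matrix with residue dimnames.
#' @export
read_blosum <- function(path = system.file("extdata", "BLOSUM62.txt",
                                           package = "resubr")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  mat <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  rownames(mat) <- vapply(rows, `[`, character(1), 1)
  colnames(mat) <- header
  mat
}

#' @rdname read_blosum
#' @param pairs Character vector of two-letter pairs (e.g. `c("WY", "IV")`).
#' @param matrix Score matrix from [read_blosum()].
#' @return `blosum_pair_scores()`: a tibble with `pair` and `score`.
#' @export
blosum_pair_scores <- function(pairs, matrix = read_blosum()) {
  if (length(pairs) == 0) stop("no pairs given")
  pairs <- toupper(as.character(pairs))
  if (any(nchar(pairs) != 2)) {
    stop("pairs must be two-letter codes, got: ",
         paste(pairs[nchar(pairs) != 2], collapse = ", "))
  }
  a <- substr(pairs, 1, 1)
  b <- substr(pairs, 2, 2)
  unknown <- setdiff(unique(c(a, b)), rownames(matrix))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  tibble::tibble(pair = pairs, score = matrix[cbind(a, b)])
}

#' @rdname read_blosum
#' @return `blosum_cherry_score()`: the mean pairwise score (a scalar).
#' @export
blosum_cherry_score <- function(pairs, matrix = read_blosum()) {
  mean(blosum_pair_scores(pairs, matrix)$score)
}

#' The nine aaRS cherries and the five false cherries
#'
#' Amino acid pairs whose aminoacyl-tRNA synthetases form cherries on the
#' Class I and II family trees (`aars_cherries()`), and cross-class control
#' pairs that do not (`false_cherries()`).
#' @return Character vector of two-letter pairs.
#' @export
aars_cherries <- function() {
  c("WY", "IV", "EQ", "AG", "SG", "PT", "FH", "DN", "DK")
}

#' @rdname aars_cherries
#' @export
false_cherries <- function() {
  c("LS", "CF", "NQ", "DE", "FY")
}

new_experiment_report <- function(kind, results, summary, seed, settings) {
  structure(list(kind = kind, results = results, summary = summary,
                 seed = seed, settings = settings),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", x$kind, "-", nrow(x$results),
      "replicates (seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) x$results

#' @export
glance.experiment_report <- function(x, ...) x$summary

#' Coverage simulation study
#'
#' The well-calibrated-Bayes check: draw the truth from the prior, simulate
#' an alignment, run MCMC under the same priors, and ask how often each
#' parameter's 95% credible interval contains the truth — approximately
#' 95% of replicates when the model and sampler are correct. Replicates
#' whose chain fails the ESS floor are flagged, excluded from the coverage
#' summary, and counted.
#'
#' @param n_reps Number of replicates (>= 10).
#' @param n_taxa,L Tree and alignment size per replicate.
#' @param basis Substitution basis (frequencies/exchangeabilities fixed at
#'   these values in both simulation and inference).
#' @param cherry Cherry state pair.
#' @param priors A [prior_spec()].
#' @param control An [mcmc_control()] for the per-replicate chains.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @param draw Parameters drawn fresh from the prior in each replicate and
#'   passed to inference as known (see [sample_from_prior()]).
#' @param anchor_frac Depth fraction of the root height at which the
#'   boundary prior is anchored (the nearest internal node's age; `NULL`
#'   keeps the anchor already in `priors`).
#' @param ess_floor Minimum ESS (on `te` and `tree_length`) for a
#'   replicate to enter the summary.
#' @return An `experiment_report` with per-replicate records and a
#'   per-parameter coverage summary (with binomial 95% intervals).
#' @export
coverage_experiment <- function(n_reps = 20L, n_taxa = 10L, L = 100L,
                                basis, cherry = c("W", "Y"),
                                priors = prior_spec(),
                                control = mcmc_control(n_iter = 6000L,
                                                       thin = 5L),
                                seed = 1L, draw = c("pi", "r", "shape"),
                                anchor_frac = 0.65, ess_floor = 30) {
  if (n_reps < 10) stop("coverage needs at least 10 replicates")
  if (!is.null(anchor_frac)) {
    priors$anchor <- list(type = "depth_frac", frac = anchor_frac)
  }
  pars <- c("te", "nu", "root_height", "tree_length")
  results <- purrr::map_dfr(seq_len(n_reps), function(rep) {
    set.seed(seed + rep)
    truth <- sample_from_prior(priors, n_taxa, L, basis, cherry,
                               draw = draw, k = control$k)
    run <- resub_mcmc(truth$aln, truth$basis, cherry, tree = truth$tree,
                      priors = priors, control = control,
                      init = list(shape = truth$params$shape,
                                  clock_rate = truth$params$clock_rate),
                      seed = seed + rep)
    tr <- burned_trace(run)
    truth_vals <- c(te = truth$params$te, nu = truth$params$nu,
                    root_height = truth$params$root_height,
                    tree_length = truth$params$tree_length)
    ess_ok <- effective_sample_size(tr$te) >= ess_floor &&
      effective_sample_size(tr$tree_length) >= ess_floor
    purrr::map_dfr(pars, function(p) {
      ci <- stats::quantile(tr[[p]], c(0.025, 0.975), names = FALSE)
      tibble::tibble(replicate = rep, parameter = p,
                     truth = truth_vals[[p]],
                     estimate = mean(tr[[p]]),
                     lower = ci[1], upper = ci[2],
                     covered = truth_vals[[p]] >= ci[1] &
                       truth_vals[[p]] <= ci[2],
                     ess_ok = ess_ok, seed = seed + rep)
    })
  })
  ok <- results[results$ess_ok, , drop = FALSE]
  summary <- ok |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(n = dplyr::n(),
                     coverage_pct = 100 * mean(.data$covered),
                     covered = sum(.data$covered)) |>
    dplyr::mutate(
      lower_pct = 100 * stats::qbeta(0.025, .data$covered + 0.5,
                                     .data$n - .data$covered + 0.5),
      upper_pct = 100 * stats::qbeta(0.975, .data$covered + 0.5,
                                     .data$n - .data$covered + 0.5),
      excluded = n_reps - .data$n)
  new_experiment_report("coverage", results, summary, seed,
                        list(n_reps = n_reps, n_taxa = n_taxa, L = L,
                             ess_floor = ess_floor))
}

#' Model-recovery simulation study
#'
#' Simulates data under the null and under resub (50/50), infers the model
#' indicator by MCMC, and classifies each replicate with the Bayes factor
#' 10 rule into "no resub", "?", or "resub". Correct calls should dominate
#' and confident wrong calls should be rare, increasingly so with more
#' sites.
#'
#' @inheritParams coverage_experiment
#' @param n_reps_per_model Replicates for each truth (null and resub).
#' @param anchor_frac Depth fraction (of the root height) at which the
#'   boundary's anchor node is chosen; the boundary prior is centred on
#'   that clade's MRCA age, placing the old epoch well inside the tree.
#' @return An `experiment_report`; `results` holds one row per replicate
#'   with `p_resub` and the call, `summary` the confusion counts.
#' @export
model_recovery_experiment <- function(n_taxa = 20L, L = 50L,
                                      n_reps_per_model = 10L,
                                      basis, cherry = c("W", "Y"),
                                      priors = prior_spec(),
                                      control = mcmc_control(n_iter = 6000L,
                                                             thin = 5L),
                                      seed = 1L, anchor_frac = 0.65) {
  prior_odds <- sum(priors$is_prior[-1]) / priors$is_prior[1]
  grid <- tibble::tibble(
    rep = seq_len(2L * n_reps_per_model),
    truth_resub = rep(c(FALSE, TRUE), each = n_reps_per_model))
  results <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    set.seed(seed + 97L * i)
    tree <- simulate_bd_tree(priors$bd$lambda, priors$bd$r0, priors$bd$rho,
                             n = n_taxa)
    pri <- priors
    pri$anchor <- list(type = "depth_frac", frac = anchor_frac)
    is_true <- if (grid$truth_resub[i]) sample(1:3, 1) else 0L
    te_true <- rte_prior(1, anchor_height(tree, pri$anchor), pri$delta)
    cfg <- resub_config(cherry[1], cherry[2], Is = is_true,
                        te = te_true, nu = stats::runif(1))
    aln <- simulate_alignment(tree, basis, cfg,
                              discrete_gamma_rates(1, control$k),
                              clock_model(1), L)
    run <- resub_mcmc(aln, basis, cherry, tree = tree,
                      priors = pri, control = control,
                      seed = seed + 97L * i)
    p <- model_support(run)[["p_resub"]]
    tibble::tibble(replicate = i, truth_resub = grid$truth_resub[i],
                   Is_true = is_true, te_true = te_true, p_resub = p,
                   call = classify_support(p, prior_odds),
                   seed = seed + 97L * i)
  })
  summary <- results |>
    dplyr::count(.data$truth_resub, .data$call) |>
    tidyr::pivot_wider(names_from = "call", values_from = "n",
                       values_fill = 0L)
  new_experiment_report("model_recovery", results, summary, seed,
                        list(n_taxa = n_taxa, L = L,
                             n_reps_per_model = n_reps_per_model))
}

# the internal, non-root node whose height is closest to frac * root
# height (the root itself for two-taxon trees)
node_near_depth <- function(tree, frac) {
  internal <- setdiff((tree$ntip + 1L):length(tree$parent), tree$root)
  if (length(internal) == 0) return(tree$root)
  target <- frac * root_height(tree)
  internal[which.min(abs(tree$heights[internal] - target))]
}

clade_taxa <- function(tree, node) {
  if (node <= tree$ntip) return(tree$labels[node])
  unlist(lapply(tree$children[[node]], clade_taxa, tree = tree))
}

#' Divergence-age bias under the fixed-alphabet assumption
#'
#' Simulates alignments under resub (old epoch, saltation burst, reduced
#' alphabet), calibrates a subset of internal nodes at their true ages
#' while leaving the root free, and compares root-height and old-epoch
#' duration estimates under (a) the fixed-alphabet null (`Is` fixed at 0)
#' and (b) the resub model (`Is` averaged over). Under the null the extra
#' substitutions injected by the alphabet transition must be absorbed by
#' longer branches, so the epoch duration `th - te` and tree height `th`
#' are overestimated; resub corrects this.
#'
#' @inheritParams coverage_experiment
#' @param n_calibrations Number of calibrated internal nodes.
#' @param calibration_cv Relative standard deviation of each lognormal
#'   calibration.
#' @param anchor_frac Depth fraction at which the boundary anchor node is
#'   chosen.
#' @return An `experiment_report`; `summary` holds the mean relative bias
#'   (%) of `th` and `th - te` per condition.
#' @export
age_bias_experiment <- function(n_reps = 8L, n_taxa = 20L, L = 100L,
                                basis, cherry = c("W", "Y"),
                                priors = prior_spec(),
                                control = mcmc_control(n_iter = 8000L,
                                                       thin = 5L,
                                                       estimate_topology = FALSE),
                                seed = 1L, n_calibrations = 3L,
                                calibration_cv = 0.02, anchor_frac = 0.65) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  results <- purrr::map_dfr(seq_len(n_reps), function(rep) {
    set.seed(seed + 131L * rep)
    tree <- simulate_bd_tree(priors$bd$lambda, priors$bd$r0, priors$bd$rho,
                             n = n_taxa)
    anchor <- list(type = "depth_frac", frac = anchor_frac)
    th_true <- root_height(tree)
    te_true <- rte_prior(1, anchor_height(tree, anchor), priors$delta)
    nu_true <- stats::runif(1)
    is_true <- sample(1:3, 1)
    cfg <- resub_config(cherry[1], cherry[2], Is = is_true, te = te_true,
                        nu = nu_true)
    aln <- simulate_alignment(tree, basis, cfg,
                              discrete_gamma_rates(1, control$k),
                              clock_model(1), L)
    # calibrate interior nodes at their true ages; the root stays free and
    # every calibration sits clearly below the epoch boundary, so the
    # boundary's saltation lands root-ward of all age constraints (as in
    # deep-calibration dating, where the calibrated ancestors are younger
    # than the alphabet transition)
    internal <- setdiff((tree$ntip + 1L):length(tree$parent), tree$root)
    eligible <- internal[tree$heights[internal] <=
                           0.5 * anchor_height(tree, anchor)]
    if (length(eligible) < n_calibrations) {
      eligible <- internal[order(tree$heights[internal])][
        seq_len(min(length(internal), n_calibrations))]
    }
    cal_nodes <- eligible[order(tree$heights[eligible])]
    cal_nodes <- cal_nodes[unique(round(seq(1, length(cal_nodes),
                                            length.out = n_calibrations)))]
    cals <- lapply(cal_nodes, function(nd) {
      list(name = paste0("node", nd), taxa = clade_taxa(tree, nd),
           M = tree$heights[nd], S = calibration_cv * tree$heights[nd])
    })
    pri <- priors
    pri$anchor <- anchor
    pri$calibrations <- cals
    run_one <- function(is_fixed) {
      ctl <- control
      ctl$is_fixed <- is_fixed
      run <- resub_mcmc(aln, basis, cherry, tree = tree, priors = pri,
                        control = ctl, init = list(te = te_true),
                        seed = seed + 131L * rep)
      tr <- burned_trace(run)
      tibble::tibble(th_hat = mean(tr$root_height),
                     dur_hat = mean(tr$root_height - tr$te))
    }
    null_fit <- run_one(0L)
    resub_fit <- run_one(NULL)
    dur_true <- th_true - te_true
    tibble::tibble(
      replicate = rep, Is_true = is_true, te_true = te_true,
      nu_true = nu_true, th_true = th_true, dur_true = dur_true,
      condition = c("null", "resub"),
      th_hat = c(null_fit$th_hat, resub_fit$th_hat),
      dur_hat = c(null_fit$dur_hat, resub_fit$dur_hat),
      th_bias_pct = 100 * (c(null_fit$th_hat, resub_fit$th_hat) - th_true) /
        th_true,
      dur_bias_pct = 100 * (c(null_fit$dur_hat, resub_fit$dur_hat) -
                              dur_true) / dur_true,
      seed = seed + 131L * rep)
  })
  summary <- results |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(),
                     th_bias_pct = mean(.data$th_bias_pct),
                     dur_bias_pct = mean(.data$dur_bias_pct))
  new_experiment_report("age_bias", results, summary, seed,
                        list(n_reps = n_reps, n_taxa = n_taxa, L = L,
                             n_calibrations = n_calibrations))
}

#' Coverage / bias report plot
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot: truth-vs-estimate panels (coverage), stacked call
#'   counts (model recovery), or bias distributions (age bias).
#' @export
autoplot.experiment_report <- function(object, ...) {
  res <- object$results
  if (object$kind == "coverage") {
    ggplot2::ggplot(res, ggplot2::aes(.data$truth, .data$estimate)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             alpha = 0.4, width = 0) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$covered)) +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::theme_minimal()
  } else if (object$kind == "model_recovery") {
    ggplot2::ggplot(res, ggplot2::aes(.data$truth_resub, fill = .data$call)) +
      ggplot2::geom_bar(position = "stack") +
      ggplot2::labs(x = "simulated under resub", y = "replicates") +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(res, c("th_bias_pct", "dur_bias_pct"),
                                names_to = "quantity",
                                values_to = "bias_pct")
    ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$bias_pct)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~quantity, scales = "free_y") +
      ggplot2::theme_minimal()
  }
}
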