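#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a resub MCMC run
#'
#' One row per traced continuous parameter with the posterior mean, median,
#' standard deviation, central 95% credible interval, and effective sample
#' size, computed after burn-in.
#'
#' @param x A `resub_mcmc` or `resub_chains` object.
#' @param burnin Burn-in fraction override.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `median`, `sd`,
#'   `conf.low`, `conf.high`, `ess`.
#' @export
tidy.resub_mcmc <- function(x, burnin = NULL, ...) {
  tr <- burned_trace(x, burnin)
  pars <- intersect(c("te", "nu", "shape", "clock_rate", "root_height",
                      "tree_length", "likelihood", "posterior"),
                    names(tr))
  purrr::map_dfr(pars, function(p) {
    v <- tr[[p]]
    tibble::tibble(
      term = p, estimate = mean(v), median = stats::median(v),
      sd = stats::sd(v),
      conf.low = stats::quantile(v, 0.025, names = FALSE),
      conf.high = stats::quantile(v, 0.975, names = FALSE),
      ess = effective_sample_size(v))
  })
}

#' @rdname tidy.resub_mcmc
#' @export
tidy.resub_chains <- function(x, burnin = NULL, ...) {
  pooled <- structure(list(trace = x$trace,
                           control = x$chains[[1]]$control),
                      class = "resub_mcmc")
  out <- tidy.resub_mcmc(pooled, burnin = 0, ...)
  out$ess <- unname(x$ess[out$term])
  out
}

#' One-row summary of a resub MCMC run
#'
#' @param x A `resub_mcmc` object.
#' @param ... Unused.
#' @return A tibble with the hypothesis supports, the Bayes-factor call,
#'   mean acceptance rate, and sample counts.
#' @export
glance.resub_mcmc <- function(x, ...) {
  s <- model_support(x)
  prior_odds <- sum(x$priors$is_prior[-1]) / x$priors$is_prior[1]
  tibble::tibble(
    n_samples = nrow(x$trace),
    p_Is0 = s[["p_Is0"]], p_Is1 = s[["p_Is1"]],
    p_Is2 = s[["p_Is2"]], p_Is3 = s[["p_Is3"]],
    p_resub = s[["p_resub"]],
    call = classify_support(s[["p_resub"]], prior_odds),
    mean_accept = stats::weighted.mean(x$acceptance$rate,
                                       x$acceptance$proposed, na.rm = TRUE))
}

#' Trace plots for a resub MCMC run
#'
#' @param object A `resub_mcmc` object.
#' @param pars Parameters to display.
#' @param ... Unused.
#' @return A ggplot of faceted parameter traces.
#' @export
autoplot.resub_mcmc <- function(object, pars = c("posterior", "te", "nu",
                                                 "root_height"), ...) {
  tr <- object$trace
  long <- tidyr::pivot_longer(tr[, c("Sample", intersect(pars, names(tr)))],
                              -"Sample", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$Sample, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
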