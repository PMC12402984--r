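#' Molecular clock models
#'
#' A strict clock applies one rate (substitutions/site/time-unit) to every
#' branch; the uncorrelated lognormal relaxed clock multiplies it by
#' per-branch multipliers (stored on the [time_tree()]) drawn from a
#' mean-one lognormal with standard deviation `sdlog` on the log scale.
#'
#' @param rate Mean clock rate, > 0.
#' @param mode `"strict"` or `"lognormal"`.
#' @param sdlog Log-scale standard deviation of branch multipliers
#'   (lognormal mode).
#' @return A list of class `"clock_model"`.
#' @export
clock_model <- function(rate = 1, mode = c("strict", "lognormal"),
                        sdlog = 0.5) {
  mode <- match.arg(mode)
  if (rate <= 0) stop("clock rate must be positive")
  structure(list(rate = rate, mode = mode, sdlog = sdlog),
            class = "clock_model")
}

#' Draw relaxed-clock branch-rate multipliers onto a tree
#'
#' Under the uncorrelated lognormal relaxed clock each branch's rate is
#' the clock's mean rate times an iid lognormal multiplier with mean 1
#' (log-scale mean `-sdlog^2 / 2`). A strict clock leaves all multipliers
#' at 1.
#'
#' @param tree A [time_tree()].
#' @param clock A [clock_model()].
#' @return The tree with its `rate_mult` field filled in.
#' @export
draw_branch_rates <- function(tree, clock) {
  if (clock$mode == "lognormal") {
    n <- length(tree$parent)
    tree$rate_mult <- stats::rlnorm(n, -clock$sdlog^2 / 2, clock$sdlog)
  } else {
    tree$rate_mult <- rep(1, length(tree$parent))
  }
  tree
}

# Assemble the C++ pruning inputs shared by likelihood calls.
pruning_inputs <- function(tree, basis, config) {
  Qn <- normalize_rate_matrix(build_rate_matrix(basis))
  eig <- rate_matrix_eigen(Qn)
  m <- length(basis$states)
  if (config$Is > 0L) {
    red <- reduce_alphabet(basis, config)
    Qr <- normalize_rate_matrix(build_rate_matrix(red$basis))
    eigr <- rate_matrix_eigen(Qr)
    Xi <- saltation_matrix(basis, config)
    rf_red <- as.numeric(red$basis$pi)
  } else {
    eigr <- list(values = 0, U = matrix(1, 1, 1), Ui = matrix(1, 1, 1))
    Xi <- matrix(1, 1, 1)
    rf_red <- 1
  }
  list(eig = eig, eigr = eigr, Xi = Xi,
       rf_full = as.numeric(basis$pi), rf_red = rf_red)
}

#' Epoch-aware tree log-likelihood
#'
#' Computes `log p(D | T, theta)` by Felsenstein pruning on a dated tree
#' under a resub model: branches wholly inside the young epoch use the
#' full-alphabet transition matrix, branches wholly inside the old epoch
#' the reduced one, and boundary-crossing branches the rectangular
#' epoch-spanning matrix. Partial likelihoods above the boundary live in
#' the reduced state space and the root (or origin) vector is dotted with
#' [root_frequencies()]. Site-rate categories are averaged with equal
#' weights and sites are summed in log space over compressed patterns.
#'
#' @param tree A [time_tree()] whose tip labels match the alignment taxa.
#' @param aln An [aa_alignment()].
#' @param basis The young-epoch [substitution_basis()].
#' @param config A [resub_config()].
#' @param site_model A [discrete_gamma_rates()] model (default: one
#'   category, rate 1).
#' @param clock A [clock_model()].
#' @param per_site Also return per-pattern site log-likelihoods?
#' @return The log-likelihood (a scalar). With `per_site = TRUE`, a list
#'   with `loglik`, `site_log` (per unique pattern), `weights`, and
#'   `patterns`.
#' @export
tree_log_likelihood <- function(tree, aln, basis, config,
                                site_model = discrete_gamma_rates(1, 1),
                                clock = clock_model(), per_site = FALSE) {
  if (!setequal(rownames(aln), tree$labels)) {
    missing <- setdiff(tree$labels, rownames(aln))
    extra <- setdiff(rownames(aln), tree$labels)
    stop("taxa mismatch between tree and alignment",
         if (length(missing)) paste0("; missing from alignment: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; absent from tree: ",
                                   paste(extra, collapse = ", ")))
  }
  if (!identical(as.character(attr(aln, "states")),
                 as.character(basis$states))) {
    stop("alignment alphabet does not match the substitution basis")
  }
  aln <- aln[tree$labels, , drop = FALSE]
  pc <- pattern_compress(aln)
  cube <- leaf_partials(pc$patterns, basis$states)
  pin <- pruning_inputs(tree, basis, config)
  res <- epoch_pruning_cpp(
    children = tree$children, heights = tree$heights,
    order = postorder_internal(tree), root = tree$root,
    has_origin = !is.na(tree$origin_height),
    origin_height = if (is.na(tree$origin_height)) -1 else tree$origin_height,
    branch_rate = clock$rate * tree$rate_mult,
    te = config$te, is0 = config$Is == 0L,
    U = pin$eig$U, Ui = pin$eig$Ui, ev = pin$eig$values,
    Ur = pin$eigr$U, Uir = pin$eigr$Ui, evr = pin$eigr$values,
    Xi = pin$Xi, rf_full = pin$rf_full, rf_red = pin$rf_red,
    leaf_part = cube, cat_rates = site_model$rates, weights = pc$weights)
  if (per_site) {
    list(loglik = res$loglik, site_log = as.numeric(res$site_log),
         weights = pc$weights, patterns = pc$patterns)
  } else {
    res$loglik
  }
}
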