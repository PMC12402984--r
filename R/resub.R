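#' Configure a refinement-expansion (resub) model
#'
#' A resub configuration names the cherry of amino acids `(alpha, beta)`,
#' the model indicator `Is`, the epoch boundary age `te`, and the saltation
#' fraction `nu`. The four hypotheses are:
#'
#' * `Is = 0`: null; both epochs share the full alphabet.
#' * `Is = 1`: refinement; `alpha` and `beta` were merged into one
#'   low-specificity state `alpha/beta` in the old epoch.
#' * `Is = 2`: expansion; `beta` was absent from the old alphabet.
#' * `Is = 3`: expansion with the roles transposed; `alpha` was absent.
#'
#' The discarded index `gamma0` and retained index `gamma1` follow from
#' `Is`: refinement and `Is = 2` discard `beta`; `Is = 3` discards `alpha`.
#'
#' @param alpha,beta State labels of the cherry (e.g. `"W"`, `"Y"`).
#' @param Is Integer model indicator in `0:3`.
#' @param te Epoch boundary age (time units, >= 0). The young epoch is
#'   `[0, te]`, the old epoch `(te, root age]`.
#' @param nu Saltation fraction in `[0, 1]`: the proportion of retained-state
#'   characters that jump to the newly coded state at the boundary.
#' @return A list of class `"resub_config"`.
#' @examples
#' resub_config("W", "Y", Is = 3, te = 0.5, nu = 0.25)
#' @export
resub_config <- function(alpha, beta, Is = 0L, te = 0, nu = 0) {
  if (identical(alpha, beta)) {
    stop("cherry states alpha and beta must differ")
  }
  Is <- as.integer(Is)
  if (!Is %in% 0:3) stop("Is must be one of 0, 1, 2, 3")
  if (te < 0) stop("boundary age te must be >= 0")
  if (nu < 0 || nu > 1) stop("saltation fraction nu must lie in [0, 1]")
  g <- switch(Is + 1L,
              list(gamma0 = NA_character_, gamma1 = NA_character_),
              list(gamma0 = beta,  gamma1 = alpha),   # refinement: merge
              list(gamma0 = beta,  gamma1 = alpha),   # expansion: beta new
              list(gamma0 = alpha, gamma1 = beta))    # expansion: alpha new
  structure(list(alpha = alpha, beta = beta, Is = Is,
                 gamma0 = g$gamma0, gamma1 = g$gamma1, te = te, nu = nu),
            class = "resub_config")
}

#' @export
print.resub_config <- function(x, ...) {
  lab <- c("null (shared alphabet)", "refinement (merge)",
           "expansion (beta new)", "expansion (alpha new)")[x$Is + 1]
  cat("<resub_config>", x$alpha, "/", x$beta, " Is =", x$Is,
      paste0("[", lab, "]"), " te =", format(x$te), " nu =", format(x$nu), "\n")
  invisible(x)
}

#' Reduce a substitution basis to the old-epoch alphabet
#'
#' Builds the (m-1)-state basis of the old epoch under the hypothesis held
#' by `config`. Refinement merges the cherry into a single state at
#' equilibrium between its sub-states (frequency the sum, exchangeabilities
#' the frequency-weighted average of the merged rows); expansion deletes the
#' discarded state's row and column and renormalizes the remaining
#' frequencies. `Is = 0` returns the basis unchanged.
#'
#' @param basis A [substitution_basis()] for the young (full) epoch.
#' @param config A [resub_config()].
#' @return A list of class `"reduced_basis"`: `basis` (the reduced
#'   [substitution_basis()]), `merged_label` (e.g. `"W/Y"`, refinement only),
#'   and `index_map` (integer vector mapping reduced indices to full ones).
#' @export
reduce_alphabet <- function(basis, config) {
  stopifnot(inherits(basis, "sub_basis"), inherits(config, "resub_config"))
  states <- as.character(basis$states)
  if (config$Is > 0L && !all(c(config$alpha, config$beta) %in% states)) {
    stop("cherry (", config$alpha, ", ", config$beta,
         ") not found in the alphabet")
  }
  if (config$Is == 0L) {
    return(structure(list(basis = basis, merged_label = NULL,
                          index_map = seq_along(states)),
                     class = "reduced_basis"))
  }
  i0 <- match(config$gamma0, states)
  i1 <- match(config$gamma1, states)
  keep <- setdiff(seq_along(states), i0)
  r <- basis$r
  pi <- basis$pi
  merged_label <- NULL
  if (config$Is == 1L) {
    # Merge gamma0 into gamma1; the merged state sits in gamma1's slot.
    pim <- pi[i1] + pi[i0]
    others <- setdiff(seq_along(states), c(i0, i1))
    rm <- (r[i1, others] * pi[i1] + r[i0, others] * pi[i0]) / pim
    r[i1, others] <- rm
    r[others, i1] <- rm
    pi[i1] <- pim
    merged_label <- paste0(config$alpha, "/", config$beta)
    rp <- r[keep, keep, drop = FALSE]
    pp <- pi[keep]
    labels <- states[keep]
    labels[match(i1, keep)] <- merged_label
  } else {
    rp <- r[keep, keep, drop = FALSE]
    pp <- pi[keep] / (1 - pi[i0])
    labels <- states[keep]
  }
  pp <- pp / sum(pp)
  dimnames(rp) <- list(labels, labels)
  names(pp) <- labels
  structure(list(basis = substitution_basis(rp, pp, labels),
                 merged_label = merged_label, index_map = keep),
            class = "reduced_basis")
}

#' Saltation matrix for the epoch boundary
#'
#' The (m-1) x m row-stochastic matrix Xi that transfers probability into
#' the newly coded state the instant a lineage crosses from the old epoch
#' into the young one. In every row except the retained cherry state's, a
#' mass equal to the new state's equilibrium frequency `pi[gamma0]` (and,
#' under refinement, also `pi[gamma1]`) leaks into the new (and retained)
#' state; the retained state's row sends fraction `nu` to the new state and
#' keeps `1 - nu`.
#'
#' Rows are indexed by the old (reduced) alphabet and columns by the young
#' (full) one.
#'
#' @inheritParams reduce_alphabet
#' @return An (m-1) x m matrix with rows summing to 1.
#' @export
saltation_matrix <- function(basis, config) {
  stopifnot(inherits(basis, "sub_basis"), inherits(config, "resub_config"))
  if (config$Is == 0L) {
    stop("saltation is undefined under the null model (Is = 0)")
  }
  states <- as.character(basis$states)
  pi <- basis$pi
  i0 <- match(config$gamma0, states)
  i1 <- match(config$gamma1, states)
  red <- reduce_alphabet(basis, config)
  keep <- red$index_map
  mr <- length(keep)
  Xi <- matrix(0, mr, length(states),
               dimnames = list(as.character(red$basis$states), states))
  for (k in seq_len(mr)) {
    fi <- keep[k]
    if (fi == i1) {
      Xi[k, i0] <- config$nu
      Xi[k, i1] <- 1 - config$nu
    } else if (config$Is == 1L) {
      Xi[k, i0] <- pi[i0]
      Xi[k, i1] <- pi[i1]
      Xi[k, fi] <- Xi[k, fi] + 1 - pi[i0] - pi[i1]
    } else {
      Xi[k, i0] <- pi[i0]
      Xi[k, fi] <- Xi[k, fi] + 1 - pi[i0]
    }
  }
  Xi
}

#' Transition probabilities across the epoch boundary
#'
#' For a lineage spending genetic distance `tau2` in the old epoch and
#' `tau1` in the young epoch, the transition matrix is the product
#' `P'(tau2) %*% Xi %*% P(tau1)`: old-epoch substitution in the reduced
#' alphabet, the instantaneous saltation, then young-epoch substitution in
#' the full alphabet. Each epoch factor is normalized with its own
#' equilibrium frequencies. Rows are indexed by the old (reduced) alphabet,
#' columns by the young (full) one.
#'
#' Under the null (`Is = 0`) the two epochs share one process and the
#' result collapses to `P(tau1 + tau2)`.
#'
#' @inheritParams reduce_alphabet
#' @param tau2 Genetic distance accrued in the old epoch (>= 0).
#' @param tau1 Genetic distance accrued in the young epoch (>= 0).
#' @return A row-stochastic matrix, (m-1) x m when `Is > 0`, m x m under
#'   the null.
#' @export
epoch_transition_matrix <- function(basis, config, tau2, tau1) {
  if (tau1 < 0 || tau2 < 0) stop("epoch distances must be >= 0")
  Qn <- normalize_rate_matrix(build_rate_matrix(basis))
  if (config$Is == 0L) {
    return(transition_matrix(Qn, tau1 + tau2))
  }
  red <- reduce_alphabet(basis, config)
  Qr <- normalize_rate_matrix(build_rate_matrix(red$basis))
  P2 <- transition_matrix(Qr, tau2)
  P1 <- transition_matrix(Qn, tau1)
  Xi <- saltation_matrix(basis, config)
  P <- P2 %*% Xi %*% P1
  dimnames(P) <- dimnames(Xi)
  P
}

#' Root frequencies under a resub model
#'
#' When the resub model is active (`Is > 0`) and the root (or origin) is
#' older than the boundary `te`, the stationary frequencies of the reduced
#' old-epoch alphabet apply at the root; otherwise the full-alphabet
#' frequencies do.
#'
#' @inheritParams reduce_alphabet
#' @param root_age Age of the point where the root frequency vector is
#'   applied (the origin height when one is present, else the root height).
#' @return A named frequency vector over the applicable alphabet.
#' @export
root_frequencies <- function(basis, config, root_age) {
  if (config$Is > 0L && root_age > config$te) {
    reduce_alphabet(basis, config)$basis$pi
  } else {
    basis$pi
  }
}
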