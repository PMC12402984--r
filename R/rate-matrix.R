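#' Build the instantaneous rate matrix Q = r diag(pi)
#'
#' Off-diagonal entries are `Q[i, j] = r[i, j] * pi[j]`; each diagonal entry
#' is set so that its row sums to zero. The result is not yet normalized to
#' one expected substitution per unit time; see [normalize_rate_matrix()].
#'
#' @param basis A [substitution_basis()].
#' @return An m x m matrix of class `"rate_matrix"` with attribute
#'   `normalized = FALSE` and the basis frequencies attached as `"pi"`.
#' @export
build_rate_matrix <- function(basis) {
  stopifnot(inherits(basis, "sub_basis"))
  Q <- basis$r %*% diag(basis$pi)
  dimnames(Q) <- dimnames(basis$r)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(Q, class = c("rate_matrix", "matrix"),
            pi = basis$pi, normalized = FALSE)
}

#' Normalize a rate matrix to one expected substitution per unit time
#'
#' Divides Q by the mean outgoing rate `-sum(pi * diag(Q))`, so that genetic
#' distance is measured in expected substitutions per site.
#'
#' @param Q A rate matrix whose rows sum to zero.
#' @param pi Equilibrium frequencies; defaults to the frequencies attached to
#'   `Q` by [build_rate_matrix()].
#' @return The normalized matrix, class `"rate_matrix"`, `normalized = TRUE`.
#' @export
normalize_rate_matrix <- function(Q, pi = attr(Q, "pi")) {
  if (is.null(pi)) stop("pi must be supplied when Q carries no frequencies")
  if (max(abs(rowSums(Q))) > 1e-8) {
    stop("rows of Q must sum to zero before normalization")
  }
  mu <- -sum(pi * diag(Q))
  if (!is.finite(mu) || mu <= 0) {
    stop("degenerate model: mean outgoing rate is ", format(mu),
         "; cannot normalize an all-zero rate matrix")
  }
  structure(Q / mu, class = c("rate_matrix", "matrix"),
            pi = pi, normalized = TRUE)
}

# Spectral decomposition of a reversible rate matrix. With S the symmetric
# similarity transform diag(sqrt(pi)) Q diag(1/sqrt(pi)), exp(Q tau) =
# D^{-1/2} V exp(L tau) V' D^{1/2}; numerically stable for any tau >= 0.
rate_matrix_eigen <- function(Q, pi = attr(Q, "pi")) {
  d <- sqrt(pi)
  S <- Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(values = es$values,
       U = es$vectors / d,        # D^{-1/2} V
       Ui = t(es$vectors) * rep(d, each = length(d)))  # V' D^{1/2}
}

expm_eigen <- function(eig, tau) {
  P <- eig$U %*% (exp(eig$values * tau) * eig$Ui)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix P(tau) = exp(Q tau)
#'
#' Exponentiates a (normalized) rate matrix over a genetic distance `tau`
#' in expected substitutions per site. Reversible matrices are exponentiated
#' through the spectral decomposition of their symmetrized form; tiny
#' negative round-off entries are clamped at zero and rows renormalized.
#'
#' @param Qn A rate matrix, usually normalized (see
#'   [normalize_rate_matrix()]; callers may deliberately pass an
#'   unnormalized matrix, e.g. in tests).
#' @param tau Non-negative genetic distance (substitutions per site).
#' @param pi Frequencies for the reversible decomposition; defaults to those
#'   attached to `Qn`. When `NULL`, a dense Pade exponential
#'   ([Matrix::expm()]) is used instead.
#' @return An m x m row-stochastic matrix.
#' @export
transition_matrix <- function(Qn, tau, pi = attr(Qn, "pi")) {
  if (tau < 0) stop("genetic distance tau must be >= 0, got ", tau)
  m <- nrow(Qn)
  if (tau == 0) {
    P <- diag(m)
    dimnames(P) <- dimnames(Qn)
    return(P)
  }
  if (is.null(pi)) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(as.matrix(Qn) * tau)))
  } else {
    P <- expm_eigen(rate_matrix_eigen(Qn, pi), tau)
  }
  if (any(!is.finite(P))) {
    stop("non-finite entries in exp(Q tau); rcond(Q) = ",
         format(tryCatch(rcond(as.matrix(Qn)), error = function(e) NA)))
  }
  dimnames(P) <- dimnames(Qn)
  P
}

#' Discrete-gamma site-rate categories
#'
#' Yang-style discretization of Gamma(shape, rate = shape) rate variation
#' across sites into `k` equal-probability categories, each represented by
#' the mean of the gamma density over its quantile interval; the category
#' rates average exactly 1.
#'
#' @param shape Positive gamma shape parameter.
#' @param k Number of categories (default 4).
#' @return A list of class `"site_rates"` with `shape`, `k`, and sorted
#'   `rates` (length k, mean 1).
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (shape <= 0) stop("gamma shape must be positive")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k == 1L) {
    rates <- 1
  } else {
    # E[X | q_{i-1} < X <= q_i] for X ~ Gamma(a, a) equals k * difference of
    # Gamma(a + 1, a) CDF values at the category bounds.
    bounds <- stats::qgamma(seq_len(k - 1) / k, shape = shape, rate = shape)
    upper <- c(stats::pgamma(bounds, shape = shape + 1, rate = shape), 1)
    lower <- c(0, upper[-k])
    rates <- k * (upper - lower)
    rates <- rates / mean(rates)
  }
  structure(list(shape = shape, k = k, rates = sort(rates)),
            class = "site_rates")
}

#' @export
print.site_rates <- function(x, ...) {
  cat("<site_rates> gamma shape", format(x$shape), "in", x$k, "categories:",
      paste(format(x$rates, digits = 4), collapse = " "), "\n")
  invisible(x)
}
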