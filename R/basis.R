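#' Substitution basis: exchangeabilities and equilibrium frequencies
#'
#' A substitution basis couples an alphabet with a symmetric exchangeability
#' matrix `r` and an equilibrium frequency simplex `pi`. Together they define
#' the time-reversible rate matrix Q = r diag(pi) used within one coding
#' epoch.
#'
#' @param r Symmetric m x m numeric matrix of non-negative exchangeabilities.
#'   The diagonal is ignored.
#' @param pi Numeric vector of m strictly positive frequencies summing to 1.
#' @param states An [alphabet()] (or character vector coerced to one). If
#'   omitted, taken from the dimnames of `r` or names of `pi`.
#' @return An object of class `"sub_basis"` with elements `states`, `r`, `pi`.
#' @examples
#' b <- substitution_basis(
#'   r = matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3),
#'   pi = c(0.6, 0.1, 0.3),
#'   states = c("x", "W", "Y")
#' )
#' build_rate_matrix(b)
#' @export
substitution_basis <- function(r, pi, states = NULL) {
  if (is.null(states)) {
    states <- rownames(r) %||% names(pi)
    if (is.null(states)) stop("states must be given or carried by r/pi names")
  }
  states <- alphabet(states)
  m <- length(states)
  r <- as.matrix(r)
  if (!all(dim(r) == m)) {
    stop("r must be ", m, " x ", m, " to match the alphabet")
  }
  if (length(pi) != m) stop("pi must have length ", m)
  pi <- as.numeric(pi)
  if (any(pi <= 0)) {
    stop("all frequencies must be positive; offending state: ",
         states[which(pi <= 0)[1]])
  }
  if (abs(sum(pi) - 1) > 1e-12) {
    stop("frequencies must sum to 1 within 1e-12 (got ",
         format(sum(pi), digits = 15), ")")
  }
  diag(r) <- 0
  if (any(r < 0)) {
    bad <- which(r < 0, arr.ind = TRUE)[1, ]
    stop("exchangeabilities must be non-negative; offending entry: (",
         states[bad[1]], ",", states[bad[2]], ")")
  }
  asym <- abs(r - t(r))
  if (max(asym) > 1e-9) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("r must be symmetric; offending entry: (",
         states[bad[1]], ",", states[bad[2]], ")")
  }
  dimnames(r) <- list(as.character(states), as.character(states))
  names(pi) <- as.character(states)
  structure(list(states = states, r = r, pi = pi), class = "sub_basis")
}

#' @export
print.sub_basis <- function(x, ...) {
  cat("<sub_basis> m =", length(x$states), "states:",
      paste(x$states, collapse = " "), "\n")
  cat("pi:", paste(format(x$pi, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Read exchangeabilities and frequencies from a PAML-style rate file
#'
#' Parses the lower-triangle text layout used to distribute empirical amino
#' acid models (LG, WAG, and relatives): 19 lines with 1..19 exchangeability
#' values followed by a line (or lines) of 20 equilibrium frequencies.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the rate-matrix text file.
#' @param states Alphabet the file is indexed by; defaults to the canonical
#'   20 amino acids in one-letter alphabetical order.
#' @return A [substitution_basis()].
#' @export
read_paml_rates <- function(path, states = aa_alphabet()) {
  m <- length(states)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  nums <- suppressWarnings(as.numeric(unlist(strsplit(paste(lines, collapse = " "),
                                                      "[[:space:]]+"))))
  if (anyNA(nums)) stop("non-numeric token in rate file ", path)
  need <- m * (m - 1) / 2 + m
  if (length(nums) < need) {
    stop("rate file ", path, " holds ", length(nums),
         " numbers; expected at least ", need)
  }
  r <- matrix(0, m, m)
  k <- 1
  for (i in 2:m) {
    for (j in 1:(i - 1)) {
      r[i, j] <- r[j, i] <- nums[k]
      k <- k + 1
    }
  }
  pi <- nums[k:(k + m - 1)]
  pi <- pi / sum(pi)
  substitution_basis(r, pi, states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
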