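#' Coding alphabets
#'
#' An alphabet is an ordered set of single-character state labels. The
#' canonical protein alphabet holds the 20 standard amino acids in one-letter
#' alphabetical order; toy alphabets of any size m >= 2 are supported for
#' worked examples and simulation studies.
#'
#' @param states Character vector of unique single-character state labels.
#' @return A character vector of class `"alphabet"`.
#' @examples
#' aa_alphabet()
#' alphabet(c("x", "W", "Y"))
#' @export
alphabet <- function(states) {
  states <- as.character(states)
  if (length(states) < 2) {
    stop("an alphabet needs at least 2 states, got ", length(states))
  }
  if (anyDuplicated(states)) {
    stop("alphabet labels must be unique; duplicated: ",
         paste(unique(states[duplicated(states)]), collapse = ", "))
  }
  if (any(nchar(states) < 1)) {
    stop("alphabet labels must be non-empty")
  }
  structure(states, class = "alphabet")
}

#' @rdname alphabet
#' @export
aa_alphabet <- function() {
  alphabet(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
}

#' @export
print.alphabet <- function(x, ...) {
  cat("<alphabet> m =", length(x), ":", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

# Ambiguity expansion: which full-alphabet states a character is compatible
# with. '-', 'X', '?' are fully ambiguous; B/Z/J expand to their standard sets.
ambiguity_states <- function(ch, states) {
  if (ch %in% states) return(ch)   # genuine states win over ambiguity codes
  full <- c("-", "X", "?", ".")
  if (ch %in% full) return(states)
  expand <- list(B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"))
  if (ch %in% names(expand) && all(expand[[ch]] %in% states)) {
    return(expand[[ch]])
  }
  if (!ch %in% states) {
    stop("character '", ch, "' is not in the alphabet and is not a ",
         "recognized ambiguity code")
  }
  ch
}
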