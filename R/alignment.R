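#' Amino acid alignments
#'
#' An alignment is an N x L character matrix over an alphabet, with taxon
#' labels as row names. Gap and ambiguity codes (`-`, `X`, `?`) are treated
#' as fully ambiguous; `B`, `Z`, `J` expand to their standard amino acid
#' sets when those states are present.
#'
#' @param seqs Named character vector of sequences, or a character matrix
#'   with one row per taxon.
#' @param states The [alphabet()] the sequences are written in.
#' @return A character matrix of class `"aa_alignment"` with the alphabet
#'   attached as attribute `"states"`.
#' @export
aa_alignment <- function(seqs, states = aa_alphabet()) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      stop("all sequences must share one length; got ",
           paste(unique(lens), collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  # normalize case, but never away from a genuine alphabet state (toy
  # alphabets may use lower-case labels)
  fix <- !mat %in% as.character(states)
  mat[fix] <- toupper(mat[fix])
  legal <- c(as.character(states), "-", "X", "?", ".", "B", "Z", "J")
  bad <- !mat %in% legal
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("illegal residue '", mat[idx[1], idx[2]], "' in sequence '",
         rownames(mat)[idx[1]], "' at site ", idx[2])
  }
  structure(mat, class = c("aa_alignment", "matrix"), states = states)
}

#' @export
`[.aa_alignment` <- function(x, i, j, ..., drop = TRUE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out, class = c("aa_alignment", "matrix"),
              states = attr(x, "states"))
  } else {
    out
  }
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment>", nrow(x), "sequences x", ncol(x), "sites over",
      length(attr(x, "states")), "states\n")
  invisible(x)
}

#' Read and write FASTA alignments
#'
#' `read_fasta()` parses an aligned FASTA file, normalizing residues to
#' upper case, rejecting duplicate identifiers, and reporting illegal
#' characters with their line number. `write_fasta()` round-trips exactly
#' (gaps preserved).
#'
#' @param path File path.
#' @param states Target [alphabet()].
#' @return `read_fasta()` returns an [aa_alignment()].
#' @export
read_fasta <- function(path, states = aa_alphabet()) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no FASTA records in ", path)
  if (headers[1] != 1 && any(nzchar(trimws(lines[seq_len(headers[1] - 1)])))) {
    stop("sequence data before the first '>' header at line 1 of ", path)
  }
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    stop("empty sequence identifier at line ", headers[which(!nzchar(ids))[1]])
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate identifier '", dup, "' at line ",
         headers[which(ids == dup)[2]])
  }
  bounds <- c(headers, length(lines) + 1L)
  legal <- c(as.character(states), "-", "X", "?", ".", "B", "Z", "J")
  seqs <- character(length(headers))
  st <- as.character(states)
  for (k in seq_along(headers)) {
    block <- seq(bounds[k] + 1L, bounds[k + 1L] - 1L)
    block <- block[block <= length(lines) & block > bounds[k]]
    parts <- character(length(block))
    for (bi in seq_along(block)) {
      ln <- block[bi]
      chars <- strsplit(trimws(lines[ln]), "")[[1]]
      chars <- ifelse(chars %in% st, chars, toupper(chars))
      ok <- chars %in% legal
      if (!all(ok)) {
        stop("illegal residue character '", chars[!ok][1], "' at line ", ln,
             " of ", path)
      }
      parts[bi] <- paste(chars, collapse = "")
    }
    seqs[k] <- paste(parts, collapse = "")
  }
  names(seqs) <- ids
  aa_alignment(seqs, states)
}

#' @rdname read_fasta
#' @param aln An [aa_alignment()].
#' @param width Residues per line.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Compress an alignment into weighted unique site patterns
#'
#' Likelihoods are computed per unique column and weighted by column
#' multiplicity; the compressed likelihood equals the uncompressed one.
#'
#' @param aln An [aa_alignment()].
#' @return A list with `patterns` (N x P character matrix of unique
#'   columns), `weights` (column multiplicities summing to L), and `index`
#'   (which pattern each original site maps to).
#' @export
pattern_compress <- function(aln) {
  keys <- apply(aln, 2, paste, collapse = "\r")
  uniq <- !duplicated(keys)
  index <- match(keys, keys[uniq])
  patterns <- aln[, uniq, drop = FALSE]
  list(patterns = patterns, weights = as.numeric(tabulate(index, sum(uniq))),
       index = index)
}

# Leaf partial-likelihood cube: m x P x N with a 1 for every state a
# character is compatible with.
leaf_partials <- function(patterns, states) {
  st <- as.character(states)
  m <- length(st)
  N <- nrow(patterns)
  P <- ncol(patterns)
  cube <- array(0, c(m, P, N))
  for (i in seq_len(N)) {
    for (j in seq_len(P)) {
      cube[match(ambiguity_states(patterns[i, j], st), st), j, i] <- 1
    }
  }
  cube
}
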