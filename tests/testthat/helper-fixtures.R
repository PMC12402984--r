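# Shared fixtures: the m = 3 worked-example basis (states x, W, Y), toy
# trees, a random-basis factory, and the brute-force enumeration oracle
# used to validate the epoch-aware pruning.

toy_basis <- function() {
  substitution_basis(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3),
                     c(0.6, 0.1, 0.3), c("x", "W", "Y"))
}

random_basis <- function(m, states = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(states)) {
    states <- if (m == 20) aa_alphabet() else letters[seq_len(m)]
  }
  r <- matrix(0, m, m)
  r[upper.tri(r)] <- stats::rexp(m * (m - 1) / 2)
  r <- r + t(r)
  pi <- stats::rgamma(m, 2)
  pi <- pi / sum(pi)
  substitution_basis(r, pi, states)
}

flat_basis20 <- function() {
  substitution_basis(matrix(1, 20, 20), rep(0.05, 20), aa_alphabet())
}

# one tip below an origin; two tips joined at 0.5 below an origin at 1
tree_one_taxon <- function(origin = 1) {
  time_tree(c(0L), 0, "A", origin_height = origin)
}

tree_two_taxon <- function(root = 0.5, origin = 1) {
  time_tree(c(3L, 3L, 0L), c(0, 0, root), c("A", "B"),
            origin_height = origin)
}

tree_three_taxon <- function() {
  # ((A:0.3, B:0.3):0.4, C:0.7)
  time_tree(c(4L, 4L, 5L, 5L, 0L), c(0, 0, 0, 0.3, 0.7),
            c("A", "B", "C"))
}

# Brute-force site-pattern likelihoods: enumerate every assignment of
# states to internal nodes (and the origin), with branch matrices built
# from the dense Pade exponential (Matrix::expm) and the boundary crossing
# as an explicit double sum over intermediate states. Independent of the
# pruning code path.
oracle_pattern_lik <- function(tree, basis, config, rates = 1) {
  states <- as.character(basis$states)
  m <- length(states)
  Qn <- normalize_rate_matrix(build_rate_matrix(basis))
  red <- reduce_alphabet(basis, config)
  Qr <- normalize_rate_matrix(build_rate_matrix(red$basis))
  Xi <- if (config$Is > 0) saltation_matrix(basis, config)
  pade <- function(M, tau) {
    if (tau == 0) return(diag(nrow(M)))
    as.matrix(Matrix::expm(Matrix::Matrix(unclass(M) * tau)))
  }
  is0 <- config$Is == 0
  te <- config$te
  in_old <- function(h) !is0 && h > te
  branch_M <- function(hp, hc, rate) {
    if (!in_old(hp)) return(pade(Qn, rate * (hp - hc)))
    if (in_old(hc)) return(pade(Qr, rate * (hp - hc)))
    P2 <- pade(Qr, rate * (hp - te))
    P1 <- pade(Qn, rate * (te - hc))
    out <- matrix(0, nrow(P2), ncol(P1))
    for (i in seq_len(nrow(P2))) {
      for (j in seq_len(ncol(P1))) {
        out[i, j] <- sum(outer(P2[i, ], P1[, j]) * Xi)
      }
    }
    out
  }
  n_node <- length(tree$parent)
  ntip <- tree$ntip
  has_origin <- !is.na(tree$origin_height)
  # branch matrices depend only on (branch, rate): memoize across the
  # pattern x assignment enumeration
  memo <- new.env(parent = emptyenv())
  branch_M_memo <- function(hp, hc, rate) {
    key <- paste(hp, hc, rate, sep = "_")
    got <- memo[[key]]
    if (is.null(got)) {
      got <- branch_M(hp, hc, rate)
      memo[[key]] <- got
    }
    got
  }
  top_h <- if (has_origin) tree$origin_height else root_height(tree)
  rf <- root_frequencies(basis, config, top_h)
  space_dim <- function(h) if (in_old(h)) nrow(Qr) else m
  int_dims <- if (n_node > ntip) {
    vapply(tree$heights[(ntip + 1):n_node], space_dim, numeric(1))
  } else {
    numeric(0)
  }
  o_dim <- if (has_origin) space_dim(tree$origin_height)
  function(pattern) {
    leaf_idx <- match(pattern, states)
    one_rate <- function(rate) {
      grid <- expand.grid(c(lapply(int_dims, seq_len),
                            if (has_origin) list(seq_len(o_dim))))
      if (nrow(grid) == 0) grid <- data.frame(.dummy = 1)
      total <- 0
      for (g in seq_len(nrow(grid))) {
        assign <- as.integer(grid[g, ])
        node_state <- function(node) {
          if (node <= ntip) leaf_idx[node] else assign[node - ntip]
        }
        p <- if (has_origin) rf[assign[length(assign)]] else
          rf[node_state(tree$root)]
        if (has_origin) {
          M <- branch_M_memo(tree$origin_height, root_height(tree),
                             rate * tree$rate_mult[tree$root])
          p <- p * M[assign[length(assign)], node_state(tree$root)]
        }
        for (node in seq_len(n_node)) {
          if (node == tree$root) next
          M <- branch_M_memo(tree$heights[tree$parent[node]],
                             tree$heights[node],
                             rate * tree$rate_mult[node])
          p <- p * M[node_state(tree$parent[node]), node_state(node)]
        }
        total <- total + p
      }
      total
    }
    mean(vapply(rates, one_rate, numeric(1)))
  }
}

# all m^N patterns of an N-taxon tree over the toy alphabet
all_patterns <- function(states, n) {
  as.matrix(do.call(expand.grid,
                    c(rep(list(as.character(states)), n),
                      stringsAsFactors = FALSE)))
}

pattern_alignment <- function(pattern, taxa, states) {
  aa_alignment(stats::setNames(as.character(pattern), taxa), states = states)
}

laplace_cdf <- function(q, location = 0, scale = 1) {
  z <- (q - location) / scale
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}
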