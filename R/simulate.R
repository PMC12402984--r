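#' Simulate a birth-death(-sampling) time-tree
#'
#' Two conditioning modes are available:
#'
#' * **Conditioned on N extant taxa** (default): the rho-sampled
#'   birth-death process conditioned on `n` sampled extant tips is drawn
#'   constructively — the `n - 1` speciation ages are iid from the
#'   conditioned node-age density (via its closed-form quantile function)
#'   and the ranked labelled topology is uniform, realized by merging
#'   uniformly chosen lineage pairs backwards in time.
#' * **Conditioned on the origin height**: lineages are grown forward in
#'   time from one ancestor at the origin (birth rate `lambda`, death rate
#'   `lambda / r0`), extant tips are sampled with probability `rho`, and
#'   the run is retried until the requested number of extant tips (when
#'   `n` is given, otherwise at least one) survives. With
#'   `fossils = TRUE`, non-extant tips are retained as dated tips.
#'
#' @param lambda Per-lineage birth rate.
#' @param r0 Reproduction number `lambda / mu` (> 1).
#' @param rho Extant sampling fraction in (0, 1].
#' @param n Number of extant tips to condition on.
#' @param origin Origin height for forward conditioning (`NULL` for the
#'   constructive N-conditioned sampler).
#' @param fossils Retain dated non-extant tips (forward mode only); they
#'   are kept with probability `fossil_rho`.
#' @param fossil_rho Sampling probability of a non-extant tip.
#' @param max_tries Retry budget for forward conditioning.
#' @return A [time_tree()]; extant tips are labelled `t1, t2, ...` and
#'   fossil tips `f1, f2, ...`.
#' @export
simulate_bd_tree <- function(lambda = 2, r0 = 2, rho = 1, n = NULL,
                             origin = NULL, fossils = FALSE,
                             fossil_rho = 0.5, max_tries = 10000L) {
  bd <- list(lambda = lambda, r0 = r0, rho = rho)
  if (is.null(origin)) {
    if (is.null(n)) stop("give n (extant tips) or an origin height")
    if (fossils) stop("fossils require origin-conditioned forward simulation")
    times <- sort(bd_node_quantile(stats::runif(n - 1), bd))
    build_ranked_tree(times, n)
  } else {
    simulate_bd_forward(bd, origin, n, fossils, fossil_rho, max_tries)
  }
}

# Uniform ranked labelled topology on given sorted speciation ages.
build_ranked_tree <- function(times, n) {
  n_node <- 2L * n - 1L
  parent <- integer(n_node)
  heights <- c(rep(0, n), times)
  active <- seq_len(n)
  for (k in seq_along(times)) {
    node <- n + k
    pair <- sample(seq_along(active), 2L)
    parent[active[pair]] <- node
    active <- c(active[-pair], node)
  }
  time_tree(parent, heights, paste0("t", seq_len(n)))
}

simulate_bd_forward <- function(bd, origin, n, fossils, fossil_rho,
                                max_tries) {
  mu <- bd$lambda / bd$r0
  for (try in seq_len(max_tries)) {
    parent <- 0L
    end_h <- NA_real_
    alive <- 1L
    h_now <- origin
    ok <- TRUE
    while (length(alive) > 0 && h_now > 0) {
      h_next <- h_now - stats::rexp(1, length(alive) * (bd$lambda + mu))
      if (h_next <= 0) {
        end_h[alive] <- 0
        h_now <- 0
        break
      }
      who <- if (length(alive) == 1L) alive else sample(alive, 1L)
      if (stats::runif(1) < bd$lambda / (bd$lambda + mu)) {
        parent <- c(parent, who, who)
        end_h <- c(end_h, NA_real_, NA_real_)
        end_h[who] <- h_next
        alive <- c(setdiff(alive, who), length(parent) - 1L, length(parent))
      } else {
        end_h[who] <- h_next
        alive <- setdiff(alive, who)
      }
      h_now <- h_next
      if (length(parent) > 200000L) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    is_tip <- !seq_along(parent) %in% parent
    extant <- which(is_tip & end_h == 0)
    keep_extant <- extant[stats::runif(length(extant)) <= bd$rho]
    if (is.null(n)) {
      if (length(keep_extant) < 2) next
    } else if (length(keep_extant) != n) next
    dead_tips <- which(is_tip & end_h > 0)
    keep_fossil <- if (fossils) {
      dead_tips[stats::runif(length(dead_tips)) <= fossil_rho]
    } else integer(0)
    tt <- prune_forward_tree(parent, end_h, keep_extant, keep_fossil, origin)
    if (!is.null(tt)) return(tt)
  }
  stop("conditioning unreachable after ", max_tries, " attempts")
}

# Reduce the grown lineage table to the sampled tips, suppressing
# unifurcations, and return a time_tree (dated tips allowed).
prune_forward_tree <- function(parent, end_h, keep_extant, keep_fossil,
                               origin) {
  keep_tips <- c(keep_extant, keep_fossil)
  if (length(keep_tips) < 2) return(NULL)
  n_raw <- length(parent)
  has_sampled <- logical(n_raw)
  for (t in keep_tips) {
    i <- t
    while (i != 0L && !has_sampled[i]) {
      has_sampled[i] <- TRUE
      i <- parent[i]
    }
  }
  n_sampled_kids <- tabulate(parent[has_sampled & parent != 0L], n_raw)
  internal_raw <- which(n_sampled_kids >= 2L)
  retained_parent <- function(i) {
    p <- parent[i]
    while (p != 0L && n_sampled_kids[p] < 2L) p <- parent[p]
    p
  }
  ntip <- length(keep_tips)
  n_int <- length(internal_raw)
  if (n_int != ntip - 1L) return(NULL)
  id <- integer(n_raw)
  id[keep_tips] <- seq_len(ntip)
  id[internal_raw] <- ntip + seq_len(n_int)
  np <- integer(ntip + n_int)
  heights <- c(end_h[keep_tips], end_h[internal_raw])
  for (i in c(keep_tips, internal_raw)) {
    rp <- retained_parent(i)
    np[id[i]] <- if (rp == 0L) 0L else id[rp]
  }
  labels <- c(paste0("t", seq_along(keep_extant)),
              if (length(keep_fossil)) paste0("f", seq_along(keep_fossil)))
  time_tree(np, heights, labels, origin_height = origin,
            tips_dated = length(keep_fossil) > 0)
}

#' Simulate an alignment under the two-epoch process
#'
#' For each site a rate category is drawn, the root (or origin) state is
#' drawn from [root_frequencies()], and states are evolved down every
#' branch: old-epoch segments use the reduced transition matrix, the
#' boundary crossing applies one categorical draw from the matching row of
#' the saltation matrix, and young-epoch segments use the full matrix.
#' Extant leaves emit full-alphabet characters.
#'
#' @param tree A [time_tree()].
#' @param basis Young-epoch [substitution_basis()].
#' @param config A [resub_config()].
#' @param site_model A [discrete_gamma_rates()] model.
#' @param clock A [clock_model()].
#' @param L Number of sites.
#' @return An [aa_alignment()] of `tree$ntip` sequences by `L` sites.
#' @export
simulate_alignment <- function(tree, basis, config,
                               site_model = discrete_gamma_rates(1, 1),
                               clock = clock_model(), L = 100L) {
  states <- as.character(basis$states)
  m <- length(states)
  Qn <- normalize_rate_matrix(build_rate_matrix(basis))
  eig <- rate_matrix_eigen(Qn)
  is0 <- config$Is == 0L
  if (!is0) {
    red <- reduce_alphabet(basis, config)
    Qr <- normalize_rate_matrix(build_rate_matrix(red$basis))
    eigr <- rate_matrix_eigen(Qr)
    Xi <- saltation_matrix(basis, config)
    mr <- length(red$basis$states)
  }
  in_old <- function(h) !is0 && h > config$te
  cat_of_site <- sample.int(site_model$k, L, replace = TRUE)
  evolve <- function(idx, P) {
    out <- integer(length(idx))
    for (s in unique(idx)) {
      sel <- idx == s
      out[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE,
                             prob = P[s, ])
    }
    out
  }
  seg <- function(idx, eig_use, tau_by_cat, cats) {
    out <- idx
    for (c in unique(cats)) {
      sel <- cats == c
      if (tau_by_cat[c] > 0) {
        P <- expm_eigen(eig_use, tau_by_cat[c])
        out[sel] <- evolve(idx[sel], P)
      }
    }
    out
  }
  branch_down <- function(idx, hp, hc, rate, cats) {
    # idx indexed in the parent's space; returns child-space indices
    taus <- split_branch_at_boundary(hp, hc, config$te, rate)
    taus_cat2 <- taus["tau2"] * site_model$rates
    taus_cat1 <- taus["tau1"] * site_model$rates
    if (!in_old(hp)) {
      return(seg(idx, eig, (taus_cat1 + taus_cat2), cats))
    }
    if (in_old(hc)) {
      return(seg(idx, eigr, taus_cat1 + taus_cat2, cats))
    }
    idx <- seg(idx, eigr, taus_cat2, cats)
    idx <- evolve(idx, Xi)  # reduced -> full at the boundary
    seg(idx, eig, taus_cat1, cats)
  }
  top_h <- if (!is.na(tree$origin_height)) tree$origin_height else
    root_height(tree)
  rf <- root_frequencies(basis, config, top_h)
  state_idx <- vector("list", length(tree$parent))
  top_idx <- sample.int(length(rf), L, replace = TRUE, prob = rf)
  if (!is.na(tree$origin_height)) {
    top_idx <- branch_down(top_idx, tree$origin_height,
                           root_height(tree),
                           clock$rate * tree$rate_mult[tree$root],
                           cat_of_site)
  }
  state_idx[[tree$root]] <- top_idx
  for (node in rev(postorder_internal(tree))) {
    for (ch in tree$children[[node]]) {
      state_idx[[ch]] <- branch_down(state_idx[[node]],
                                     tree$heights[node], tree$heights[ch],
                                     clock$rate * tree$rate_mult[ch],
                                     cat_of_site)
    }
  }
  seqs <- matrix("", tree$ntip, L, dimnames = list(tree$labels, NULL))
  for (t in seq_len(tree$ntip)) {
    if (in_old(tree$heights[t])) {
      # dated tip above the boundary: report the reduced-state label mapped
      # into the full alphabet (a merged state emits the retained label)
      lab <- states[red$index_map][state_idx[[t]]]
    } else {
      lab <- states[state_idx[[t]]]
    }
    seqs[t, ] <- lab
  }
  aa_alignment(seqs, basis$states)
}

#' Draw a full ground-truth record from the prior
#'
#' Samples a tree from the birth-death prior and model parameters from
#' `priors` (those flagged for estimation in `draw`), then simulates an
#' alignment — the front half of a coverage study replicate.
#'
#' @param priors A [prior_spec()].
#' @param n_taxa,L Tree and alignment sizes.
#' @param basis Base [substitution_basis()]; its `pi` and `r` are used
#'   as-is unless drawn.
#' @param cherry Length-2 character vector naming the cherry states.
#' @param draw Character vector naming parameters to draw from their
#'   priors rather than fix: any of `"pi"`, `"r"`, `"shape"`, `"clock"`.
#' @param shape,clock_rate Fixed values used when not drawn.
#' @param k Gamma categories.
#' @return A list with `params` (one-row tibble of the truth), `tree`,
#'   `aln`, `basis`, `config`, `site_model`, `clock`.
#' @export
sample_from_prior <- function(priors, n_taxa, L, basis, cherry,
                              draw = character(0), shape = 1,
                              clock_rate = 1, k = 4L) {
  tree <- simulate_bd_tree(priors$bd$lambda, priors$bd$r0, priors$bd$rho,
                           n = n_taxa)
  if ("pi" %in% draw) {
    m <- length(basis$states)
    pi <- stats::rgamma(m, 1, 1)
    pi <- pi / sum(pi)
    basis <- substitution_basis(basis$r, pi, basis$states)
  }
  if ("r" %in% draw) {
    m <- length(basis$states)
    r <- matrix(0, m, m)
    r[upper.tri(r)] <- stats::rexp(m * (m - 1) / 2, priors$r_rate)
    r <- r + t(r)
    basis <- substitution_basis(r, basis$pi, basis$states)
  }
  if ("shape" %in% draw) shape <- stats::rexp(1, 1 / priors$shape_mean)
  if ("clock" %in% draw) {
    clock_rate <- stats::rlnorm(1, priors$clock_meanlog, priors$clock_sdlog)
  }
  Is <- sample(0:3, 1, prob = priors$is_prior)
  anchor_h <- anchor_height(tree, priors$anchor)
  te <- rte_prior(1, anchor_h, priors$delta)
  nu <- stats::runif(1)
  config <- resub_config(cherry[1], cherry[2], Is = Is, te = te, nu = nu)
  site_model <- discrete_gamma_rates(shape, k)
  clock <- clock_model(clock_rate)
  aln <- simulate_alignment(tree, basis, config, site_model, clock, L)
  params <- tibble::tibble(Is = Is, te = te, nu = nu, shape = shape,
                           clock_rate = clock_rate,
                           root_height = root_height(tree),
                           tree_length = tree_length(tree),
                           anchor_height = anchor_h)
  list(params = params, tree = tree, aln = aln, basis = basis,
       config = config, site_model = site_model, clock = clock)
}
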