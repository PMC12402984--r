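#' Rooted, dated, ultrametric time-trees
#'
#' A `time_tree` is a rooted binary tree whose leaves sit at height 0 and
#' whose internal nodes carry ages (heights) in time units. Nodes `1..N`
#' are the tips; internal nodes are `N+1..2N-1`. An optional origin height
#' above the root supports stem branches, and each node carries a rate
#' multiplier for the branch above it (all 1 under a strict clock).
#'
#' @param parent Integer vector: parent index per node, 0 at the root.
#' @param heights Numeric node heights; tips at 0.
#' @param labels Tip labels (length N).
#' @param origin_height Optional origin age above the root (`NA` for none).
#' @param rate_mult Per-branch rate multipliers (length `2N-1`, default 1).
#' @param tips_dated Allow tips at positive heights (serially sampled,
#'   non-extant taxa); by default every tip must sit at height 0.
#' @return An object of class `"time_tree"`.
#' @export
time_tree <- function(parent, heights, labels,
                      origin_height = NA_real_, rate_mult = NULL,
                      tips_dated = FALSE) {
  n_node <- length(parent)
  ntip <- (n_node + 1) / 2
  if (ntip != floor(ntip)) stop("a rooted binary tree has an odd node count")
  ntip <- as.integer(ntip)
  if (length(heights) != n_node) stop("heights must cover every node")
  if (length(labels) != ntip) stop("need one label per tip")
  if (is.null(rate_mult)) rate_mult <- rep(1, n_node)
  root <- which(parent == 0L)
  if (length(root) != 1) stop("exactly one root (parent 0) required")
  if (!tips_dated) {
    if (max(abs(heights[seq_len(ntip)])) > 1e-9) {
      bad <- which.max(abs(heights[seq_len(ntip)]))
      stop("tree is not ultrametric: leaf '", labels[bad], "' has height ",
           heights[bad])
    }
    heights[seq_len(ntip)] <- 0
  }
  children <- split(seq_len(n_node)[parent != 0L], parent[parent != 0L])
  kids <- vector("list", n_node)
  kids[as.integer(names(children))] <- children
  n_kids <- lengths(kids)
  if (n_node > 1 && any(n_kids[(ntip + 1):n_node] != 2L)) {
    stop("tree must be binary: node ",
         which(n_kids != 2L & seq_len(n_node) > ntip)[1], " has ",
         n_kids[which(n_kids != 2L & seq_len(n_node) > ntip)[1]], " children")
  }
  for (i in seq_len(n_node)) {
    if (parent[i] > 0L && heights[parent[i]] <= heights[i] - 1e-12) {
      stop("parent height must exceed child height (node ", i, ")")
    }
  }
  if (!is.na(origin_height) && origin_height < heights[root]) {
    stop("origin height must be at or above the root height")
  }
  structure(list(ntip = ntip, parent = as.integer(parent),
                 children = kids, heights = as.numeric(heights),
                 labels = as.character(labels), root = root,
                 origin_height = origin_height,
                 rate_mult = as.numeric(rate_mult)),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("<time_tree>", x$ntip, "tips, root height",
      format(root_height(x), digits = 6),
      if (!is.na(x$origin_height)) paste(", origin", format(x$origin_height)),
      "\n")
  invisible(x)
}

#' @rdname time_tree
#' @param tree A `time_tree`.
#' @export
root_height <- function(tree) tree$heights[tree$root]

#' Total tree length in time units
#'
#' Sum of all branch durations (excluding the origin branch).
#' @param tree A [time_tree()].
#' @export
tree_length <- function(tree) {
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  sum(tree$heights[tree$parent[nonroot]] - tree$heights[nonroot])
}

#' Height of the most recent common ancestor of a taxon set
#' @param tree A [time_tree()].
#' @param taxa Character vector of tip labels.
#' @export
mrca_height <- function(tree, taxa) {
  tree$heights[mrca_node(tree, taxa)]
}

mrca_node <- function(tree, taxa) {
  idx <- match(taxa, tree$labels)
  if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  anc <- function(i) {
    path <- i
    while (tree$parent[i] != 0L) {
      i <- tree$parent[i]
      path <- c(path, i)
    }
    path
  }
  common <- Reduce(intersect, lapply(idx, anc))
  common[which.min(tree$heights[common])]
}

# Internal nodes ordered by increasing height (children always precede
# parents on an ultrametric tree); ties broken by index.
postorder_internal <- function(tree) {
  if (length(tree$parent) == 1L) return(integer(0))
  internal <- (tree$ntip + 1L):length(tree$parent)
  internal[order(tree$heights[internal], internal)]
}

#' Convert between time_tree and ape phylo
#'
#' @param tree A [time_tree()].
#' @return `tt_to_phylo()` returns an [ape::as.phylo] object with branch
#'   lengths in time units; `phylo_to_tt()` builds a [time_tree()] from a
#'   rooted, binary, ultrametric `phylo`.
#' @export
tt_to_phylo <- function(tree) {
  n <- length(tree$parent)
  ntip <- tree$ntip
  internal <- (ntip + 1L):n
  # ape wants the root first among internal nodes
  ord <- c(tree$root, setdiff(internal, tree$root))
  renum <- integer(n)
  renum[seq_len(ntip)] <- seq_len(ntip)
  renum[ord] <- ntip + seq_along(ord)
  nonroot <- setdiff(seq_len(n), tree$root)
  edge <- cbind(renum[tree$parent[nonroot]], renum[nonroot])
  lengths <- tree$heights[tree$parent[nonroot]] - tree$heights[nonroot]
  phy <- list(edge = edge, edge.length = lengths, tip.label = tree$labels,
              Nnode = ntip - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' @rdname tt_to_phylo
#' @param phy An [ape::as.phylo] tree with branch lengths in time units.
#' @param origin_height Optional origin age.
#' @param tol Ultrametricity tolerance on leaf heights.
#' @export
phylo_to_tt <- function(phy, origin_height = NA_real_, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("expected a phylo object")
  if (is.null(phy$edge.length)) stop("tree must carry branch lengths")
  if (!ape::is.binary(phy)) stop("polytomies are not supported")
  if (!ape::is.rooted(phy)) stop("tree must be rooted and binary")
  depth <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  th <- max(depth[seq_len(ntip)])
  heights <- th - depth
  tips <- heights[seq_len(ntip)]
  if (max(abs(tips)) > tol) {
    stop("tree is not ultrametric within ", tol, ": leaf '",
         phy$tip.label[which.max(abs(tips))], "' is off by ",
         format(max(abs(tips))))
  }
  heights[seq_len(ntip)] <- 0
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  time_tree(parent, heights, phy$tip.label, origin_height = origin_height)
}

#' Read and write dated Newick trees
#'
#' Trees are stored as rooted binary Newick with branch lengths in time
#' units; node heights are reconstructed with the leaves at height 0 and
#' ultrametricity is validated. NEXUS input is accepted by
#' `read_newick_dated()` via [ape::read.nexus()].
#'
#' @param path File path.
#' @param origin_height Optional origin age attached to the tree.
#' @param tol Ultrametricity tolerance.
#' @return `read_newick_dated()` returns a [time_tree()].
#' @export
read_newick_dated <- function(path, origin_height = NA_real_, tol = 1e-6) {
  first <- readLines(path, n = 50L, warn = FALSE)
  phy <- if (any(grepl("^\\s*#NEXUS", first, ignore.case = TRUE))) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (is.null(phy)) stop("could not parse a tree from ", path)
  phylo_to_tt(phy, origin_height = origin_height, tol = tol)
}

#' @rdname read_newick_dated
#' @param tree A [time_tree()].
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tt_to_phylo(tree), file = path)
  invisible(path)
}

#' Split a branch at the epoch boundary
#'
#' Partitions the genetic distance of the branch from `parent_height` down
#' to `child_height` into the old-epoch part `tau2` (above `te`) and the
#' young-epoch part `tau1` (at or below `te`), under a branch rate in
#' substitutions/site/time. A branch wholly below the boundary is
#' attributed entirely to the young epoch.
#'
#' @param parent_height,child_height Node ages with
#'   `parent_height > child_height`.
#' @param te Epoch boundary age.
#' @param rate Branch rate (substitutions per site per time unit), > 0.
#' @return Named numeric vector `c(tau2, tau1)`.
#' @export
split_branch_at_boundary <- function(parent_height, child_height, te, rate) {
  if (parent_height <= child_height) {
    stop("parent_height must exceed child_height")
  }
  if (rate <= 0) stop("rate must be positive")
  tau2 <- rate * max(0, parent_height - max(te, child_height))
  tau1 <- rate * (min(te, parent_height) - child_height)
  if (te <= child_height) {
    tau2 <- rate * (parent_height - child_height)
    tau1 <- 0
  }
  c(tau2 = tau2, tau1 = tau1)
}
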