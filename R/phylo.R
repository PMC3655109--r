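#' @name phylo
#' @title Distance-based phylogenetics for allele alignments
#' @description
#' Jukes-Cantor (or p-) distance matrices, a Saitou-Nei neighbor-joining
#' implementation with deterministic tie-breaking and non-negative branch
#' lengths, and nonparametric bootstrap support by column resampling.
#' Trees are returned as `ape::phylo` objects, so the usual newick export
#' and plotting machinery applies.
NULL

pair_mismatch_proportions <- function(align) {
  m <- align_matrix(align)
  n <- nrow(m)
  p <- matrix(0, n, n, dimnames = list(names(align), names(align)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p[i, j] <- p[j, i] <- mean(m[i, ] != m[j, ])
  }
  p
}

#' Jukes-Cantor distance matrix
#'
#' d = -(3/4) log(1 - 4p/3) with p the pairwise mismatch proportion.
#' Saturated pairs (p >= 3/4) are outside the model's domain and raise an
#' error naming the pair.
#'
#' @param align an alignment acceptable to [as_allele_alignment()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
jc_distance <- function(align) {
  align <- as_allele_alignment(align)
  p <- pair_mismatch_proportions(align)
  sat <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)
  if (nrow(sat) > 0)
    stop(sprintf("saturated pair (p >= 3/4): %s vs %s",
                 rownames(p)[sat[1, 1]], colnames(p)[sat[1, 2]]))
  d <- jc_correct(p)
  diag(d) <- 0
  d
}

#' p-distance matrix
#'
#' @inheritParams jc_distance
#' @return symmetric matrix of pairwise mismatch proportions.
#' @export
p_distance <- function(align) {
  pair_mismatch_proportions(as_allele_alignment(align))
}

# JC distances with a rank-preserving fallback for saturated pairs, used
# inside bootstrap replicates where dropping the replicate would bias
# support: each saturated pair gets the replicate's maximum finite distance
# plus an increment that preserves the p-distance ordering among the
# saturated pairs.
jc_distance_robust <- function(align) {
  p <- pair_mismatch_proportions(align)
  d <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  ok <- p < 0.75
  d[ok] <- jc_correct(p[ok])
  if (!all(ok)) {
    dmax <- if (any(ok & upper.tri(p))) max(d[ok & upper.tri(p)]) else 1
    sat <- which(!ok & upper.tri(p), arr.ind = TRUE)
    ranks <- rank(p[sat], ties.method = "first")
    for (k in seq_len(nrow(sat))) {
      val <- dmax + 0.5 + 0.01 * ranks[k]
      d[sat[k, 1], sat[k, 2]] <- d[sat[k, 2], sat[k, 1]] <- val
    }
  }
  diag(d) <- 0
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard neighbor joining on a distance matrix using the Q-criterion;
#' among tied minima the pair earliest in (row, column) order is joined, so
#' the output is deterministic. Negative branch-length estimates are
#' clamped to zero and the clamped deficit recorded in the
#' `negative_deficit` attribute.
#'
#' @param dm symmetric distance matrix with labels (>= 3 taxa), e.g. from
#'   [jc_distance()].
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  labels <- rownames(dm) %||% sprintf("t%d", seq_len(nrow(dm)))
  frags <- labels                      # newick fragment per active node
  d <- dm
  deficit <- 0
  n <- nrow(d)
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # earliest (i, j), i < j, attaining the minimum
    best <- c(NA_integer_, NA_integer_); bestval <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (q[i, j] < bestval) { bestval <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { deficit <- deficit - li; li <- 0 }
    if (lj < 0) { deficit <- deficit - lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.10f,%s:%.10f)", frags[i], li, frags[j], lj)
    dnew <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frags <- c(frags[keep], newfrag)
    n <- n - 1
  }
  # three-point terminal configuration
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- c(la, lb, lc)
  neg <- lens < 0
  deficit <- deficit + sum(-lens[neg])
  lens[neg] <- 0
  nwk <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                 frags[1], lens[1], frags[2], lens[2], frags[3], lens[3])
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_deficit") <- deficit
  tree
}

# Canonical unrooted bipartitions of a phylo tree: for every internal edge,
# the tip-label set on the side not containing the alphabetically first
# tip, serialized as a string. Trivial splits (single tip / all tips) are
# dropped.
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- sort(attr(parts, "labels")[p])
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2)
      out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `n_replicates` times; the support of
#' each internal edge is the percentage of replicate trees containing the
#' same bipartition. Saturated pairs inside a replicate are given the
#' replicate's maximum finite distance with p-distance rank ordering
#' preserved, rather than dropping the replicate.
#'
#' @param align an alignment acceptable to [as_allele_alignment()].
#' @param n_replicates bootstrap replicates (default 1000; 0 returns the
#'   point tree without supports).
#' @param seed RNG seed.
#' @param model `"jc"` (Jukes-Cantor, default) or `"p"` (p-distance).
#' @return an `ape::phylo` tree whose internal `node.label`s hold integer
#'   bootstrap percentages (root label empty).
#' @export
bootstrap_support <- function(align, n_replicates = 1000L, seed = NULL,
                              model = c("jc", "p")) {
  model <- match.arg(model)
  align <- as_allele_alignment(align)
  distfun <- if (model == "jc") jc_distance else p_distance
  point <- nj_tree(distfun(align))
  if (n_replicates < 1) return(point)
  m <- align_matrix(align)
  L <- ncol(m)
  robust_distfun <- if (model == "jc") jc_distance_robust else p_distance
  counts <- stats::setNames(numeric(length(tree_splits(point))),
                            tree_splits(point))
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot <- stats::setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                    collapse = ""), names(align))
      class(boot) <- "allele_alignment"
      bt <- nj_tree(robust_distfun(boot))
      hits <- intersect(tree_splits(bt), names(counts))
      counts[hits] <- counts[hits] + 1
    }
  })
  support <- round(100 * counts / n_replicates)
  # attach to the point tree's internal nodes
  parts <- ape::prop.part(point)
  tips <- sort(point$tip.label)
  anchor <- tips[1]
  labels <- character(point$Nnode)
  for (k in seq_along(parts)) {
    side <- sort(attr(parts, "labels")[parts[[k]]])
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "\r")
    labels[k] <- if (key %in% names(support)) as.character(support[[key]]) else ""
  }
  point$node.label <- labels
  point
}

#' Write a tree to newick
#'
#' Branch lengths at 6 decimals, supports (if present) as internal node
#' labels.
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
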