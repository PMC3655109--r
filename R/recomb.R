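#' @name recomb
#' @title Recombination, gene conversion and linkage statistics
#' @description
#' The Hudson-Kaplan four-gamete lower bound on recombination events (RM),
#' a gene-conversion fragment scan in the style of Sawyer's permutation
#' test (unusually long runs of agreement between sequence pairs across
#' polymorphic sites, judged against column-shuffled replicates), and a
#' multilocus linkage-disequilibrium randomization test on allele
#' presence/absence using the standardized index of association r̄d.
NULL

# Segregating-site structure of an alignment: positions of polymorphic
# columns and which are strictly biallelic.
segregating_sites <- function(align) {
  m <- align_matrix(as_allele_alignment(align))
  n_states <- apply(m, 2, function(col) length(unique(col)))
  pos <- which(n_states >= 2)
  list(positions = pos, biallelic = n_states[pos] == 2,
       states = m[, pos, drop = FALSE])
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Over all ordered pairs of biallelic segregating sites, a pair is
#' incompatible under an infinite-sites model iff all four gametes occur;
#' each incompatible pair demands a recombination breakpoint strictly
#' between its two sites. RM is the size of a minimum set of breakpoints
#' hitting every incompatible open interval, computed by the classic
#' interval-reduction/greedy-stabbing algorithm (optimal for intervals).
#' Sites with more than two states are excluded.
#'
#' @param align an alignment acceptable to [as_allele_alignment()].
#' @return object of class `rm_result`: list with `rm` (integer),
#'   `intervals` (data frame of the disjoint incompatible intervals that
#'   certify the bound, alignment positions) and `n_incompatible` (total
#'   incompatible site pairs).
#' @export
four_gamete_rm <- function(align) {
  seg <- segregating_sites(align)
  bial <- which(seg$biallelic)
  if (length(bial) < 2)
    return(structure(list(rm = 0L,
                          intervals = data.frame(left = integer(0),
                                                 right = integer(0)),
                          n_incompatible = 0L),
                     class = "rm_result"))
  pos <- seg$positions[bial]
  states <- seg$states[, bial, drop = FALSE]
  k <- length(pos)
  lefts <- integer(0); rights <- integer(0)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    gametes <- unique(paste0(states[, a], states[, b]))
    if (length(gametes) == 4) {
      lefts <- c(lefts, pos[a]); rights <- c(rights, pos[b])
    }
  }
  n_inc <- length(lefts)
  if (n_inc == 0)
    return(structure(list(rm = 0L,
                          intervals = data.frame(left = integer(0),
                                                 right = integer(0)),
                          n_incompatible = 0L),
                     class = "rm_result"))
  # Greedy stabbing: process by right endpoint; a breakpoint just left of a
  # `right` covers every interval whose left end lies before it.
  ord <- order(rights, lefts)
  lefts <- lefts[ord]; rights <- rights[ord]
  chosen_l <- integer(0); chosen_r <- integer(0)
  covered_until <- -Inf  # breakpoint position of the last chosen stab
  for (t in seq_along(lefts)) {
    if (lefts[t] >= covered_until) {   # open interval not hit by last stab
      chosen_l <- c(chosen_l, lefts[t])
      chosen_r <- c(chosen_r, rights[t])
      covered_until <- rights[t]
    }
  }
  structure(list(rm = length(chosen_l),
                 intervals = data.frame(left = chosen_l, right = chosen_r),
                 n_incompatible = n_inc),
            class = "rm_result")
}

#' @export
print.rm_result <- function(x, ...) {
  cat(sprintf("Hudson-Kaplan RM = %d (%d incompatible site pairs)\n",
              x$rm, x$n_incompatible))
  invisible(x)
}

#' Gene-conversion fragment scan with permutation tests
#'
#' Restricted to polymorphic columns, each unordered sequence pair's inner
#' fragments are its maximal runs of agreement; the score of a pair is the
#' length (in polymorphic sites) of its longest run. The null distribution
#' comes from randomly permuting the order of the polymorphic columns, the
#' same permutation applied to all sequences per replicate, which preserves
#' every pairwise agreement total while destroying positional clustering.
#' Replicates are ranked against the observation by the full sorted
#' agreement-run profile (longest run first, then the remaining runs,
#' lexicographically), and pairwise p-values are the add-one fraction of
#' replicates ranking strictly better. The profile ranking makes exact ties
#' rare for ordinary pairs (keeping the null rejection rate near nominal),
#' while ties favor the observed arrangement, so a pair agreeing at every
#' polymorphic site attains the minimum attainable p. The global p applies
#' the same ranking to the alignment-wide best profile.
#'
#' @param align an alignment acceptable to [as_allele_alignment()].
#' @param n_permutations number of column-order permutations (default
#'   10000); must be >= 1.
#' @param seed RNG seed (p-values are bit-reproducible given a seed).
#' @return object of class `geneconv_result`: list with `fragments`
#'   (per-pair data frame: seq1, seq2, start, end, aln_start, aln_end,
#'   length, score, pairwise_p), `global_p`, `sig_fraction` (fraction of
#'   pairs with pairwise p < 0.05), `n_polymorphic`, `n_permutations`.
#'   With fewer than 3 polymorphic sites a no-test sentinel is returned
#'   (`tested = FALSE`).
#' @export
geneconv_scan <- function(align, n_permutations = 10000L, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  align <- as_allele_alignment(align)
  if (length(align) < 2) stop("need at least 2 sequences")
  seg <- segregating_sites(align)
  ns <- length(seg$positions)
  if (ns < 3)
    return(structure(list(tested = FALSE, n_polymorphic = ns,
                          fragments = NULL, global_p = NA_real_,
                          sig_fraction = NA_real_,
                          n_permutations = as.integer(n_permutations)),
                     class = "geneconv_result"))
  n <- length(align)
  pair_idx <- utils::combn(n, 2)
  npair <- ncol(pair_idx)
  agree <- matrix(0L, npair, ns)
  for (k in seq_len(npair)) {
    agree[k, ] <- as.integer(seg$states[pair_idx[1, k], ] ==
                               seg$states[pair_idx[2, k], ])
  }
  obs <- cpp_max_runs(agree)
  # locate the observed best fragment of each pair (first maximal run)
  frag_bounds <- t(vapply(seq_len(npair), function(k) {
    r <- rle(agree[k, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- which(r$values == 1L & r$lengths == obs[k])[1]
    if (is.na(best)) c(NA_integer_, NA_integer_)
    else c(starts[best], ends[best])
  }, integer(2)))
  perm_res <- with_seed(seed, {
    perms <- t(vapply(seq_len(n_permutations),
                      function(i) sample.int(ns) - 1L, integer(ns)))
    cpp_geneconv_perm(agree, perms)
  })
  pairwise_p <- (1 + perm_res$counts) / (n_permutations + 1)
  global_p <- (1 + perm_res$global_count) / (n_permutations + 1)
  fragments <- data.frame(seq1 = names(align)[pair_idx[1, ]],
                          seq2 = names(align)[pair_idx[2, ]],
                          start = frag_bounds[, 1], end = frag_bounds[, 2],
                          aln_start = seg$positions[frag_bounds[, 1]],
                          aln_end = seg$positions[frag_bounds[, 2]],
                          length = obs, score = obs,
                          pairwise_p = pairwise_p, stringsAsFactors = FALSE)
  structure(list(tested = TRUE, fragments = fragments, global_p = global_p,
                 sig_fraction = mean(pairwise_p < 0.05),
                 n_polymorphic = ns,
                 n_permutations = as.integer(n_permutations)),
            class = "geneconv_result")
}

#' @export
print.geneconv_result <- function(x, ...) {
  if (!isTRUE(x$tested)) {
    cat(sprintf("Gene-conversion scan: no test (%d polymorphic sites)\n",
                x$n_polymorphic))
    return(invisible(x))
  }
  cat(sprintf("Gene-conversion scan over %d pairs, %d polymorphic sites:\n",
              nrow(x$fragments), x$n_polymorphic))
  cat(sprintf("  global p = %.4g; %.1f%% of pairs with pairwise p < 0.05\n",
              x$global_p, 100 * x$sig_fraction))
  invisible(x)
}

#' Allele presence/absence matrix from genotype calls
#'
#' @param calls a [call_genotypes()] result (individuals with no retained
#'   alleles are dropped).
#' @return binary matrix, individuals x alleles, allele ids as in
#'   [build_population_table()].
#' @export
presence_matrix <- function(calls) {
  called <- Filter(function(g) nrow(g$alleles) > 0, calls)
  if (length(called) == 0) stop("no genotyped individuals")
  pop <- suppressWarnings(build_population_table(calls))
  m <- matrix(0L, length(called), nrow(pop),
              dimnames = list(names(called), pop$allele_id))
  for (ind in names(called)) {
    hit <- match(called[[ind]]$alleles$sequence, pop$sequence)
    m[ind, hit] <- 1L
  }
  m
}

rbar_d <- function(m) {
  # per-locus pairwise mismatch vectors; population-variance convention
  npair_var <- function(v) mean(v^2) - mean(v)^2
  d_l <- lapply(seq_len(ncol(m)), function(l)
    as.vector(stats::dist(m[, l], method = "manhattan")))
  D <- Reduce(`+`, d_l)
  var_l <- vapply(d_l, npair_var, numeric(1))
  VD <- npair_var(D)
  sum_cov <- 0
  for (l in seq_len(length(var_l) - 1)) {
    sum_cov <- sum_cov + sum(sqrt(var_l[l] * var_l[(l + 1):length(var_l)]))
  }
  list(IA = VD / sum(var_l) - 1,
       rbarD = (VD - sum(var_l)) / (2 * sum_cov))
}

#' Multilocus linkage-disequilibrium randomization test
#'
#' Tests association among allele presence/absence columns with the
#' standardized index of association r̄d. The null distribution shuffles
#' each column independently across individuals (breaking between-locus
#' association while preserving allele frequencies); the p-value is the
#' add-one fraction of randomizations with a statistic at least as large
#' as observed. Monomorphic columns are dropped.
#'
#' @param presence binary individuals x alleles matrix
#'   (see [presence_matrix()]).
#' @param n_randomizations number of column shuffles (default 10000).
#' @param seed RNG seed.
#' @return object of class `ld_result`: list with `rbarD`, `IA`, `p`,
#'   `n_loci`, `n_randomizations`; `tested = FALSE` sentinel when fewer
#'   than 2 polymorphic columns remain.
#' @export
ld_randomization <- function(presence, n_randomizations = 10000L,
                             seed = NULL) {
  if (n_randomizations < 1) stop("n_randomizations must be >= 1")
  stopifnot(is.matrix(presence), all(presence %in% c(0, 1)))
  if (any(rowSums(presence) == 0))
    stop("presence matrix has an all-zero individual row")
  freq <- colMeans(presence)
  poly <- presence[, freq > 0 & freq < 1, drop = FALSE]
  if (ncol(poly) < 2)
    return(structure(list(tested = FALSE, rbarD = NA_real_, IA = NA_real_,
                          p = NA_real_, n_loci = ncol(poly),
                          n_randomizations = as.integer(n_randomizations)),
                     class = "ld_result"))
  obs <- rbar_d(poly)
  n_ind <- nrow(poly)
  with_seed(seed, {
    hits <- 0L
    for (r in seq_len(n_randomizations)) {
      shuf <- apply(poly, 2, function(col) col[sample.int(n_ind)])
      if (rbar_d(shuf)$rbarD >= obs$rbarD) hits <- hits + 1L
    }
    structure(list(tested = TRUE, rbarD = obs$rbarD, IA = obs$IA,
                   p = (1 + hits) / (n_randomizations + 1),
                   n_loci = ncol(poly),
                   n_randomizations = as.integer(n_randomizations)),
              class = "ld_result")
  })
}

#' @export
print.ld_result <- function(x, ...) {
  if (!isTRUE(x$tested)) {
    cat(sprintf("LD randomization: no test (%d polymorphic loci)\n", x$n_loci))
    return(invisible(x))
  }
  cat(sprintf("LD over %d loci: r_bar_d = %.4f (IA = %.4f), p = %.4g (%d randomizations)\n",
              x$n_loci, x$rbarD, x$IA, x$p, x$n_randomizations))
  invisible(x)
}
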