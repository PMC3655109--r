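#' @name selstats
#' @title Divergence and selection statistics on an allele alignment
#' @description
#' Pairwise nucleotide and amino-acid differences, Nei-Gojobori (1986)
#' synonymous/nonsynonymous substitution rates with the Jukes-Cantor
#' multiple-hit correction, a one-tailed Z-test of positive selection
#' (dN > dS), and per-residue variability computed as one minus a
#' Valdar-style weighted sum-of-pairs conservation score.
NULL

#' Validate an allele alignment
#'
#' @param x named character vector of nucleotide sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @return a named character vector of uppercase ACGT sequences of equal
#'   length divisible by 3, class `allele_alignment`.
#' @export
as_allele_alignment <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  stopifnot(is.character(x), length(x) >= 1)
  x <- toupper(x)
  if (length(unique(nchar(x))) != 1)
    stop("alignment sequences must have equal length")
  if (nchar(x[1]) %% 3 != 0)
    stop("alignment length must be divisible by 3 (reading frame 0)")
  if (any(grepl("[^ACGT]", x)))
    stop("alignment must contain only A, C, G, T (no ambiguity codes or gaps)")
  if (is.null(names(x))) names(x) <- sprintf("seq_%02d", seq_along(x))
  structure(x, class = "allele_alignment")
}

align_matrix <- function(align) {
  do.call(rbind, strsplit(unclass(align), "", fixed = TRUE))
}

#' Pairwise sequence differences
#'
#' Hamming difference counts over all unordered sequence pairs, at the
#' nucleotide level or after translating in frame 0. The summary (min,
#' max, median, mean, sd) is taken over the lower-triangle values.
#'
#' @param align an alignment acceptable to [as_allele_alignment()].
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @return object of class `pairwise_diffs`: list with `matrix` (symmetric
#'   integer matrix) and `summary`.
#' @export
pairwise_differences <- function(align, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  align <- as_allele_alignment(align)
  if (length(align) < 2) stop("need at least 2 sequences")
  seqs <- if (level == "amino_acid") translate_dna(align) else unclass(align)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(align), names(align)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  vals <- d[lower.tri(d)]
  structure(list(matrix = d, level = level,
                 summary = c(min = min(vals), max = max(vals),
                             median = stats::median(vals), mean = mean(vals),
                             sd = stats::sd(vals))),
            class = "pairwise_diffs")
}

#' @export
print.pairwise_diffs <- function(x, ...) {
  cat(sprintf("Pairwise %s differences over %d sequences:\n",
              gsub("_", " ", x$level), nrow(x$matrix)))
  print(round(x$summary, 2))
  invisible(x)
}

# --- Nei-Gojobori machinery -------------------------------------------------
# Synonymous sites of a codon: at each position, the fraction of the three
# possible single-base changes that preserve the amino acid; changes to stop
# codons count as nonsynonymous, so s + n = 3 per codon.
ng_env <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(ng_env$tab)) return(ng_env$tab)
  gc <- genetic_code()
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  syn_sites <- vapply(codons, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
      alt <- ch; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (!(alt %in% STOP_CODONS) && gc[[alt]] == gc[[cod]]) s <- s + 1 / 3
    }
    s
  }, numeric(1))
  ng_env$tab <- list(gc = gc, codons = codons, syn_sites = syn_sites,
                     index = stats::setNames(seq_along(codons), codons))
  ng_env$tab
}

# Average synonymous/nonsynonymous change counts over all minimal mutational
# pathways between two codons, excluding pathways that pass through a stop
# codon (if every pathway does, all are averaged as a fallback).
codon_path_counts <- function(c1, c2) {
  tab <- ng_tables()
  gc <- tab$gc
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(ch1 != ch2)
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(diff_pos) else
    if (k == 2) list(diff_pos, rev(diff_pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(p) diff_pos[p])
  walk <- function(order) {
    cur <- ch1
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      a <- paste(cur, collapse = ""); b <- paste(nxt, collapse = "")
      if (b %in% STOP_CODONS || a %in% STOP_CODONS)
        return(NULL)
      if (gc[[a]] == gc[[b]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk))
  if (length(paths) == 0) {
    # all pathways hit a stop: average over them anyway
    walk_any <- function(order) {
      cur <- ch1; sd <- 0; nd <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- ch2[pos]
        a <- paste(cur, collapse = ""); b <- paste(nxt, collapse = "")
        aa_a <- if (a %in% STOP_CODONS) "*" else gc[[a]]
        aa_b <- if (b %in% STOP_CODONS) "*" else gc[[b]]
        if (aa_a == aa_b) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    paths <- lapply(perms, walk_any)
  }
  colMeans(do.call(rbind, paths))
}

# Lazy 64 x 64 caches of pathway-averaged (sd, nd) per codon pair.
ng_pair_tables <- function() {
  if (!is.null(ng_env$sd)) return(list(sd = ng_env$sd, nd = ng_env$nd))
  tab <- ng_tables()
  n <- length(tab$codons)
  sdm <- matrix(0, n, n); ndm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      p <- codon_path_counts(tab$codons[i], tab$codons[j])
      sdm[i, j] <- sdm[j, i] <- p["sd"]
      ndm[i, j] <- ndm[j, i] <- p["nd"]
    }
  }
  ng_env$sd <- sdm; ng_env$nd <- ndm
  list(sd = sdm, nd = ndm)
}

jc_correct <- function(p) -0.75 * log(1 - 4 * p / 3)

# Delta-method variance of the JC-corrected rate: Var(p)/ (1 - 4p/3)^2 with
# binomial Var(p) = p(1-p)/sites.
jc_variance <- function(p, sites) (p * (1 - p) / sites) / (1 - 4 * p / 3)^2

#' Nei-Gojobori dN/dS with Jukes-Cantor correction
#'
#' For every unordered sequence pair: synonymous (S) and nonsynonymous (N)
#' site counts by the one-third-fraction method, averaged over the two
#' sequences; observed synonymous/nonsynonymous differences (sd, nd)
#' averaged over all minimal mutational pathways per codon pair (pathways
#' through stop codons excluded); proportions pS = sd/S, pN = nd/N; and
#' Jukes-Cantor corrected rates d = -(3/4) log(1 - 4p/3). The overall dN
#' and dS are means over valid pairs; the Z statistic uses delta-method
#' variances of the means treating pairs as independent, with a one-tailed
#' p-value for dN > dS. Pairs with p >= 3/4 have an undefined corrected
#' rate and are excluded from the means with a warning.
#'
#' @param align an alignment acceptable to [as_allele_alignment()]; stop
#'   codons are rejected.
#' @param correction `"jukes_cantor"` (default) or `"none"` (report the raw
#'   proportions as rates).
#' @return object of class `dnds_result`: list with `pairs` (per-pair data
#'   frame), `dN`, `dS`, `var_dN`, `var_dS`, `Z`, `p`, `n_pairs`,
#'   `n_excluded`.
#' @export
nei_gojobori <- function(align, correction = c("jukes_cantor", "none")) {
  correction <- match.arg(correction)
  align <- as_allele_alignment(align)
  if (length(align) < 2) stop("need at least 2 sequences")
  if (any(has_inframe_stop(align)))
    stop("alignment contains in-frame stop codons")
  tab <- ng_tables()
  pt <- ng_pair_tables()
  cod <- do.call(rbind, lapply(unclass(align),
                               function(s) tab$index[codons_of(s)]))
  site_counts <- rowSums(matrix(tab$syn_sites[cod], nrow = nrow(cod)))
  n <- length(align)
  L <- nchar(align[1])
  pair_idx <- utils::combn(n, 2)
  rows <- vector("list", ncol(pair_idx))
  for (k in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    S <- (site_counts[i] + site_counts[j]) / 2
    N <- L - S
    idx <- cbind(cod[i, ], cod[j, ])
    sd_obs <- sum(pt$sd[idx])
    nd_obs <- sum(pt$nd[idx])
    pS <- if (S > 0) sd_obs / S else 0
    pN <- if (N > 0) nd_obs / N else 0
    if (correction == "jukes_cantor") {
      valid <- pS < 0.75 && pN < 0.75
      dS <- if (pS < 0.75) jc_correct(pS) else NA_real_
      dN <- if (pN < 0.75) jc_correct(pN) else NA_real_
      vS <- if (valid) jc_variance(pS, S) else NA_real_
      vN <- if (valid) jc_variance(pN, N) else NA_real_
    } else {
      valid <- TRUE
      dS <- pS; dN <- pN
      vS <- pS * (1 - pS) / S
      vN <- pN * (1 - pN) / N
    }
    rows[[k]] <- data.frame(seq1 = names(align)[i], seq2 = names(align)[j],
                            S = S, N = N, sd = sd_obs, nd = nd_obs,
                            pS = pS, pN = pN, dS = dS, dN = dN,
                            var_dS = vS, var_dN = vN, valid = valid,
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  excl <- sum(!pairs$valid)
  if (excl > 0)
    warning(excl, " pair(s) with p >= 3/4: Jukes-Cantor correction ",
            "undefined; excluded from overall means")
  ok <- pairs[pairs$valid, ]
  m <- nrow(ok)
  dN <- mean(ok$dN); dS <- mean(ok$dS)
  var_dN <- sum(ok$var_dN) / m^2
  var_dS <- sum(ok$var_dS) / m^2
  denom <- sqrt(var_dN + var_dS)
  Z <- if (is.finite(denom) && denom > 0) (dN - dS) / denom else NA_real_
  p <- if (is.na(Z)) NA_real_ else stats::pnorm(Z, lower.tail = FALSE)
  structure(list(pairs = pairs, dN = dN, dS = dS, var_dN = var_dN,
                 var_dS = var_dS, Z = Z, p = p, n_pairs = m,
                 n_excluded = excl, correction = correction),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori over %d pairs (%s correction):\n",
              x$n_pairs, gsub("_", "-", x$correction)))
  cat(sprintf("  dN = %.4f, dS = %.4f, dN/dS = %s\n", x$dN, x$dS,
              if (x$dS > 0) sprintf("%.3f", x$dN / x$dS) else "Inf"))
  if (is.na(x$Z)) {
    cat("  Z-test: not available (degenerate variance)\n")
  } else {
    cat(sprintf("  Z = %.3f, one-tailed p (dN > dS) = %.4g\n", x$Z, x$p))
  }
  invisible(x)
}

#' Z-test for positive selection
#'
#' One-tailed test of dN > dS from a [nei_gojobori()] result:
#' Z = (dN - dS) / sqrt(var dN + var dS) against the standard normal.
#'
#' @param result a `dnds_result`.
#' @return list with `Z` and `p`; both `NA` with a message when variances
#'   are degenerate (e.g. identical sequences).
#' @export
ztest_positive_selection <- function(result) {
  stopifnot(inherits(result, "dnds_result"))
  if (is.na(result$Z)) {
    message("no test: degenerate variance (alignment without divergence)")
    return(list(Z = NA_real_, p = NA_real_))
  }
  list(Z = result$Z, p = result$p)
}

#' Per-residue variability (1 - weighted sum-of-pairs conservation)
#'
#' For each amino-acid column, conservation is the weighted mean pairwise
#' similarity sum(w_i w_j m(a_i, a_j)) / sum(w_i w_j) with an identity
#' similarity matrix by default, and sequence weights proportional to each
#' sequence's mean distance from the others (distance-based weighting in
#' the style of Valdar's conservation scores, which down-weights clusters
#' of near-duplicate sequences). Variability is y = 1 - conservation, so
#' invariant columns score 0 and fully distinct columns score 1.
#'
#' @param align an alignment acceptable to [as_allele_alignment()].
#' @param similarity `"identity"`, or a symmetric numeric matrix in [0,1]
#'   with amino-acid single-letter dimnames.
#' @param weighting `"distance_based"` (default) or `"equal"`.
#' @param offset added to the 1-based codon column index to report site
#'   positions in an external residue-numbering frame.
#' @return object of class `residue_variability`: data frame (column,
#'   external_site, conservation, variability) with the sequence `weights`
#'   as an attribute.
#' @export
residue_variability <- function(align, similarity = "identity",
                                weighting = c("distance_based", "equal"),
                                offset = 0L) {
  weighting <- match.arg(weighting)
  align <- as_allele_alignment(align)
  aa <- do.call(rbind, strsplit(translate_dna(align), "", fixed = TRUE))
  n <- nrow(aa); ncol_aa <- ncol(aa)
  if (n < 2) stop("need at least 2 sequences")
  sim <- function(a, b) {
    if (identical(similarity, "identity")) as.numeric(a == b)
    else similarity[cbind(a, b)]
  }
  if (weighting == "distance_based") {
    dmat <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- mean(aa[i, ] != aa[j, ])
    }
    w <- rowSums(dmat) / (n - 1)
    if (all(w == 0)) w <- rep(1, n)   # identical sequences: equal weights
  } else {
    w <- rep(1, n)
  }
  w <- w / mean(w)
  pair_idx <- utils::combn(n, 2)
  ww <- w[pair_idx[1, ]] * w[pair_idx[2, ]]
  cons <- vapply(seq_len(ncol_aa), function(col) {
    s <- sim(aa[pair_idx[1, ], col], aa[pair_idx[2, ], col])
    sum(ww * s) / sum(ww)
  }, numeric(1))
  out <- data.frame(column = seq_len(ncol_aa),
                    external_site = seq_len(ncol_aa) + as.integer(offset),
                    conservation = cons, variability = 1 - cons)
  attr(out, "weights") <- stats::setNames(w, names(align))
  class(out) <- c("residue_variability", "data.frame")
  out
}

#' Plot residue variability along the alignment
#'
#' @param x a [residue_variability()] result.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.residue_variability <- function(x, ...) {
  graphics::barplot(x$variability, names.arg = x$external_site,
                    xlab = "residue", ylab = "variability (1 - conservation)",
                    ...)
}
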