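# Independent oracles used to freeze expected values. These deliberately
# re-derive everything from first principles (plain DP, recursive
# enumeration, exhaustive search) rather than calling package internals.

# Plain unit-cost edit distance (exact character equality).
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  D <- matrix(0L, m + 1, n + 1)
  D[, 1] <- 0:m; D[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n)) {
    D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]), D[i, j + 1] + 1,
                           D[i + 1, j] + 1)
  }
  D[m + 1, n + 1]
}

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)
oracle_stops <- names(oracle_code)[oracle_code == "*"]

# Nei-Gojobori per-codon synonymous sites: fraction of the three possible
# changes at each position that preserve the amino acid (stops nonsyn).
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
    alt <- ch; alt[pos] <- b; alt <- paste(alt, collapse = "")
    if (!(alt %in% oracle_stops) &&
        oracle_code[[alt]] == oracle_code[[codon]]) s <- s + 1 / 3
  }
  s
}

# Recursive pathway enumeration between two codons: average (sd, nd) over
# all orderings of the differing positions, skipping orderings that visit a
# stop codon (all-orderings fallback when every one does).
oracle_path_counts <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  diffs <- which(ch1 != ch2)
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  recurse <- function(cur, remaining, allow_stops) {
    if (length(remaining) == 0) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      codon_next <- paste(nxt, collapse = "")
      if (!allow_stops && codon_next %in% oracle_stops) next
      aa_a <- if (paste(cur, collapse = "") %in% oracle_stops) "*"
              else oracle_code[[paste(cur, collapse = "")]]
      aa_b <- if (codon_next %in% oracle_stops) "*" else oracle_code[[codon_next]]
      step <- if (aa_a == aa_b) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      for (tail in recurse(nxt, setdiff(remaining, pos), allow_stops))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- recurse(ch1, diffs, allow_stops = FALSE)
  if (length(paths) == 0) paths <- recurse(ch1, diffs, allow_stops = TRUE)
  colMeans(do.call(rbind, paths))
}

# Exhaustive minimum number of breakpoints hitting all four-gamete
# incompatible open intervals of an alignment.
oracle_rm <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  states <- apply(m, 2, function(col) length(unique(col)))
  sites <- which(states == 2)
  if (length(sites) < 2) return(0L)
  lefts <- integer(0); rights <- integer(0)
  for (a in seq_along(sites)[-length(sites)]) {
    for (b in (a + 1):length(sites)) {
      g <- unique(paste0(m[, sites[a]], m[, sites[b]]))
      if (length(g) == 4) {
        lefts <- c(lefts, sites[a]); rights <- c(rights, sites[b])
      }
    }
  }
  if (length(lefts) == 0) return(0L)
  # candidate breakpoints: gap just left of each interval's right endpoint
  cands <- sort(unique(rights)) - 0.5
  for (k in seq_along(cands)) {
    for (pick in utils::combn(length(cands), k, simplify = FALSE)) {
      bp <- cands[pick]
      if (all(vapply(seq_along(lefts), function(t)
        any(bp > lefts[t] & bp < rights[t]), logical(1)))) return(k)
    }
  }
  length(cands)
}

random_codons <- function(n) {
  non_stop <- setdiff(names(oracle_code), oracle_stops)
  sample(non_stop, n, replace = TRUE)
}

# Random additive distance matrix from a random tree with positive branch
# lengths; returns the matrix and the generating ape tree.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# Demultiplexed-read data frame built directly from per-replicate variant
# count specs, for exercising the allele-calling filters in isolation.
demux_from_counts <- function(rep1, rep2, individual = "ind_001") {
  mk <- function(counts, rep) {
    if (length(counts) == 0) return(NULL)
    data.frame(read_id = paste0("r", rep, "_", seq_len(sum(counts))),
               individual = individual, replicate = rep,
               insert = rep(names(counts), counts), orientation = "fwd",
               stringsAsFactors = FALSE)
  }
  rbind(mk(rep1, 1L), mk(rep2, 2L))
}
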