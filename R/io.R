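#' Write statistics results to conventional files
#'
#' Writes whichever results are supplied into `dir` using the pipeline's
#' conventional layout: `dnds.json` + `dnds_pairs.tsv` for a
#' [nei_gojobori()] result, `variability.tsv` for [residue_variability()],
#' `rm.json` for [four_gamete_rm()], `geneconv.tsv` + `geneconv.json` for
#' [geneconv_scan()], and `ld.json` for [ld_randomization()]. JSON output
#' requires the jsonlite package.
#'
#' @param dir output directory (created if needed).
#' @param dnds,variability,rm,geneconv,ld optional results to write.
#' @return invisibly, the paths written.
#' @export
write_stats <- function(dir, dnds = NULL, variability = NULL, rm = NULL,
                        geneconv = NULL, ld = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- function(x, path) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON output requires the jsonlite package")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  tsv <- function(x, path) utils::write.table(x, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  paths <- character(0)
  if (!is.null(dnds)) {
    stopifnot(inherits(dnds, "dnds_result"))
    p1 <- file.path(dir, "dnds.json")
    json(dnds[c("dN", "dS", "var_dN", "var_dS", "Z", "p", "n_pairs",
                "n_excluded", "correction")], p1)
    p2 <- file.path(dir, "dnds_pairs.tsv")
    tsv(dnds$pairs, p2)
    paths <- c(paths, dnds = p1, dnds_pairs = p2)
  }
  if (!is.null(variability)) {
    stopifnot(inherits(variability, "residue_variability"))
    p <- file.path(dir, "variability.tsv")
    tsv(as.data.frame(variability), p)
    paths <- c(paths, variability = p)
  }
  if (!is.null(rm)) {
    stopifnot(inherits(rm, "rm_result"))
    p <- file.path(dir, "rm.json")
    json(list(rm = rm$rm, n_incompatible = rm$n_incompatible,
              intervals = rm$intervals), p)
    paths <- c(paths, rm = p)
  }
  if (!is.null(geneconv)) {
    stopifnot(inherits(geneconv, "geneconv_result"))
    p1 <- file.path(dir, "geneconv.json")
    json(list(tested = geneconv$tested, global_p = geneconv$global_p,
              sig_fraction = geneconv$sig_fraction,
              n_polymorphic = geneconv$n_polymorphic,
              n_permutations = geneconv$n_permutations), p1)
    paths <- c(paths, geneconv = p1)
    if (isTRUE(geneconv$tested)) {
      p2 <- file.path(dir, "geneconv.tsv")
      tsv(geneconv$fragments, p2)
      paths <- c(paths, geneconv_fragments = p2)
    }
  }
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "ld_result"))
    p <- file.path(dir, "ld.json")
    json(ld[c("tested", "rbarD", "IA", "p", "n_loci", "n_randomizations")], p)
    paths <- c(paths, ld = p)
  }
  invisible(paths)
}
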