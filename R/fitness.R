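#' @name fitness
#' @title Body condition and its quadratic association with MHC diversity
#' @description
#' Body condition is the residual of an ordinary least-squares regression
#' of curved carapace length (CCL) on curved carapace width (CCW) - a
#' size-corrected condition proxy, since larger female turtles lay larger
#' clutches. The association with individual MHC diversity is modelled as
#' condition ~ allele count + allele count^2; a negative quadratic
#' coefficient indicates an optimum at intermediate diversity.
NULL

#' Body condition from morphometrics
#'
#' OLS regression of CCL on CCW; the residuals are the condition proxy.
#'
#' @param table data frame with columns `individual`, `ccl`, `ccw`
#'   (centimetres; see [simulate_morphometrics()]).
#' @return named numeric vector of residuals (names = individual ids).
#' @export
body_condition <- function(table) {
  need <- c("individual", "ccl", "ccw")
  if (!all(need %in% names(table)))
    stop("morphometrics table needs columns: ", paste(need, collapse = ", "))
  if (nrow(table) < 3) stop("need at least 3 individuals")
  if (any(table$ccl <= 0) || any(table$ccw <= 0))
    stop("CCL and CCW must be positive")
  if (anyDuplicated(table$individual)) stop("duplicate individual ids")
  if (stats::var(table$ccw) == 0)
    stop("constant CCW: regression undefined")
  fit <- stats::lm(ccl ~ ccw, data = table)
  stats::setNames(stats::resid(fit), table$individual)
}

#' Quadratic fit of condition on allele count
#'
#' OLS of body condition on the individual allele count and its square
#' (raw, uncentred counts by default, so the printed equation reads
#' condition = b0 + b1 k + b2 k^2). Two-sided coefficient p-values.
#'
#' @param condition named numeric vector from [body_condition()].
#' @param allele_counts named positive integer vector of per-individual
#'   allele counts; matched to `condition` by name.
#' @param center center counts before squaring (off by default).
#' @return object of class `fitness_fit`: list with `coefficients`
#'   (estimate, std_error, t_value, p_value for intercept, linear,
#'   quadratic), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
quadratic_fit <- function(condition, allele_counts, center = FALSE) {
  stopifnot(all(allele_counts > 0), all(allele_counts == round(allele_counts)))
  if (!is.null(names(condition)) && !is.null(names(allele_counts))) {
    common <- intersect(names(condition), names(allele_counts))
    if (length(common) == 0) stop("no shared individual ids")
    condition <- condition[common]
    allele_counts <- allele_counts[common]
  } else if (length(condition) != length(allele_counts)) {
    stop("condition and allele_counts must pair up")
  }
  n <- length(condition)
  if (n < 4) stop("need at least 4 observations")
  k <- as.numeric(allele_counts)
  if (center) k <- k - mean(k)
  if (length(unique(k)) < 3)
    stop("allele counts collinear: need at least 3 distinct counts ",
         "to separate linear and quadratic terms")
  df <- data.frame(y = as.numeric(condition), k = k)
  fit <- stats::lm(y ~ k + I(k^2), data = df)
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t_value", "p_value")
  rownames(coefs) <- c("intercept", "linear", "quadratic")
  structure(list(coefficients = coefs, r_squared = sm$r.squared, n = n,
                 centered = center, fit = fit),
            class = "fitness_fit")
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat(sprintf("Condition ~ allele count + count^2 (n = %d%s):\n", x$n,
              if (x$centered) ", centered counts" else ""))
  print(round(x$coefficients, 4))
  cat(sprintf("R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
plot.fitness_fit <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d$k, d$y, xlab = "MHC allele count",
                 ylab = "body condition (CCL residual, cm)", ...)
  ks <- seq(min(d$k), max(d$k), length.out = 100)
  b <- x$coefficients$estimate
  graphics::lines(ks, b[1] + b[2] * ks + b[3] * ks^2)
  invisible(x)
}

#' Allele counts per individual from genotype calls
#'
#' @param calls a [call_genotypes()] result.
#' @return named integer vector (ungenotypable individuals dropped).
#' @export
allele_counts <- function(calls) {
  counts <- vapply(calls, function(g) nrow(g$alleles), integer(1))
  counts[counts > 0]
}
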