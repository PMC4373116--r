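#' 2x2 case-control allele count table for one SNP
#'
#' Counts allele copies (2 per subject) of the counted allele: `a` in cases,
#' `c` in controls, with `b = 2*n_case - a` and `d = 2*n_control - c` the
#' other-allele copies.
#'
#' @param g genotype column, entries in `{0, 1, 2}`.
#' @param y a [phenotype()] or binary vector (1 = case).
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
allele_table <- function(g, y) {
  y <- pheno_y(y)
  g <- as.numeric(g)
  if (length(g) != length(y)) stop("genotype and phenotype lengths differ")
  if (!all(g %in% c(0, 1, 2))) stop("genotypes must be 0, 1 or 2")
  a <- sum(g[y == 1L])
  cc <- sum(g[y == 0L])
  c(a = a, b = 2 * sum(y) - a, c = cc, d = 2 * sum(1 - y) - cc)
}

#' Squared chi-squared SNP weight
#'
#' The weight of a SNP is the square of its single-SNP allelic chi-squared
#' statistic:
#' `w = { (ad - bc)^2 (a+b+c+d) / [(a+b)(a+c)(c+d)(b+d)] }^2`.
#' If any margin of the 2x2 table is zero (monomorphic SNP or empty group)
#' the SNP carries no association signal and the weight is 0.
#'
#' @param tab named vector `c(a, b, c, d)` from [allele_table()].
#' @return Non-negative weight.
#' @export
chi2_weight <- function(tab) {
  a <- tab[["a"]]; b <- tab[["b"]]; cc <- tab[["c"]]; d <- tab[["d"]]
  n <- a + b + cc + d
  if (n <= 0) stop("all-zero allele table")
  den <- (a + b) * (a + cc) * (cc + d) * (b + d)
  if (den == 0) return(0)
  chi2 <- (a * d - b * cc)^2 * n / den
  chi2^2
}

#' Per-SNP weight vector
#'
#' Applies [chi2_weight()] to every column of a genotype matrix.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype()] or binary vector.
#' @return Numeric vector of non-negative weights, named by SNP id.
#' @export
weight_vector <- function(G, y) {
  g <- geno_mat(G)
  y <- pheno_y(y)
  if (nrow(g) != length(y)) stop("genotype and phenotype dimensions differ")
  a <- colSums(g * y)
  cc <- colSums(g * (1 - y))
  w <- weights_from_allele_counts(a, cc, sum(y), sum(1 - y))
  names(w) <- colnames(g)
  w
}

## Vectorised weight computation from counted-allele copies in cases (a) and
## controls (cc); a and cc may be matrices (SNP x permutation).
weights_from_allele_counts <- function(a, cc, n_case, n_control) {
  b <- 2 * n_case - a
  d <- 2 * n_control - cc
  n <- 2 * (n_case + n_control)
  den <- (2 * n_case) * (a + cc) * (2 * n_control) * (b + d)
  chi2 <- (a * d - b * cc)^2 * n / ifelse(den == 0, 1, den)
  chi2[den == 0] <- 0
  chi2^2
}
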