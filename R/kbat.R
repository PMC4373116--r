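## Kernel-based association test (KBAT): allele-match kernel U-statistics,
## within/between sum-of-squares decomposition, ratio statistic, permutation
## p-values.  All heavy paths work from per-group genotype-category counts,
## never from explicit O(n^2) pair loops.

## allele-match kernel values h(g1, g2) and their squares, indexed g+1
AM_TABLE <- matrix(c(1, 0.5, 0,
                     0.5, 0.5, 0.5,
                     0, 0.5, 1), 3L, 3L, byrow = TRUE)

#' Allele-match kernel between two genotypes
#'
#' Writing each additive genotype as an unordered allele pair, the kernel is
#' the fraction of the four allele cross-comparisons that match:
#' `h(0,0) = h(2,2) = 1`, `h(0,2) = 0`, and `h = 0.5` whenever a heterozygote
#' is involved.  Symmetric and invariant to flipping the allele coding of
#' both arguments.
#'
#' @param g1,g2 genotype codes in `{0, 1, 2}` (vectorised).
#' @return Kernel values in `[0, 1]`.
#' @export
am_kernel <- function(g1, g2) {
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2))
    stop("genotype codes must be 0, 1 or 2")
  AM_TABLE[cbind(g1 + 1L, g2 + 1L)]
}

## Sum over unordered within-group pairs of h and h^2, from genotype-category
## counts.  n0, n1, n2 may be matrices (SNP x replicate-permutation).
pair_kernel_sums <- function(n0, n1, n2) {
  sum_h  <- n0 * (n0 - 1) / 2 + n2 * (n2 - 1) / 2 +
    n1 * (n1 - 1) / 4 + (n0 * n1 + n1 * n2) / 2
  sum_h2 <- n0 * (n0 - 1) / 2 + n2 * (n2 - 1) / 2 +
    0.25 * (n1 * (n1 - 1) / 2 + n0 * n1 + n1 * n2)
  list(h = sum_h, h2 = sum_h2)
}

## Core decomposition from count matrices: counts per genotype category in
## cases (c0, c1, c2; SNP x R) and totals per category (t0, t1, t2; length p).
kbat_from_counts <- function(c0, c1, c2, t0, t1, t2, n_case, n_control) {
  m1 <- n_case * (n_case - 1) / 2
  m2 <- n_control * (n_control - 1) / 2
  s_case <- pair_kernel_sums(c0, c1, c2)
  s_ctrl <- pair_kernel_sums(t0 - c0, t1 - c1, t2 - c2)
  U1 <- s_case$h / m1
  U2 <- s_ctrl$h / m2
  Ubar <- (U1 + U2) / 2
  W <- (s_case$h2 - m1 * U1^2) + (s_ctrl$h2 - m2 * U2^2)
  B <- m1 * (U1 - Ubar)^2 + m2 * (U2 - Ubar)^2
  list(U1 = U1, U2 = U2, Ubar = Ubar, W = pmax(W, 0), B = B,
       m1 = m1, m2 = m2)
}

genotype_indicators <- function(g) {
  list(d0 = (g == 0L) * 1, d1 = (g == 1L) * 1, d2 = (g == 2L) * 1)
}

#' Within/between kernel-score decomposition per SNP
#'
#' For each SNP `k` and group `l` (cases, controls), `U_l` is the mean
#' pairwise allele-match kernel within the group over its
#' `m_l = n_l (n_l - 1) / 2` pairs; `W_k` is the sum over both groups of
#' squared deviations of pair scores from their group mean, and
#' `B_k = sum_l m_l (U_l - U)^2` with `U = (U_1 + U_2) / 2` is the
#' between-group sum of squares.  Computed in O(n) per SNP from
#' genotype-category counts.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype()] or binary vector; each group needs >= 2 subjects.
#' @return An object of class `kbat_decomposition`: list with per-SNP vectors
#'   `U1`, `U2`, `Ubar`, `W`, `B` and pair counts `m1`, `m2`.
#' @export
kbat_decompose <- function(G, y) {
  g <- geno_mat(G)
  y <- pheno_y(y)
  if (nrow(g) != length(y)) stop("genotype and phenotype dimensions differ")
  n_case <- sum(y); n_control <- sum(1 - y)
  if (n_case < 2L || n_control < 2L)
    stop("each group needs at least 2 subjects")
  d <- genotype_indicators(g)
  c0 <- colSums(d$d0 * y); c1 <- colSums(d$d1 * y); c2 <- colSums(d$d2 * y)
  dec <- kbat_from_counts(c0, c1, c2,
                          colSums(d$d0), colSums(d$d1), colSums(d$d2),
                          n_case, n_control)
  structure(dec, class = "kbat_decomposition", snp_ids = colnames(g))
}

#' KBAT ratio statistic
#'
#' Unweighted: `sum_k B_k / sum_k W_k`.  Weighted: both sums are weighted
#' per SNP, `sum_k w_k B_k / sum_k w_k W_k`, which keeps the statistic
#' invariant to rescaling all weights.
#'
#' @param dec a [kbat_decompose()] result.
#' @param w optional non-negative weight vector (one per SNP); `NULL` for the
#'   unweighted statistic.
#' @return The statistic value.
#' @export
kbat_statistic <- function(dec, w = NULL) {
  if (is.null(w)) w <- rep(1, length(dec$W))
  if (length(w) != length(dec$W)) stop("weight length must match SNP count")
  if (any(w < 0)) stop("weights must be non-negative")
  den <- sum(w * dec$W)
  if (den <= 0) stop("degenerate SNP-set: zero within-group kernel variance")
  sum(w * dec$B) / den
}

## n x (n_perm) matrix of permuted labels
perm_label_matrix <- function(y, n_perm) {
  vapply(seq_len(n_perm), function(r) sample(y), numeric(length(y)))
}

#' KBAT permutation test
#'
#' Computes the observed (optionally chi-squared-weighted) KBAT statistic and
#' a permutation p-value: phenotype labels are permuted uniformly, the
#' statistic — including the weights, which depend on the labels — is
#' recomputed for every permutation, and the add-one estimator
#' `p = (1 + #\{T_r >= T_0\}) / (n_perm + 1)` is reported.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype()] or binary vector.
#' @param weighted use the squared chi-squared SNP weights of
#'   [weight_vector()]?
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return An object of class `snpset_test` with elements `statistic`,
#'   `p.value`, `method`, `n_perm`.
#' @export
kbat_test <- function(G, y, weighted = FALSE, n_perm = 999L, seed = NULL) {
  g <- geno_mat(G)
  y <- pheno_y(y)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  Y <- cbind(y, perm_label_matrix(y, n_perm))
  stat <- kbat_stats_batch(g, Y, weighted = weighted)
  new_snpset_test(stat[1L], perm_pvalue(stat),
                  method = paste0(if (weighted) "weighted ", "KBAT"),
                  n_perm = n_perm)
}

## KBAT statistics for every column of a label matrix Y (observed labels
## first); returns a vector of statistics.  Used by kbat_test and the
## replicate harness (which shares one Y across all method variants).
kbat_stats_batch <- function(g, Y, weighted = FALSE, subset = NULL) {
  n_case <- sum(Y[, 1L]); n_control <- nrow(Y) - n_case
  d <- genotype_indicators(g)
  c0 <- crossprod(d$d0, Y); c1 <- crossprod(d$d1, Y); c2 <- crossprod(d$d2, Y)
  dec <- kbat_from_counts(c0, c1, c2,
                          colSums(d$d0), colSums(d$d1), colSums(d$d2),
                          n_case, n_control)
  w <- if (weighted)
    weights_from_allele_counts(c1 + 2 * c2,
                               (colSums(d$d1) - c1) + 2 * (colSums(d$d2) - c2),
                               n_case, n_control)
  else 1
  B <- w * dec$B
  W <- w * dec$W
  if (!is.null(subset)) {
    B <- B[subset, , drop = FALSE]
    W <- W[subset, , drop = FALSE]
  }
  colSums(as.matrix(B)) / colSums(as.matrix(W))
}

## add-one permutation p-value; stat[1] is observed, the rest permuted.
## Non-finite permuted statistics are never counted as exceedances.
perm_pvalue <- function(stat) {
  t0 <- stat[1L]
  if (!is.finite(t0)) stop("degenerate SNP-set: observed statistic undefined")
  (1 + sum(stat[-1L] >= t0, na.rm = TRUE)) / length(stat)
}

new_snpset_test <- function(statistic, p.value, method, n_perm = NULL,
                            null_params = NULL) {
  structure(list(statistic = unname(statistic), p.value = unname(p.value),
                 method = method, n_perm = n_perm, null_params = null_params),
            class = "snpset_test")
}

#' @export
print.snpset_test <- function(x, ...) {
  cat("\n\tSNP-set association test:", x$method, "\n\n")
  cat("statistic =", format(x$statistic, digits = 6),
      ", p-value =", format(x$p.value, digits = 4), "\n")
  if (!is.null(x$n_perm))
    cat("p-value from", x$n_perm, "label permutations (add-one estimator)\n")
  if (!is.null(x$null_params))
    cat(sprintf("analytic null: scaled chi-squared, kappa = %.4g, nu = %.4g\n",
                x$null_params[["kappa"]], x$null_params[["nu"]]))
  invisible(x)
}
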