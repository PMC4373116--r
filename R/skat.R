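## Sequence kernel association test (SKAT): logistic null model, weighted
## linear kernel, Q statistic, Satterthwaite scaled-chi-squared analytic null,
## and a permutation fallback used by default for data-dependent weights.

#' Fit the logistic null model
#'
#' Maximum-likelihood logistic regression of the binary phenotype on an
#' intercept plus any covariates (no genotypes).  With no covariates the
#' fitted probability is the case fraction for every subject.
#'
#' @param y a [phenotype()] (its `covariates`, if any, enter the model) or a
#'   binary vector.
#' @return An object of class `skat_null_model`: list with fitted
#'   probabilities `p0`, coefficients `alpha`, design matrix `X` and `y`.
#' @export
fit_null_logistic <- function(y) {
  ph <- as_phenotype(y)
  X <- cbind(`(Intercept)` = rep(1, length(ph$y)), ph$covariates)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  fit <- stats::glm.fit(X, ph$y, family = stats::binomial(),
                        control = list(epsilon = 1e-8, maxit = 50L))
  if (!fit$converged) stop("logistic null model did not converge (separation?)")
  p0 <- fit$fitted.values
  if (any(p0 <= 0) || any(p0 >= 1))
    stop("logistic null model fitted probabilities degenerate (separation?)")
  structure(list(p0 = p0, alpha = fit$coefficients, X = X, y = ph$y),
            class = "skat_null_model")
}

#' @export
print.skat_null_model <- function(x, ...) {
  cat("SKAT logistic null model:", length(x$y), "subjects,",
      ncol(x$X) - 1L, "covariate(s)\n")
  print(x$alpha)
  invisible(x)
}

#' Weighted linear SKAT kernel
#'
#' `K = G diag(w) G'` with additive genotypes `G`; unweighted when `w` is
#' `NULL`.  Symmetric positive semidefinite.
#'
#' @param G a [genotype_matrix()].
#' @param w optional non-negative SNP weight vector.
#' @return An `n x n` kernel matrix.
#' @export
skat_kernel <- function(G, w = NULL) {
  g <- geno_mat(G)
  if (is.null(w)) return(tcrossprod(g))
  if (length(w) != ncol(g)) stop("weight length must match SNP count")
  if (any(w < 0)) stop("weights must be non-negative")
  tcrossprod(g * rep(sqrt(w), each = nrow(g)))   # G diag(w) G'
}

#' SKAT Q statistic
#'
#' `Q = (y - p0)' K (y - p0) / 2`, the variance-component score statistic of
#' the logistic kernel-machine model; non-negative for PSD kernels.
#'
#' @param K kernel matrix from [skat_kernel()].
#' @param y a [phenotype()] or binary vector.
#' @param null a [fit_null_logistic()] result.
#' @return The Q value.
#' @export
q_statistic <- function(K, y, null) {
  r <- pheno_y(y) - null$p0
  drop(crossprod(r, K %*% r)) / 2
}

#' Satterthwaite moments of the SKAT null distribution
#'
#' Under the null, Q is approximated by `kappa * chisq(nu)` with the scale
#' and degrees of freedom chosen by two-moment matching: with
#' `V = diag(p0 (1 - p0))` and the projected variance
#' `P0 = V - V X (X' V X)^{-1} X' V`, the null mean and variance of Q are
#' `mu = tr(P0 K) / 2` and `sigma2 = tr(P0 K P0 K) / 2`, giving
#' `kappa = sigma2 / (2 mu)` and `nu = 2 mu^2 / sigma2` (so `kappa nu = mu`
#' and `2 kappa^2 nu = sigma2`).
#'
#' @param K kernel matrix.
#' @param null a [fit_null_logistic()] result.
#' @return An object of class `skat_null` with `kappa`, `nu`, `mu`, `sigma2`.
#' @export
skat_null_moments <- function(K, null) {
  v <- null$p0 * (1 - null$p0)
  X <- null$X
  VX <- v * X
  P0 <- diag(v) - VX %*% solve(crossprod(X, VX), t(VX))
  PK <- P0 %*% K
  mu <- sum(diag(PK)) / 2
  sigma2 <- sum(PK * t(PK)) / 2
  if (mu <= 0 || sigma2 <= 0) stop("degenerate null: kernel carries no variance")
  structure(list(kappa = sigma2 / (2 * mu), nu = 2 * mu^2 / sigma2,
                 mu = mu, sigma2 = sigma2), class = "skat_null")
}

## p-space moments for the linear kernel K = G diag(w) G': identical to
## skat_null_moments(skat_kernel(G, w), null) but O(n p^2) instead of O(n^3).
## A = G' P0 G is computed without forming the n x n projector.
skat_moments_linear <- function(g, w, null) {
  v <- null$p0 * (1 - null$p0)
  X <- null$X
  VG <- v * g
  XtVG <- crossprod(X, VG)
  A <- crossprod(g, VG) - crossprod(XtVG, solve(crossprod(X, v * X), XtVG))
  WA <- if (is.null(w)) A else w * A
  mu <- sum(diag(WA)) / 2
  sigma2 <- sum(WA * t(WA)) / 2
  if (mu <= 0 || sigma2 <= 0) stop("degenerate null: kernel carries no variance")
  list(kappa = sigma2 / (2 * mu), nu = 2 * mu^2 / sigma2,
       mu = mu, sigma2 = sigma2)
}

skat_analytic_pvalue <- function(Q, mom) {
  stats::pchisq(Q / mom$kappa, df = mom$nu, lower.tail = FALSE)
}

#' SKAT association test
#'
#' Unweighted SKAT uses the analytic scaled-chi-squared null by default.
#' Weighted SKAT (squared chi-squared weights, which depend on the phenotype)
#' defaults to a permutation p-value, since data-dependent weights invalidate
#' the analytic null; each permutation refits the intercept-only null on the
#' permuted labels and recomputes the weights.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype()] or binary vector.
#' @param weighted use [weight_vector()] weights?
#' @param pvalue `"analytic"` or `"permutation"`; default analytic for
#'   unweighted, permutation for weighted.
#' @param n_perm permutations for the permutation path (default 999).
#' @param seed optional integer seed.
#' @return An object of class `snpset_test`.
#' @export
skat_test <- function(G, y, weighted = FALSE,
                      pvalue = if (weighted) "permutation" else "analytic",
                      n_perm = 999L, seed = NULL) {
  pvalue <- match.arg(pvalue, c("analytic", "permutation"))
  g <- geno_mat(G)
  ph <- as_phenotype(y)
  null <- fit_null_logistic(ph)
  w <- if (weighted) weight_vector(g, ph) else NULL
  s <- crossprod(g, ph$y - null$p0)           # score vector G'(y - p0)
  Q <- 0.5 * sum((if (is.null(w)) 1 else w) * s^2)
  method <- paste0(if (weighted) "weighted ", "SKAT (", pvalue, ")")
  if (pvalue == "analytic") {
    mom <- skat_moments_linear(g, w, null)
    return(new_snpset_test(Q, skat_analytic_pvalue(Q, mom), method,
                           null_params = c(kappa = mom$kappa, nu = mom$nu)))
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  Y <- cbind(ph$y, perm_label_matrix(ph$y, n_perm))
  stat <- skat_stats_batch(g, Y, weighted = weighted)
  new_snpset_test(stat[1L], perm_pvalue(stat), method, n_perm = n_perm)
}

## Q statistics for every column of a label matrix (observed first), under
## the intercept-only null (p0 = mean(y), unchanged by permutation).
skat_stats_batch <- function(g, Y, weighted = FALSE, subset = NULL) {
  p0 <- mean(Y[, 1L])
  S <- crossprod(g, Y - p0)                   # p x (R+1) score vectors
  if (weighted) {
    n_case <- sum(Y[, 1L]); n_control <- nrow(Y) - n_case
    d <- genotype_indicators(g)
    c1 <- crossprod(d$d1, Y); c2 <- crossprod(d$d2, Y)
    w <- weights_from_allele_counts(c1 + 2 * c2,
                                    (colSums(d$d1) - c1) + 2 * (colSums(d$d2) - c2),
                                    n_case, n_control)
  } else w <- 1
  Q <- w * S^2
  if (!is.null(subset)) Q <- Q[subset, , drop = FALSE]
  0.5 * colSums(as.matrix(Q))
}
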