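## Replicate-level orchestration: type-I error and power estimation for the
## eight test variants, the four-SNP-set comparison, and the threshold study.
## All randomness flows from one master seed; replicate r's stream depends
## only on (seed, r), so replicates could be evaluated in any order.

#' The eight test variants
#'
#' `kbat`/`skat` on the original SNP-set, `*-tag` on the tag SNP-set, and
#' `w*` for the chi-squared-weighted versions.
#' @export
METHOD_VARIANTS <- c("kbat", "kbat-tag", "wkbat", "wkbat-tag",
                     "skat", "skat-tag", "wskat", "wskat-tag")

replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(r) * 7919) %% 2147483629) + 1L
}

#' Run one SNP-set association test
#'
#' Convenience dispatcher over [kbat_test()] and [skat_test()], optionally
#' restricting the genotype columns to a tag SNP-set first.
#'
#' @param G a [genotype_matrix()].
#' @param y a [phenotype()] or binary vector.
#' @param method `"kbat"` or `"skat"`.
#' @param weighted use squared chi-squared SNP weights?
#' @param tags optional [select_tags()] result or integer column indices;
#'   when given, the test runs on the tag columns only.
#' @param n_perm permutations for permutation p-values.
#' @param seed optional integer seed.
#' @param ... passed on to the underlying test (e.g. `pvalue=` for SKAT).
#' @return An object of class `snpset_test`.
#' @export
assoc_test <- function(G, y, method = c("kbat", "skat"), weighted = FALSE,
                       tags = NULL, n_perm = 999L, seed = NULL, ...) {
  method <- match.arg(method)
  g <- geno_mat(G)
  if (!is.null(tags)) {
    idx <- if (inherits(tags, "tag_set")) tags$tags else as.integer(tags)
    if (length(idx) && (min(idx) < 1L || max(idx) > ncol(g)))
      stop("tag index out of range")
    g <- g[, idx, drop = FALSE]
  }
  res <- if (method == "kbat")
    kbat_test(g, y, weighted = weighted, n_perm = n_perm, seed = seed, ...)
  else
    skat_test(g, y, weighted = weighted, n_perm = n_perm, seed = seed, ...)
  if (!is.null(tags)) res$method <- paste0(res$method, " [tag SNP-set]")
  res
}

## p-values for all requested variants on one replicate, sharing one
## permutation label matrix (so variant comparisons are paired) and one set
## of genotype-category count matrices.
all_method_pvalues <- function(g, y, tag_idx, methods, n_perm) {
  Y <- cbind(y, perm_label_matrix(y, n_perm))
  n_case <- sum(y); n_control <- length(y) - n_case
  d <- genotype_indicators(g)
  t0 <- colSums(d$d0); t1 <- colSums(d$d1); t2 <- colSums(d$d2)
  need_counts <- any(methods %in% c("kbat", "kbat-tag", "wkbat", "wkbat-tag",
                                    "wskat", "wskat-tag"))
  if (need_counts) {
    c0 <- crossprod(d$d0, Y); c1 <- crossprod(d$d1, Y); c2 <- crossprod(d$d2, Y)
    w <- weights_from_allele_counts(c1 + 2 * c2,
                                    (t1 - c1) + 2 * (t2 - c2),
                                    n_case, n_control)
  }
  out <- stats::setNames(rep(NA_real_, length(methods)), methods)
  kb <- intersect(methods, c("kbat", "kbat-tag", "wkbat", "wkbat-tag"))
  if (length(kb)) {
    dec <- kbat_from_counts(c0, c1, c2, t0, t1, t2, n_case, n_control)
    for (m in kb) {
      wm <- if (m %in% c("wkbat", "wkbat-tag")) w else 1
      B <- wm * dec$B; W <- wm * dec$W
      if (grepl("-tag$", m)) {
        B <- B[tag_idx, , drop = FALSE]; W <- W[tag_idx, , drop = FALSE]
      }
      out[m] <- perm_pvalue(colSums(as.matrix(B)) / colSums(as.matrix(W)))
    }
  }
  if (any(c("skat", "skat-tag") %in% methods)) {
    null <- list(p0 = rep(mean(y), length(y)),
                 X = matrix(1, length(y), 1L), y = y)
    s <- crossprod(g, y - mean(y))
    v <- mean(y) * (1 - mean(y))
    gc <- sweep(g, 2L, colMeans(g))
    A <- v * crossprod(gc)
    for (m in intersect(methods, c("skat", "skat-tag"))) {
      idx <- if (m == "skat-tag") tag_idx else seq_len(ncol(g))
      Ai <- A[idx, idx, drop = FALSE]
      mu <- sum(diag(Ai)) / 2
      sigma2 <- sum(Ai * Ai) / 2
      Q <- 0.5 * sum(s[idx]^2)
      out[m] <- stats::pchisq(Q / (sigma2 / (2 * mu)), df = 2 * mu^2 / sigma2,
                              lower.tail = FALSE)
    }
  }
  ws <- intersect(methods, c("wskat", "wskat-tag"))
  if (length(ws)) {
    S <- crossprod(g, Y - mean(y))
    Qm <- w * S^2
    for (m in ws) {
      Qi <- if (m == "wskat-tag") Qm[tag_idx, , drop = FALSE] else Qm
      out[m] <- perm_pvalue(0.5 * colSums(as.matrix(Qi)))
    }
  }
  out
}

## Shared replicate loop.  Returns an n_replicates x methods p-value matrix.
run_replicates <- function(name, spec, methods, n_replicates, n_perm, seed,
                           t = 0.9, n_case = 500L, n_control = 500L,
                           causal = NULL, mask_causal = FALSE,
                           rr_het = 1.25, rr_hom = 1.5, baseline_risk = 0.1) {
  stopifnot(all(methods %in% METHOD_VARIANTS))
  P <- matrix(NA_real_, n_replicates, length(methods),
              dimnames = list(NULL, methods))
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    sc <- make_scenario(name, spec, causal = causal,
                        mask_causal = mask_causal, rr_het = rr_het,
                        rr_hom = rr_hom, baseline_risk = baseline_risk)
    dat <- simulate_case_control(sc$panel, sc$model, n_case, n_control)
    g <- dat$genotypes$genotypes[, sc$genotyped, drop = FALSE]
    sub <- haplotype_panel(sc$tag_haplotypes$alleles[, sc$genotyped, drop = FALSE],
                           sc$tag_haplotypes$snp_ids[sc$genotyped])
    poly <- drop_monomorphic(sub, quiet = TRUE)
    ts <- select_tags(poly, t = t)
    tag_idx <- attr(poly, "kept")[ts$tags]
    P[r, ] <- all_method_pvalues(g, dat$phenotype$y, tag_idx, methods, n_perm)
  }
  P
}

#' Empirical type-I error of the test variants
#'
#' Simulates null-model case-control replicates, selects tags per replicate
#' from that replicate's reserved 200-haplotype subsample, runs the requested
#' variants and reports rejection fractions at each significance level with
#' binomial standard errors.
#'
#' @param methods subset of [METHOD_VARIANTS].
#' @param n_replicates number of null replicates.
#' @param alpha_levels significance levels (default 0.05 and 0.01).
#' @param n_perm permutations per permutation test (default 199).
#' @param seed master integer seed; replicate `r` depends only on
#'   `(seed, r)`.
#' @param spec a [panel_spec()].
#' @param t tag-selection r-squared threshold.
#' @param n_case,n_control group sizes (defaults 500/500).
#' @return A data.frame with columns `method`, `alpha`, `estimate`, `se`,
#'   `n_replicates`; the per-replicate p-value matrix is kept in attribute
#'   `"pvalues"`.
#' @export
run_calibration <- function(methods = METHOD_VARIANTS, n_replicates = 500L,
                            alpha_levels = c(0.05, 0.01), n_perm = 199L,
                            seed = 1L, spec = panel_spec(), t = 0.9,
                            n_case = 500L, n_control = 500L) {
  P <- run_replicates("null", spec, methods, n_replicates, n_perm, seed,
                      t = t, n_case = n_case, n_control = n_control)
  summarize_rejections(P, alpha_levels)
}

#' Empirical power of the test variants
#'
#' Same replicate loop as [run_calibration()] under a causal disease model.
#'
#' @inheritParams run_calibration
#' @param scenario `"one_causal"` or `"two_causal"`.
#' @param alpha significance level for the power estimate.
#' @param causal explicit causal indices or `NULL` to draw per replicate.
#' @param mask_causal drop causal SNPs from the genotyped set (ungenotyped
#'   causal scenario)?
#' @param rr_het,rr_hom,baseline_risk disease-model parameters.
#' @return As [run_calibration()], with one row per method at `alpha`.
#' @export
run_power <- function(methods = METHOD_VARIANTS, n_replicates = 500L,
                      scenario = c("one_causal", "two_causal"),
                      alpha = 0.05, n_perm = 199L, seed = 1L,
                      spec = panel_spec(), t = 0.9,
                      n_case = 500L, n_control = 500L, causal = NULL,
                      mask_causal = FALSE, rr_het = 1.25, rr_hom = 1.5,
                      baseline_risk = 0.1) {
  scenario <- match.arg(scenario)
  P <- run_replicates(scenario, spec, methods, n_replicates, n_perm, seed,
                      t = t, n_case = n_case, n_control = n_control,
                      causal = causal, mask_causal = mask_causal,
                      rr_het = rr_het, rr_hom = rr_hom,
                      baseline_risk = baseline_risk)
  summarize_rejections(P, alpha)
}

summarize_rejections <- function(P, alpha_levels) {
  n <- nrow(P)
  out <- do.call(rbind, lapply(alpha_levels, function(a) {
    est <- colMeans(P <= a, na.rm = TRUE)
    data.frame(method = colnames(P), alpha = a, estimate = est,
               se = sqrt(est * (1 - est) / n), n_replicates = n,
               row.names = NULL)
  }))
  attr(out, "pvalues") <- P
  out
}

#' Compare weighted SKAT across four SNP-set choices
#'
#' Per causal replicate, runs weighted SKAT (permutation p-values) on four
#' column subsets: the original SNP-set, the selected tag SNP-set, the
#' complement of the tag set ("untag") and a random subset matched in size
#' to the tag set (drawn fresh each replicate).
#'
#' @inheritParams run_power
#' @return A data.frame with rejection fractions per SNP-set at `alpha`;
#'   per-replicate p-values in attribute `"pvalues"`.
#' @export
compare_snp_sets <- function(n_replicates = 300L,
                             scenario = c("two_causal", "one_causal"),
                             alpha = 0.05, n_perm = 199L, seed = 1L,
                             spec = panel_spec(), t = 0.9,
                             n_case = 500L, n_control = 500L, causal = NULL,
                             rr_het = 1.25, rr_hom = 1.5,
                             baseline_risk = 0.1) {
  scenario <- match.arg(scenario)
  sets <- c("original", "tag", "untag", "random")
  P <- matrix(NA_real_, n_replicates, 4L, dimnames = list(NULL, sets))
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    sc <- make_scenario(scenario, spec, causal = causal, rr_het = rr_het,
                        rr_hom = rr_hom, baseline_risk = baseline_risk)
    dat <- simulate_case_control(sc$panel, sc$model, n_case, n_control)
    g <- dat$genotypes$genotypes
    poly <- drop_monomorphic(sc$tag_haplotypes, quiet = TRUE)
    ts <- select_tags(poly, t = t)
    tag_idx <- attr(poly, "kept")[ts$tags]
    untag <- setdiff(seq_len(ncol(g)), tag_idx)   # may be empty at t = 1
    rnd <- sort(sample.int(ncol(g), length(tag_idx)))
    y <- dat$phenotype$y
    Y <- cbind(y, perm_label_matrix(y, n_perm))
    d <- genotype_indicators(g)
    c1 <- crossprod(d$d1, Y); c2 <- crossprod(d$d2, Y)
    w <- weights_from_allele_counts(
      c1 + 2 * c2, (colSums(d$d1) - c1) + 2 * (colSums(d$d2) - c2),
      sum(y), length(y) - sum(y))
    S <- crossprod(g, Y - mean(y))
    Qm <- w * S^2
    subsets <- list(original = seq_len(ncol(g)), tag = tag_idx,
                    untag = untag, random = rnd)
    P[r, ] <- vapply(subsets, function(idx) {
      if (!length(idx)) return(NA_real_)
      perm_pvalue(0.5 * colSums(Qm[idx, , drop = FALSE]))
    }, numeric(1))
  }
  out <- summarize_rejections(P, alpha)
  names(out)[1] <- "snp_set"
  out
}

#' Tag count and within-cluster LD across thresholds
#'
#' @param panel a [haplotype_panel()] without monomorphic columns.
#' @param t_values thresholds to sweep.
#' @return A data.frame with columns `t`, `n_tags` and
#'   `mean_within_r2` (mean off-diagonal r-squared over within-cluster SNP
#'   pairs; `NA` when every cluster is a singleton).  `n_tags` is
#'   non-decreasing in `t`.
#' @export
threshold_sweep <- function(panel, t_values = seq(0, 1, by = 0.1)) {
  panel <- as_haplotype_panel(panel)
  r2 <- ld_r2_matrix(panel)
  rows <- lapply(t_values, function(t) {
    blocks <- partition_components(threshold_adjacency(r2, t))
    prs <- unlist(lapply(blocks, function(b) {
      if (length(b) < 2L) return(NULL)
      r2[b, b][upper.tri(matrix(0, length(b), length(b)))]
    }))
    data.frame(t = t, n_tags = length(blocks),
               mean_within_r2 = if (length(prs)) mean(prs) else NA_real_)
  })
  do.call(rbind, rows)
}
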