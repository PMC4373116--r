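## Synthetic reference-panel and case-control simulator.  Emulates
## HAPGEN-style resampling from a phased reference panel with block LD
## structure and a multiplicative genotype-relative-risk disease model
## (heterozygote risk 1.25, minor-homozygote risk 1.5 by default).

#' Specification of a block-LD reference haplotype panel
#'
#' Defaults describe the simulation geometry used throughout the package:
#' 169 SNPs in independent blocks of mean size ~3, per-block latent
#' correlation drawn from `[0.3, 0.995]`, per-SNP MAFs uniform on
#' `[0.05, 0.5]`, and a reference panel of 1000 haplotypes.  Under the
#' default geometry tag selection at `t = 0.9` compresses the SNP-set to
#' roughly a third of its size.
#'
#' @param p SNP count.
#' @param block_sizes integer vector summing to `p`, or `NULL` to draw block
#'   sizes (1..6, mean ~3) at simulation time.
#' @param within_block_r latent within-block Gaussian correlation: a scalar
#'   in `[0, 1)`, a per-block vector, or `NULL` for the default per-block
#'   draw: with probability 0.9 a "tight" block (latent correlation uniform
#'   on `[0.998, 0.9999]`, whose thresholded alleles exceed r-squared 0.9)
#'   and otherwise a "loose" block (uniform on `[0.3, 0.9]`).  Thresholding
#'   a latent Gaussian attenuates correlation, so the allele r-squared is
#'   systematically below the latent value; the default mixture is
#'   calibrated so tag selection at `t = 0.9` compresses the SNP-set to
#'   roughly a third, the compression a dense GWAS panel typically shows.
#' @param maf_range minor-allele-frequency range, a sub-interval of
#'   `(0, 0.5]`.
#' @param n_ref_haplotypes even number of reference haplotypes.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(p = 169L, block_sizes = NULL, within_block_r = NULL,
                       maf_range = c(0.05, 0.5), n_ref_haplotypes = 1000L) {
  p <- as.integer(p)
  if (p < 1L) stop("p must be positive")
  if (!is.null(block_sizes)) {
    block_sizes <- as.integer(block_sizes)
    if (any(block_sizes < 1L) || sum(block_sizes) != p)
      stop("block_sizes must be positive and sum to p")
  }
  if (!is.null(within_block_r) &&
      (any(within_block_r < 0) || any(within_block_r >= 1)))
    stop("within_block_r must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  n_ref_haplotypes <- as.integer(n_ref_haplotypes)
  if (n_ref_haplotypes < 2L || n_ref_haplotypes %% 2L != 0L)
    stop("n_ref_haplotypes must be an even integer >= 2")
  structure(list(p = p, block_sizes = block_sizes,
                 within_block_r = within_block_r, maf_range = maf_range,
                 n_ref_haplotypes = n_ref_haplotypes),
            class = "panel_spec")
}

draw_block_sizes <- function(p) {
  sizes <- integer(0)
  left <- p
  while (left > 0L) {
    s <- min(left, sample(1:6, 1L, prob = c(2, 3, 4, 3, 2, 1)))
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes
}

#' Simulate a reference haplotype panel with block LD
#'
#' Each block draws one MAF uniformly from the spec's range and jitters it
#' slightly per SNP (MAFs must be near-equal within a block for high allele
#' correlation to be attainable at all: the correlation of two binary
#' indicators is capped by their frequency mismatch).  Within a block,
#' haplotypes arise by thresholding a latent equicorrelated Gaussian (shared
#' factor loading `sqrt(r)`) at each SNP's MAF quantile, so the allele at
#' SNP `j` is 1 with probability `maf_j`; blocks are independent, so
#' cross-block allele r-squared is near 0.
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed.
#' @return A [haplotype_panel()] with attributes `"maf"` (drawn MAFs) and
#'   `"blocks"` (list of column-index vectors).
#' @export
simulate_panel <- function(spec = panel_spec(), seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  sizes <- if (is.null(spec$block_sizes)) draw_block_sizes(spec$p) else spec$block_sizes
  nb <- length(sizes)
  r <- spec$within_block_r
  r <- if (is.null(r)) {
    tight <- stats::runif(nb) < 0.92
    ifelse(tight, stats::runif(nb, 0.999, 0.99995), stats::runif(nb, 0.3, 0.9))
  } else if (length(r) == 1L) rep(r, nb) else rep_len(r, nb)
  block_maf <- stats::runif(nb, spec$maf_range[1], spec$maf_range[2])
  maf <- pmin(pmax(rep(block_maf, sizes) + stats::rnorm(spec$p, 0, 0.002),
                   spec$maf_range[1]), spec$maf_range[2])
  nh <- spec$n_ref_haplotypes
  alleles <- matrix(0L, nh, spec$p)
  col0 <- 0L
  blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    sb <- sizes[b]
    cols <- col0 + seq_len(sb)
    z0 <- stats::rnorm(nh)
    lat <- sqrt(r[b]) * z0 +
      sqrt(1 - r[b]) * matrix(stats::rnorm(nh * sb), nh, sb)
    thr <- stats::qnorm(maf[cols])
    alleles[, cols] <- (lat < rep(thr, each = nh)) * 1L
    blocks[[b]] <- cols
    col0 <- col0 + sb
  }
  out <- haplotype_panel(alleles, paste0("snp", seq_len(spec$p)))
  attr(out, "maf") <- maf
  attr(out, "blocks") <- blocks
  out
}

#' Resample subject genotypes from a reference panel
#'
#' Each subject is the sum of two haplotypes drawn uniformly with replacement
#' from the panel (HAPGEN-style resampling); at large panel size genotype
#' frequencies follow Hardy-Weinberg proportions at the panel allele
#' frequencies.
#'
#' @param panel a [haplotype_panel()].
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return A [genotype_matrix()].
#' @export
sample_genotypes <- function(panel, n, seed = NULL) {
  panel <- as_haplotype_panel(panel)
  if (nrow(panel$alleles) == 0L) stop("empty panel")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  i1 <- sample.int(nrow(panel$alleles), n, replace = TRUE)
  i2 <- sample.int(nrow(panel$alleles), n, replace = TRUE)
  genotype_matrix(panel$alleles[i1, , drop = FALSE] +
                    panel$alleles[i2, , drop = FALSE], panel$snp_ids)
}

#' Multiplicative genotype-relative-risk disease model
#'
#' Disease probability of a subject is
#' `baseline_risk * prod_c rr(g_c)` over the causal SNPs `c`, with
#' `rr(0) = 1`, `rr(1) = rr_het`, `rr(2) = rr_hom`, capped at 1.
#'
#' @param causal integer vector of causal SNP column indices (empty = null
#'   model).
#' @param rr_het heterozygote relative risk (default 1.25).
#' @param rr_hom minor-homozygote relative risk (default 1.5).
#' @param baseline_risk baseline disease probability in `(0, 1)`.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(causal = integer(0), rr_het = 1.25, rr_hom = 1.5,
                          baseline_risk = 0.1) {
  if (any(c(rr_het, rr_hom) < 0)) stop("relative risks must be >= 0")
  if (baseline_risk <= 0 || baseline_risk > 1)
    stop("baseline_risk must be in (0, 1]")
  structure(list(causal = as.integer(causal), rr_het = rr_het,
                 rr_hom = rr_hom, baseline_risk = baseline_risk),
            class = "disease_model")
}

disease_prob <- function(g_causal, dm) {
  n <- nrow(g_causal)
  if (!length(dm$causal)) return(rep(dm$baseline_risk, n))
  rr <- c(1, dm$rr_het, dm$rr_hom)
  rel <- matrix(rr[as.vector(g_causal) + 1L], n)
  pmin(dm$baseline_risk * apply(rel, 1L, prod), 1)
}

#' Simulate a retrospective case-control sample
#'
#' Subjects are drawn prospectively ([sample_genotypes()]), assigned disease
#' status by a Bernoulli draw with the [disease_model()] probability, and
#' retained until the case and control quotas are filled (rejection
#' sampling); cases come first in the output.
#'
#' @param panel a [haplotype_panel()].
#' @param dm a [disease_model()] (causal indices refer to panel columns).
#' @param n_case,n_control group quotas (defaults 500/500).
#' @param seed optional integer seed.
#' @param max_draws guard against non-termination (default `5e6`).
#' @return A list with `genotypes` (a [genotype_matrix()]) and `phenotype`
#'   (a [phenotype()]).
#' @export
simulate_case_control <- function(panel, dm, n_case = 500L, n_control = 500L,
                                  seed = NULL, max_draws = 5e6) {
  panel <- as_haplotype_panel(panel)
  if (length(dm$causal) &&
      (min(dm$causal) < 1L || max(dm$causal) > ncol(panel$alleles)))
    stop("causal index out of range")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  need_ca <- n_case; need_co <- n_control
  got_ca <- got_co <- list()
  drawn <- 0
  while (need_ca > 0L || need_co > 0L) {
    batch <- max(200L, ceiling(1.5 * (need_ca / max(dm$baseline_risk, 1e-3) +
                                        need_co)))
    batch <- min(batch, 2e5)
    drawn <- drawn + batch
    if (drawn > max_draws)
      stop("case/control quotas not reached after ", max_draws, " draws")
    g <- sample_genotypes(panel, batch)$genotypes
    pr <- disease_prob(g[, dm$causal, drop = FALSE], dm)
    is_case <- stats::runif(batch) < pr
    if (need_ca > 0L) {
      take <- which(is_case)[seq_len(min(need_ca, sum(is_case)))]
      if (length(take)) {
        got_ca[[length(got_ca) + 1L]] <- g[take, , drop = FALSE]
        need_ca <- need_ca - length(take)
      }
    }
    if (need_co > 0L) {
      take <- which(!is_case)[seq_len(min(need_co, sum(!is_case)))]
      if (length(take)) {
        got_co[[length(got_co) + 1L]] <- g[take, , drop = FALSE]
        need_co <- need_co - length(take)
      }
    }
  }
  g <- rbind(do.call(rbind, got_ca), do.call(rbind, got_co))
  list(genotypes = genotype_matrix(g, panel$snp_ids),
       phenotype = phenotype(rep(c(1L, 0L), c(n_case, n_control))))
}

#' Bundle a simulation scenario
#'
#' Assembles a reference panel, a disease model and the tag-selection
#' subsample: 200 haplotypes (100 subjects' worth, resampled from the panel)
#' reserved for forming the tag SNP-set, mirroring a design where only a
#' small haplotyped subset of subjects informs tag selection.  Causal SNPs
#' can be masked from the "genotyped" set to emulate scenarios where a
#' causal SNP is not on the genotyping array.
#'
#' @param name `"null"`, `"one_causal"` or `"two_causal"`.
#' @param spec a [panel_spec()].
#' @param causal explicit causal column indices, or `NULL` to draw them
#'   (none / one / two according to `name`).
#' @param mask_causal logical: drop the causal SNPs from the genotyped
#'   column set?
#' @param rr_het,rr_hom,baseline_risk disease-model parameters.
#' @param seed integer seed.
#' @return A list with `panel`, `model` (a [disease_model()]),
#'   `tag_haplotypes` (200-row [haplotype_panel()]) and `genotyped`
#'   (integer vector of genotyped column indices).
#' @export
make_scenario <- function(name = c("null", "one_causal", "two_causal"),
                          spec = panel_spec(), causal = NULL,
                          mask_causal = FALSE, rr_het = 1.25, rr_hom = 1.5,
                          baseline_risk = 0.1, seed = NULL) {
  name <- match.arg(name)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  panel <- simulate_panel(spec)
  n_causal <- switch(name, null = 0L, one_causal = 1L, two_causal = 2L)
  if (is.null(causal)) {
    causal <- if (n_causal) sample.int(spec$p, n_causal) else integer(0)
  } else {
    causal <- as.integer(causal)
    if (length(causal) && (min(causal) < 1L || max(causal) > spec$p))
      stop("causal index out of range")
  }
  dm <- disease_model(causal, rr_het, rr_hom, baseline_risk)
  sub <- sample.int(nrow(panel$alleles), 200L, replace = TRUE)
  tag_hap <- haplotype_panel(panel$alleles[sub, , drop = FALSE],
                             panel$snp_ids)
  genotyped <- seq_len(spec$p)
  if (mask_causal && length(causal)) genotyped <- setdiff(genotyped, causal)
  list(panel = panel, model = dm, tag_haplotypes = tag_hap,
       genotyped = genotyped)
}
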