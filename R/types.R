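#' Construct a phased haplotype panel
#'
#' A haplotype panel holds the phased alleles of `2m` haplotypes (two per
#' subject) at `p` SNP loci, coded 0 for the reference/major allele and 1 for
#' the counted (ALT/minor) allele.  It is the input to LD computation and tag
#' SNP selection.
#'
#' @param alleles numeric or integer matrix with entries in `{0, 1}`; one row
#'   per haplotype (the row count must be even), one column per SNP.
#' @param snp_ids character vector of unique SNP identifiers, one per column.
#'   Defaults to the column names of `alleles`, or `snp1..snpP`.
#' @param positions optional integer vector of 1-based base-pair coordinates.
#' @return An object of class `haplotype_panel` with elements `alleles`,
#'   `snp_ids` and `positions`.
#' @seealso [ld_r2_matrix()], [select_tags()], [simulate_panel()]
#' @export
haplotype_panel <- function(alleles, snp_ids = NULL, positions = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype rows must come in subject pairs (even row count), got ",
         nrow(alleles))
  if (length(alleles) && !all(alleles %in% c(0L, 1L)))
    stop("haplotype alleles must all be 0 or 1")
  if (is.null(snp_ids)) {
    snp_ids <- colnames(alleles)
    if (is.null(snp_ids))
      snp_ids <- if (ncol(alleles)) paste0("snp", seq_len(ncol(alleles))) else character(0)
  }
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(alleles))
    stop("length(snp_ids) must equal ncol(alleles)")
  if (anyDuplicated(snp_ids))
    stop("snp_ids must be unique")
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != ncol(alleles) || any(positions < 0L))
      stop("positions must be non-negative, one per SNP")
  }
  colnames(alleles) <- snp_ids
  structure(list(alleles = alleles, snp_ids = snp_ids, positions = positions),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$alleles), "haplotypes (",
      nrow(x$alleles) / 2L, "subjects ) x", ncol(x$alleles), "SNPs\n")
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

as_haplotype_panel <- function(x) {
  if (inherits(x, "haplotype_panel")) x else haplotype_panel(x)
}

#' Construct a genotype matrix
#'
#' Genotypes are additively coded: 0/1/2 copies of the counted (ALT/minor)
#' allele per subject per SNP.
#'
#' @param genotypes numeric matrix with entries in `{0, 1, 2}`; one row per
#'   subject, one column per SNP.
#' @param snp_ids character vector of SNP identifiers, one per column.
#' @return An object of class `genotype_matrix` with elements `genotypes` and
#'   `snp_ids`.
#' @export
genotype_matrix <- function(genotypes, snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (length(genotypes) && !all(genotypes %in% c(0L, 1L, 2L)))
    stop("genotypes must all be 0, 1 or 2")
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids))
      snp_ids <- if (ncol(genotypes)) paste0("snp", seq_len(ncol(genotypes))) else character(0)
  }
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(genotypes))
    stop("length(snp_ids) must equal ncol(genotypes)")
  colnames(genotypes) <- snp_ids
  structure(list(genotypes = genotypes, snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$genotypes), "subjects x",
      ncol(x$genotypes), "SNPs (0/1/2 additive coding)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) x else genotype_matrix(x)
}

geno_mat <- function(G) {
  G <- as_genotype_matrix(G)
  G$genotypes
}

#' Construct a case-control phenotype
#'
#' @param y binary vector: 1 = case, 0 = control.
#' @param covariates optional numeric matrix of covariates (one row per
#'   subject) entering the SKAT null model; may be `NULL`.
#' @return An object of class `phenotype` with elements `y` and `covariates`.
#' @export
phenotype <- function(y, covariates = NULL) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop("phenotype y must be binary 0/1")
  if (sum(y) == 0L || sum(y) == length(y))
    stop("phenotype must contain at least one case and one control")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(y))
      stop("covariates must have one row per subject")
  }
  structure(list(y = y, covariates = covariates), class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat("Phenotype:", sum(x$y), "cases /", sum(1 - x$y), "controls",
      if (!is.null(x$covariates)) paste0("; ", ncol(x$covariates), " covariate(s)"),
      "\n")
  invisible(x)
}

as_phenotype <- function(x) {
  if (inherits(x, "phenotype")) x else phenotype(x)
}

pheno_y <- function(y) as_phenotype(y)$y

#' Derive subject genotypes from a haplotype panel
#'
#' Sums the two haplotype rows of each subject (rows `2k-1` and `2k`) into an
#' additive 0/1/2 genotype.
#'
#' @param panel a [haplotype_panel()].
#' @return A [genotype_matrix()] with one row per subject.
#' @export
panel_to_genotypes <- function(panel) {
  panel <- as_haplotype_panel(panel)
  a <- panel$alleles
  odd <- seq(1L, nrow(a), by = 2L)
  g <- a[odd, , drop = FALSE] + a[odd + 1L, , drop = FALSE]
  genotype_matrix(g, panel$snp_ids)
}

#' Flip allele coding so that the counted allele is the minor allele
#'
#' Columns whose counted-allele frequency exceeds 0.5 are flipped
#' (`x -> 1 - x` for haplotypes, `g -> 2 - g` for genotypes).  LD r-squared,
#' the chi-squared weights and both test statistics are invariant to
#' per-column flips, so polarity only affects reporting.
#'
#' @param x a [haplotype_panel()] or [genotype_matrix()].
#' @return An object of the same class with flipped columns; the indices of
#'   the flipped columns are stored in attribute `"flipped"`.
#' @export
polarize_minor <- function(x) {
  if (inherits(x, "haplotype_panel")) {
    freq <- colMeans(x$alleles)
    flip <- unname(which(freq > 0.5))
    if (length(flip)) x$alleles[, flip] <- 1L - x$alleles[, flip]
    attr(x, "flipped") <- flip
    return(x)
  }
  x <- as_genotype_matrix(x)
  freq <- colMeans(x$genotypes) / 2
  flip <- unname(which(freq > 0.5))
  if (length(flip)) x$genotypes[, flip] <- 2L - x$genotypes[, flip]
  attr(x, "flipped") <- flip
  x
}
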