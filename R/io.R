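## File readers/writers.  Only the GT field of a VCF is consulted; sites must
## be biallelic and complete (missingness is rejected, not imputed).

strip_gt <- function(gt) sub(":.*$", "", gt)

read_vcf_gt <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L)
    return(list(gt = matrix(character(0), 0, 0), id = character(0),
                pos = integer(0), chrom = character(0),
                ref = character(0), alt = character(0)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multi-allelic record(s) at VCF data line(s) ",
         paste(which(multi), collapse = ", "), "; only biallelic sites are supported")
  gt <- vcf@gt
  if (ncol(gt) < 2L)
    stop("VCF '", path, "' has no sample columns")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[is.na(ids) | ids == ".", "CHROM"], ":",
                                         fix[is.na(ids) | ids == ".", "POS"])
  list(gt = strip_gt(gt[, -1L, drop = FALSE]), id = ids,
       pos = as.integer(fix[, "POS"]), chrom = fix[, "CHROM"],
       ref = fix[, "REF"], alt = alt)
}

#' Read a phased haplotype panel from a VCF
#'
#' Every sample must carry a phased (pipe-separated) GT at every biallelic
#' site.  Each sample contributes two consecutive haplotype rows (left allele
#' first); allele 1 is the ALT allele.
#'
#' @param path path to a VCF 4.x file (plain text or gzip).
#' @return A [haplotype_panel()].
#' @export
read_haplotypes_vcf <- function(path) {
  v <- read_vcf_gt(path)
  if (length(v$id) == 0L)
    return(haplotype_panel(matrix(0L, 0, 0)))
  gt <- v$gt                                   # sites x samples
  bad <- which(matrix(!grepl("^[01]\\|[01]$", gt), nrow(gt)), arr.ind = TRUE)
  if (nrow(bad)) {
    g1 <- gt[bad[1, 1], bad[1, 2]]
    if (grepl("/", g1, fixed = TRUE))
      stop("unphased genotype '", g1, "' at VCF data line ", bad[1, 1],
           ", sample ", bad[1, 2], call. = FALSE)
    stop("missing or invalid genotype '", g1, "' at VCF data line ", bad[1, 1],
         ", sample ", bad[1, 2], call. = FALSE)
  }
  left  <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  right <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  n_s <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * n_s, ncol = nrow(gt))
  alleles[seq(1L, 2L * n_s, by = 2L), ] <- t(left)
  alleles[seq(2L, 2L * n_s, by = 2L), ] <- t(right)
  haplotype_panel(alleles, snp_ids = v$id, positions = v$pos)
}

#' Write a haplotype panel as a minimal phased VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param chrom chromosome label used for every record.
#' @return `path`, invisibly.
#' @export
write_haplotypes_vcf <- function(panel, path, chrom = "1") {
  panel <- as_haplotype_panel(panel)
  a <- panel$alleles
  n_s <- nrow(a) / 2L
  pos <- if (is.null(panel$positions)) seq_len(ncol(a)) else panel$positions
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   if (n_s) paste0("S", seq_len(n_s))), collapse = "\t"))
  recs <- vapply(seq_len(ncol(a)), function(j) {
    gts <- paste0(a[seq(1L, 2L * n_s, by = 2L), j], "|",
                  a[seq(2L, 2L * n_s, by = 2L), j])
    paste(c(chrom, pos[j], panel$snp_ids[j], "A", "G", ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read an additive genotype matrix
#'
#' VCF genotypes (phased or not) are summed to 0/1/2 ALT-allele counts; a TSV
#' must have a header row of SNP ids and one subject row per line.  Missing
#' genotypes and entries outside `{0, 1, 2}` are rejected.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    g <- as.matrix(tab)
    bad <- which(is.na(g) | !(g %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad))
      stop("genotype out of {0,1,2} at subject row ", bad[1, 1],
           ", column '", colnames(tab)[bad[1, 2]], "'", call. = FALSE)
    return(genotype_matrix(g, colnames(tab)))
  }
  v <- read_vcf_gt(path)
  if (length(v$id) == 0L)
    return(genotype_matrix(matrix(0L, 0, 0)))
  gt <- v$gt
  bad <- which(matrix(!grepl("^[01][|/][01]$", gt), nrow(gt)), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing or invalid genotype '", gt[bad[1, 1], bad[1, 2]],
         "' at VCF data line ", bad[1, 1], ", sample ", bad[1, 2], call. = FALSE)
  g <- matrix(as.integer(substr(gt, 1L, 1L)) + as.integer(substr(gt, 3L, 3L)),
              nrow = nrow(gt))
  genotype_matrix(t(g), v$id)
}

#' Write a genotype matrix as TSV
#'
#' The header row holds the SNP ids; each following row is one subject.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(G, path) {
  G <- as_genotype_matrix(G)
  utils::write.table(G$genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a phenotype file
#'
#' TSV with columns `sample_id`, `y` (0 = control, 1 = case) and any further
#' columns treated as covariates.
#'
#' @param path input path.
#' @return A [phenotype()]; sample ids are kept as `names(x$y)`.
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(c("sample_id", "y") %in% colnames(tab)))
    stop("phenotype TSV must have columns sample_id and y")
  cov <- setdiff(colnames(tab), c("sample_id", "y"))
  ph <- phenotype(tab$y,
                  if (length(cov)) as.matrix(tab[, cov, drop = FALSE]) else NULL)
  names(ph$y) <- tab$sample_id
  ph
}

#' Write a tag SNP-set as TSV
#'
#' One row per tag, columns `tag_snp_id` and `cluster_members`
#' (comma-joined SNP ids), ordered by tag index.
#'
#' @param ts a [select_tags()] result, or a list with elements `tags`
#'   (integer indices) and `clusters` (list of integer vectors).
#' @param snp_ids character vector mapping indices to SNP ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tagset <- function(ts, snp_ids, path) {
  idx <- unlist(c(ts$tags, ts$clusters), use.names = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > length(snp_ids)))
    stop("tag/cluster index out of range for ", length(snp_ids), " SNP ids")
  ord <- order(ts$tags)
  lines <- c("tag_snp_id\tcluster_members",
             vapply(ord, function(k) {
               paste0(snp_ids[ts$tags[k]], "\t",
                      paste(snp_ids[ts$clusters[[k]]], collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tag SNP-set TSV back into indices
#'
#' @param path file written by [write_tagset()].
#' @param snp_ids the SNP id vector of the matrix the indices refer to.
#' @return A list with `tags` (integer vector) and `clusters` (list of
#'   integer vectors), in file order.
#' @export
read_tagset <- function(path, snp_ids) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  tags <- match(tab$tag_snp_id, snp_ids)
  if (anyNA(tags))
    stop("tag id(s) not found in snp_ids: ",
         paste(tab$tag_snp_id[is.na(tags)], collapse = ", "))
  clusters <- lapply(strsplit(tab$cluster_members, ",", fixed = TRUE),
                     function(m) {
                       i <- match(m, snp_ids)
                       if (anyNA(i)) stop("cluster member id not found in snp_ids")
                       i
                     })
  list(tags = as.integer(tags), clusters = clusters)
}
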