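# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (O(n^2) loops, matrix-power reachability) so they check
# the package's optimised paths from a different direction.

# all-pairs reachability by repeated boolean matrix multiplication
brute_components <- function(adj) {
  p <- nrow(adj)
  reach <- adj > 0
  for (i in seq_len(p)) reach <- reach | ((reach %*% reach) > 0)
  groups <- unique(apply(reach, 1L, function(row) paste(which(row), collapse = ",")))
  lapply(strsplit(groups, ","), as.integer)
}

# canonical form of a partition (list of index sets) for set comparison
canon_partition <- function(blocks) {
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, min, integer(1)))]
}

# O(n^2) KBAT decomposition straight from the definitions
brute_kbat_decompose <- function(G, y) {
  G <- as.matrix(G)
  p <- ncol(G)
  U1 <- U2 <- W <- B <- numeric(p)
  m1 <- choose(sum(y), 2)
  m2 <- choose(sum(1 - y), 2)
  for (k in seq_len(p)) {
    ss <- ww <- numeric(2)
    us <- numeric(2)
    for (l in 1:2) {
      g <- G[y == (2 - l), k]      # l=1 cases, l=2 controls
      pairs <- utils::combn(length(g), 2)
      h <- tagassoc::am_kernel(g[pairs[1, ]], g[pairs[2, ]])
      us[l] <- mean(h)
      ww[l] <- sum((h - mean(h))^2)
    }
    U1[k] <- us[1]; U2[k] <- us[2]
    ub <- mean(us)
    W[k] <- sum(ww)
    B[k] <- m1 * (us[1] - ub)^2 + m2 * (us[2] - ub)^2
  }
  list(U1 = U1, U2 = U2, W = W, B = B, m1 = m1, m2 = m2)
}

# a panel whose blocks are exact column copies => within-block r2 = 1
copy_block_panel <- function(n_hap, block_cols, seed = 1) {
  set.seed(seed)
  base <- matrix(rbinom(n_hap * length(block_cols), 1, 0.4), n_hap)
  alleles <- base[, rep(seq_along(block_cols), block_cols), drop = FALSE]
  while (any(colMeans(alleles) %in% c(0, 1))) {   # guard tiny n
    base <- matrix(rbinom(n_hap * length(block_cols), 1, 0.4), n_hap)
    alleles <- base[, rep(seq_along(block_cols), block_cols), drop = FALSE]
  }
  haplotype_panel(alleles)
}

random_genotypes <- function(n, p, seed) {
  set.seed(seed)
  matrix(sample(0:2, n * p, replace = TRUE), n, p)
}

balanced_y <- function(n) rep(c(1L, 0L), length.out = n)

write_mini_vcf <- function(path, gts, ids = NULL) {
  # gts: site x sample character matrix of GT strings
  n_site <- nrow(gts); n_s <- ncol(gts)
  if (is.null(ids)) ids <- paste0("rs", seq_len(n_site))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("S", seq_len(n_s))), collapse = "\t"))
  recs <- vapply(seq_len(n_site), function(i)
    paste(c("1", i * 100L, ids[i], "A", "G", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, recs), path)
  path
}
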