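test_that("r2 matches hand-computed values on 4-haplotype fixtures", {
  pan <- haplotype_panel(cbind(c(0, 0, 1, 1), c(0, 0, 1, 1)))
  expect_equal(ld_r2_matrix(pan)[1, 2], 1)
  pan <- haplotype_panel(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_equal(ld_r2_matrix(pan)[1, 2], 0)
  # frozen hand computation: r = (0.5/3) / (sqrt(1/3) * 0.5), r^2 = 1/3
  pan <- haplotype_panel(cbind(c(0, 0, 1, 1), c(0, 1, 1, 1)))
  expect_equal(ld_r2_matrix(pan)[1, 2], 1 / 3, tolerance = 1e-12)
})

test_that("monomorphic columns are refused by name and droppable", {
  pan <- haplotype_panel(cbind(c(0, 0, 1, 1), c(1, 1, 1, 1)),
                         snp_ids = c("ok", "mono"))
  expect_error(ld_r2_matrix(pan), "mono")
  expect_warning(kept <- drop_monomorphic(pan), "mono")
  expect_equal(kept$snp_ids, "ok")
  expect_equal(attr(kept, "kept"), 1L)
})

test_that("thresholding is strict and validates t", {
  r2 <- matrix(0.9, 3, 3); diag(r2) <- 1
  expect_equal(threshold_adjacency(r2, 0.9), diag(3))
  r2 <- matrix(c(1, 0.95, 0.2, 0.95, 1, 0.93, 0.2, 0.93, 1), 3, 3)
  adj <- threshold_adjacency(r2, 0.9)
  expect_equal(adj, matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3))
  expect_true(all(threshold_adjacency(r2, 0) == 1))
  expect_error(threshold_adjacency(r2, 1.2), "\\[0, 1\\]")
})

test_that("partition matches brute-force reachability on random graphs", {
  set.seed(11)
  for (rep in 1:20) {
    p <- sample(2:12, 1)
    adj <- matrix(rbinom(p * p, 1, 0.2), p, p)
    adj <- 1 * ((adj + t(adj)) > 0); diag(adj) <- 1
    expect_equal(canon_partition(partition_components(adj)),
                 canon_partition(brute_components(adj)))
  }
})

test_that("block contents are independent of the random start order", {
  set.seed(12)
  p <- 10
  adj <- matrix(rbinom(p * p, 1, 0.25), p, p)
  adj <- 1 * ((adj + t(adj)) > 0); diag(adj) <- 1
  base <- canon_partition(partition_components(adj))
  for (s in c(1, 99, 2024))
    expect_equal(canon_partition(partition_components(adj, seed = s)), base)
})

test_that("identity adjacency gives singleton blocks; isolated nodes kept", {
  expect_equal(partition_components(diag(4)), list(1L, 2L, 3L, 4L))
  adj <- diag(4); adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1
  expect_equal(canon_partition(partition_components(adj)),
               list(c(1L, 2L, 3L), 4L))
})

test_that("representative maximises within-block LD row sum, min index on ties", {
  r2 <- matrix(c(1, 0.95, 0.2, 0.95, 1, 0.93, 0.2, 0.93, 1), 3, 3)
  expect_equal(select_representative(1:3, r2), 2L)    # row sums 2.15, 2.88, 2.13
  expect_equal(select_representative(3L, r2), 3L)
  r2b <- matrix(c(1, 0.95, 0.95, 1), 2, 2)
  expect_equal(select_representative(1:2, r2b), 1L)   # tie at 1.95
  expect_error(select_representative(integer(0), r2), "empty")
})

test_that("select_tags collapses copy-blocks and honours threshold limits", {
  panel <- copy_block_panel(60, c(2, 2))      # columns 1=2, 3=4 exactly
  ts <- select_tags(panel, t = 0.9)
  expect_equal(length(ts$tags), 2L)
  expect_equal(canon_partition(ts$clusters), list(c(1L, 2L), c(3L, 4L)))

  # t = 1: strict inequality means even perfect LD adds no edge
  expect_equal(length(select_tags(panel, t = 1)$tags), ncol(panel$alleles))

  # t = 0 on a connected panel: one tag
  conn <- copy_block_panel(60, 4)
  expect_equal(length(select_tags(conn, t = 0)$tags), 1L)
})

test_that("tag selection is invariant to SNP column permutation", {
  set.seed(14)
  sp <- panel_spec(p = 24, n_ref_haplotypes = 300)
  panel <- drop_monomorphic(simulate_panel(sp, seed = 21), quiet = TRUE)
  p <- ncol(panel$alleles)
  perm <- sample.int(p)
  permuted <- haplotype_panel(panel$alleles[, perm, drop = FALSE],
                              panel$snp_ids[perm])
  ts1 <- select_tags(panel, t = 0.8)
  ts2 <- select_tags(permuted, t = 0.8)
  # clusters must agree as SNP-id sets under the relabeling
  ids1 <- canon_ids <- lapply(ts1$clusters, function(b) sort(panel$snp_ids[b]))
  ids2 <- lapply(ts2$clusters, function(b) sort(permuted$snp_ids[b]))
  expect_setequal(vapply(ids1, paste, character(1), collapse = ","),
                  vapply(ids2, paste, character(1), collapse = ","))
})

test_that("raising t only refines the partition and never shrinks the tag count", {
  panel <- drop_monomorphic(
    simulate_panel(panel_spec(p = 30, n_ref_haplotypes = 400), seed = 31),
    quiet = TRUE)
  r2 <- ld_r2_matrix(panel)
  ts_vals <- c(0, 0.3, 0.6, 0.9, 1)
  parts <- lapply(ts_vals, function(t)
    partition_components(threshold_adjacency(r2, t)))
  n_tags <- lengths(parts)
  expect_true(all(diff(n_tags) >= 0))
  # refinement: every block at the higher t sits inside one block at lower t
  for (i in seq_len(length(parts) - 1)) {
    lower <- parts[[i]]; higher <- parts[[i + 1]]
    for (b in higher) {
      holder <- vapply(lower, function(lb) all(b %in% lb), logical(1))
      expect_equal(sum(holder), 1L)
    }
  }
})

test_that("r2 is invariant to flipping any column's allele coding", {
  set.seed(15)
  a <- matrix(rbinom(80, 1, 0.4), 20, 4)
  while (any(colMeans(a) %in% c(0, 1))) a <- matrix(rbinom(80, 1, 0.4), 20, 4)
  base <- ld_r2_matrix(haplotype_panel(a))
  for (j in 1:4) {
    b <- a; b[, j] <- 1L - b[, j]
    expect_equal(ld_r2_matrix(haplotype_panel(b)), base, tolerance = 1e-12)
  }
})
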