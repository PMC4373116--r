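#' Pairwise LD matrix (r-squared) of a haplotype panel
#'
#' For SNPs `i`, `j` the LD coefficient is the squared sample Pearson
#' correlation of the two allele indicator columns across the `2m`
#' haplotypes.  The diagonal is 1 and all entries lie in `[0, 1]`.
#'
#' @param panel a [haplotype_panel()] with at least two haplotypes and no
#'   monomorphic column (see [drop_monomorphic()]).
#' @return A `p x p` symmetric numeric matrix with SNP ids as dimnames.
#' @export
ld_r2_matrix <- function(panel) {
  panel <- as_haplotype_panel(panel)
  a <- panel$alleles
  if (nrow(a) < 2L) stop("need at least 2 haplotypes to compute LD")
  v <- apply(a, 2L, stats::var)
  if (any(v == 0))
    stop("monomorphic SNP column(s): ",
         paste(panel$snp_ids[v == 0], collapse = ", "),
         "; drop them first (see drop_monomorphic())")
  r2 <- stats::cor(a)^2
  diag(r2) <- 1
  r2
}

#' Drop monomorphic columns from a haplotype panel
#'
#' @param panel a [haplotype_panel()].
#' @param quiet suppress the warning listing dropped SNPs.
#' @return The panel restricted to polymorphic columns; the kept column
#'   indices (into the original panel) are in attribute `"kept"`.
#' @export
drop_monomorphic <- function(panel, quiet = FALSE) {
  panel <- as_haplotype_panel(panel)
  f <- colMeans(panel$alleles)
  keep <- unname(which(f > 0 & f < 1))
  if (length(keep) < ncol(panel$alleles) && !quiet)
    warning("dropping ", ncol(panel$alleles) - length(keep),
            " monomorphic SNP(s): ",
            paste(panel$snp_ids[setdiff(seq_along(f), keep)], collapse = ", "))
  out <- haplotype_panel(panel$alleles[, keep, drop = FALSE],
                         panel$snp_ids[keep],
                         if (is.null(panel$positions)) NULL else panel$positions[keep])
  attr(out, "kept") <- keep
  out
}

#' Threshold an LD matrix into a graph adjacency matrix
#'
#' Edge `i ~ j` is present iff `r2[i, j] > t` (strict) or `i == j`.
#'
#' @param ld symmetric LD r-squared matrix.
#' @param t threshold in `[0, 1]`.
#' @return A binary symmetric matrix with unit diagonal.
#' @export
threshold_adjacency <- function(ld, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1)
    stop("threshold t must be a single number in [0, 1]")
  adj <- (ld > t) * 1L
  diag(adj) <- 1L
  adj
}

#' Partition SNPs into connected components of the LD graph
#'
#' Blocks are the connected components of the thresholded LD graph: starting
#' from an arbitrary unassigned SNP, all SNPs reachable through above-threshold
#' edges are pulled into the same block, and the process repeats until every
#' SNP is assigned.  The starting order (controlled by `seed`) affects only
#' the order in which blocks are emitted, never their contents.
#'
#' @param adj binary symmetric adjacency matrix with unit diagonal.
#' @param seed optional integer; when given, block emission order follows a
#'   seeded random traversal instead of smallest-first.
#' @return A list of integer vectors (sorted within block) partitioning
#'   `1..p`.
#' @export
partition_components <- function(adj, seed = NULL) {
  p <- nrow(adj)
  if (p == 0L) return(list())
  if (!isTRUE(all.equal(adj, t(adj))))
    stop("adjacency must be symmetric")
  start_order <- seq_len(p)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
    start_order <- sample.int(p)
  }
  assigned <- logical(p)
  blocks <- list()
  nbrs <- apply(adj != 0, 1L, which, simplify = FALSE)
  for (s in start_order) {
    if (assigned[s]) next
    frontier <- s
    assigned[s] <- TRUE
    comp <- s
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[!assigned[nxt]]
      assigned[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    blocks[[length(blocks) + 1L]] <- sort(comp)
  }
  blocks
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Select the representative (tag) SNP of a block
#'
#' The tag is the SNP maximising the within-block row sum of the LD matrix
#' (the diagonal term contributes a constant 1 to every candidate); ties are
#' broken by the smallest index.
#'
#' @param block non-empty integer vector of SNP indices.
#' @param ld LD r-squared matrix.
#' @return The tag SNP index.
#' @export
select_representative <- function(block, ld) {
  block <- sort(as.integer(block))
  if (!length(block)) stop("empty block")
  rs <- rowSums(ld[block, block, drop = FALSE])
  block[which.max(rs)]   # which.max returns the first (smallest-index) maximum
}

#' Select a tag SNP-set from a haplotype panel
#'
#' The LD-graph tag selection algorithm: (1) compute pairwise r-squared,
#' (2) connect SNP pairs with r-squared strictly above `t`, (3) partition the
#' graph into connected components, (4) pick each component's representative
#' as the SNP with the largest within-component LD row sum (ties to the
#' smallest index).  At `t = 1` every SNP tags itself; at `t = 0` a fully
#' connected panel collapses to a single tag.
#'
#' @param panel a [haplotype_panel()] without monomorphic columns.
#' @param t LD r-squared threshold in `[0, 1]`; default 0.9.
#' @param seed optional integer controlling block emission order only.
#' @return An object of class `tag_set`: list with `tags` (integer indices
#'   into the panel columns), `clusters` (list of integer vectors, one per
#'   tag), `snp_ids`, `t`.
#' @export
select_tags <- function(panel, t = 0.9, seed = NULL) {
  panel <- as_haplotype_panel(panel)
  r2 <- ld_r2_matrix(panel)
  adj <- threshold_adjacency(r2, t)
  blocks <- partition_components(adj, seed = seed)
  tags <- vapply(blocks, select_representative, integer(1), ld = r2)
  structure(list(tags = tags, clusters = blocks,
                 snp_ids = panel$snp_ids, t = t),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("Tag SNP-set:", length(x$tags), "tags from", length(x$snp_ids),
      "SNPs (r² threshold ", x$t, ")\n", sep = " ")
  cat("Tags:", paste(utils::head(x$snp_ids[x$tags], 10L), collapse = ", "),
      if (length(x$tags) > 10L) "...", "\n")
  invisible(x)
}

#' @export
summary.tag_set <- function(object, ...) {
  sizes <- lengths(object$clusters)
  cat("Tag SNP-set summary\n")
  cat("  original SNPs :", length(object$snp_ids), "\n")
  cat("  tags          :", length(object$tags),
      sprintf("(%.1f%% of original)", 100 * length(object$tags) /
                max(1L, length(object$snp_ids))), "\n")
  cat("  cluster sizes : min", min(sizes), "/ median", stats::median(sizes),
      "/ max", max(sizes), "\n")
  invisible(object)
}
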