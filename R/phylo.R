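# Distance-based family trees with bootstrap support: p-distance
# (optionally Poisson-corrected) + neighbor joining, with column
# bootstrap and bipartition support. A deterministic stand-in for
# maximum-likelihood inference: clade membership, not branch lengths,
# is the tested surface.

# character matrix (sequences x columns) from a gap-aligned set
.aln_matrix <- function(alignment) {
  stopifnot(length(alignment) >= 2L, !is.null(names(alignment)))
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

.pdist_from_mat <- function(m, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no ungapped overlap between ", rownames(m)[i], " and ",
           rownames(m)[j])
    p <- mean(m[i, ok] != m[j, ok])
    d[i, j] <- d[j, i] <- if (correction == "poisson") -log(1 - p) else p
  }
  d
}

#' Pairwise distances from a multiple alignment
#'
#' Proportion of mismatching columns under pairwise gap deletion;
#' `correction = "poisson"` applies `-ln(1 - p)`.
#'
#' @param alignment named character vector of equal-length aligned
#'   peptides (gap `-`).
#' @param correction `"none"` or `"poisson"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pdistance <- function(alignment, correction = c("none", "poisson")) {
  .pdist_from_mat(.aln_matrix(alignment), correction)
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration with deterministic tie-breaking (the
#' lowest-index pair among Q-criterion minima within 1e-12) and
#' negative branch lengths clamped to zero (count recorded in the
#' `clamped` attribute). Exact on additive distance matrices.
#'
#' @param d symmetric distance matrix (>= 3 taxa) with labelled rows.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  nodes <- labels
  clamped <- 0L
  bl <- function(x) { if (x < 0) { clamped <<- clamped + 1L; 0 } else x }
  while (n > 3L) {
    r <- rowSums(d)
    best <- NULL; qbest <- Inf
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      q <- (n - 2) * d[i, j] - r[i] - r[j]
      if (q < qbest - 1e-12) { qbest <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- bl(0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- bl(d[i, j] - (0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))))
    new_node <- sprintf("(%s:%.12g,%s:%.12g)", nodes[i], bi, nodes[j], bj)
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    d[i, ] <- du; d[, i] <- du; d[i, i] <- 0
    nodes[i] <- new_node
    keep <- setdiff(seq_len(n), j)
    d <- d[keep, keep, drop = FALSE]
    nodes <- nodes[keep]
    n <- n - 1L
  }
  b1 <- bl(0.5 * (d[1, 2] + d[1, 3] - d[2, 3]))
  b2 <- bl(0.5 * (d[1, 2] + d[2, 3] - d[1, 3]))
  b3 <- bl(0.5 * (d[1, 3] + d[2, 3] - d[1, 2]))
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nodes[1], b1, nodes[2], b2, nodes[3], b3)
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#' Deterministic under `seed`.
#'
#' @param alignment named character vector of aligned peptides.
#' @param n_replicates bootstrap replicates (>= 1). Default 600.
#' @param seed integer seed.
#' @param correction distance correction, see [pdistance()].
#' @param display_threshold support percentage below which
#'   [display_newick()] hides the label. Default 70.
#' @return list of class `support_tree`: `tree` (`ape::phylo` whose
#'   `node.label` carries support in `[0, 100]`, `NA` at the root),
#'   `n_replicates`, `display_threshold`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 600L, seed = 1L,
                              correction = c("none", "poisson"),
                              display_threshold = 70) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  correction <- match.arg(correction)
  m <- .aln_matrix(alignment)
  tree <- neighbor_joining(.pdist_from_mat(m, correction))
  trees <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      neighbor_joining(.pdist_from_mat(m[, cols, drop = FALSE], correction))
    })
  })
  counts <- ape::prop.clades(tree, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_replicates
  support[1] <- NA # root of the unrooted representation: trivial split
  tree$node.label <- support
  structure(list(tree = tree, n_replicates = as.integer(n_replicates),
                 display_threshold = display_threshold),
            class = "support_tree")
}

#' Newick string with supports filtered at the display threshold
#'
#' Full supports are always retained in the `support_tree`; this
#' renders the conventional figure form in which only supports at or
#' above the threshold are printed.
#'
#' @param st a [bootstrap_support()] result (or an `ape::phylo`).
#' @param threshold display threshold; defaults to the tree's own.
#' @return single Newick string.
#' @export
display_newick <- function(st, threshold = NULL) {
  tree <- if (inherits(st, "support_tree")) st$tree else st
  thr <- threshold %||%
    (if (inherits(st, "support_tree")) st$display_threshold else 70)
  s <- tree$node.label
  if (!is.null(s)) {
    sn <- suppressWarnings(as.numeric(s))
    tree$node.label <- ifelse(!is.na(sn) & sn >= thr,
                              format(round(sn), trim = TRUE), "")
  }
  ape::write.tree(tree)
}

#' Does the tree contain a clade as a bipartition?
#'
#' @param tree an `ape::phylo`.
#' @param tips character vector of tip labels.
#' @return `TRUE` iff some internal edge splits exactly `tips` from the
#'   rest.
#' @export
has_bipartition <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(tips, labs))
  if (anyNA(target)) stop("tip(s) not in tree")
  all_tips <- seq_along(labs)
  comp <- sort(setdiff(all_tips, target))
  any(vapply(parts, function(p) identical(sort(p), target) ||
               identical(sort(p), comp), logical(1)))
}

#' Support value for a planted clade
#'
#' @param st a [bootstrap_support()] result.
#' @param tips tip labels of the clade.
#' @return the support percentage of the matching bipartition, or `NA`
#'   if the original tree does not contain it.
#' @export
clade_support <- function(st, tips) {
  stopifnot(inherits(st, "support_tree"))
  tree <- st$tree
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(tips, labs))
  if (anyNA(target)) stop("tip(s) not in tree")
  comp <- sort(setdiff(seq_along(labs), target))
  for (k in seq_along(parts)[-1]) { # skip the trivial root partition
    p <- sort(parts[[k]])
    if (identical(p, target) || identical(p, comp))
      return(as.numeric(tree$node.label[k]))
  }
  NA_real_
}
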