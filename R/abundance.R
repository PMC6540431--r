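# Fragment-to-transcript assignment by k-mer pseudo-alignment, EM
# abundance estimation with multi-mapping resolution, gene-level FPKM,
# and the heat-map matrix (log2(FPKM+1), per-sample breakpoints).

#' Build a fragment/transcript compatibility table
#'
#' A transcript is compatible with a fragment iff both mates' distinct
#' k-mer sets (in their better of forward / reverse-complement
#' orientation) reach at least `tau` containment in the transcript's
#' k-mer set. Fragments compatible with nothing are counted as
#' unmapped.
#'
#' @param pairs data.frame with `seq1`, `seq2` (see
#'   [read_fastq_pairs()]).
#' @param transcripts named character vector.
#' @param k k-mer length; must satisfy `8 <= k <= read length`.
#' @param tau containment threshold. Default 0.8.
#' @param fragment_mean mean fragment length used for effective
#'   lengths (`L - fragment_mean + 1`, floored at 1). Default 200.
#' @return list of class `compat_table`: `compat` (per-fragment integer
#'   vectors of transcript indices), `efflen` (named), `transcripts`
#'   (ids), `n_unmapped`, `n_mapped`.
#' @export
build_compatibility <- function(pairs, transcripts, k = 25L, tau = 0.8,
                                fragment_mean = 200L) {
  if (k < 8L) stop("k must be >= 8")
  if (k > min(nchar(c(pairs$seq1, pairs$seq2))))
    stop("k exceeds the read length")
  compat <- .kmer_compat_cpp(pairs$seq1, pairs$seq2, unname(transcripts),
                             as.integer(k), tau)
  efflen <- pmax(nchar(transcripts) - fragment_mean + 1, 1)
  names(efflen) <- names(transcripts)
  n_un <- sum(lengths(compat) == 0L)
  structure(list(compat = compat, efflen = efflen,
                 transcripts = names(transcripts),
                 n_unmapped = n_un, n_mapped = length(compat) - n_un),
            class = "compat_table")
}

#' EM expected fragment counts per transcript
#'
#' Standard length-normalized multinomial EM: the E-step assigns each
#' mapped fragment to its compatible transcripts proportionally to
#' `theta_t / efflen_t`; the M-step sets `theta` proportional to the
#' expected counts. Iterates until `max |delta theta| <= tol`. Expected
#' counts sum to the number of mapped fragments at every iteration.
#'
#' @param table a [build_compatibility()] result.
#' @param max_iter,tol convergence controls.
#' @return named numeric vector of expected counts (all zero, with a
#'   warning, when every fragment is unmapped); attribute `theta`
#'   carries the final proportions, `loglik` the final observed-data
#'   log-likelihood, and `count_sums` the total expected count at each
#'   iteration (conservation diagnostic).
#' @export
em_expected_counts <- function(table, max_iter = 1000L, tol = 1e-8) {
  stopifnot(inherits(table, "compat_table"))
  nt <- length(table$transcripts)
  mapped <- table$compat[lengths(table$compat) > 0L]
  if (length(mapped) == 0L) {
    warning("all fragments unmapped")
    out <- stats::setNames(numeric(nt), table$transcripts)
    attr(out, "theta") <- stats::setNames(rep(NA_real_, nt),
                                          table$transcripts)
    return(out)
  }
  # collapse fragments into equivalence classes by compatibility pattern
  keys <- vapply(mapped, function(x) paste(x, collapse = ","), character(1))
  cls <- table(keys)
  class_sets <- lapply(strsplit(names(cls), ",", fixed = TRUE), as.integer)
  class_n <- as.numeric(cls)
  efflen <- as.numeric(table$efflen)
  theta <- rep(1 / nt, nt)
  counts <- numeric(nt)
  count_sums <- numeric(0)
  for (it in seq_len(max_iter)) {
    counts[] <- 0
    ll <- 0
    for (ci in seq_along(class_sets)) {
      s <- class_sets[[ci]]
      w <- theta[s] / efflen[s]
      tw <- sum(w)
      if (tw <= 0) w <- rep(1 / length(s), length(s)) else w <- w / tw
      counts[s] <- counts[s] + class_n[ci] * w
      if (tw > 0) ll <- ll + class_n[ci] * log(tw)
    }
    count_sums <- c(count_sums, sum(counts))
    new_theta <- counts / sum(counts)
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    if (delta <= tol) break
  }
  out <- stats::setNames(counts, table$transcripts)
  attr(out, "theta") <- stats::setNames(theta, table$transcripts)
  attr(out, "loglik") <- ll
  attr(out, "iterations") <- it
  attr(out, "count_sums") <- count_sums
  out
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / ((efflen / 1e3) * (total / 1e6))`.
#'
#' @param expected_count expected fragment count(s).
#' @param effective_length_nt effective length(s), >= 1.
#' @param total_mapped_fragments total mapped fragments, >= 1.
#' @return FPKM value(s).
#' @export
fpkm <- function(expected_count, effective_length_nt,
                 total_mapped_fragments) {
  if (any(effective_length_nt < 1)) stop("effective length must be >= 1")
  if (total_mapped_fragments < 1) stop("total mapped fragments must be >= 1")
  expected_count / ((effective_length_nt / 1e3) *
                      (total_mapped_fragments / 1e6))
}

#' Roll transcript counts up to gene-level FPKM
#'
#' Gene expected count is the sum over member transcripts; gene
#' effective length is the count-weighted mean of member effective
#' lengths (unweighted mean when all member counts are zero).
#'
#' @param counts named per-transcript expected counts.
#' @param efflen named per-transcript effective lengths.
#' @param genes_map named character vector (transcript -> gene).
#' @param total total mapped fragments.
#' @return data.frame: `gene_id`, `expected_count`, `effective_length`,
#'   `fpkm`. A transcript with nonzero count missing from the map is an
#'   error naming it.
#' @export
gene_level <- function(counts, efflen, genes_map, total) {
  missing_tx <- setdiff(names(counts)[counts > 0], names(genes_map))
  if (length(missing_tx))
    stop("transcript(s) with nonzero counts not in genes_trans_map: ",
         paste(missing_tx, collapse = ", "))
  tx <- intersect(names(counts), names(genes_map))
  gene <- unname(genes_map[tx])
  cnt <- counts[tx]; el <- efflen[tx]
  out <- do.call(rbind, lapply(split(seq_along(tx), gene), function(i) {
    gc <- sum(cnt[i])
    gel <- if (gc > 0) sum(cnt[i] * el[i]) / gc else mean(el[i])
    data.frame(expected_count = gc, effective_length = gel,
               fpkm = fpkm(gc, max(gel, 1), total))
  }))
  out <- data.frame(gene_id = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Heat-map matrix and per-sample breakpoints
#'
#' Transforms gene FPKM to `log2(FPKM + 1)` and computes the rendering
#' breakpoints per sample: minimum fixed at 1, midpoint at the sample's
#' 75th percentile of transformed values (linear interpolation between
#' order statistics), maximum at the sample's own maximum. Samples
#' never share a scale. An all-zero sample yields breakpoints
#' `(1, 0, 0)` and is flagged degenerate.
#'
#' @param fpkm_matrix non-negative numeric matrix, genes x samples.
#' @return list of class `expression_matrix` with `fpkm`,
#'   `transformed`, and `breakpoints` (data.frame: sample, min, mid,
#'   max, degenerate).
#' @export
heatmap_matrix <- function(fpkm_matrix) {
  fpkm_matrix <- as.matrix(fpkm_matrix)
  if (any(fpkm_matrix < 0)) stop("FPKM must be non-negative")
  transformed <- log2(fpkm_matrix + 1)
  samples <- colnames(transformed) %||% as.character(seq_len(ncol(transformed)))
  bp <- do.call(rbind, lapply(seq_len(ncol(transformed)), function(j) {
    v <- transformed[, j]
    degenerate <- all(v == 0)
    data.frame(sample = samples[j], min = 1,
               mid = if (degenerate) 0
                     else unname(stats::quantile(v, 0.75, type = 7)),
               max = max(v), degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  structure(list(fpkm = fpkm_matrix, transformed = transformed,
                 breakpoints = bp),
            class = "expression_matrix")
}

#' Per-family share of summed FPKM
#'
#' @param gene_fpkm numeric matrix (genes x samples) or vector.
#' @param family named character vector mapping gene id -> family.
#' @return matrix (families x samples) of percentages summing to 100
#'   per sample; a sample with zero total FPKM yields `NA` shares with
#'   a warning.
#' @export
family_share <- function(gene_fpkm, family) {
  m <- as.matrix(gene_fpkm)
  fam <- family[rownames(m)]
  if (anyNA(fam)) stop("every gene needs a family assignment")
  out <- rowsum(m, fam)
  tot <- colSums(out)
  if (any(tot == 0)) warning("sample(s) with zero total FPKM")
  sweep(out, 2, tot, "/") * 100
}

#' Write a gene x sample FPKM matrix as TSV
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
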