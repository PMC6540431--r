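# Independent oracles. These deliberately avoid the package's own code
# paths: the codon table is a literal, alignments are enumerated, and
# counting is done the slow, obvious way.

# -- codon table oracle (hand-entered standard code) --------------------
.oracle_codons <- local({
  txt <- paste0(
    "TTT:F TTC:F TTA:L TTG:L CTT:L CTC:L CTA:L CTG:L ATT:I ATC:I ATA:I ",
    "ATG:M GTT:V GTC:V GTA:V GTG:V TCT:S TCC:S TCA:S TCG:S CCT:P CCC:P ",
    "CCA:P CCG:P ACT:T ACC:T ACA:T ACG:T GCT:A GCC:A GCA:A GCG:A TAT:Y ",
    "TAC:Y TAA:* TAG:* CAT:H CAC:H CAA:Q CAG:Q AAT:N AAC:N AAA:K AAG:K ",
    "GAT:D GAC:D GAA:E GAG:E TGT:C TGC:C TGA:* TGG:W CGT:R CGC:R CGA:R ",
    "CGG:R AGT:S AGC:S AGA:R AGG:R GGT:G GGC:G GGA:G GGG:G")
  kv <- strsplit(strsplit(txt, " +")[[1]], ":")
  stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
})

oracle_translate <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return("")
  out <- character(0)
  for (p in seq(1, n - 2, by = 3)) {
    cod <- substr(seq, p, p + 2)
    aa <- .oracle_codons[cod]
    out <- c(out, if (is.na(aa)) "X" else aa)
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

# -- end-gap-free unit-scored alignment oracle -------------------------
# match +1, mismatch -1, internal gap -1, terminal gaps free; reports
# the match count of the match-richest optimal alignment ((score,
# matches) lexicographic DP over all end cells on the last row/column)
oracle_nw_matches <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0L, n + 1, m + 1); M <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    eq <- x[i] == y[j]
    cand_s <- c(S[i, j] + if (eq) 1L else -1L, S[i, j + 1] - 1L,
                S[i + 1, j] - 1L)
    cand_m <- c(M[i, j] + as.integer(eq), M[i, j + 1], M[i + 1, j])
    best <- max(cand_s)
    S[i + 1, j + 1] <- best
    M[i + 1, j + 1] <- max(cand_m[cand_s == best])
  }
  ends_s <- c(S[n + 1, ], S[, m + 1], 0L)
  ends_m <- c(M[n + 1, ], M[, m + 1], 0L)
  best <- max(ends_s)
  max(ends_m[ends_s == best])
}

# -- exhaustive local-alignment enumeration oracle ---------------------
# A local alignment is a monotone matching of query and subject
# positions (aligned columns; substitutions allowed) with interior
# affine gap costs. All matchings are enumerated; ends are free.
oracle_sw_score <- function(q, s, mat, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  best <- 0
  gapcost <- function(d) if (d > 0) gap_open + gap_extend * d else 0
  for (k in seq_len(min(n, m))) {
    qi_sets <- utils::combn(n, k, simplify = FALSE)
    si_sets <- utils::combn(m, k, simplify = FALSE)
    for (qi in qi_sets) for (si in si_sets) {
      sc_sum <- sum(mat[cbind(sc[si], qc[qi])])
      if (k > 1) {
        dq <- diff(qi) - 1L; ds <- diff(si) - 1L
        sc_sum <- sc_sum - sum(vapply(dq, gapcost, 0)) -
          sum(vapply(ds, gapcost, 0))
      }
      if (sc_sum > best) best <- sc_sum
    }
  }
  best
}

# -- brute-force greedy clustering oracle (no prefilter) ---------------
oracle_collapse <- function(transcripts, threshold) {
  ord <- order(-nchar(transcripts), names(transcripts))
  ids <- names(transcripts)[ord]
  reps <- character(0)
  membership <- character(0)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      if (pairwise_identity(transcripts[[id]], transcripts[[r]]) >=
          threshold) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, id); hit <- id }
    membership[[id]] <- hit
  }
  list(representatives = reps, membership = membership[names(transcripts)])
}

# -- naive per-frame ORF scan oracle -----------------------------------
oracle_orfs <- function(seq, min_len_aa) {
  L <- nchar(seq)
  out <- list()
  for (strand in c(1L, -1L)) for (off in 0:2) {
    w <- if (strand == 1L) seq else oracle_revcomp(seq)
    if (nchar(w) - off < 3) next
    aa <- strsplit(oracle_translate(substr(w, off + 1, nchar(w))), "")[[1]]
    ncod <- length(aa)
    cod1 <- substring(substr(w, off + 1, nchar(w)),
                      seq(1, 3 * ncod, 3), seq(3, 3 * ncod, 3))
    seg_start <- 1L
    i <- 1L
    while (i <= ncod + 1L) {
      if (i > ncod || aa[i] == "*") {
        cs <- seg_start; ce <- i - 1L
        if (ce >= cs) {
          terminated <- i <= ncod
          atg <- which(cod1[cs:ce] == "ATG")
          rec <- NULL
          if (length(atg)) {
            a0 <- cs + atg[1] - 1L
            rec <- list(c1 = a0, c2 = ce,
                        class = if (terminated) "complete" else "partial3",
                        stop = terminated)
          } else if (cs == 1L) {
            rec <- list(c1 = 1L, c2 = ce,
                        class = if (terminated) "partial5" else "internal",
                        stop = terminated)
          }
          if (!is.null(rec) && rec$c2 - rec$c1 + 1L >= min_len_aa) {
            pep <- paste(aa[rec$c1:rec$c2], collapse = "")
            wa <- off + 3L * (rec$c1 - 1L)
            wb <- off + 3L * (rec$c2 + as.integer(rec$stop))
            if (strand == -1L) { t <- wa; wa <- L - wb; wb <- L - t }
            out[[length(out) + 1L]] <- data.frame(
              frame = strand * (off + 1L), start = wa, end = wb,
              peptide = pep, completeness = rec$class,
              stringsAsFactors = FALSE)
          }
        }
        seg_start <- i + 1L
      }
      i <- i + 1L
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$frame, df$start), , drop = FALSE]
}

# -- percentile (linear interpolation between order statistics) --------
oracle_percentile75 <- function(v) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h); hi <- ceiling(h)
  unname(v[lo] + (h - lo) * (v[hi] - v[lo]))
}

# random sequences
rand_nt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
rand_aa <- function(n, len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}
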