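# Ground-truthed synthetic transcriptomes and read sets. The generator
# plants gene-family members (reverse-translated with uniform synonymous
# codon choice) into transcripts with UTRs, class-controlled truncation,
# near-duplicate isoforms and GC-matched decoys, then simulates paired-end
# reads from a stated abundance vector. Everything is deterministic under
# a fixed seed.

#' Specify a synthetic gene family
#'
#' @param family_id family label, e.g. `"OR"`.
#' @param n_members number of member genes (>= 1).
#' @param mean_orf_len_aa mean complete-ORF length in amino acids (>= 30).
#' @param aa_divergence expected pairwise amino-acid divergence among
#'   members, in `[0, 0.9]`. (Divergence is realised by mutating each
#'   member independently from a common ancestor; pairwise divergence
#'   saturates near 0.95, so values above 0.9 are rejected.)
#' @param seed integer seed for this family's sequences.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(family_id, n_members, mean_orf_len_aa,
                        aa_divergence = 0, seed = 1L) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  if (n_members < 1L) stop("n_members must be >= 1")
  if (mean_orf_len_aa < 30) stop("mean_orf_len_aa must be >= 30")
  if (aa_divergence < 0 || aa_divergence >= 1)
    stop("aa_divergence must lie in [0, 1)")
  if (aa_divergence > 0.9)
    stop("aa_divergence above 0.9 is not representable by this generator")
  structure(list(family_id = family_id, n_members = as.integer(n_members),
                 mean_orf_len_aa = as.integer(mean_orf_len_aa),
                 aa_divergence = aa_divergence, seed = as.integer(seed)),
            class = "family_spec")
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# aa -> synonymous codon list (standard code, stops excluded)
.codons_by_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), gc)
    }
    tab
  }
})

# Uniform synonymous reverse translation of one peptide.
.reverse_translate <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  cb <- .codons_by_aa()
  codons <- vapply(aa, function(a) {
    opts <- cb[[a]]
    opts[[sample.int(length(opts), 1L)]]
  }, character(1))
  paste(codons, collapse = "")
}

# Per-member mutation rate r such that two members independently mutated
# from the ancestor at rate r show expected pairwise divergence d.
.member_rate <- function(d) {
  if (d <= 0) return(0)
  f <- function(r) 2 * r * (1 - r) + r^2 * 18 / 19 - d
  stats::uniroot(f, c(0, 0.97), tol = 1e-10)$root
}

#' Generate a synthetic protein family
#'
#' Members are drawn by mutating a random ancestor (first residue fixed
#' to M) so that expected pairwise divergence equals
#' `spec$aa_divergence`; all members of one family share the ancestor's
#' length, which is drawn near `mean_orf_len_aa`.
#'
#' @param spec a [family_spec()].
#' @return list with `proteins` (named character vector, each starting
#'   with M), `identity` (pairwise identity matrix) and `spec`.
#' @export
make_family_reference <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- max(30L, as.integer(round(stats::rnorm(1, spec$mean_orf_len_aa,
                                                0.02 * spec$mean_orf_len_aa))))
    ancestor <- c("M", sample(.AA20, L - 1L, replace = TRUE))
    r <- .member_rate(spec$aa_divergence)
    proteins <- vapply(seq_len(spec$n_members), function(i) {
      m <- ancestor
      if (r > 0 && L > 1L) {
        hit <- which(stats::runif(L - 1L) < r) + 1L # never touch the M
        for (p in hit) m[p] <- sample(setdiff(.AA20, m[p]), 1L)
      }
      paste(m, collapse = "")
    }, character(1))
    names(proteins) <- sprintf("%s%d", spec$family_id, seq_len(spec$n_members))
    n <- length(proteins)
    idm <- diag(1, n)
    dimnames(idm) <- list(names(proteins), names(proteins))
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      idm[i, j] <- idm[j, i] <- pairwise_identity(proteins[[i]], proteins[[j]])
    }
    list(proteins = proteins, identity = idm, spec = spec)
  })
}

.COMPLETENESS_CLASSES <- c("complete", "partial5", "partial3", "internal")

.random_nt <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Plant gene families into a synthetic transcriptome
#'
#' Each family member is reverse-translated, wrapped in UTRs and
#' truncated according to its completeness class: `complete` transcripts
#' carry UTR + ATG..stop + UTR; `partial5` transcripts start in-frame at
#' the transcript 5' end (no 5' UTR, start codon lost); `partial3`
#' transcripts run off the 3' end without a stop; `internal` fragments
#' lose both ends. Near-duplicate isoforms copy a planted transcript with
#' 1% nucleotide substitutions; decoys are random sequence with GC
#' matched to the planted transcripts within 0.05.
#'
#' @param families list of [family_spec()] objects.
#' @param completeness_mix named fractions over
#'   complete/partial5/partial3/internal; must sum to 1.
#' @param utr_len_range length-2 non-negative integer range for UTRs.
#' @param n_decoys number of unrelated decoy transcripts.
#' @param near_duplicate_rate per-transcript probability of emitting a
#'   >= 98%-identical isoform copy.
#' @param frac_reverse fraction of planted transcripts reverse-
#'   complemented (strand `-` in the truth table).
#' @param seed integer seed.
#' @return list with `transcripts` (named character), `truth`
#'   (data.frame: transcript_id, gene_id, family_id, member_id, class,
#'   orf_start, orf_end, strand, near_duplicate; ORF coordinates are
#'   0-based half-open on the transcript's own forward strand and cover
#'   the coding region excluding the stop codon), `proteins` (list of
#'   per-family named peptide vectors) and `genes_trans_map`.
#' @export
plant_transcriptome <- function(families,
                                completeness_mix = c(complete = 1),
                                utr_len_range = c(30L, 300L),
                                n_decoys = 0L,
                                near_duplicate_rate = 0,
                                frac_reverse = 0,
                                seed = 1L) {
  if (inherits(families, "family_spec")) families <- list(families)
  stopifnot(all(vapply(families, inherits, TRUE, "family_spec")))
  if (any(utr_len_range < 0)) stop("utr_len_range must be non-negative")
  mix <- completeness_mix[.COMPLETENESS_CLASSES]
  mix[is.na(mix)] <- 0
  names(mix) <- .COMPLETENESS_CLASSES
  if (abs(sum(mix) - 1) > 1e-9)
    stop("completeness_mix must sum to 1 over ",
         paste(.COMPLETENESS_CLASSES, collapse = "/"))
  refs <- lapply(families, make_family_reference)
  with_seed(seed, {
    tx <- character(0); rows <- list()
    for (fr in refs) {
      fam <- fr$spec$family_id
      classes <- sample(.COMPLETENESS_CLASSES, length(fr$proteins),
                        replace = TRUE, prob = mix)
      for (i in seq_along(fr$proteins)) {
        pep <- fr$proteins[[i]]
        cds <- .reverse_translate(pep)
        stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
        np <- nchar(pep)
        cls <- classes[[i]]
        utr5 <- sample(utr_len_range[1]:utr_len_range[2], 1L)
        utr3 <- sample(utr_len_range[1]:utr_len_range[2], 1L)
        if (cls == "complete") {
          s <- paste0(.random_nt(utr5), cds, stop_codon, .random_nt(utr3))
          orf <- c(utr5, utr5 + 3L * np)
        } else if (cls == "partial5") {
          cut <- max(1L, round(np * stats::runif(1, 0.1, 0.4)))
          aa <- strsplit(pep, "")[[1]]
          while (cut < np - 1L && aa[cut + 1L] == "M") cut <- cut + 1L
          kept <- substr(cds, 3L * cut + 1L, 3L * np)
          s <- paste0(kept, stop_codon, .random_nt(utr3))
          orf <- c(0L, nchar(kept))
        } else if (cls == "partial3") {
          cut <- max(1L, round(np * stats::runif(1, 0.1, 0.4)))
          kept <- substr(cds, 1L, 3L * (np - cut))
          s <- paste0(.random_nt(utr5), kept)
          orf <- c(utr5, utr5 + nchar(kept))
        } else { # internal
          c5 <- max(1L, round(np * stats::runif(1, 0.1, 0.25)))
          c3 <- max(1L, round(np * stats::runif(1, 0.1, 0.25)))
          aa <- strsplit(pep, "")[[1]]
          while (c5 < np - c3 - 2L && aa[c5 + 1L] == "M") c5 <- c5 + 1L
          kept <- substr(cds, 3L * c5 + 1L, 3L * (np - c3))
          s <- kept
          orf <- c(0L, nchar(kept))
        }
        strand <- "+"
        if (stats::runif(1) < frac_reverse) {
          L <- nchar(s)
          s <- revcomp(s)
          orf <- c(L - orf[2], L - orf[1])
          strand <- "-"
        }
        tid <- sprintf("%s_m%02d_t1", fam, i)
        gid <- sprintf("%s_g%02d", fam, i)
        tx[[tid]] <- s
        rows[[length(rows) + 1L]] <-
          data.frame(transcript_id = tid, gene_id = gid, family_id = fam,
                     member_id = names(fr$proteins)[i], class = cls,
                     orf_start = orf[1], orf_end = orf[2], strand = strand,
                     near_duplicate = FALSE, stringsAsFactors = FALSE)
      }
    }
    # near-duplicate isoforms: 1% substitutions, same gene
    base <- rows
    for (row in base) {
      if (stats::runif(1) < near_duplicate_rate) {
        src <- tx[[row$transcript_id]]
        chars <- strsplit(src, "")[[1]]
        n_edit <- max(1L, round(0.01 * length(chars)))
        pos <- sample.int(length(chars), n_edit)
        for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                  chars[p]), 1L)
        tid <- sub("_t1$", "_t2", row$transcript_id)
        tx[[tid]] <- paste(chars, collapse = "")
        row$transcript_id <- tid
        row$near_duplicate <- TRUE
        rows[[length(rows) + 1L]] <- row
      }
    }
    # decoys: GC matched within 0.05, lengths resampled from the plants
    if (n_decoys > 0L) {
      planted_gc <- mean(vapply(tx, .gc_fraction, numeric(1)))
      lens <- nchar(tx)
      for (d in seq_len(n_decoys)) {
        gc <- min(0.95, max(0.05, planted_gc + stats::runif(1, -0.05, 0.05)))
        tid <- sprintf("decoy_%03d", d)
        tx[[tid]] <- .random_nt(sample(lens, 1L), gc)
        rows[[length(rows) + 1L]] <-
          data.frame(transcript_id = tid, gene_id = tid, family_id = NA,
                     member_id = NA, class = "decoy", orf_start = NA,
                     orf_end = NA, strand = "+", near_duplicate = FALSE,
                     stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    list(transcripts = tx, truth = truth,
         proteins = stats::setNames(lapply(refs, `[[`, "proteins"),
                                    vapply(refs, function(r) r$spec$family_id,
                                           character(1))),
         genes_trans_map = stats::setNames(truth$gene_id,
                                           truth$transcript_id))
  })
}

# substitute bases in reads at a fixed per-base rate
.mutate_reads <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[p]), 1L)
    seqs[[i]] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a transcript set
#'
#' Fragments are drawn multinomially with probability proportional to
#' `theta` weighted by effective length (`L - insert_mean + 1`, floored
#' at 1); mate 1 reads the fragment 5' end forward, mate 2 the 3' end
#' reverse-complemented. Disjoint fractions of pairs are contaminated
#' with an adaptor prefix, with > 5% N bases, or with > 50% of bases
#' below Q10, on a randomly chosen mate.
#'
#' @param transcripts named character vector.
#' @param theta abundance simplex over `transcripts` (sums to 1).
#' @param n_fragments total fragment count.
#' @param read_len read length; must be shorter than every transcript.
#' @param insert_mean,insert_sd fragment-length distribution (normal,
#'   clamped to `[read_len, transcript length]`).
#' @param error_rate per-base substitution rate.
#' @param adaptor_rate,nfrac_rate,lowq_rate contamination fractions.
#' @param adaptor adaptor sequence used for contamination.
#' @param seed integer seed.
#' @return list with `pairs` (data.frame: read_id, seq1, qual1, seq2,
#'   qual2), `truth` (list: `counts` named per-transcript fragment
#'   counts summing to `n_fragments`; `theta`) and `contamination`
#'   (data.frame: read_id, type in none/adaptor/nfrac/lowq).
#' @export
simulate_reads <- function(transcripts, theta, n_fragments,
                           read_len = 90L, insert_mean = 200L,
                           insert_sd = 20L, error_rate = 0.001,
                           adaptor_rate = 0, nfrac_rate = 0, lowq_rate = 0,
                           adaptor = "AGATCGGAAGAGCACACGTCT",
                           seed = 1L) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  stopifnot(length(theta) == length(transcripts), all(theta >= 0))
  if (abs(sum(theta) - 1) > 1e-9) stop("theta must sum to 1")
  lens <- nchar(transcripts)
  if (read_len >= min(lens))
    stop("read_len must be shorter than the shortest transcript")
  if (adaptor_rate + nfrac_rate + lowq_rate > 1)
    stop("contamination rates must sum to at most 1")
  with_seed(seed, {
    efflen <- pmax(lens - insert_mean + 1, 1)
    p <- theta * efflen
    if (sum(p) <= 0) stop("theta places no mass on usable transcripts")
    counts <- as.vector(stats::rmultinom(1, n_fragments, p / sum(p)))
    names(counts) <- names(transcripts)
    seq1 <- seq2 <- character(n_fragments)
    origin <- character(n_fragments)
    k <- 0L
    for (t in seq_along(transcripts)) {
      ct <- counts[t]
      if (ct == 0L) next
      L <- lens[t]
      ins <- pmin(pmax(round(stats::rnorm(ct, insert_mean, insert_sd)),
                       read_len), L)
      starts <- 1L + floor(stats::runif(ct) * (L - ins + 1))
      s <- transcripts[[t]]
      i <- k + seq_len(ct)
      seq1[i] <- substring(s, starts, pmin(starts + read_len - 1L, L))
      seq2[i] <- revcomp(substring(s, starts + ins - read_len,
                                   starts + ins - 1L))
      origin[i] <- names(transcripts)[t]
      k <- k + ct
    }
    ord <- sample.int(n_fragments)
    seq1 <- seq1[ord]; seq2 <- seq2[ord]; origin <- origin[ord]
    seq1 <- .mutate_reads(seq1, error_rate)
    seq2 <- .mutate_reads(seq2, error_rate)
    qual1 <- strrep("F", nchar(seq1))
    qual2 <- strrep("F", nchar(seq2))
    u <- stats::runif(n_fragments)
    type <- rep("none", n_fragments)
    type[u < adaptor_rate] <- "adaptor"
    type[u >= adaptor_rate & u < adaptor_rate + nfrac_rate] <- "nfrac"
    type[u >= adaptor_rate + nfrac_rate &
           u < adaptor_rate + nfrac_rate + lowq_rate] <- "lowq"
    which_mate <- 1L + (stats::runif(n_fragments) < 0.5)
    for (i in which(type != "none")) {
      if (which_mate[i] == 1L) { s <- seq1[i]; q <- qual1[i] }
      else { s <- seq2[i]; q <- qual2[i] }
      n <- nchar(s)
      if (type[i] == "adaptor") {
        al <- min(nchar(adaptor), n)
        s <- paste0(substr(adaptor, 1L, al), substr(s, al + 1L, n))
      } else if (type[i] == "nfrac") {
        m <- max(ceiling(0.08 * n), floor(0.05 * n) + 1L)
        pos <- sample.int(n, m)
        chars <- strsplit(s, "")[[1]]; qc <- strsplit(q, "")[[1]]
        chars[pos] <- "N"; qc[pos] <- "#"
        s <- paste(chars, collapse = ""); q <- paste(qc, collapse = "")
      } else { # lowq
        m <- max(ceiling(0.6 * n), floor(0.5 * n) + 1L)
        pos <- sample.int(n, m)
        qc <- strsplit(q, "")[[1]]
        qc[pos] <- "&" # Q5
        q <- paste(qc, collapse = "")
      }
      if (which_mate[i] == 1L) { seq1[i] <- s; qual1[i] <- q }
      else { seq2[i] <- s; qual2[i] <- q }
    }
    ids <- sprintf("frag%07d", seq_len(n_fragments))
    list(pairs = data.frame(read_id = ids, seq1 = seq1, qual1 = qual1,
                            seq2 = seq2, qual2 = qual2,
                            stringsAsFactors = FALSE),
         truth = list(counts = counts, theta = theta, origin = origin),
         contamination = data.frame(read_id = ids, type = type,
                                    stringsAsFactors = FALSE))
  })
}
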