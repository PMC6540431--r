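# Iterative gene-family annotation: known-gene matching, novel-candidate
# discovery under family-specific ORF-length filters, pseudogene
# flagging, gene-model collapse proposals and sequential nomenclature.
# Discovery repeats with newly found members added to the query set
# until a round adds nothing (fixpoint) or max_rounds is reached.

#' Family annotation policy
#'
#' @param family_id family label.
#' @param avg_complete_orf_len_aa average length of a complete ORF in
#'   the family (aa); the length filter cutoff is
#'   `min_fraction * avg_complete_orf_len_aa`, strict.
#' @param min_fraction fraction of the family average a candidate ORF
#'   must exceed. Default 0.5.
#' @param known_identity_floor amino-acid identity to a reference at or
#'   above which a candidate is treated as an isoform of the known gene
#'   rather than a novel gene. Default 0.98.
#' @return object of class `family_policy`.
#' @export
family_policy <- function(family_id, avg_complete_orf_len_aa,
                          min_fraction = 0.5, known_identity_floor = 0.98) {
  stopifnot(avg_complete_orf_len_aa > 0,
            min_fraction > 0, min_fraction <= 1)
  structure(list(family_id = family_id,
                 avg_complete_orf_len_aa = avg_complete_orf_len_aa,
                 min_fraction = min_fraction,
                 known_identity_floor = known_identity_floor),
            class = "family_policy")
}

#' Default policies for the seven chemosensory families
#'
#' Average complete-ORF lengths: OR 406, GR 447, IR 676, OBP 178,
#' CSP 132, CXE 563, CYP 510 aa.
#'
#' @return named list of [family_policy()] objects.
#' @export
default_family_policies <- function() {
  avg <- c(OR = 406, GR = 447, IR = 676, OBP = 178, CSP = 132,
           CXE = 563, CYP = 510)
  stats::setNames(lapply(names(avg), function(f) family_policy(f, avg[[f]])),
                  names(avg))
}

#' Family ORF-length filter
#'
#' Passes iff `length_aa > min_fraction * avg_complete_orf_len_aa`
#' (strictly greater): an OR candidate passes at 204 aa and fails at
#' exactly 203 aa.
#'
#' @param length_aa candidate ORF length (aa) — or a row of
#'   [find_orfs()] output, whose `length_aa` is used.
#' @param policy a [family_policy()].
#' @return logical.
#' @export
length_filter <- function(length_aa, policy) {
  stopifnot(inherits(policy, "family_policy"))
  if (is.list(length_aa)) length_aa <- length_aa$length_aa
  length_aa > policy$min_fraction * policy$avg_complete_orf_len_aa
}

# empty annotation record table
.empty_records <- function() {
  data.frame(name = character(0), family_id = character(0),
             gene_id = character(0), transcript_id = character(0),
             status = character(0), frame = integer(0),
             orf_start = integer(0), orf_end = integer(0),
             completeness = character(0), length_aa = integer(0),
             peptide = character(0), discovered_in_iteration = integer(0),
             query_id = character(0), evalue = numeric(0),
             pct_identity = numeric(0), contains_internal_stop = logical(0),
             stringsAsFactors = FALSE)
}

.record_row <- function(name, family, hit, orf, status, iteration) {
  data.frame(name = name, family_id = family,
             gene_id = if (is.null(hit)) NA_character_ else hit$gene_id,
             transcript_id = if (is.null(hit)) NA_character_
                             else hit$transcript_id,
             status = status,
             frame = if (is.null(orf)) NA_integer_ else orf$frame,
             orf_start = if (is.null(orf)) NA_integer_ else orf$start,
             orf_end = if (is.null(orf)) NA_integer_ else orf$end,
             completeness = if (is.null(orf)) NA_character_
                            else orf$completeness,
             length_aa = if (is.null(orf)) NA_integer_ else orf$length_aa,
             peptide = if (is.null(orf)) NA_character_ else orf$peptide,
             discovered_in_iteration = iteration,
             query_id = if (is.null(hit)) NA_character_ else hit$query_id,
             evalue = if (is.null(hit)) NA_real_ else hit$evalue,
             pct_identity = if (is.null(hit)) NA_real_ else hit$pct_identity,
             contains_internal_stop = if (is.null(hit)) NA
                                      else hit$contains_internal_stop,
             stringsAsFactors = FALSE)
}

# best ORF on a hit's transcript/frame overlapping the hit's subject span
.best_orf_for_hit <- function(orfs, hit) {
  cand <- orfs[orfs$frame == hit$frame &
                 orfs$aa_end > hit$s_start & orfs$aa_start < hit$s_end, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  as.list(cand[which.max(cand$length_aa), ])
}

# hit-guided candidate ORF: best overlapping call, refined by alignment
# coverage; an ORF whose ATG the homology marks as internal is extended
# back to its (transcript-anchored) segment start before the refined
# completeness is applied
.candidate_from_hit <- function(orfs, hit, query_len, seq) {
  orf <- .best_orf_for_hit(orfs, hit)
  if (is.null(orf)) return(NULL)
  refined <- classify_against_hit(orf, hit, query_len)
  structural_start <- orf$completeness %in% c("complete", "partial3")
  if (refined %in% c("partial5", "internal") && structural_start &&
      orf$aa_seg_start == 0L)
    orf <- extend_orf_to_segment(orf, seq)
  orf$completeness <- refined
  orf
}

#' Match previously annotated genes to the transcriptome
#'
#' Each known reference is assigned the gene cluster of its top hit;
#' references whose aligned region carries in-frame stop codons with no
#' qualifying ORF are flagged as pseudogenized; references without any
#' hit are reported `not_found`. Two known genes resolving to the same
#' gene cluster are both recorded (a collapse proposal, via
#' [propose_collapses()]) rather than silently merged.
#'
#' @param known_refs named list (family id -> named character vector of
#'   reference peptides).
#' @param transcripts named character vector.
#' @param hits optional precomputed [search_homology()] result for the
#'   reference queries; computed when `NULL`.
#' @param policies named list of [family_policy()] objects.
#' @param config a [search_config()].
#' @param genes_map optional transcript -> gene map.
#' @return annotation record data.frame (statuses `known`,
#'   `flagged_pseudogenized`, `not_found`).
#' @export
match_known <- function(known_refs, transcripts, hits = NULL,
                        policies = default_family_policies(),
                        config = search_config(), genes_map = NULL) {
  queries <- unlist(unname(lapply(known_refs, function(x) as.list(x))),
                    recursive = FALSE)
  queries <- stats::setNames(unlist(queries),
                             unlist(lapply(known_refs, names)))
  qfam <- rep(names(known_refs), vapply(known_refs, length, 0L))
  names(qfam) <- names(queries)
  if (is.null(hits))
    hits <- search_homology(queries, transcripts, config, genes_map)
  orf_cache <- new.env(parent = emptyenv())
  get_orfs <- function(tid) {
    # scan at floor 1: hit-guided refinement decides what qualifies
    if (is.null(orf_cache[[tid]]))
      orf_cache[[tid]] <- find_orfs(transcripts[[tid]], tid, 1L)
    orf_cache[[tid]]
  }
  rows <- list()
  for (qid in names(queries)) {
    fam <- qfam[[qid]]
    pol <- policies[[fam]]
    gene <- top_hit_transcript(qid, hits)
    if (is.na(gene)) {
      rows[[length(rows) + 1L]] <- .record_row(qid, fam, NULL, NULL,
                                               "not_found", 0L)
      next
    }
    h <- hits[hits$query_id == qid & hits$gene_id == gene, , drop = FALSE]
    h <- as.list(h[order(h$evalue, -h$raw_score)[1], ])
    orf <- .candidate_from_hit(get_orfs(h$transcript_id), h,
                               nchar(queries[[qid]]),
                               transcripts[[h$transcript_id]])
    qualifying <- !is.null(orf) && !is.null(pol) && length_filter(orf, pol)
    status <- if (h$contains_internal_stop && !qualifying)
      "flagged_pseudogenized" else "known"
    rows[[length(rows) + 1L]] <- .record_row(qid, fam, h, orf, status, 0L)
  }
  out <- do.call(rbind, c(list(.empty_records()), rows))
  rownames(out) <- NULL
  out
}

#' Iterative family annotation
#'
#' Round 0 matches known references ([match_known()]); each subsequent
#' round searches the current query set, and hits on still-unannotated
#' gene clusters that pass the family length filter and are not
#' pseudogenized become novel records whose peptides join the query
#' set. Iteration stops when a round adds no record, or at
#' `max_rounds`. Novel records are then named sequentially
#' ([assign_names()]).
#'
#' @inheritParams match_known
#' @param max_rounds maximum discovery rounds (>= 1). `max_rounds = 1`
#'   disables iterative discovery beyond the reference queries.
#' @return list with `records` (annotation data.frame), `log`
#'   (per-round additions), `queries` (final query set),
#'   `isoform_evidence` (hits treated as isoforms of known genes).
#' @export
iterate_annotation <- function(transcripts, known_refs,
                               policies = default_family_policies(),
                               config = search_config(), genes_map = NULL,
                               max_rounds = 10L) {
  stopifnot(max_rounds >= 1L)
  if (length(transcripts) == 0L)
    return(list(records = .empty_records(),
                log = data.frame(round = 1L, added = 0L),
                queries = character(0), isoform_evidence = .empty_records()))
  queries <- stats::setNames(unlist(unname(known_refs)),
                             unlist(lapply(known_refs, names)))
  qfam <- stats::setNames(rep(names(known_refs),
                              vapply(known_refs, length, 0L)),
                          names(queries))
  hits0 <- search_homology(queries, transcripts, config, genes_map)
  records <- match_known(known_refs, transcripts, hits = hits0,
                         policies = policies, config = config,
                         genes_map = genes_map)
  annotated <- split(records$gene_id[!is.na(records$gene_id)],
                     records$family_id[!is.na(records$gene_id)])
  orf_cache <- new.env(parent = emptyenv())
  get_orfs <- function(tid) {
    if (is.null(orf_cache[[tid]]))
      orf_cache[[tid]] <- find_orfs(transcripts[[tid]], tid, 1L)
    orf_cache[[tid]]
  }
  iso_rows <- list()
  log <- list()
  all_queries <- queries
  pending_hits <- hits0
  novel_i <- 0L
  for (round in seq_len(max_rounds)) {
    added <- 0L
    next_queries <- character(0)
    h <- pending_hits
    if (nrow(h)) {
      h$family <- qfam[h$query_id]
      # candidate = unannotated gene cluster within the query's family
      h <- h[!mapply(function(f, g) g %in% (annotated[[f]] %||% character(0)),
                     h$family, h$gene_id), , drop = FALSE]
    }
    if (nrow(h)) {
      # isoforms of known genes: near-exact identity to a reference
      floor_of <- vapply(h$family, function(f)
        policies[[f]]$known_identity_floor %||% 0.98, numeric(1))
      is_ref <- h$query_id %in% names(queries)
      iso <- is_ref & h$pct_identity >= floor_of
      if (any(iso)) iso_rows[[length(iso_rows) + 1L]] <- h[iso, , drop = FALSE]
      h <- h[!iso, , drop = FALSE]
    }
    if (nrow(h)) {
      h <- h[order(h$evalue, -h$raw_score, h$transcript_id), , drop = FALSE]
      for (key in unique(paste(h$family, h$gene_id, sep = "\r"))) {
        fam <- sub("\r.*$", "", key)
        gene <- sub("^.*\r", "", key)
        if (gene %in% (annotated[[fam]] %||% character(0))) next
        hh <- h[h$family == fam & h$gene_id == gene, , drop = FALSE]
        best <- as.list(hh[1, ])
        pol <- policies[[fam]]
        if (is.null(pol)) next
        orf <- .candidate_from_hit(get_orfs(best$transcript_id), best,
                                   nchar(all_queries[[best$query_id]]),
                                   transcripts[[best$transcript_id]])
        qualifying <- !is.null(orf) && length_filter(orf, pol)
        if (!qualifying) {
          if (best$contains_internal_stop) {
            novel_i <- novel_i + 1L
            rec <- .record_row(sprintf(".cand%04d", novel_i), fam, best,
                               orf, "flagged_pseudogenized", round)
            records <- rbind(records, rec)
            annotated[[fam]] <- c(annotated[[fam]], gene)
            added <- added + 1L
          }
          next
        }
        novel_i <- novel_i + 1L
        provisional <- sprintf(".cand%04d", novel_i)
        rec <- .record_row(provisional, fam, best, orf, "novel", round)
        records <- rbind(records, rec)
        annotated[[fam]] <- c(annotated[[fam]], gene)
        next_queries[[provisional]] <- orf$peptide
        all_queries[[provisional]] <- orf$peptide
        qfam[[provisional]] <- fam
        added <- added + 1L
      }
    }
    log[[round]] <- data.frame(round = round, added = added)
    if (added == 0L) break
    if (round == max_rounds) break
    new_queries <- next_queries
    if (length(next_queries) == 0L) break
    pending_hits <- search_homology(next_queries, transcripts, config,
                                    genes_map)
  }
  records <- assign_names(records, known_refs)
  list(records = records, log = do.call(rbind, log),
       queries = c(queries,
                   stats::setNames(records$peptide[records$status == "novel"],
                                   records$name[records$status == "novel"])),
       isoform_evidence = do.call(rbind, c(list(NULL), iso_rows)))
}

#' Sequential nomenclature for novel records
#'
#' Novel (and flagged) records receive the next free integer suffix in
#' their family, in discovery order (iteration, then E-value), starting
#' after the highest suffix present in the existing inventory. A
#' proposed name colliding with the inventory is an error.
#'
#' @param records annotation record data.frame.
#' @param known_refs named list of reference peptide sets; their names
#'   form the existing inventory per family.
#' @return the records with `name` filled for novel/flagged entries.
#' @export
assign_names <- function(records, known_refs) {
  for (fam in unique(records$family_id)) {
    inventory <- names(known_refs[[fam]]) %||% character(0)
    suffixes <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1",
                                                inventory)))
    nxt <- if (all(is.na(suffixes))) 1L else max(suffixes, na.rm = TRUE) + 1L
    idx <- which(records$family_id == fam &
                   records$status %in% c("novel", "flagged_pseudogenized") &
                   grepl("^\\.cand", records$name))
    if (!length(idx)) next
    ord <- idx[order(records$discovered_in_iteration[idx],
                     records$evalue[idx])]
    for (i in ord) {
      nm <- sprintf("%s%d", fam, nxt)
      if (nm %in% inventory)
        stop("name collision for ", nm, " in family ", fam)
      records$name[i] <- nm
      nxt <- nxt + 1L
    }
  }
  records
}

#' Propose collapses of records sharing a gene cluster
#'
#' Records from the same family whose hits land on one gene cluster
#' with mutually overlapping subject spans are merged: the surviving
#' name is the first in `precedence` (default: lexicographic by name),
#' the rest become `collapsed_alias`. Records on one gene with disjoint
#' spans (possible fusion transcript) are left alone with a warning;
#' cross-family sharing is reported, never merged.
#'
#' @param records annotation record data.frame.
#' @param precedence optional character vector of names; earlier wins.
#' @return list with `records` (aliases marked) and `proposals`
#'   (data.frame describing each merge or warning).
#' @export
propose_collapses <- function(records, precedence = NULL) {
  proposals <- list()
  live <- records$status %in% c("known", "novel")
  key <- paste(records$family_id, records$gene_id, sep = "\r")
  for (k in unique(key[live & !is.na(records$gene_id)])) {
    idx <- which(key == k & live)
    if (length(idx) < 2L) next
    # overlap of subject spans on the shared transcript/frame
    spans <- records[idx, c("orf_start", "orf_end")]
    overlapping <- TRUE
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      if (is.na(spans$orf_start[a]) || is.na(spans$orf_start[b])) next
      if (spans$orf_end[a] <= spans$orf_start[b] ||
          spans$orf_end[b] <= spans$orf_start[a]) overlapping <- FALSE
    }
    fam <- records$family_id[idx[1]]
    if (!overlapping) {
      warning("records ", paste(records$name[idx], collapse = ", "),
              " share gene ", records$gene_id[idx[1]],
              " with disjoint spans; not collapsed")
      proposals[[length(proposals) + 1L]] <- data.frame(
        gene_id = records$gene_id[idx[1]], family_id = fam,
        action = "warn_disjoint",
        names = paste(records$name[idx], collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    nm <- records$name[idx]
    ord <- if (!is.null(precedence)) {
      pr <- match(nm, precedence)
      pr[is.na(pr)] <- length(precedence) + seq_len(sum(is.na(pr)))
      idx[order(pr)]
    } else idx[order(nm)]
    keep <- ord[1]
    for (i in ord[-1]) records$status[i] <- "collapsed_alias"
    proposals[[length(proposals) + 1L]] <- data.frame(
      gene_id = records$gene_id[keep], family_id = fam, action = "collapse",
      names = paste(c(records$name[keep],
                      records$name[setdiff(ord, keep)]), collapse = ","),
      stringsAsFactors = FALSE)
  }
  # cross-family sharing: report only
  gk <- records$gene_id[live & !is.na(records$gene_id)]
  gf <- records$family_id[live & !is.na(records$gene_id)]
  for (g in unique(gk)) {
    fams <- unique(gf[gk == g])
    if (length(fams) > 1L)
      proposals[[length(proposals) + 1L]] <- data.frame(
        gene_id = g, family_id = paste(fams, collapse = ","),
        action = "cross_family_report", names = NA_character_,
        stringsAsFactors = FALSE)
  }
  list(records = records,
       proposals = do.call(rbind, c(list(NULL), proposals)) %||%
         data.frame(gene_id = character(0), family_id = character(0),
                    action = character(0), names = character(0)))
}

#' Write annotation records as TSV
#' @param records annotation record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
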