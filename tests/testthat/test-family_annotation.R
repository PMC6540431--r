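test_that("length filter arithmetic is strict at every family boundary", {
  pols <- default_family_policies()
  avgs <- c(OR = 406, GR = 447, IR = 676, OBP = 178, CSP = 132,
            CXE = 563, CYP = 510)
  for (f in names(avgs)) {
    cutoff <- 0.5 * avgs[[f]]
    expect_false(length_filter(floor(cutoff), pols[[f]]))
    expect_true(length_filter(floor(cutoff) + 1L, pols[[f]]))
    # the boundary itself fails (strict ">")
    expect_false(length_filter(cutoff, pols[[f]]))
  }
  # the worked OR/OBP instances
  expect_true(length_filter(204, pols$OR))
  expect_false(length_filter(203, pols$OR))
  expect_true(length_filter(90, pols$OBP))
})

annotation_world <- function(seed = 90, n_members = 5, known = 2,
                             divergence = 0.25) {
  pt <- plant_transcriptome(list(family_spec("OR", n_members, 120,
                                             divergence, seed = seed)),
                            n_decoys = 6, seed = seed + 1)
  list(pt = pt, refs = list(OR = pt$proteins$OR[seq_len(known)]),
       policies = list(OR = family_policy("OR", 120)))
}

test_that("match_known: known, pseudogenized, and not_found statuses", {
  w <- annotation_world()
  recs <- match_known(w$refs, w$pt$transcripts, policies = w$policies,
                      genes_map = w$pt$genes_trans_map)
  expect_setequal(recs$name, names(w$refs$OR))
  expect_true(all(recs$status == "known"))
  expect_true(all(recs$pct_identity >= 0.98))
  expect_identical(recs$gene_id,
                   unname(w$pt$genes_trans_map[
                     w$pt$truth$transcript_id[match(recs$name,
                                                    w$pt$truth$member_id)]]))

  # removing a member's transcript -> not_found
  tx2 <- w$pt$transcripts[names(w$pt$transcripts) != "OR_m01_t1"]
  tx2 <- tx2[grepl("decoy", names(tx2))] # only decoys left
  recs2 <- match_known(w$refs, tx2, policies = w$policies)
  expect_true(all(recs2$status == "not_found"))

  # three in-frame stops planted inside the ORF -> flagged_pseudogenized
  tr <- w$pt$truth[which(w$pt$truth$member_id == "OR1"), ]
  s <- w$pt$transcripts[[tr$transcript_id]]
  for (cod in c(30, 60, 90)) {
    p <- tr$orf_start + 3 * cod
    s <- paste0(substr(s, 1, p), "TAA", substr(s, p + 4, nchar(s)))
  }
  tx3 <- w$pt$transcripts
  tx3[[tr$transcript_id]] <- s
  recs3 <- match_known(w$refs, tx3, policies = w$policies,
                       genes_map = w$pt$genes_trans_map)
  expect_identical(recs3$status[recs3$name == "OR1"],
                   "flagged_pseudogenized")
  expect_true(recs3$contains_internal_stop[recs3$name == "OR1"])
})

test_that("iterate_annotation: recall, decoy precision, fixpoint, naming", {
  w <- annotation_world(seed = 92, n_members = 6, known = 3)
  ann <- iterate_annotation(w$pt$transcripts, w$refs,
                            policies = w$policies,
                            genes_map = w$pt$genes_trans_map)
  recs <- ann$records
  # recall 1.0: every planted gene annotated; no decoys
  planted_genes <- unique(w$pt$truth$gene_id[!is.na(w$pt$truth$member_id)])
  expect_setequal(recs$gene_id, planted_genes)
  expect_false(any(grepl("decoy", recs$gene_id)))
  expect_identical(sum(recs$status == "known"), 3L)
  expect_identical(sum(recs$status == "novel"), 3L)
  # novel names continue the inventory: OR4, OR5, OR6
  expect_setequal(recs$name[recs$status == "novel"],
                  c("OR4", "OR5", "OR6"))
  # every novel passes its family's length filter
  expect_true(all(vapply(which(recs$status == "novel"), function(i)
    length_filter(recs$length_aa[i], w$policies$OR), logical(1))))
  # monotone growth and fixpoint: last round adds nothing
  expect_true(all(diff(ann$log$added) <= 0) ||
                ann$log$added[nrow(ann$log)] == 0L)
  # re-running with the full query set as knowns adds nothing new
  refs2 <- list(OR = ann$queries)
  pol2 <- w$policies
  ann2 <- iterate_annotation(w$pt$transcripts, refs2, policies = pol2,
                             genes_map = w$pt$genes_trans_map)
  expect_identical(sum(ann2$records$status == "novel"), 0L)
  # determinism
  again <- iterate_annotation(w$pt$transcripts, w$refs,
                              policies = w$policies,
                              genes_map = w$pt$genes_trans_map)
  expect_identical(again$records, recs)
  # empty transcriptome -> empty records
  e <- iterate_annotation(character(0), w$refs, policies = w$policies)
  expect_identical(nrow(e$records), 0L)
})

test_that("stepping-stone member is found only when iteration is enabled", {
  st <- stepping_stone_scenario()
  full <- iterate_annotation(st$transcripts, st$refs,
                             policies = st$policies,
                             genes_map = st$genes_map)
  expect_true("STA_t" %in% full$records$transcript_id)
  expect_true("STB_t" %in% full$records$transcript_id)
  b <- full$records[full$records$transcript_id == "STB_t", ]
  expect_gte(b$discovered_in_iteration, 2L)
  one <- iterate_annotation(st$transcripts, st$refs,
                            policies = st$policies,
                            genes_map = st$genes_map, max_rounds = 1L)
  expect_true("STA_t" %in% one$records$transcript_id)
  expect_false("STB_t" %in% one$records$transcript_id)
})

test_that("collapse proposals merge overlapping same-gene records", {
  base <- data.frame(name = c("IR2", "IR3", "IR4"), family_id = "IR",
                     gene_id = "g1", transcript_id = "t1",
                     status = "known", frame = 1L,
                     orf_start = c(10L, 13L, 10L),
                     orf_end = c(700L, 700L, 650L),
                     completeness = "complete", length_aa = 200L,
                     peptide = "M", discovered_in_iteration = 0L,
                     query_id = c("IR2", "IR3", "IR4"), evalue = 1e-30,
                     pct_identity = 0.99, contains_internal_stop = FALSE,
                     stringsAsFactors = FALSE)
  out <- propose_collapses(base)
  expect_identical(sum(out$records$status == "collapsed_alias"), 2L)
  expect_identical(out$records$status[out$records$name == "IR2"], "known")
  expect_identical(out$proposals$action, "collapse")

  # disjoint spans (fusion transcript): warn, never merge
  base$orf_start <- c(0L, 400L, 800L)
  base$orf_end <- c(300L, 700L, 1100L)
  expect_warning(out2 <- propose_collapses(base), "disjoint")
  expect_false(any(out2$records$status == "collapsed_alias"))

  # cross-family sharing is reported, not merged
  base2 <- base[1:2, ]
  base2$orf_start <- c(0L, 10L); base2$orf_end <- c(300L, 310L)
  base2$family_id <- c("IR", "OR")
  out3 <- propose_collapses(base2)
  expect_true("cross_family_report" %in% out3$proposals$action)
  expect_false(any(out3$records$status == "collapsed_alias"))
})

test_that("assign_names extends the inventory sequentially", {
  recs <- data.frame(name = c("OR10", ".cand0001", ".cand0002"),
                     family_id = "OR", gene_id = c("g1", "g2", "g3"),
                     transcript_id = "t", status = c("known", "novel",
                                                     "novel"),
                     frame = 1L, orf_start = 0L, orf_end = 3L,
                     completeness = "complete", length_aa = 300L,
                     peptide = "M",
                     discovered_in_iteration = c(0L, 2L, 1L),
                     query_id = "q", evalue = c(0, 1e-20, 1e-40),
                     pct_identity = 0.5, contains_internal_stop = FALSE,
                     stringsAsFactors = FALSE)
  # inventory through OR46 -> novels named OR47, OR48 in discovery order
  inv <- list(OR = stats::setNames(rep("M", 46), paste0("OR", 1:46)))
  named <- assign_names(recs, inv)
  expect_identical(named$name[named$discovered_in_iteration == 1L], "OR47")
  expect_identical(named$name[named$discovered_in_iteration == 2L], "OR48")
  # empty inventory -> suffix 1
  named2 <- assign_names(recs, list(OR = character(0)))
  expect_setequal(named2$name[named2$status == "novel"], c("OR1", "OR2"))
})
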