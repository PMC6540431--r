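test_that("six-frame translation matches the codon-table oracle", {
  expect_identical(six_frame_translate("ATGAAATAA")[["+1"]], "MK*")

  with_seed(70, {
    for (i in 1:12) {
      s <- rand_nt(1, 300)
      fr <- six_frame_translate(s)
      rc <- oracle_revcomp(s)
      expect_identical(fr[["+1"]], oracle_translate(s))
      expect_identical(fr[["+2"]], oracle_translate(substr(s, 2, 300)))
      expect_identical(fr[["+3"]], oracle_translate(substr(s, 3, 300)))
      expect_identical(fr[["-1"]], oracle_translate(rc))
      expect_identical(fr[["-2"]], oracle_translate(substr(rc, 2, 300)))
      expect_identical(fr[["-3"]], oracle_translate(substr(rc, 3, 300)))
    }
  })

  # reverse-complement property and N handling
  s <- "ATGNNNAAATAA"
  expect_identical(six_frame_translate(s)[["+1"]], "MXK*")
  expect_identical(six_frame_translate(s)[["-1"]],
                   six_frame_translate(revcomp(s))[["+1"]])
  # length < 3: empty frames, no error
  expect_identical(unname(six_frame_translate("AT")), rep("", 6))
})

test_that("find_orfs closed cases", {
  one <- find_orfs("ATGAAATAA", min_len_aa = 1)
  fwd <- one[one$frame == 1, ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$peptide, "MK")
  expect_identical(fwd$completeness, "complete")
  expect_identical(fwd$length_aa, 2L)
  expect_identical(c(fwd$start, fwd$end), c(0L, 9L)) # stop included

  # no ATG after the in-frame stop -> no complete ORF anywhere in +1
  poly <- paste0("AAATGA", strrep("A", 30))
  o <- find_orfs(poly, min_len_aa = 1)
  expect_false(any(o$completeness == "complete" & o$frame == 1))

  # N-containing codons never act as start or stop
  o2 <- find_orfs("AANGAAATAA", min_len_aa = 1)
  expect_false(any(vapply(seq_len(nrow(o2)), function(i)
    grepl("^ATG", substr("AANGAAATAA", o2$start[i] + 1, o2$end[i])) &&
      o2$frame[i] == 2 && o2$completeness[i] == "complete", logical(1))))
})

test_that("find_orfs equals the naive per-frame scan oracle", {
  with_seed(71, {
    for (i in 1:200) {
      s <- rand_nt(1, sample(60:240, 1))
      got <- find_orfs(s, min_len_aa = 5)
      got <- got[order(got$frame, got$start),
                 c("frame", "start", "end", "peptide", "completeness")]
      rownames(got) <- NULL
      want <- oracle_orfs(s, 5L)
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        rownames(want) <- NULL
        expect_identical(got, want)
      }
    }
  })
})

test_that("every reported peptide re-translates from its interval; revcomp symmetry", {
  with_seed(72, {
    for (i in 1:25) {
      s <- rand_nt(1, 200)
      o <- find_orfs(s, min_len_aa = 3)
      for (k in seq_len(nrow(o)))
        expect_identical(orf_peptide_from_coords(as.list(o[k, ]), s),
                         o$peptide[k])
      # complete-ORF count invariant under reverse complement
      o_rc <- find_orfs(revcomp(s), min_len_aa = 3)
      expect_identical(sum(o$completeness == "complete"),
                       sum(o_rc$completeness == "complete"))
    }
  })
})

test_that("top ORF call recovers planted complete ORFs", {
  pt <- plant_transcriptome(list(family_spec("OR", 6, 90, 0.2, seed = 73)),
                            completeness_mix = c(complete = 1), seed = 74)
  for (i in seq_len(nrow(pt$truth))) {
    tr <- pt$truth[i, ]
    top <- find_orfs(pt$transcripts[[tr$transcript_id]],
                     tr$transcript_id)[1, ]
    expect_identical(top$completeness, "complete")
    expect_identical(top$start, tr$orf_start)
    expect_identical(top$end, tr$orf_end + 3L) # call includes the stop
    expect_identical(top$peptide,
                     unname(pt$proteins$OR[tr$member_id]))
  }
})

test_that("homology coverage refines completeness calls", {
  orf <- list(transcript_id = "t", frame = 1L, start = 30L, end = 120L,
              peptide = strrep("K", 30), completeness = "complete",
              length_aa = 30L, aa_start = 10L, aa_end = 40L)
  # alignment covers the query N-terminus and starts upstream of the
  # ATG -> the internal start is spurious
  hit <- list(transcript_id = "t", frame = 1L, q_start = 0L, q_end = 50L,
              s_start = 2L, s_end = 40L)
  expect_identical(classify_against_hit(orf, hit, query_len = 60L),
                   "partial5")
  # alignment consistent with the called start -> unchanged
  hit2 <- list(transcript_id = "t", frame = 1L, q_start = 8L, q_end = 40L,
               s_start = 18L, s_end = 40L)
  expect_identical(classify_against_hit(orf, hit2, query_len = 60L),
                   "complete")
  # ORF missing its stop stays partial3 whatever the C-terminal coverage
  orf3 <- within(orf, completeness <- "partial3")
  expect_identical(classify_against_hit(orf3, hit2, query_len = 80L),
                   "partial3")
  # frame mismatch rejected
  hit3 <- within(hit, frame <- 2L)
  expect_error(classify_against_hit(orf, hit3, 60L), "frame")
})

test_that("truth-labelled partial5 plants classify as partial5 via hits", {
  pt <- plant_transcriptome(list(family_spec("OR", 10, 90, 0.2, seed = 75)),
                            completeness_mix = c(partial5 = 1), seed = 76)
  refs <- pt$proteins$OR
  hits <- search_homology(refs, pt$transcripts,
                          genes_map = pt$genes_trans_map)
  n_ok <- 0L
  for (i in seq_len(nrow(pt$truth))) {
    tr <- pt$truth[i, ]
    h <- hits[hits$query_id == tr$member_id &
                hits$transcript_id == tr$transcript_id, ][1, ]
    orfs <- find_orfs(pt$transcripts[[tr$transcript_id]],
                      tr$transcript_id, min_len_aa = 1)
    orf <- orfs[orfs$frame == h$frame &
                  orfs$aa_end > h$s_start & orfs$aa_start < h$s_end, ]
    orf <- orf[which.max(orf$length_aa), ]
    cls <- classify_against_hit(as.list(orf), as.list(h),
                                nchar(refs[[tr$member_id]]))
    if (identical(cls, "partial5")) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / nrow(pt$truth), 0.95)
})
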