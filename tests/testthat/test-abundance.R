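test_that("compatibility: unique mapping, unmapped reads, shared isoforms", {
  tx <- with_seed(100, stats::setNames(rand_nt(3, 600),
                                       c("T1", "T2", "T3")))
  sim <- simulate_reads(tx, c(1, 0, 0), 300, read_len = 60,
                        insert_mean = 150, error_rate = 0, seed = 101)
  ct <- build_compatibility(sim$pairs, tx, k = 25)
  expect_identical(ct$n_unmapped, 0L)
  expect_true(all(vapply(ct$compat, identical, logical(1), 1L)))

  # random non-transcript fragments map nowhere
  junk <- with_seed(102, data.frame(read_id = paste0("j", 1:20),
                                    seq1 = rand_nt(20, 60),
                                    qual1 = strrep("F", 60),
                                    seq2 = rand_nt(20, 60),
                                    qual2 = strrep("F", 60)))
  ctj <- build_compatibility(junk, tx, k = 25)
  expect_identical(ctj$n_unmapped, 20L)

  # 99%-identical isoforms share most fragments, and compatibility
  # matches a brute-force per-read containment check
  # 99% identity realised as a divergent 5' end (alternative first
  # exon), so fragments clear of it pseudo-align to both isoforms
  iso <- with_seed(103, {
    a <- rand_nt(1, 1000)
    chars <- strsplit(a, "")[[1]]
    for (p in 1:10) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               chars[p]), 1)
    c(I1 = a, I2 = paste(chars, collapse = ""))
  })
  stopifnot(pairwise_identity(iso[["I1"]], iso[["I2"]]) >= 0.98)
  simi <- simulate_reads(iso, c(0.5, 0.5), 400, read_len = 60,
                         insert_mean = 150, error_rate = 0, seed = 104)
  cti <- build_compatibility(simi$pairs, iso, k = 25)
  expect_gt(mean(lengths(cti$compat) == 2L), 0.5)
  kmers <- function(s, k) unique(substring(s, 1:(nchar(s) - k + 1),
                                           k:nchar(s)))
  txk <- lapply(iso, kmers, k = 25)
  for (i in seq_len(50)) {
    want <- which(vapply(txk, function(tk) {
      all(vapply(c(simi$pairs$seq1[i], simi$pairs$seq2[i]), function(rd) {
        f <- max(mean(kmers(rd, 25) %in% tk),
                 mean(kmers(revcomp(rd), 25) %in% tk))
        f >= 0.8
      }, logical(1)))
    }, logical(1)))
    expect_identical(cti$compat[[i]], as.integer(unname(want)))
  }
  expect_error(build_compatibility(simi$pairs, iso, k = 5), "k must")
})

test_that("EM: fixed points, symmetry, conservation, monotone likelihood", {
  tx <- with_seed(105, stats::setNames(rand_nt(4, 500), paste0("T", 1:4)))
  sim <- simulate_reads(tx, c(0.4, 0.3, 0.2, 0.1), 2000, read_len = 60,
                        insert_mean = 150, error_rate = 0, seed = 106)
  ct <- build_compatibility(sim$pairs, tx, k = 25)
  ec <- em_expected_counts(ct)
  # uniquely mapped fragments: expected counts = raw counts
  if (all(lengths(ct$compat) == 1L)) {
    raw <- tabulate(unlist(ct$compat), nbins = 4)
    expect_equal(unname(ec), raw, ignore_attr = TRUE)
  }
  # conservation
  expect_equal(sum(ec), ct$n_mapped)

  # two equal-efflen transcripts sharing every fragment -> 50/50
  shared <- structure(list(compat = rep(list(c(1L, 2L)), 100),
                           efflen = c(A = 300, B = 300),
                           transcripts = c("A", "B"),
                           n_unmapped = 0L, n_mapped = 100L),
                      class = "compat_table")
  ecs <- em_expected_counts(shared)
  expect_equal(unname(ecs), c(50, 50), ignore_attr = TRUE)

  # all unmapped -> zeros with a warning
  none <- structure(list(compat = list(integer(0), integer(0)),
                         efflen = c(A = 300, B = 300),
                         transcripts = c("A", "B"),
                         n_unmapped = 2L, n_mapped = 0L),
                    class = "compat_table")
  expect_warning(z <- em_expected_counts(none), "unmapped")
  expect_equal(unname(z), c(0, 0), ignore_attr = TRUE)
})

test_that("FPKM closed form, gene roll-up, and scale invariance", {
  expect_equal(fpkm(10, 2000, 1e6), 5)
  expect_equal(fpkm(0, 2000, 1e6), 0)
  expect_error(fpkm(1, 0.5, 1e6), "effective length")
  expect_error(fpkm(1, 2000, 0), "total")

  with_seed(107, {
    for (i in 1:20) {
      cnt <- runif(1, 0, 1e4); el <- runif(1, 100, 5000)
      tot <- runif(1, 1e5, 1e7)
      expect_equal(fpkm(cnt, el, tot), cnt / ((el / 1e3) * (tot / 1e6)))
    }
  })
  # duplicating every fragment leaves FPKM unchanged
  expect_equal(fpkm(20, 2000, 2e6), fpkm(10, 2000, 1e6))

  counts <- c(t1 = 10, t2 = 0, t3 = 30, t4 = 15)
  efflen <- c(t1 = 1000, t2 = 2000, t3 = 1500, t4 = 900)
  map <- c(t1 = "g1", t2 = "g1", t3 = "g2", t4 = "g3")
  g <- gene_level(counts, efflen, map, 1e6)
  # zero-count member contributes no weight: g1 efflen = t1's
  expect_equal(g$effective_length[g$gene_id == "g1"], 1000)
  expect_equal(g$expected_count[g$gene_id == "g1"], 10)
  # single-transcript gene: FPKM equals the transcript's
  expect_equal(g$fpkm[g$gene_id == "g2"], fpkm(30, 1500, 1e6))
  # weighted-mean oracle
  expect_equal(g$effective_length, vapply(split(names(map), map), function(tt) {
    w <- counts[tt]
    if (sum(w) > 0) sum(w * efflen[tt]) / sum(w) else mean(efflen[tt])
  }, 0)[g$gene_id], ignore_attr = TRUE)
  expect_error(gene_level(c(counts, tx = 5), c(efflen, tx = 100), map, 1e6),
               "tx")
})

test_that("heat-map transform and per-sample breakpoints", {
  m <- matrix(c(0, 1, 7, 0, 3, 15), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  hm <- heatmap_matrix(m)
  expect_equal(unname(hm$transformed[, "s1"]), c(0, 1, 3))
  expect_equal(hm$transformed, log2(m + 1))
  expect_equal(hm$breakpoints$min, c(1, 1))
  expect_equal(hm$breakpoints$max, unname(apply(log2(m + 1), 2, max)))

  # 75th percentile matches the sort-based oracle, per sample
  with_seed(108, {
    big <- matrix(rexp(300, 0.1), 100, 3,
                  dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
    hb <- heatmap_matrix(big)
    for (j in 1:3)
      expect_equal(hb$breakpoints$mid[j],
                   oracle_percentile75(log2(big[, j] + 1)))
  })

  # all-zero sample flagged degenerate with breakpoints (1, 0, 0)
  z <- heatmap_matrix(matrix(0, 4, 1, dimnames = list(paste0("g", 1:4),
                                                      "empty")))
  expect_true(z$breakpoints$degenerate)
  expect_equal(unlist(z$breakpoints[1, c("min", "mid", "max")]),
               c(min = 1, mid = 0, max = 0))
})

test_that("family shares normalize to 100 and recover planted ratios", {
  m <- matrix(c(30, 10, 45, 15), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  fam <- c(gA = "OBP", gB = "CSP")
  sh <- family_share(m, fam)
  expect_equal(colSums(sh), c(s1 = 100, s2 = 100))
  expect_equal(sh["OBP", "s1"], 75)
  one <- family_share(m[1, , drop = FALSE], fam[1])
  expect_equal(unname(one[1, ]), c(100, 100))
})
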