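# Shared fixtures, built in code. Seeds are fixed up front; scenario
# parameters state the synthetic world (4 families x 8 members at
# divergence 0.3, 20% partial ORFs, 30 decoys, 5% near-duplicates) and
# are not tuning knobs.

scenario_families <- function() list(
  family_spec("OR", 8, 406, 0.3, seed = 101),
  family_spec("GR", 8, 447, 0.3, seed = 102),
  family_spec("OBP", 8, 178, 0.3, seed = 103),
  family_spec("CSP", 8, 132, 0.3, seed = 104))

scenario_policies <- function() {
  p <- default_family_policies()
  p[c("OR", "GR", "OBP", "CSP")]
}

# cached so the acceptance suite builds the world once
default_scenario <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pt <- plant_transcriptome(
      scenario_families(),
      completeness_mix = c(complete = 0.8, partial5 = 0.1, partial3 = 0.1),
      n_decoys = 30L, near_duplicate_rate = 0.05, seed = 2017L)
    cl <- collapse(pt$transcripts)
    refs <- lapply(pt$proteins, function(p) p[1:3]) # members 1-3 are "known"
    cache <<- list(pt = pt, cl = cl, refs = refs)
    cache
  }
})

run_scenario_annotation <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- default_scenario()
    cache <<- iterate_annotation(sc$cl$representatives, sc$refs,
                                 policies = scenario_policies(),
                                 genes_map = sc$pt$genes_trans_map)
    cache
  }
})

# A deliberately two-hop world: reference R0, member A within reach of
# R0, member B within reach of A only (short, highly diverged family so
# the one-hop search cannot bridge R0 -> B at the E-value cutoff).
stepping_stone_scenario <- function() {
  mutate_pep <- function(pep, rate, seed) {
    with_seed(seed, {
      aa <- strsplit(pep, "")[[1]]
      alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      hit <- which(stats::runif(length(aa)) < rate)
      hit <- hit[hit > 1] # keep the M
      for (p in hit) aa[p] <- sample(setdiff(alpha, aa[p]), 1)
      paste(aa, collapse = "")
    })
  }
  r0 <- with_seed(301, paste(c("M", sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                    "")[[1]],
                                           59, replace = TRUE)),
                             collapse = ""))
  a <- mutate_pep(r0, 0.45, 302)
  b <- mutate_pep(a, 0.45, 303)
  encode <- function(pep, seed) with_seed(seed, {
    cds <- chemannot:::.reverse_translate(pep)
    paste0(chemannot:::.random_nt(40), cds, "TAA",
           chemannot:::.random_nt(40))
  })
  tx <- c(STR_t = encode(r0, 310), STA_t = encode(a, 311),
          STB_t = encode(b, 312))
  decoys <- with_seed(313, stats::setNames(rand_nt(5, 300),
                                           paste0("STdecoy_", 1:5)))
  transcripts <- c(tx, decoys)
  list(transcripts = transcripts,
       refs = list(ST = c(ST1 = r0)),
       policies = list(ST = family_policy("ST", 60)),
       genes_map = stats::setNames(names(transcripts), names(transcripts)),
       peps = c(R0 = r0, A = a, B = b))
}

# equal-length gap-free alignment of several planted families, for tree
# tests: within-family divergence << between-family divergence
clade_alignment <- function(n_fam = 4, n_per = 4, len = 80,
                            within = 0.1, seed = 400) {
  fams <- lapply(seq_len(n_fam), function(f)
    make_family_reference(family_spec(paste0("F", f), n_per, len, within,
                                      seed = seed + f))$proteins)
  aln <- unlist(fams)
  L <- min(nchar(aln))
  stats::setNames(substr(aln, 1, L), names(aln))
}
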