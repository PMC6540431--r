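---
title: "Methods: annotating chemosensory gene families in de novo transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating chemosensory gene families in de novo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemannot)
```

## The problem

Insects detect odours and tastants through several multigene families —
odorant receptors (OR), gustatory receptors (GR), ionotropic receptors
(IR), odorant-binding proteins (OBP), chemosensory proteins (CSP), and
candidate odorant-degrading enzymes (carboxylesterases, CXE/CCE, and
cytochrome P450s, CYP). For non-model species these families are
catalogued by sequencing tissue transcriptomes (antenna, proboscis,
brain, body), assembling them de novo, and mining the assembly with
protein queries from previously characterised genes. `chemannot`
implements that mining pipeline as reusable, tested code, together with
a ground-truthed synthetic-data generator that stands in for the raw
sequencing data, which are far beyond desk scale.

The pipeline stages mirror a typical study design:

1. **Read QC** (`filter_pairs`): drop read pairs with sequenced
   adaptors, more than 5% unknown bases, or more than 50% of bases
   below Phred 10.
2. **Redundancy collapse** (`collapse`): greedy clustering at 98%
   identity with an 8-mer prefilter, retaining the largest sequence of
   each cluster (the cd-hit-est `-c 0.98 -n 8` behaviour).
3. **ORF prediction** (`find_orfs`): six-frame translation, stop-to-stop
   segment scanning, completeness classes complete / 5'-partial /
   3'-partial / internal.
4. **Translated homology search** (`search_homology`): affine-gap
   Smith–Waterman of protein queries against all six frames, BLOSUM62,
   gap open 11 / extend 1, Karlin–Altschul E-values with cutoff 1e-05
   and at most 50 hits per query.
5. **Iterative annotation** (`iterate_annotation`): known genes are
   matched to their top-hit gene cluster; remaining hits that pass the
   family ORF-length filter become novel genes whose peptides join the
   query set; the search repeats until a round adds nothing.
6. **Quantification** (`build_compatibility`, `em_expected_counts`,
   `fpkm`, `gene_level`): k-mer pseudo-alignment, EM resolution of
   multi-mapping fragments, gene-level FPKM through a
   gene-to-transcript map.
7. **Heat-map matrix** (`heatmap_matrix`): log2(FPKM+1) with per-sample
   colour breakpoints (min 1, midpoint at the 75th percentile, max at
   the sample maximum).
8. **Family trees** (`pdistance`, `neighbor_joining`,
   `bootstrap_support`): p-distance NJ trees with column-bootstrap
   support, 600 replicates by default, supports below 70 hidden in
   display output.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_n_fraction` | 0.05 | strictly-greater fraction of N bases that removes a read |
| `max_lowq_fraction`, `q_threshold` | 0.50, 10 | strictly-greater fraction of sub-Q10 bases that removes a read |
| `threshold`, `word_size` (collapse) | 0.98, 8 | clustering identity and prefilter word |
| `gap_open`, `gap_extend` | 11, 1 | affine gap penalties (BLOSUM62) |
| `lambda`, `K` | 0.267, 0.041 | gapped Karlin–Altschul constants for BLOSUM62/11/1 |
| `e_max` | 1e-05 | E-value cutoff for reported hits |
| `avg_complete_orf_len_aa` | OR 406, GR 447, IR 676, OBP 178, CSP 132, CXE 563, CYP 510 | family averages; candidates must exceed 50% of them, strictly |
| `known_identity_floor` | 0.98 | identity at/above which a candidate is an isoform of a known gene |
| `k`, `tau` (pseudo-alignment) | 25, 0.8 | k-mer length and per-mate containment threshold |
| `n_replicates`, display threshold | 600, 70 | bootstrap replicates and support display cutoff |

All boundary semantics follow the documented wording: the length filter
and the QC fractions are strict (`>`), so an OR candidate of exactly
203 aa fails while 204 aa passes, and a read with exactly 5% N is kept.

## The synthetic world

`plant_transcriptome` builds transcriptomes in which the truth is known
by construction. Family members are drawn by mutating a common ancestor
so that the *expected pairwise* amino-acid divergence equals the
requested value (the per-member rate is solved from
`2r(1-r) + r^2·18/19 = d`; the construction saturates near d = 0.95, so
requests above 0.9 are rejected). Members are reverse-translated with
uniform synonymous codon choice, wrapped in random UTRs (default 30-300
nt), and truncated according to their completeness class; `partial5`
transcripts start in-frame at the transcript 5' end with the start
codon removed, `partial3` transcripts run off the 3' end without a
stop. Near-duplicate isoforms copy a planted transcript with 1%
substitutions (comfortably inside the 98% collapse threshold);
decoys are random sequence GC-matched to the plants within ±0.05 so
composition alone cannot separate them. Reads are drawn multinomially
with probability proportional to abundance × effective length, with
normal insert sizes, optional substitution errors, and disjoint
contamination classes (adaptor prefix, >5% N, >50% low-quality bases)
that exercise each QC criterion.

What the generator does **not** emulate: indels in reads, positional or
GC coverage bias, strand-specific chemistry, sequencing-machine error
profiles, chimeric/fragmented assembly artefacts, and alternative
splicing beyond near-duplicate isoforms. A green test therefore
establishes algorithmic correctness on data with the assumed
statistical structure, not robustness to every artefact of real
assemblies.

The default validation scenario plants 4 families × 8 members at
divergence 0.3 with 20% partial ORFs, 30 decoys and 5% near-duplicate
isoforms, uses members 1-3 of each family as the "known" references,
and requires recall 1.0 on planted genes with zero decoy annotations.
A separate two-hop scenario plants a short (60 aa) family in which
member B is detectable from member A only (0.45 mutation per hop):
B must appear in round ≥ 2 and must be absent when iteration is
disabled.

## Numerical and design choices

**Identity for clustering.** cd-hit's identity is "matches over the
shorter sequence", but the alignment behind it must not reward end
gaps: a free-gap global alignment degenerates into a longest common
subsequence, and with forced end gaps mismatches become effectively
rewarded, so a 500 nt partial transcript can reach "98%" against an
unrelated 1.5 kb transcript. `pairwise_identity` therefore scores an
end-gap-free (semi-global) alignment at match +1 / mismatch −1 /
internal gap −1, terminal gaps free, and counts the matches of the
match-richest optimal alignment. Identical sequences give 1.0, one
substitution in 100 nt gives 0.99, and containment of a truncated copy
gives 1.0 — which is exactly what "retain the largest of sequences of
different sizes" needs. The 8-mer prefilter only skips pairs for which
a guaranteed-run argument proves the threshold unreachable.

**Alignment semantics.** The search is full dynamic programming (no
heuristic seeding); an optional amino-acid 4-mer prefilter may only
skip subject frames sharing no word with the query. E-values use
`E = K·m·n·exp(−λS)` with `n` the total residues across all six frames
of the transcript set; BLAST's effective-length corrections are
deliberately omitted, so E-values are conservative and comparable only
within this implementation. Stops translate as `*` and score via the
substitution matrix's `*` column, which lets alignments cross
pseudogene stop codons and drive the `contains_internal_stop` flag.

**Completeness arbitration.** `find_orfs` is purely structural: per
stop-to-stop segment, an ATG yields a complete or 3'-partial call, and
only ATG-free, transcript-anchored segments yield 5'-partial/internal
calls. Homology then arbitrates: if a hit projects the query N-terminus
more than 5 aa upstream of a called ATG, the start is deemed spurious
(`classify_against_hit`), and the call is stretched back to its
transcript-anchored segment start (`extend_orf_to_segment`). This
codifies a judgement the original procedure made manually from BLAST
alignments, and is what lets 5'-partial genes with internal methionines
pass the family length filter.

**Known vs novel.** A candidate aligning to a reference at ≥ 0.98
identity over the aligned region is recorded as isoform evidence of the
known gene, not as a novel gene. The floor is applied to amino-acid
identity: the pipeline's references are proteins, so the original
nucleotide-level criterion is not computable here; at these identity
levels the two measures agree for synonymous-free comparisons.

**EM quantification.** Fragments are collapsed into equivalence classes
by compatibility pattern; the E-step splits each class proportionally
to `theta/efflen`, the M-step renormalises, and iteration stops when
`max |Δtheta| ≤ 1e-8` (cap 1000 iterations). Total expected counts
equal the number of mapped fragments at every iteration (exposed as the
`count_sums` attribute). Effective length is `L − mean fragment + 1`,
floored at 1; gene effective length is the count-weighted mean of
member effective lengths, falling back to the plain mean for
all-zero genes. The k-mer containment rule (k = 25, τ = 0.8) tolerates
no more than a handful of errors per mate — a single substitution kills
up to k of the ~66 k-mers of a 90 nt read — so highly error-laden reads
drop out as unmapped rather than cross-assigning.

**Percentiles.** Heat-map midpoints use linear interpolation between
order statistics (type-7 quantiles), matching the spreadsheet
conditional-formatting convention the matrix is designed for.

**Trees.** NJ with the lowest-index tie-break among Q-criterion minima
(tolerance 1e-12) and negative branch lengths clamped to zero; on
additive matrices the generating topology and branch lengths are
recovered exactly. Bootstrap resamples alignment columns, rebuilds the
NJ tree, and scores original bipartitions via `ape::prop.clades`.
NJ + p-distance deliberately replaces maximum-likelihood inference:
clade membership on clade-structured data is the tested surface, not
branch lengths. The alignment is consumed, not produced — the synthetic
generator's families are gap-free by construction; real data should be
aligned externally (e.g. MAFFT) first.

**Determinism.** Every stochastic operation takes an explicit seed and
restores the caller's RNG state (`with_seed`), so end-to-end reruns are
byte-identical; the acceptance suite asserts this on the annotation
TSV, FPKM TSV and Newick outputs.

## Known limitations

* E-values are not bit-compatible with BLAST; cross-tool thresholds
  should be re-calibrated.
* Clustering compares forward strands only; the generator plants
  duplicates on the forward strand. Reverse-strand *genes* are still
  found (the search covers all six frames).
* The synthetic divergence construction cannot exceed pairwise
  divergence 0.9.
* Cross-species nomenclature coordination, signal-peptide prediction
  and ML phylogenetics are out of scope; collapse/flag decisions beyond
  the mechanical rules are emitted as proposals for human review.
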