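# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so that library calls never clobber a user's stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of nucleotide sequences
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Codon -> amino-acid lookup (standard code), built once at load.
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a nucleotide string in frame +1
#'
#' Standard genetic code; stops are rendered `*`; any codon containing a
#' character outside A/C/G/T (e.g. N) translates to `X`. Trailing 1-2 nt
#' are ignored.
#'
#' @param seq single nucleotide string.
#' @return single amino-acid string (possibly empty for `nchar(seq) < 3`).
#' @export
translate_nt <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Uppercase and validate a nucleotide alphabet; returns the offending
# characters (empty if clean).
.bad_nt_chars <- function(seq) {
  setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), c("A", "C", "G", "T", "N"))
}

# GC fraction of one sequence (N excluded from the denominator).
.gc_fraction <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  acgt <- chars[chars != "N"]
  if (length(acgt) == 0L) return(NA_real_)
  mean(acgt %in% c("G", "C"))
}
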