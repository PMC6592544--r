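# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT_ALPHABET <- c("A", "C", "G", "T")

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with `set.seed(seed)` while preserving (and afterwards
#' restoring) the caller's RNG state, so seeded package functions never
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seeds (base seed + stream index), kept within 32-bit
# integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483587) + 1L
}

#' Translate nucleotide CDR3 sequences to amino acids
#'
#' Standard-code translation via Biostrings. Sequences whose length is not a
#' multiple of 3 translate to `NA` (out of frame); stop codons appear as `*`.
#'
#' @param nt character vector of nucleotide sequences.
#' @return character vector of amino-acid sequences (`NA` where out of frame).
#' @export
translate_cdr3 <- function(nt) {
  nt <- toupper(nt)
  aa <- rep(NA_character_, length(nt))
  inframe <- !is.na(nt) & nchar(nt) %% 3L == 0L & nchar(nt) > 0L
  if (any(inframe)) {
    aa[inframe] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[inframe]),
      no.init.codon = TRUE, if.fuzzy.codon = "X"
    ))
  }
  aa
}

# TRUE for amino-acid strings made only of the 20 canonical letters.
is_canonical_aa <- function(aa) {
  !is.na(aa) & nchar(aa) > 0L & !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), aa)
}

# Strip IMGT-style allele suffixes ("TRBV9*01" -> "TRBV9").
strip_allele <- function(x) sub("\\*.*$", "", x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
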