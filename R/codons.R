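# Codon-level utilities shared by library design, barcoding and the
# simulator. Translation uses the standard genetic code from Biostrings.

AA_ALPHABET_20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Most-used human codon per amino acid
#'
#' A fixed, deterministic reverse-translation table: for every canonical
#' residue, the codon most frequently used in human coding sequence. Using a
#' single codon per residue makes designed oligo pools reproducible; callers
#' that want vendor-style codon sampling can pass their own table to
#' [encode_oligo()].
#'
#' @return Named character vector mapping one-letter amino-acid codes to
#'   codons.
#' @export
#' @examples
#' human_codon_preferences()[["M"]]
human_codon_preferences <- function() {
  c(
    A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
    G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
    M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "AGA",
    S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC"
  )
}

# All codons for each residue, ordered with the preferred codon first.
synonymous_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  pref <- human_codon_preferences()
  out <- lapply(AA_ALPHABET_20, function(aa) {
    cods <- names(gc)[gc == aa]
    c(pref[[aa]], setdiff(cods, pref[[aa]]))
  })
  setNames(out, AA_ALPHABET_20)
}

#' Translate DNA strings (frame 0, standard code)
#'
#' @param dna Character vector of DNA sequences; each length must be a
#'   multiple of 3.
#' @return Character vector of amino-acid sequences.
#' @export
translate_dna <- function(dna) {
  stopifnot(is.character(dna))
  bad <- nchar(dna) %% 3L != 0L
  if (any(bad)) {
    abort(sprintf(
      "translate_dna(): %d sequence(s) whose length is not a multiple of 3",
      sum(bad)
    ))
  }
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(dna),
    no.init.codon = TRUE
  ))
}

reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
}

assert_protein_sequence <- function(seq, what = "sequence") {
  if (length(seq) == 0 || any(is.na(seq)) || any(nchar(seq) == 0)) {
    abort(sprintf("%s must be non-empty", what))
  }
  chars <- unique(unlist(strsplit(seq, "", fixed = TRUE)))
  bad <- setdiff(chars, AA_ALPHABET_20)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains non-canonical residue(s): %s",
      what, paste(bad, collapse = ", ")
    ))
  }
  invisible(seq)
}

assert_dna <- function(dna, what = "DNA") {
  chars <- unique(unlist(strsplit(dna, "", fixed = TRUE)))
  bad <- setdiff(chars, c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort(sprintf("%s contains non-ACGT character(s): %s",
                  what, paste(bad, collapse = ", ")))
  }
  invisible(dna)
}

# Coerce a protein input (tibble with id/sequence, or named character
# vector) to a validated tibble.
as_protein_tbl <- function(proteins) {
  if (is.character(proteins)) {
    if (is.null(names(proteins))) {
      abort("protein character vectors must be named (names become ids)")
    }
    proteins <- tibble(id = names(proteins), sequence = unname(proteins))
  }
  proteins <- as_tibble(proteins)
  if (!all(c("id", "sequence") %in% names(proteins))) {
    abort("proteins must have columns `id` and `sequence`")
  }
  assert_protein_sequence(proteins$sequence, "protein sequence")
  if (anyDuplicated(proteins$id)) abort("duplicated protein ids")
  proteins
}
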