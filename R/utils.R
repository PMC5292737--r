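# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a sequence string into a character vector of residues
#' @noRd
seq_chars <- function(x) {
  if (is.character(x) && length(x) == 1L) strsplit(x, "", fixed = TRUE)[[1]] else as.character(x)
}

#' Round half away from zero (Table-style reporting, not banker's rounding)
#' @noRd
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

NT_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Uniform random sequence of sense codons forming a clean open reading frame
#'
#' Builds `ATG` + (`n_codons` - 2) random sense codons + a stop codon, i.e. a
#' single-frame ORF of `3 * n_codons` bp whose translation has
#' `n_codons - 1` amino acids.  Used by the test-suite and the acceptance
#' script to construct ORFs with known arithmetic.
#'
#' @param n_codons total codon count including the start and the terminal stop.
#' @param seed optional integer seed.
#' @return a single nucleotide string.
#' @export
random_orf <- function(n_codons, seed = NULL) {
  stopifnot(n_codons >= 2)
  if (!is.null(seed)) set.seed(seed)
  sense <- sense_codons()
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

#' All 61 sense codons of the standard nuclear genetic code
#' @return character vector of codons.
#' @export
sense_codons <- function() {
  all <- as.vector(outer(outer(NT_ALPHABET, NT_ALPHABET, paste0), NT_ALPHABET, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Translate a vector of codons with the standard code (via ape)
#' @noRd
translate_codons <- function(codons) {
  if (length(codons) == 0L) return(character(0))
  nt <- unlist(strsplit(codons, "", fixed = TRUE), use.names = FALSE)
  m <- matrix(tolower(nt), nrow = 1)
  aa <- ape::trans(ape::as.DNAbin(m), code = 1)
  as.vector(unclass(as.character(aa)))
}

#' @noRd
is_gapped <- function(x) any(seq_chars(x) %in% c("-", "."))

#' Normalise an unordered element-pair table to a two-column character matrix
#' with each row sorted, used wherever pairs act as set keys.
#' @noRd
normalize_pairs <- function(pairs) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  }
  m <- as.matrix(pairs[, 1:2, drop = FALSE])
  t(apply(m, 1L, function(r) sort(as.character(r))))
}

#' @noRd
pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}
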