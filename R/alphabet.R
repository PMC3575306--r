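#' @useDynLib engevo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods is
#' @importFrom stats setNames rbinom runif rgeom
#' @importFrom utils head tail write.table read.table
NULL

# IUPAC nucleotide ambiguity sets, extended with inosine (I).
# Inosine hybridises with any template base, so as a *matching* symbol it
# behaves like N; as a *synthesis* symbol it is a single molecular species.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", I = "I"
)

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                "P","S","T","W","Y","V")

#' Split a string into single characters
#' @param x a length-1 character
#' @return character vector of single letters
#' @keywords internal
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validate a degenerate nucleotide pattern
#'
#' A pattern is a string over the IUPAC nucleotide alphabet extended with
#' inosine (`I`). Case is ignored.
#'
#' @param pattern length-1 character
#' @return the upper-cased pattern, invisibly usable
#' @keywords internal
check_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  p <- toupper(pattern)
  bad <- setdiff(unique(chars(p)), names(IUPAC_SETS))
  if (length(bad)) {
    stop("illegal symbol(s) in degenerate pattern: ", paste(bad, collapse = ", "))
  }
  p
}

#' Reverse-complement a degenerate pattern
#'
#' IUPAC-aware reverse complement; the complement of inosine is inosine.
#' Applying the function twice returns the input (involution).
#'
#' @param pattern degenerate nucleotide pattern (IUPAC + I)
#' @return the reverse complement, upper case
#' @examples
#' reverse_primer("AAR")   # "YTT"
#' @export
reverse_primer <- function(pattern) {
  p <- check_pattern(pattern)
  paste(rev(unname(IUPAC_COMPLEMENT[chars(p)])), collapse = "")
}

#' Reverse-complement a concrete DNA string
#' @param x DNA string (A/C/G/T/N)
#' @return reverse complement
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate DNA to protein
#'
#' Standard genetic code; codons containing `N` translate to `X`; trailing
#' partial codons are dropped.
#'
#' @param dna DNA string
#' @return amino-acid string (may contain `*` for stop, `X` for ambiguous)
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  dna <- substr(dna, 1L, 3L * n)
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     if.fuzzy.codon = "X"))
}

# codon table: named character vector codon -> amino acid
CODON_TABLE <- {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# amino acid -> character vector of codons (sense codons only)
AA_CODONS <- split(names(CODON_TABLE), CODON_TABLE)

#' Do a degenerate symbol and a template base match?
#'
#' Set-intersection semantics: two IUPAC symbols match when their base sets
#' intersect; inosine matches any base.
#'
#' @param a,b single IUPAC/I symbols (vectors allowed, recycled)
#' @return logical vector
#' @keywords internal
iupac_match <- function(a, b) {
  mapply(function(x, y) length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0L,
         toupper(a), toupper(b), USE.NAMES = FALSE)
}
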