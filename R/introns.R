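## Homology-guided intron inference: protein-anchored spliced alignment of a
## genomic fragment against a homologous reference catalytic-domain sequence,
## with canonical GT..AG boundaries. The chain of ungapped exons maximising
## the translated substitution score (BLOSUM62) minus a per-intron penalty is
## found by dynamic programming (src/spliced_align.cpp).

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

encode_dna <- function(x) {
  v <- BASE_CODE[chars(toupper(x))]
  v[is.na(v)] <- 4L
  unname(v)
}

# substitution matrix and codon->row lookup, built once per session
scoring_env <- new.env(parent = emptyenv())

get_scoring <- function() {
  if (!is.null(scoring_env$submat)) return(scoring_env)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  letters <- rownames(sm)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # index = b0*16 + b1*4 + b2 with A,C,G,T = 0..3; build in that order
  idx_codon <- character(64)
  for (b0 in 0:3) for (b1 in 0:3) for (b2 in 0:3) {
    idx_codon[b0 * 16 + b1 * 4 + b2 + 1] <-
      paste0(bases[b0 + 1], bases[b1 + 1], bases[b2 + 1])
  }
  aa <- CODON_TABLE[idx_codon]
  codon_aa <- match(aa, letters) - 1L
  scoring_env$submat <- sm
  scoring_env$letters <- letters
  scoring_env$codon_aa <- codon_aa
  scoring_env$aa_x <- match("X", letters) - 1L
  scoring_env
}

as_protein_string <- function(reference) {
  x <- if (inherits(reference, "XString")) as.character(reference) else
    as.character(reference)
  x <- toupper(x)
  if (grepl("^[ACGTN]+$", x)) {
    # a CDS: conceptual translation, frame 0, trailing stop dropped
    x <- translate_dna(x)
    x <- sub("\\*$", "", x)
  }
  if (grepl("\\*", x)) stop("reference protein contains internal stop codons")
  x
}

#' Condition signalled when no homologous splice solution exists
#' @param message error text
#' @param best_score best partial alignment score reached
#' @param identity best identity reached
#' @keywords internal
no_splice_error <- function(message, best_score = NA_real_, identity = NA_real_) {
  structure(class = c("engevo_no_splice", "error", "condition"),
            list(message = message, call = sys.call(-1),
                 best_score = best_score, identity = identity))
}

#' Infer intron positions in a genomic fragment by reference homology
#'
#' Reconstructs the exon-intron structure of a genomic amplicon by spliced
#' alignment against a homologous reference coding sequence or protein:
#' candidate donors (GT) and acceptor (AG) dinucleotides are enumerated and
#' the chain of ungapped exons maximising the BLOSUM62 score of the
#' translated splice product against the reference, minus a fixed per-intron
#' penalty, is selected by dynamic programming with leftmost-donor
#' tie-breaking.
#'
#' Intron phases follow the usual convention: phase 0 between two codons,
#' phase 1 after the first and phase 2 after the second base of a codon.
#' `coding_offset` (coding nucleotides 5' of the intron within the fragment)
#' is measured from a frame-anchored origin, so `phase == coding_offset %% 3`
#' always holds and phases are invariant to where the fragment starts.
#'
#' @param genomic DNA fragment (character, `DNAString`, or named length-1
#'   `DNAStringSet`)
#' @param reference homologous reference: protein or in-frame CDS; a
#'   `XStringSet`/list/character vector of several references may be given,
#'   in which case the highest-scoring one is used and recorded
#' @param min_intron minimum intron length in bp (default 20; introns as
#'   short as 27 bp occur in these gene families, so typical 40+ bp floors
#'   would be wrong)
#' @param intron_penalty score deducted per intron (BLOSUM62 half-bit units)
#' @param identity_floor minimum amino-acid identity of the spliced
#'   translation to the reference over the aligned span; below it a
#'   `engevo_no_splice` error carrying the best partial score is raised
#' @param allow_gc_donor also permit non-canonical GC donors (flagged in the
#'   `donor` column of the result)
#' @return an object of class `spliced_gene`: list with `id`, `genomic`,
#'   `introns` (data.frame: `start`, `end`, `length`, `donor`, `acceptor`,
#'   `coding_offset`, `phase`, `protein_pos`), `cds` (spliced DNA),
#'   `protein` (conceptual translation in the inferred frame), `ref_id`,
#'   `ref_start` (0-based codon offset of the fragment in the reference),
#'   `score` and `identity`
#' @export
infer_introns <- function(genomic, reference, min_intron = 20L,
                          intron_penalty = 15, identity_floor = 0.4,
                          allow_gc_donor = FALSE) {
  stopifnot(min_intron >= 4L)
  gseq <- template_as_string(genomic)
  gid <- template_id_of(genomic, default = "genomic")
  refs <- if (inherits(reference, "XStringSet")) as.list(as.character(reference))
          else if (is.list(reference)) reference
          else as.list(reference)
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    names(refs) <- if (length(refs) == 1L) "reference" else
      paste0("reference_", seq_along(refs))
  }
  sc <- get_scoring()
  genc <- encode_dna(gseq)

  best <- NULL
  for (k in seq_along(refs)) {
    prot <- as_protein_string(refs[[k]])
    renc <- match(chars(prot), sc$letters) - 1L
    if (anyNA(renc)) stop("reference contains unknown residues")
    fit <- spliced_align_cpp(genc, renc, sc$submat, sc$codon_aa, sc$aa_x,
                             as.integer(min_intron), intron_penalty,
                             allow_gc_donor)
    if (is.null(best) || (!is.na(fit$score) && fit$score > best$fit$score)) {
      best <- list(fit = fit, ref_id = names(refs)[k], protein = prot)
    }
  }
  fit <- best$fit
  if (is.na(fit$score)) stop(no_splice_error("spliced alignment failed"))

  ns <- length(fit$intron_start)
  c0 <- fit$c0
  r0 <- c0 %% 3L
  anchor <- c0 - r0   # frame-anchored origin in reference coding coordinates
  introns <- data.frame(
    start = as.integer(fit$intron_start),
    end = as.integer(fit$intron_end),
    length = as.integer(fit$intron_end - fit$intron_start),
    donor = vapply(fit$intron_start, function(s) substr(gseq, s + 1, s + 2), ""),
    acceptor = vapply(fit$intron_end, function(e) substr(gseq, e - 1, e), ""),
    coding_offset = as.integer(fit$c_at_donor - anchor),
    phase = as.integer(fit$c_at_donor %% 3L),
    stringsAsFactors = FALSE
  )
  # codon the intron interrupts (phase > 0) or immediately precedes (phase
  # 0), 1-based in the fragment's own translated protein
  first_full <- ceiling(c0 / 3)           # 0-based ref codon of first full codon
  introns$protein_pos <- as.integer(fit$c_at_donor %/% 3L - first_full + 1L)
  stopifnot(all(introns$phase == introns$coding_offset %% 3L))

  cds <- splice(gseq, introns)
  lead_trim <- (3L - r0) %% 3L            # partial first codon, if any
  protein <- translate_dna(substr(cds, lead_trim + 1L, nchar(cds)))
  # identity over the aligned span
  ref_prot <- best$protein
  cend <- fit$cend
  j0 <- first_full + 1L
  j1 <- cend %/% 3L
  identity <- if (j1 >= j0) {
    a <- chars(protein)[seq_len(j1 - j0 + 1L)]
    b <- chars(ref_prot)[j0:j1]
    mean(a == b)
  } else NA_real_
  if (!is.na(identity) && identity < identity_floor) {
    stop(no_splice_error(sprintf(
      "no homologous splice solution: best identity %.2f below floor %.2f (score %.1f)",
      identity, identity_floor, fit$score), best_score = fit$score,
      identity = identity))
  }
  structure(list(id = gid, genomic = gseq, introns = introns, cds = cds,
                 protein = protein, ref_id = best$ref_id,
                 ref_start = first_full, score = fit$score,
                 identity = identity),
            class = "spliced_gene")
}

#' @export
print.spliced_gene <- function(x, ...) {
  cat(sprintf("<spliced_gene> %s: %d bp genomic, %d intron(s), %d bp cds (ref %s, id %.0f%%)\n",
              x$id, nchar(x$genomic), nrow(x$introns), nchar(x$cds),
              x$ref_id, 100 * x$identity))
  if (nrow(x$introns)) print(x$introns)
  invisible(x)
}

#' Splice introns out of a genomic sequence
#'
#' @param genomic DNA string (or `DNAString`)
#' @param introns data.frame with 0-based half-open `start`/`end` columns
#'   (e.g. the `introns` component of a `spliced_gene`), sorted and
#'   non-overlapping
#' @return the concatenated exon DNA; `nchar(result) == nchar(genomic) -
#'   sum(lengths)`
#' @export
splice <- function(genomic, introns) {
  g <- template_as_string(genomic)
  if (is.null(introns) || nrow(introns) == 0L) return(g)
  s <- introns$start
  e <- introns$end
  if (any(s < 0L) || any(e > nchar(g)) || any(e <= s)) {
    stop("introns out of range")
  }
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (any(s[-1L] < e[-length(e)])) stop("introns overlap")
  keep_start <- c(0L, e)
  keep_end <- c(s, nchar(g))
  paste(vapply(seq_along(keep_start), function(i) {
    if (keep_end[i] > keep_start[i]) substr(g, keep_start[i] + 1L, keep_end[i]) else ""
  }, character(1)), collapse = "")
}

#' Compare a spliced sequence against an experimentally derived cDNA
#'
#' Anchors the two sequences at the ungapped offset maximising agreement and
#' reports every mismatching position over the overlap, optionally ignoring
#' a stated number of bases at each overlap end (primer-derived ends).
#'
#' @param spliced DNA string (the splice product)
#' @param cdna DNA string (the cDNA-derived sequence)
#' @param end_trim bases ignored at both ends of the overlap
#' @return list with `ok` (TRUE iff no mismatches over the compared span),
#'   `mismatches` (data.frame: `pos_spliced`, `pos_cdna` 0-based,
#'   `spliced_base`, `cdna_base`), `offset` and `overlap`
#' @export
verify_against_cdna <- function(spliced, cdna, end_trim = 0L) {
  a <- template_as_string(spliced)
  b <- template_as_string(cdna)
  ac <- chars(a); bc <- chars(b)
  na <- length(ac); nb <- length(bc)
  # slide b over a: offset = start of b relative to start of a
  offsets <- (-nb + 1L):(na - 1L)
  agree <- vapply(offsets, function(o) {
    ia <- max(0L, o); ib <- max(0L, -o)
    ov <- min(na - ia, nb - ib)
    if (ov <= 0L) return(-1L)
    sum(ac[(ia + 1L):(ia + ov)] == bc[(ib + 1L):(ib + ov)])
  }, integer(1))
  o <- offsets[which.max(agree)]
  ia <- max(0L, o); ib <- max(0L, -o)
  ov <- min(na - ia, nb - ib)
  lo <- end_trim; hi <- ov - end_trim
  mm <- data.frame(pos_spliced = integer(), pos_cdna = integer(),
                   spliced_base = character(), cdna_base = character(),
                   stringsAsFactors = FALSE)
  if (hi > lo) {
    k <- (lo + 1L):hi
    bad <- k[ac[ia + k] != bc[ib + k]]
    if (length(bad)) {
      mm <- data.frame(pos_spliced = ia + bad - 1L, pos_cdna = ib + bad - 1L,
                       spliced_base = ac[ia + bad], cdna_base = bc[ib + bad],
                       stringsAsFactors = FALSE)
    }
  }
  list(ok = nrow(mm) == 0L, mismatches = mm, offset = o, overlap = ov)
}
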