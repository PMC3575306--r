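## In-silico PCR: degenerate-primer binding-site search and amplicon
## extraction. Matching is IUPAC set-intersection (primer ambiguity codes
## and template Ns both match by set overlap); inosine matches any base.
## Coordinates are 0-based, half-open on the forward strand of the template.

empty_sites <- function() {
  data.frame(template_id = character(), start = integer(), end = integer(),
             strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

template_as_string <- function(template) {
  if (inherits(template, "XString")) return(toupper(as.character(template)))
  if (inherits(template, "XStringSet")) {
    stopifnot(length(template) == 1L)
    return(toupper(as.character(template[[1L]])))
  }
  toupper(as.character(template))
}

template_id_of <- function(template, default = "template") {
  if (inherits(template, "XStringSet") && !is.null(names(template))) {
    return(names(template)[1L])
  }
  nm <- names(template)
  if (!is.null(nm) && nzchar(nm[1L])) nm[1L] else default
}

count_mismatches_at <- function(pat_chars, tmpl_chars, starts) {
  m <- length(pat_chars)
  vapply(starts, function(s) {
    sum(!iupac_match(pat_chars, tmpl_chars[s:(s + m - 1L)]))
  }, integer(1))
}

scan_one_strand <- function(pattern, tmpl, max_mismatch, three_prime_is_right,
                            three_prime_exact) {
  m <- nchar(pattern)
  n <- nchar(tmpl)
  if (m > n) return(integer(0))
  # I hybridises like N; Biostrings fixed = FALSE gives set-intersection
  # matching for IUPAC codes in both pattern and subject
  pat <- Biostrings::DNAString(gsub("I", "N", pattern, fixed = TRUE))
  hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(tmpl),
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE, fixed = FALSE)
  starts <- Biostrings::start(hits)  # 1-based
  if (!length(starts)) return(integer(0))
  if (three_prime_exact && max_mismatch > 0L) {
    pc <- chars(pattern)
    tc <- chars(tmpl)
    idx3 <- if (three_prime_is_right) (m - 2L):m else 1L:3L
    keep <- vapply(starts, function(s) {
      all(iupac_match(pc[idx3], tc[s + idx3 - 1L]))
    }, logical(1))
    starts <- starts[keep]
  }
  starts
}

#' Find degenerate-primer binding sites on a genomic template
#'
#' Scans both strands of a DNA template for positions where the primer
#' matches with at most `max_mismatch` mismatches under IUPAC
#' set-intersection semantics (inosine matches any base). A site on the
#' `-` strand means the primer anneals to the reverse complement, i.e. its
#' reverse complement appears on the forward strand at the reported
#' coordinates.
#'
#' @param primer a `degenerate_primer`, preset name, or pattern string
#' @param template DNA template (character, `DNAString`, or length-1
#'   `DNAStringSet`)
#' @param max_mismatch maximum number of mismatching positions (default 0)
#' @param three_prime_exact when mismatches are allowed, require the 3
#'   3'-terminal primer bases to match exactly (PCR extension realism)
#' @return data.frame with columns `template_id`, `start`, `end` (0-based,
#'   half-open, forward-strand coordinates), `strand` (`+`/`-`), and
#'   `mismatches`, sorted by `start` then `strand`. A primer longer than the
#'   template yields zero rows, not an error.
#' @export
find_sites <- function(primer, template, max_mismatch = 0L,
                       three_prime_exact = FALSE) {
  if (is.character(primer) && length(primer) == 1L &&
      primer %in% primer_presets()$name) {
    primer <- get_primer(primer)
  }
  pat <- if (inherits(primer, "degenerate_primer")) primer$pattern else
    check_pattern(primer)
  stopifnot(max_mismatch >= 0L)
  tmpl <- template_as_string(template)
  tid <- template_id_of(template)
  m <- nchar(pat)
  if (m > nchar(tmpl)) return(empty_sites())

  tc <- chars(tmpl)
  out <- empty_sites()
  plus_starts <- scan_one_strand(pat, tmpl, max_mismatch,
                                 three_prime_is_right = TRUE,
                                 three_prime_exact = three_prime_exact)
  if (length(plus_starts)) {
    mm <- count_mismatches_at(chars(pat), tc, plus_starts)
    out <- rbind(out, data.frame(template_id = tid,
                                 start = plus_starts - 1L,
                                 end = plus_starts - 1L + m,
                                 strand = "+", mismatches = mm,
                                 stringsAsFactors = FALSE))
  }
  rcpat <- reverse_primer(pat)
  if (rcpat == pat) {
    # palindromic pattern: a minus-strand hit is the same duplex site
    return(out[order(out$start, out$strand), , drop = FALSE])
  }
  minus_starts <- scan_one_strand(rcpat, tmpl, max_mismatch,
                                  three_prime_is_right = FALSE,
                                  three_prime_exact = three_prime_exact)
  if (length(minus_starts)) {
    mm <- count_mismatches_at(chars(rcpat), tc, minus_starts)
    out <- rbind(out, data.frame(template_id = tid,
                                 start = minus_starts - 1L,
                                 end = minus_starts - 1L + m,
                                 strand = "-", mismatches = mm,
                                 stringsAsFactors = FALSE))
  }
  out <- out[out$mismatches <= max_mismatch, , drop = FALSE]
  # a minus-strand hit over the same footprint as a plus-strand hit is the
  # same duplex site (self-complementary footprint): report it once
  dup <- out$strand == "-" &
    paste(out$start, out$end) %in% paste(out$start, out$end)[out$strand == "+"]
  out <- out[!dup, , drop = FALSE]
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Extract in-silico PCR amplicons
#'
#' Pairs every forward-primer site on the `+` strand with every downstream
#' reverse-primer site on the `-` strand and reports the delimited products.
#' Amplicon length includes both primer footprints (the convention under
#' which sequenced clone lengths run primer to primer).
#'
#' @param template DNA template (character, `DNAString`, or named length-1
#'   `DNAStringSet`)
#' @param fwd,rev forward/reverse primers (`degenerate_primer`, preset name,
#'   or pattern string, 5'->3' as synthesised)
#' @param max_mismatch maximum mismatches per primer site
#' @param size_range numeric length-2, inclusive amplicon length bounds
#' @param three_prime_exact see [find_sites()]
#' @return data.frame with one row per product: `template_id`, `start`,
#'   `end`, `length`, `fwd_start`, `rev_start`, `fwd_mismatches`,
#'   `rev_mismatches`, `sequence`; ordered by `start` then `length`. Zero
#'   products is a valid result.
#' @export
amplify <- function(template, fwd, rev, max_mismatch = 0L,
                    size_range = c(1, Inf), three_prime_exact = FALSE) {
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  fs <- find_sites(fwd, template, max_mismatch, three_prime_exact)
  fs <- fs[fs$strand == "+", , drop = FALSE]
  rs <- find_sites(rev, template, max_mismatch, three_prime_exact)
  rs <- rs[rs$strand == "-", , drop = FALSE]
  tmpl <- template_as_string(template)
  tid <- template_id_of(template)
  out <- data.frame(template_id = character(), start = integer(),
                    end = integer(), length = integer(),
                    fwd_start = integer(), rev_start = integer(),
                    fwd_mismatches = integer(), rev_mismatches = integer(),
                    sequence = character(), stringsAsFactors = FALSE)
  if (!nrow(fs) || !nrow(rs)) return(out)
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      if (rs$start[j] < fs$start[i]) next        # rev footprint upstream of fwd
      len <- rs$end[j] - fs$start[i]
      if (len < size_range[1] || len > size_range[2]) next
      out <- rbind(out, data.frame(
        template_id = tid, start = fs$start[i], end = rs$end[j],
        length = len, fwd_start = fs$start[i], rev_start = rs$start[j],
        fwd_mismatches = fs$mismatches[i], rev_mismatches = rs$mismatches[j],
        sequence = substr(tmpl, fs$start[i] + 1L, rs$end[j]),
        stringsAsFactors = FALSE))
    }
  }
  out[order(out$start, out$length), , drop = FALSE]
}

#' Screen a set of primer variants against a template
#'
#' Mirrors the empirical variant screening of degenerate-primer families
#' (CD1aF/bF/cF, ...): reports, per variant, whether and where it binds.
#'
#' @param primers character vector of preset names or a list of
#'   `degenerate_primer` objects
#' @param template DNA template
#' @param max_mismatch maximum mismatches
#' @return data.frame of binding sites with a `primer` column
#' @export
screen_variants <- function(primers, template, max_mismatch = 0L) {
  if (is.character(primers)) primers <- lapply(primers, get_primer)
  res <- lapply(primers, function(p) {
    s <- find_sites(p, template, max_mismatch)
    if (nrow(s)) s$primer <- p$name
    s
  })
  res <- res[vapply(res, nrow, integer(1)) > 0L]
  if (!length(res)) {
    out <- empty_sites()
    out$primer <- character(0)
    return(out)
  }
  do.call(rbind, res)
}
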