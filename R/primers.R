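#' Conserved GHF5 catalytic-domain peptide motifs
#'
#' The six peptide motifs conserved across nematode GHF5 endoglucanase
#' catalytic domains that anchor degenerate-primer design. Region names
#' follow the primer nomenclature (CD1, CD2, ENG1, CD4, ENG2, CD6).
#'
#' @return named character vector, region name -> amino-acid motif
#' @examples
#' ghf5_motifs()[["CD1"]]  # "PPYGQLS"
#' @export
ghf5_motifs <- function() {
  c(CD1  = "PPYGQLS",
    CD2  = "LKCNWN",
    ENG1 = "YVIVDW",
    CD4  = "WCQDV",
    ENG2 = "FVTEYG",
    CD6  = "ISYLNWAISD")
}

#' Reference GHF5 catalytic-domain protein scaffold
#'
#' A representative nematode GHF5 endoglucanase catalytic-domain protein
#' carrying all six conserved motifs at their natural spacing. Used as the
#' default root sequence of the gene-family simulator and as a convenient
#' homology reference.
#'
#' @return length-1 character (amino acids)
#' @export
ghf5_domain_protein <- function() {
  paste0(
    "TATPPPYGQLSVSGTKLVDSSGQPVQLIGNSLFWHQFQAQYWNAETVKALKCNWNANVVRAAVGVDLERGYMSDP",
    "TTAYNQAVAVIEAAISQGLYVIVDWHSHESHVDKAIEFFTKIAKAYGSYPHVLYETFNEPLQGVSWTDILVPYHKKVIAAI",
    "RALDSKNVIILGTPTWCQDVDIASQNPIKEYKNLMYTFHFYAATHFVNGLGAKLQTAINNGLPIFVTEYGTCSADGNGNI",
    "DTNSISSWWSLMDNLKISYLNWAISDKSETCSALKPGTPAANVGVSSSWTTSGNMVADHDKKKSTGVSCS"
  )
}

#' Published degenerate-primer presets
#'
#' The degenerate PCR primers used to amplify GHF5 cellulase catalytic-domain
#' fragments from single nematodes, stored as literal 5'->3' patterns over
#' the IUPAC alphabet plus inosine (`I`). Reverse primers are stored as
#' synthesised, i.e. already reverse-complemented relative to the coding
#' strand. Species-specific presets carry deliberate fixed-base choices and
#' two (CD1PraFc, CD1MelF) are shortened/frame-shifted relative to a clean
#' codon grid; all are kept verbatim.
#'
#' @return data.frame with columns `name`, `pattern`, `orientation`
#'   (`"forward"`/`"reverse"`), `region`, `motif`
#' @export
primer_presets <- function() {
  path <- system.file("extdata", "ghf5_primers.tsv", package = "engevo",
                      mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab$motif <- unname(ghf5_motifs()[tab$region])
  tab
}

#' Fetch one primer preset as a DegeneratePrimer
#'
#' @param name preset name, e.g. `"CD1aF"`
#' @return object of class `degenerate_primer`
#' @export
get_primer <- function(name) {
  tab <- primer_presets()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown primer preset: ", name)
  degenerate_primer(tab$name[i], tab$pattern[i], tab$orientation[i],
                    region = tab$region[i], motif = tab$motif[i])
}

#' Construct a degenerate primer
#'
#' @param name primer name
#' @param pattern 5'->3' pattern over IUPAC codes plus `I`
#' @param orientation `"forward"` or `"reverse"`
#' @param region conserved-region name (optional)
#' @param motif source peptide motif (optional)
#' @return object of class `degenerate_primer`
#' @export
degenerate_primer <- function(name, pattern, orientation = c("forward", "reverse"),
                              region = NA_character_, motif = NA_character_) {
  orientation <- match.arg(orientation)
  pattern <- check_pattern(pattern)
  if (nchar(pattern) < 12L) {
    warning("primer '", name, "' is shorter than 12 nt")
  }
  structure(list(name = name, pattern = pattern, orientation = orientation,
                 region = region, motif = motif),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s, %s): 5'-%s-3' [degeneracy %d]\n",
              x$name, x$region, x$orientation, x$pattern,
              degeneracy(x$pattern)))
  invisible(x)
}

#' Codon policies for back-translation
#'
#' A codon policy controls which codons are used per residue when a peptide
#' motif is back-translated:
#' * `full_degenerate` - every sense codon of each residue;
#' * `inosine_at_4fold` - residues encoded by a single four-fold degenerate
#'   codon box (A, G, P, T, V) are written as the two fixed bases plus
#'   inosine; all other residues fall back to their full codon set;
#' * fixed choices - `fixed` pins individual motif positions (1-based, as
#'   names) to one concrete codon, overriding the rule at that position.
#'
#' @param rule `"full_degenerate"` or `"inosine_at_4fold"`
#' @param fixed named list: motif position (as character) -> concrete codon
#' @return object of class `codon_policy`
#' @examples
#' codon_policy("inosine_at_4fold", fixed = list(`3` = "ATC"))
#' @export
codon_policy <- function(rule = c("full_degenerate", "inosine_at_4fold"),
                         fixed = list()) {
  rule <- match.arg(rule)
  if (length(fixed)) {
    stopifnot(!is.null(names(fixed)))
    for (cod in fixed) {
      cod <- toupper(cod)
      if (!cod %in% names(CODON_TABLE)) stop("fixed choice is not a codon: ", cod)
    }
  }
  structure(list(rule = rule, fixed = lapply(fixed, toupper)),
            class = "codon_policy")
}

# residues whose codon set is one four-fold box (third base free)
FOURFOLD_AA <- c("A", "G", "P", "T", "V")

codons_for_residue <- function(aa, pos, policy) {
  aa <- toupper(aa)
  if (!aa %in% names(AA_CODONS)) stop("unknown amino acid: ", aa)
  fx <- policy$fixed[[as.character(pos)]]
  if (!is.null(fx)) {
    if (CODON_TABLE[[fx]] != aa) {
      stop("fixed codon ", fx, " does not encode residue ", aa, " at position ", pos)
    }
    return(fx)
  }
  if (policy$rule == "inosine_at_4fold" && aa %in% FOURFOLD_AA) {
    return(paste0(substr(AA_CODONS[[aa]][1L], 1L, 2L), "I"))
  }
  AA_CODONS[[aa]]
}

#' Back-translate a peptide motif into a degenerate pattern
#'
#' Each residue contributes a set of candidate codons chosen by the codon
#' policy; the rendered pattern is the per-position IUPAC union of that set
#' (inosine preserved). `trim5`/`trim3` drop a stated number of bases from
#' the pattern ends, which is how primers extend a motif by part of the next
#' residue's codon (back-translate the extended motif, then trim).
#'
#' @param motif amino-acid string (standard residues)
#' @param policy a [codon_policy()]
#' @param trim5,trim3 bases to drop from the 5'/3' end
#' @return object of class `degenerate_pattern` with the rendered `pattern`
#'   string, the per-residue codon sets, and an `exact` flag saying whether
#'   the IUPAC rendering expands to exactly the codon-set product
#' @examples
#' back_translate("MW")$pattern   # "ATGTGG"
#' @export
back_translate <- function(motif, policy = codon_policy("full_degenerate"),
                           trim5 = 0L, trim3 = 0L) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) >= 1L)
  res <- chars(toupper(motif))
  sets <- lapply(seq_along(res), function(i) codons_for_residue(res[i], i, policy))
  # render: per nucleotide position, union of bases over the codon set
  render_codon <- function(set) {
    vapply(1:3, function(k) {
      syms <- unique(substr(set, k, k))
      if (identical(syms, "I")) return("I")
      bases <- sort(unique(unlist(IUPAC_SETS[syms])))
      hit <- vapply(names(IUPAC_SETS)[1:15],  # exclude I from lookup
                    function(s) identical(sort(IUPAC_SETS[[s]]), bases), logical(1))
      names(which(hit))[1L]
    }, character(1))
  }
  rendered <- lapply(sets, render_codon)
  pat <- paste(unlist(rendered), collapse = "")
  n <- nchar(pat)
  stopifnot(trim5 >= 0L, trim3 >= 0L, trim5 + trim3 < n)
  pat_trim <- substr(pat, trim5 + 1L, n - trim3)
  # exact iff per-position independence loses nothing
  n_pattern <- prod(vapply(chars(pat), function(s) {
    if (s == "I") 4 else length(IUPAC_SETS[[s]])
  }, numeric(1)))
  n_codons <- prod(vapply(sets, function(set) {
    sum(vapply(set, function(cod) prod(ifelse(chars(cod) == "I", 4, 1)), numeric(1)))
  }, numeric(1)))
  structure(list(pattern = pat_trim, codon_sets = sets, motif = toupper(motif),
                 trim5 = as.integer(trim5), trim3 = as.integer(trim3),
                 exact = isTRUE(all.equal(n_pattern, n_codons))),
            class = "degenerate_pattern")
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat(sprintf("<degenerate_pattern> %s <- %s (%sexact)\n",
              x$pattern, x$motif, if (x$exact) "" else "not "))
  invisible(x)
}

#' Expand a degenerate pattern into all concrete DNA strings
#'
#' For a plain pattern string, every IUPAC position expands to its base set
#' and inosine expands to all four bases (factor 4). For a
#' [back_translate()] result, expansion enumerates codon combinations, so
#' six-codon residues (L, S, R) expand to exactly their codons rather than
#' the looser per-position IUPAC cover.
#'
#' @param x degenerate pattern string, `degenerate_pattern`, or
#'   `degenerate_primer`
#' @return character vector of concrete DNA strings (upper case, unique)
#' @examples
#' expand_pattern("TAY")  # "TAC" "TAT"
#' @export
expand_pattern <- function(x) {
  if (inherits(x, "degenerate_primer")) x <- x$pattern
  if (inherits(x, "degenerate_pattern")) {
    per_res <- lapply(x$codon_sets, function(set) {
      unique(unlist(lapply(set, expand_plain)))
    })
    full <- apply(expand.grid(per_res, stringsAsFactors = FALSE,
                              KEEP.OUT.ATTRS = FALSE), 1L, paste, collapse = "")
    n <- nchar(full[1L])
    return(unique(substr(full, x$trim5 + 1L, n - x$trim3)))
  }
  expand_plain(x)
}

expand_plain <- function(pattern) {
  p <- check_pattern(pattern)
  sets <- IUPAC_SETS[chars(p)]
  if (prod(lengths(sets)) > 1e6) stop("pattern expansion too large")
  apply(expand.grid(sets, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
        1L, paste, collapse = "")
}

#' Degeneracy of a degenerate pattern
#'
#' Product over positions of the per-position alternative count. Inosine is
#' a single synthesised species, so it contributes factor 1 by default
#' (`count_inosine_as = "one"`); `"four"` counts its hybridisation
#' repertoire instead.
#'
#' @param x pattern string or `degenerate_primer`
#' @param count_inosine_as `"one"` or `"four"`
#' @return integer (>= 1)
#' @examples
#' degeneracy("ACGR")  # 2
#' @export
degeneracy <- function(x, count_inosine_as = c("one", "four")) {
  count_inosine_as <- match.arg(count_inosine_as)
  if (inherits(x, "degenerate_primer")) x <- x$pattern
  p <- check_pattern(x)
  facs <- vapply(chars(p), function(s) {
    if (s == "I") {
      if (count_inosine_as == "one") 1L else 4L
    } else {
      length(IUPAC_SETS[[s]])
    }
  }, integer(1))
  as.integer(prod(facs))
}
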