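## Canonical intron numbering and phase statistics. Inferred introns are
## projected onto a protein multiple alignment (positional homology), then
## matched against a canonical intron-position map; novel positions between
## canonical neighbours k and k+1 receive half-integer identifiers k+1/2,
## keeping the established numbering intact.

#' Construct a canonical intron-position map
#'
#' @param identifier numeric vector (integers or half-integers such as 4.5),
#'   strictly increasing
#' @param column alignment column (1-based) of the codon each canonical
#'   intron interrupts, strictly increasing
#' @param phase list or comma-string of admissible phases per position
#'   (positions observed in two phases, e.g. \{0,1\}, are one canonical
#'   identifier with a phase multiset)
#' @return data.frame of class `canonical_map`
#' @export
canonical_map <- function(identifier, column, phase) {
  stopifnot(length(identifier) == length(column),
            length(identifier) == length(phase))
  if (is.character(phase)) {
    phase <- lapply(strsplit(phase, ","), as.integer)
  }
  if (!is.list(phase)) phase <- as.list(as.integer(phase))
  if (any(duplicated(identifier))) stop("duplicate canonical identifiers")
  if (is.unsorted(identifier, strictly = TRUE)) {
    stop("canonical identifiers must be strictly increasing")
  }
  if (is.unsorted(column, strictly = TRUE)) {
    stop("canonical reference columns must be strictly increasing")
  }
  stopifnot(all(unlist(phase) %in% 0:2))
  out <- data.frame(identifier = as.numeric(identifier),
                    column = as.integer(column))
  out$phase <- phase
  class(out) <- c("canonical_map", "data.frame")
  out
}

#' Read / write a canonical map as TSV
#'
#' Columns `identifier`, `column`, `phase` (phases comma-separated).
#' @param path file path
#' @return a `canonical_map` (reader); invisibly `path` (writer)
#' @export
read_canonical_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", colClasses = "character")
  canonical_map(as.numeric(tab$identifier), as.integer(tab$column), tab$phase)
}

#' @rdname read_canonical_map
#' @param map a `canonical_map`
#' @export
write_canonical_map <- function(map, path) {
  tab <- data.frame(identifier = format_identifier(map$identifier),
                    column = map$column,
                    phase = vapply(map$phase, paste, "", collapse = ","))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render canonical identifiers
#'
#' Half-integers render as `"4.5"` (machine style) or `"4½"` (display).
#'
#' @param id numeric identifier(s)
#' @param style `"machine"` or `"display"`
#' @return character vector
#' @examples
#' format_identifier(c(2, 4.5), "display")  # "2" "4½"
#' @export
format_identifier <- function(id, style = c("machine", "display")) {
  style <- match.arg(style)
  half <- abs(id - floor(id) - 0.5) < 1e-9
  out <- character(length(id))
  out[!half] <- format(as.integer(round(id[!half])), trim = TRUE)
  if (style == "machine") {
    out[half] <- sprintf("%.1f", id[half])
  } else {
    out[half] <- paste0(ifelse(floor(id[half]) == 0, "0",
                               format(as.integer(floor(id[half])), trim = TRUE)),
                        "½")
  }
  out
}

#' Intron phase from coding offset
#'
#' @param x a `spliced_gene` intron row, a data.frame with a
#'   `coding_offset` column, or a numeric coding offset
#' @return integer phase(s) in \{0,1,2\}: 0 between codons, 1 after the
#'   first, 2 after the second base of a codon
#' @examples
#' phase_of(7)  # 1
#' @export
phase_of <- function(x) {
  off <- if (is.data.frame(x) || is.list(x)) x$coding_offset else x
  as.integer(off %% 3)
}

#' Project a gene's introns onto a protein alignment
#'
#' Maps each intron to the alignment column of the codon it interrupts
#' (phase > 0) or immediately precedes (phase 0); phases are retained. The
#' gene's translated protein must occur (degapped) as a row of the
#' alignment.
#'
#' @param gene a `spliced_gene`
#' @param msa protein multiple alignment (`AAStringSet` with gaps, or named
#'   character vector)
#' @param id alignment row to use; default: the row whose degapped sequence
#'   equals the gene's protein
#' @return data.frame: `intron` (index into `gene$introns`), `column`,
#'   `phase`
#' @export
project_to_alignment <- function(gene, msa, id = NULL) {
  rows <- setNames(as.character(msa), names(msa))
  if (is.null(names(rows))) names(rows) <- paste0("row_", seq_along(rows))
  if (is.null(id)) {
    degap <- gsub("-", "", rows, fixed = TRUE)
    hit <- which(toupper(degap) == toupper(gene$protein))
    if (!length(hit)) stop("gene protein not found in alignment: ", gene$id)
    id <- names(rows)[hit[1L]]
  }
  row <- toupper(rows[[id]])
  colmap <- which(chars(row) != "-")     # residue index -> alignment column
  introns <- gene$introns
  if (nrow(introns) == 0L) {
    return(data.frame(intron = integer(), column = integer(), phase = integer()))
  }
  pp <- introns$protein_pos
  if (any(pp < 1L) || any(pp > length(colmap))) {
    stop("intron maps outside the aligned protein span of ", gene$id)
  }
  data.frame(intron = seq_len(nrow(introns)),
             column = colmap[pp],
             phase = introns$phase)
}

#' Assign the canonical identifier of one intron position
#'
#' Returns the canonical identifier whose reference column lies within
#' `tolerance` alignment columns and whose phase set contains the observed
#' phase; otherwise mints the half-integer k+1/2 for a position strictly
#' between canonical k and k+1 (0.5 before the first, n+0.5 after the
#' last). Assignment is monotone: larger columns never receive smaller
#' identifiers.
#'
#' @param column alignment column of the intron position
#' @param phase observed phase (0/1/2)
#' @param map a [canonical_map()]
#' @param tolerance positional-homology window in alignment columns
#'   (default 1, with required phase compatibility)
#' @return named numeric: the identifier, with attribute `novel` (logical)
#' @export
assign_identifier <- function(column, phase, map, tolerance = 1L) {
  stopifnot(nrow(map) >= 1L)
  d <- abs(map$column - column)
  ok <- d <= tolerance &
    vapply(map$phase, function(p) phase %in% p, logical(1))
  if (any(ok)) {
    cand <- which(ok)
    cand <- cand[order(d[cand], map$identifier[cand])]
    id <- map$identifier[cand[1L]]
    attr(id, "novel") <- FALSE
    return(id)
  }
  left <- which(map$column < column)
  id <- if (length(left)) floor(map$identifier[max(left)]) + 0.5 else 0.5
  attr(id, "novel") <- TRUE
  id
}

#' Build an intron catalog over a set of spliced genes
#'
#' Projects every gene's introns to the alignment, assigns canonical (or
#' newly minted half-integer) identifiers, and records each gene's aligned
#' span so that downstream presence/absence matrices can distinguish
#' `absent` from `unknown` (a fragment that does not span a canonical
#' position cannot testify about it). Two distinct novel positions falling
#' between the same canonical pair receive the same half-integer with
#' letter suffixes `a`, `b`, ... and a warning.
#'
#' @param genes list of `spliced_gene` objects
#' @param msa protein alignment containing every gene's protein
#' @param map a [canonical_map()]
#' @param tolerance see [assign_identifier()]
#' @return object of class `intron_catalog`: list with `introns`
#'   (data.frame: `seq_id`, `identifier`, `suffix`, `label`, `phase`,
#'   `length`, `column`), `span` (data.frame: `seq_id`, `col_start`,
#'   `col_end`), `map`, `tolerance`
#' @export
build_catalog <- function(genes, msa, map, tolerance = 1L) {
  stopifnot(length(genes) >= 1L)
  rows_list <- list()
  span_list <- list()
  rows_msa <- setNames(as.character(msa), names(msa))
  if (is.null(names(rows_msa))) {
    names(rows_msa) <- paste0("row_", seq_along(rows_msa))
  }
  for (g in genes) {
    proj <- project_to_alignment(g, msa)
    degap <- gsub("-", "", toupper(rows_msa), fixed = TRUE)
    rid <- names(rows_msa)[which(degap == toupper(g$protein))[1L]]
    colmap <- which(chars(toupper(rows_msa[[rid]])) != "-")
    span_list[[g$id]] <- data.frame(seq_id = g$id,
                                    col_start = min(colmap),
                                    col_end = max(colmap))
    if (nrow(proj)) {
      ids <- numeric(nrow(proj))
      novel <- logical(nrow(proj))
      for (i in seq_len(nrow(proj))) {
        a <- assign_identifier(proj$column[i], proj$phase[i], map, tolerance)
        ids[i] <- as.numeric(a)
        novel[i] <- attr(a, "novel")
      }
      rows_list[[g$id]] <- data.frame(
        seq_id = g$id, identifier = ids, novel = novel,
        phase = proj$phase, length = g$introns$length[proj$intron],
        column = proj$column, stringsAsFactors = FALSE)
    }
  }
  introns <- if (length(rows_list)) do.call(rbind, rows_list) else
    data.frame(seq_id = character(), identifier = numeric(), novel = logical(),
               phase = integer(), length = integer(), column = integer())
  rownames(introns) <- NULL
  # suffixes for distinct novel columns sharing a minted identifier:
  # distinct means separated by more than the homology tolerance
  introns$suffix <- ""
  for (idv in unique(introns$identifier[introns$novel])) {
    sel <- which(introns$identifier == idv & introns$novel)
    cols <- introns$column[sel]
    grp <- cumsum(c(TRUE, diff(sort(unique(cols))) > tolerance))
    names(grp) <- sort(unique(cols))
    if (max(grp) > 1L) {
      warning(sprintf(
        "%d distinct novel positions between the same canonical pair (identifier %s); using letter suffixes",
        max(grp), format_identifier(idv)))
      introns$suffix[sel] <- letters[grp[as.character(introns$column[sel])]]
    }
  }
  introns$label <- paste0(format_identifier(introns$identifier), introns$suffix)
  # within a sequence, identifiers must increase with genomic position
  for (sid in unique(introns$seq_id)) {
    sub <- introns[introns$seq_id == sid, ]
    stopifnot(!is.unsorted(sub$identifier))
  }
  structure(list(introns = introns,
                 span = do.call(rbind, c(span_list, list(make.row.names = FALSE))),
                 map = map, tolerance = tolerance),
            class = "intron_catalog")
}

#' @export
print.intron_catalog <- function(x, ...) {
  cat(sprintf("<intron_catalog> %d introns across %d sequences (%d canonical positions in map)\n",
              nrow(x$introns), nrow(x$span), nrow(x$map)))
  invisible(x)
}

#' Summarise intron phases across a catalog
#'
#' Per canonical position: counts of phase 0/1/2 occurrences and the modal
#' phase; positions observed in more than one phase are flagged mixed.
#' The dataset-level fraction of pure phase-0 positions is reported as a
#' percentage rounded down to an integer.
#'
#' @param catalog an `intron_catalog`, or a data.frame with columns
#'   `seq_id`, `label` (or `identifier`) and `phase`
#' @return list with `per_position` (data.frame: `label`, `n`, `phase0`,
#'   `phase1`, `phase2`, `modal_phase`, `mixed`), `n_positions`,
#'   `n_phase0_positions`, `phase0_percent` (floored integer percentage),
#'   and `mixed_positions`
#' @export
summarize_phases <- function(catalog) {
  tab <- if (inherits(catalog, "intron_catalog")) catalog$introns else catalog
  stopifnot(nrow(tab) >= 1L)
  if (is.null(tab$label)) tab$label <- format_identifier(tab$identifier)
  per <- do.call(rbind, lapply(split(tab, tab$label), function(s) {
    cnt <- vapply(0:2, function(p) sum(s$phase == p), integer(1))
    data.frame(label = s$label[1L], n = nrow(s),
               phase0 = cnt[1L], phase1 = cnt[2L], phase2 = cnt[3L],
               modal_phase = which.max(cnt) - 1L,
               mixed = sum(cnt > 0L) > 1L,
               stringsAsFactors = FALSE)
  }))
  # order by identifier value where possible
  ord <- suppressWarnings(as.numeric(sub("([ab])$", "", per$label)))
  per <- per[order(ord, per$label), ]
  rownames(per) <- NULL
  n_pos <- nrow(per)
  n0 <- sum(!per$mixed & per$modal_phase == 0L)
  list(per_position = per,
       n_positions = n_pos,
       n_phase0_positions = n0,
       phase0_percent = as.integer(floor(100 * n0 / n_pos)),
       mixed_positions = per$label[per$mixed])
}
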