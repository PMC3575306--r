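## Readers/writers for the external formats of the pipeline: FASTA
## (sequences), newick (trees), TSV (intron reports, catalogs, character
## matrices), NEXUS (matrix interchange) and a YAML pipeline configuration.
## Stage outputs carry the configuration seed and parameters in comment
## headers so every file is self-describing.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file
#' @param moltype `"dna"` or `"protein"`; controls alphabet validation and
#'   the returned class
#' @return a `DNAStringSet` or `AAStringSet`; names are the header's first
#'   token, full descriptions kept in `mcols(x)$description`; residues are
#'   upper-cased and record order is preserved. An empty file yields an
#'   empty set.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) {
    return(if (moltype == "dna") Biostrings::DNAStringSet() else
      Biostrings::AAStringSet())
  }
  if (!startsWith(trimws(lines[nonempty[1L]]), ">")) {
    stop("FASTA parse error at line ", nonempty[1L],
         ": expected '>' header before sequence data")
  }
  legal <- if (moltype == "dna") "^[ACGTNacgtn]*$" else
    "^[A-Za-z*\\-]*$"
  for (i in nonempty) {
    l <- trimws(lines[i])
    if (startsWith(l, ">")) next
    if (!grepl(legal, l)) {
      stop("FASTA parse error at line ", i, ": illegal characters for ",
           moltype, " sequence")
    }
  }
  x <- if (moltype == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(x))
  x <- if (moltype == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(x) <- ids
  S4Vectors::mcols(x)$description <- desc
  x
}

#' Write sequences to FASTA
#'
#' @param x `XStringSet`, or named list/character vector of sequences
#' @param path output file
#' @return invisibly, `path`
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "XStringSet")) {
    x <- Biostrings::BStringSet(unlist(lapply(x, as.character)))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path newick file (single rooted or unrooted tree)
#' @return an `ape` `phylo` object
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("newick parse error: unbalanced parentheses in ", path)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("newick parse error in ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  tree
}

#' @rdname read_newick
#' @param tree a `phylo`
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a TSV with a comment header
#'
#' All pipeline outputs carry `#`-prefixed header lines recording the seed
#' and parameter values that produced them.
#'
#' @param tab data.frame (or NULL for a header-only file)
#' @param path output file
#' @param header character vector of header fields (written as `# field`)
#' @param col_names column names to write when `tab` is NULL
#' @return invisibly, `path`
#' @export
write_tsv_with_header <- function(tab, path, header = character(),
                                  col_names = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  if (is.null(tab) || nrow(tab) == 0L) {
    if (!is.null(col_names)) writeLines(paste(col_names, collapse = "\t"), con)
    else if (!is.null(tab)) writeLines(paste(names(tab), collapse = "\t"), con)
    return(invisible(path))
  }
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an intron catalog report
#'
#' One row per (sequence, intron): canonical identifier, phase, length;
#' rows ordered by sequence id then identifier, so repeated writes of the
#' same catalog are byte-identical.
#'
#' @param catalog an `intron_catalog`, or a data.frame with columns
#'   `seq_id`, `identifier` (or `label`), `phase`, `length`
#' @param path output file
#' @param config optional [pipeline_config()] whose seed/parameters are
#'   recorded in the header
#' @return invisibly, `path`
#' @export
write_report <- function(catalog, path, config = NULL) {
  tab <- if (inherits(catalog, "intron_catalog")) catalog$introns else catalog
  stopifnot(!is.null(tab))
  if (is.null(tab$label)) tab$label <- format_identifier(tab$identifier)
  ord <- order(tab$seq_id, suppressWarnings(as.numeric(sub("([ab])$", "", tab$label))),
               tab$label)
  out <- data.frame(seq_id = tab$seq_id[ord], identifier = tab$label[ord],
                    phase = tab$phase[ord], length = tab$length[ord])
  hdr <- "intron catalog report"
  if (!is.null(config)) hdr <- c(hdr, config_header(config))
  write_tsv_with_header(out, path, header = hdr)
}

#' Read / write a character matrix as TSV
#'
#' Taxa in rows; entries 1/0/NA for present/absent/unknown.
#' @param path file path
#' @return a [character_matrix()] (reader); invisibly `path` (writer)
#' @export
read_character_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    row.names = 1L, check.names = FALSE)
  character_matrix(as.matrix(tab))
}

#' @rdname read_character_matrix
#' @param m a [character_matrix()]
#' @param header comment-header fields
#' @export
write_character_matrix <- function(m, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(c("taxon", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a character matrix as a NEXUS characters block
#'
#' Unknown states are written as `?`, for interoperability with parsimony
#' software.
#'
#' @param m a [character_matrix()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_nexus_matrix <- function(m, path) {
  rows <- apply(m, 1L, function(r) {
    paste(ifelse(is.na(r), "?", r), collapse = "")
  })
  dat <- setNames(strsplit(rows, ""), rownames(m))
  ape::write.nexus.data(dat, file = path, format = "standard",
                        interleaved = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Declarative configuration of a whole pipeline run, readable from YAML;
#' command-line flags override file values and all defaults are logged into
#' output headers.
#'
#' @param genomic,references,tree,canonical_map input paths (optional)
#' @param primer_policy named primer policy/preset family to use
#' @param max_mismatch in-silico PCR mismatch tolerance
#' @param min_intron minimum intron length (bp)
#' @param intron_penalty spliced-alignment per-intron penalty
#' @param identity_floor minimum translated identity to the reference
#' @param parsimony `"fitch"` or `"dollo"`
#' @param seed random seed recorded in every output header
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genomic = NULL, references = NULL, tree = NULL,
                            canonical_map = NULL, primer_policy = "presets",
                            max_mismatch = 0L, min_intron = 20L,
                            intron_penalty = 15, identity_floor = 0.4,
                            parsimony = c("fitch", "dollo"), seed = 1L) {
  parsimony <- match.arg(parsimony)
  stopifnot(max_mismatch >= 0L, min_intron >= 4L, intron_penalty >= 0,
            identity_floor >= 0)
  structure(list(genomic = genomic, references = references, tree = tree,
                 canonical_map = canonical_map, primer_policy = primer_policy,
                 max_mismatch = as.integer(max_mismatch),
                 min_intron = as.integer(min_intron),
                 intron_penalty = intron_penalty,
                 identity_floor = identity_floor,
                 parsimony = parsimony, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file; keys as in [pipeline_config()]
#' @param overrides named list of values overriding the file (CLI flags)
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Header fields describing a pipeline configuration
#'
#' The seed and numeric parameters of a [pipeline_config()], formatted as
#' `key=value` strings for output comment headers.
#'
#' @param config a [pipeline_config()]
#' @return character vector
#' @export
config_header <- function(config) {
  numeric_keys <- c("max_mismatch", "min_intron", "intron_penalty",
                    "identity_floor", "parsimony", "seed")
  vapply(numeric_keys, function(k) paste0(k, "=", config[[k]]), character(1))
}
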