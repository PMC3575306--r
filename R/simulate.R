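## Gene-family simulator: homologous GHF5 catalytic-domain coding sequences
## evolving along a known tree, with introns gained and lost at known
## canonical slots (GT..AG structure) and the conserved primer motifs
## protected from substitution, so that every pipeline stage can be tested
## against ground truth.

# primers whose coding-strand image is fully consistent with the domain
# scaffold; the simulator guarantees these bind every simulated genomic
# sequence with zero mismatches
SIM_PRIMERS <- c(CD1 = "CD1aF", CD2 = "CD2aF", ENG1 = "ENG1",
                 CD4 = "CD4cR", ENG2 = "ENG2", CD6 = "CDGp8R")

#' Simulation configuration
#'
#' Defines the study conditions for a simulated gene family: a tree (or the
#' number of taxa for a random coalescent tree scaled to the given height),
#' a per-site substitution rate, intron gain/loss rates per canonical slot,
#' the intron length distribution, and the conserved-motif scaffold.
#'
#' Defaults emulate the data regime of single-nematode catalytic-domain
#' amplicons: 12 taxa, a 230-codon CD1..CD6 catalytic domain region carried
#' on a ~307-residue scaffold, an 18-slot canonical intron map, introns of
#' 25 bp minimum (the real families contain introns down to 27 bp), and a
#' root-to-tip substitution divergence given directly by `subst_rate` (the
#' default tree is scaled to height 1).
#'
#' @param n_taxa number of taxa when no tree is supplied
#' @param tree optional `phylo` or newick string; otherwise a random
#'   coalescent tree rescaled to `tree_height`
#' @param tree_height height of the default random tree
#' @param subst_rate expected substitutions per coding site per unit branch
#'   length (tree height 1 => root-to-tip divergence)
#' @param gain_rate,loss_rate intron gain/loss rates per canonical slot per
#'   unit branch length
#' @param intron_len_min,intron_len_mean intron length minimum and mean (bp);
#'   the minimum must not fall below the inference floor
#' @param n_slots number of canonical intron slots
#' @param root_presence probability a slot carries an intron at the root
#' @param fragment_prob probability a taxon is observed as a partial
#'   fragment (introduces unknown states in the truth matrix)
#' @param seed integer random seed (recorded in all outputs)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_taxa = 12L, tree = NULL, tree_height = 1,
                       subst_rate = 0.1, gain_rate = 0.25, loss_rate = 0.25,
                       intron_len_min = 25L, intron_len_mean = 60,
                       n_slots = 18L, root_presence = 0.35,
                       fragment_prob = 0, seed = 1L) {
  stopifnot(subst_rate >= 0, gain_rate >= 0, loss_rate >= 0,
            intron_len_min >= 4L, intron_len_mean >= intron_len_min,
            n_slots >= 1L, root_presence >= 0, root_presence <= 1,
            fragment_prob >= 0, fragment_prob <= 1)
  structure(list(n_taxa = as.integer(n_taxa), tree = tree,
                 tree_height = tree_height, subst_rate = subst_rate,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 intron_len_min = as.integer(intron_len_min),
                 intron_len_mean = intron_len_mean,
                 n_slots = as.integer(n_slots),
                 root_presence = root_presence,
                 fragment_prob = fragment_prob, seed = as.integer(seed)),
            class = "sim_config")
}

# coding-strand image of a preset primer with its residue anchor on the
# scaffold; returns nucleotide constraints on the CDS
primer_constraints <- function(name, scaffold) {
  tab <- primer_presets()
  i <- match(name, tab$name)
  pat <- tab$pattern[i]
  img <- if (tab$orientation[i] == "reverse") reverse_primer(pat) else pat
  img <- gsub("I", "N", img, fixed = TRUE)
  motif <- tab$motif[i]
  mpos <- as.integer(regexpr(motif, scaffold, fixed = TRUE))
  stopifnot(mpos > 0L)
  # best frame/offset of the image against the scaffold around the motif,
  # scored by codon-set compatibility (can some expansion of the image
  # codon encode the scaffold residue?); ties resolved towards the motif
  codon_compatible <- function(aa, syms) {
    any(vapply(AA_CODONS[[aa]], function(cod) {
      all(vapply(1:3, function(k) {
        substr(cod, k, k) %in% IUPAC_SETS[[syms[k]]]
      }, logical(1)))
    }, logical(1)))
  }
  best <- NULL
  sc_chars <- chars(scaffold)
  imgc <- chars(img)
  for (f in 0:2) {
    ncod <- (nchar(img) - f) %/% 3L
    if (ncod < 1L) next
    for (off in (mpos - 6L):(mpos + 4L)) {
      if (off < 1L || off + ncod - 1L > length(sc_chars)) next
      sc <- sum(vapply(seq_len(ncod), function(j) {
        codon_compatible(sc_chars[off + j - 1L], imgc[(f + 3L * j - 2L):(f + 3L * j)])
      }, logical(1)))
      if (is.null(best) || sc > best$sc ||
          (sc == best$sc && abs(off - mpos) < abs(best$off - mpos))) {
        best <- list(f = f, off = off, sc = sc, ncod = ncod)
      }
    }
  }
  if (best$sc < best$ncod - 1L) {
    stop("primer ", name, " could not be anchored on the scaffold")
  }
  # CDS nt position (1-based) of the first image base
  nt_start <- (best$off - 1L) * 3L + 1L - best$f
  data.frame(nt = nt_start:(nt_start + nchar(img) - 1L),
             symbol = chars(img), primer = name, stringsAsFactors = FALSE)
}

# deterministic root CDS: default codons overlaid with primer-compatible
# choices inside the designated primer footprints
build_root_cds <- function(scaffold) {
  res <- chars(scaffold)
  codons <- vapply(res, function(aa) AA_CODONS[[aa]][1L], character(1))
  cds <- chars(paste(codons, collapse = ""))
  cons <- do.call(rbind, lapply(SIM_PRIMERS, primer_constraints,
                                scaffold = scaffold))
  for (ci in unique((cons$nt - 1L) %/% 3L)) {  # 0-based codon index
    sel <- cons[(cons$nt - 1L) %/% 3L == ci, ]
    aa <- res[ci + 1L]
    pos_in_codon <- (sel$nt - 1L) %% 3L + 1L
    pick <- NULL
    for (cod in AA_CODONS[[aa]]) {
      okay <- all(mapply(function(p, s) {
        substr(cod, p, p) %in% IUPAC_SETS[[s]]
      }, pos_in_codon, sel$symbol))
      if (okay) { pick <- cod; break }
    }
    if (is.null(pick)) {
      stop("no codon of ", aa, " is compatible with primer ",
           paste(unique(sel$primer), collapse = "/"), " at codon ", ci + 1L)
    }
    cds[(ci * 3L + 1L):(ci * 3L + 3L)] <- chars(pick)
  }
  # protect every codon of the six conserved motifs plus the full primer
  # footprints: substitutions there would break motif conservation or
  # primer binding
  motif_nt <- unlist(lapply(ghf5_motifs(), function(m) {
    p <- as.integer(regexpr(m, scaffold, fixed = TRUE))
    ((p - 1L) * 3L + 1L):((p + nchar(m) - 1L) * 3L)
  }))
  list(cds = paste(cds, collapse = ""),
       protected = sort(unique(c(cons$nt, motif_nt,
                                 as.vector(outer(unique((cons$nt - 1L) %/% 3L) * 3L,
                                                 1:3, `+`))))))
}

# canonical slot placement: coding offsets spread between the outermost
# primer footprints, at codon boundaries plus a fixed phase pattern
# mirroring the phase-0 bias of real catalytic-domain introns
place_slots <- function(n_slots, cds_len, protected) {
  phases <- rep(c(0L, 0L, 1L, 0L, 2L, 0L, 0L, 0L, 2L, 0L, 0L, 1L, 0L, 2L,
                  0L, 0L, 2L, 0L), length.out = n_slots)
  lo <- min(protected) + 6L
  hi <- max(protected) - 6L
  raw <- round(seq(lo, hi, length.out = n_slots))
  offs <- integer(n_slots)
  for (i in seq_len(n_slots)) {
    o <- (raw[i] %/% 3L) * 3L + phases[i]
    # an intron interrupting a protected (primer-footprint) codon would
    # break primer binding: shift to the nearest free codon boundary
    while (o %in% protected || (o + 1L) %in% protected) o <- o + 3L
    offs[i] <- o
  }
  stopifnot(!is.unsorted(offs, strictly = TRUE), max(offs) < cds_len)
  data.frame(slot = seq_len(n_slots), coding_offset = offs, phase = phases)
}

random_intron <- function(len) {
  stopifnot(len >= 4L)
  paste0("GT", paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE),
                     collapse = ""), "AG")
}

# reject intron sequences whose insertion would create an equivalent
# shifted splice solution (unresolvable by any homology method)
unambiguous_intron <- function(len, left_ctx, right_ctx, tries = 20L) {
  for (t in seq_len(tries)) {
    intr <- random_intron(len)
    s <- paste0(left_ctx, intr, right_ctx)
    ok <- TRUE
    nL <- nchar(left_ctx)
    for (k in 1:6) {
      # shift right: identical splice product and valid GT..AG
      if (substr(s, nL + 1L, nL + k) == substr(s, nL + len + 1L, nL + len + k) &&
          substr(s, nL + k + 1L, nL + k + 2L) == "GT" &&
          substr(s, nL + len + k - 1L, nL + len + k) == "AG") ok <- FALSE
      # shift left
      if (nL >= k &&
          substr(s, nL - k + 1L, nL) == substr(s, nL + len - k + 1L, nL + len) &&
          substr(s, nL - k + 1L, nL - k + 2L) == "GT" &&
          substr(s, nL + len - k - 1L, nL + len - k) == "AG") ok <- FALSE
    }
    if (ok) return(intr)
  }
  intr
}

substitute_sites <- function(seq_chars, p, eligible) {
  if (p <= 0 || !length(eligible)) return(seq_chars)
  hit <- eligible[runif(length(eligible)) < p]
  for (i in hit) {
    alts <- setdiff(c("A", "C", "G", "T"), seq_chars[i])
    seq_chars[i] <- sample(alts, 1L)
  }
  seq_chars
}

#' Simulate a gene family with known intron history
#'
#' Evolves the catalytic-domain CDS along the tree under uniform (Jukes-
#' Cantor-like) substitution outside the protected primer-motif codons,
#' gaining and losing introns at canonical slots with recorded branch
#' events. Every intron begins `GT` and ends `AG`; substitutions never
#' create internal stop codons or touch the motif codons, so the designated
#' primer presets bind every taxon with zero mismatches.
#'
#' @param config a [sim_config()]
#' @return object of class `sim_truth`: list with `tree`, `slots`
#'   (data.frame: `slot`, `coding_offset`, `phase`), `taxa` (per tip:
#'   `genomic`, `cds`, `protein`, `introns` data.frame with genomic
#'   coordinates), `events` (data.frame: `slot`, `parent`, `child`,
#'   `child_label`, `type`), `root_presence`, `spans` (per-taxon coding
#'   coverage when fragmented, else NULL), and the `config`
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scaffold <- ghf5_domain_protein()
  root <- build_root_cds(scaffold)
  cds_len <- nchar(root$cds)
  slots <- place_slots(config$n_slots, cds_len, root$protected)
  stopifnot(config$intron_len_min >= 4L)

  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(config$n_taxa)
    tree$edge.length <- tree$edge.length *
      (config$tree_height / max(ape::node.depth.edgelength(tree)))
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
  }
  n_tip <- length(tree$tip.label)
  ts <- tree_structure(tree)
  root_node <- ts$root

  n_node <- ts$n_node
  cds_at <- vector("list", n_node)
  pres_at <- vector("list", n_node)
  iseq_at <- vector("list", n_node)

  cds_at[[root_node]] <- chars(root$cds)
  pres <- runif(config$n_slots) < config$root_presence
  iseqs <- rep(NA_character_, config$n_slots)
  glen <- function(mean_extra) {
    config$intron_len_min + rgeom(1L, 1 / (mean_extra + 1))
  }
  mean_extra <- config$intron_len_mean - config$intron_len_min
  new_intron_for <- function(slot_i, cds_chars) {
    off <- slots$coding_offset[slot_i]
    left <- paste(cds_chars[max(1L, off - 6L):off], collapse = "")
    right <- paste(cds_chars[(off + 1L):min(length(cds_chars), off + 6L)],
                   collapse = "")
    unambiguous_intron(glen(mean_extra), left, right)
  }
  for (i in which(pres)) iseqs[i] <- new_intron_for(i, cds_at[[root_node]])
  pres_at[[root_node]] <- pres
  iseq_at[[root_node]] <- iseqs

  eligible <- setdiff(seq_len(cds_len), root$protected)
  events <- list()
  edges <- ts$tree$edge
  for (k in rev(seq_len(nrow(edges)))) {      # preorder
    p <- edges[k, 1L]; ch <- edges[k, 2L]
    bl <- ts$tree$edge.length[k]
    psub <- 1 - exp(-config$subst_rate * bl)
    cdsc <- substitute_sites(cds_at[[p]], psub, eligible)
    # repair substitutions that created a stop codon
    for (ci in which(CODON_TABLE[vapply(seq_len(cds_len %/% 3L), function(j) {
      paste(cdsc[(3L * j - 2L):(3L * j)], collapse = "")
    }, character(1))] == "*")) {
      cdsc[(3L * ci - 2L):(3L * ci)] <- cds_at[[p]][(3L * ci - 2L):(3L * ci)]
    }
    pres <- pres_at[[p]]
    iseqs <- iseq_at[[p]]
    pgain <- 1 - exp(-config$gain_rate * bl)
    ploss <- 1 - exp(-config$loss_rate * bl)
    for (s in seq_len(config$n_slots)) {
      if (pres[s] && runif(1L) < ploss) {
        pres[s] <- FALSE; iseqs[s] <- NA_character_
        events[[length(events) + 1L]] <- data.frame(
          slot = s, parent = p, child = ch, type = "loss")
      } else if (!pres[s] && runif(1L) < pgain) {
        pres[s] <- TRUE
        iseqs[s] <- new_intron_for(s, cdsc)
        events[[length(events) + 1L]] <- data.frame(
          slot = s, parent = p, child = ch, type = "gain")
      } else if (pres[s] && psub > 0) {
        ic <- chars(iseqs[s])
        interior <- if (length(ic) > 4L) 3L:(length(ic) - 2L) else integer(0)
        iseqs[s] <- paste(substitute_sites(ic, psub, interior), collapse = "")
      }
    }
    cds_at[[ch]] <- cdsc
    pres_at[[ch]] <- pres
    iseq_at[[ch]] <- iseqs
  }

  taxa <- list()
  spans <- NULL
  for (i in seq_len(n_tip)) {
    cds <- paste(cds_at[[i]], collapse = "")
    pres <- pres_at[[i]]
    iseqs <- iseq_at[[i]]
    sel <- which(pres)
    offs <- slots$coding_offset[sel]
    lens <- nchar(iseqs[sel])
    gstart <- offs + c(0L, cumsum(lens))[seq_along(sel)]
    introns <- data.frame(slot = slots$slot[sel],
                          start = as.integer(gstart),
                          end = as.integer(gstart + lens),
                          length = as.integer(lens),
                          coding_offset = as.integer(offs),
                          phase = slots$phase[sel])
    genomic <- cds
    for (j in rev(seq_along(sel))) {
      genomic <- paste0(substr(genomic, 1L, offs[j]), iseqs[sel[j]],
                        substr(genomic, offs[j] + 1L, nchar(genomic)))
    }
    stopifnot(splice(genomic, introns) == cds)
    taxa[[tree$tip.label[i]]] <- list(genomic = genomic, cds = cds,
                                      protein = translate_dna(cds),
                                      introns = introns)
  }
  if (config$fragment_prob > 0) {
    spans <- list()
    all_off <- range(slots$coding_offset)
    for (tl in names(taxa)) {
      if (runif(1L) < config$fragment_prob) {
        cut <- sort(sample(seq(all_off[1L] + 3L, all_off[2L] - 3L), 2L))
        spans[[tl]] <- c(cut[1L], cut[2L])
      } else {
        spans[[tl]] <- c(0L, cds_len)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(slot = integer(), parent = integer(), child = integer(),
               type = character())
  if (nrow(ev)) {
    ev$child_label <- ifelse(ev$child <= n_tip, tree$tip.label[ev$child],
                             paste0("node_", ev$child))
  } else ev$child_label <- character(0)
  structure(list(tree = ts$tree, slots = slots, taxa = taxa, events = ev,
                 root_presence = pres_at[[root_node]], spans = spans,
                 config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d taxa, %d slots, %d events, seed %d\n",
              length(x$taxa), nrow(x$slots), nrow(x$events), x$config$seed))
  invisible(x)
}

#' Ground-truth character matrix of a simulation
#'
#' Presence/absence per canonical slot per taxon; slots outside a simulated
#' partial fragment's coding span are unknown (NA).
#'
#' @param truth a `sim_truth`
#' @return a [character_matrix()] with slot columns `"1"`, `"2"`, ...
#' @export
truth_matrix <- function(truth) {
  n_slots <- nrow(truth$slots)
  taxa <- names(truth$taxa)
  m <- matrix(0L, length(taxa), n_slots,
              dimnames = list(taxa, as.character(truth$slots$slot)))
  for (tl in taxa) {
    m[tl, as.character(truth$taxa[[tl]]$introns$slot)] <- 1L
    if (!is.null(truth$spans)) {
      sp <- truth$spans[[tl]]
      outside <- truth$slots$coding_offset < sp[1L] |
        truth$slots$coding_offset > sp[2L]
      m[tl, outside] <- NA_integer_
    }
  }
  character_matrix(m)
}

#' FASTA/newick/TSV export of a simulation
#'
#' Writes genomic FASTA, CDS FASTA, the tree, the truth intron table and
#' the truth matrix, all stamped with the simulation seed.
#'
#' @param truth a `sim_truth`
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_sim_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gfa <- file.path(dir, "genomic.fasta")
  cfa <- file.path(dir, "cds.fasta")
  write_fasta(setNames(lapply(truth$taxa, `[[`, "genomic"), names(truth$taxa)), gfa)
  write_fasta(setNames(lapply(truth$taxa, `[[`, "cds"), names(truth$taxa)), cfa)
  tre <- file.path(dir, "tree.nwk")
  ape::write.tree(truth$tree, tre)
  itab <- do.call(rbind, lapply(names(truth$taxa), function(tl) {
    d <- truth$taxa[[tl]]$introns
    if (nrow(d)) cbind(taxon = tl, d) else NULL
  }))
  ifile <- file.path(dir, "introns_truth.tsv")
  write_tsv_with_header(itab, ifile,
                        header = c(sprintf("seed=%d", truth$config$seed)))
  mfile <- file.path(dir, "matrix_truth.tsv")
  write_character_matrix(truth_matrix(truth), mfile,
                         header = c(sprintf("seed=%d", truth$config$seed)))
  invisible(c(gfa, cfa, tre, ifile, mfile))
}
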