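# Canonical intron numbering: projection onto a protein alignment,
# identifier assignment with half-integers for novel positions, and phase
# statistics.

fake_gene <- function(id, protein, protein_pos, phase, length) {
  introns <- if (length(protein_pos)) {
    data.frame(start = NA_integer_, end = NA_integer_, length = length,
               donor = "GT", acceptor = "AG",
               coding_offset = 3L * (protein_pos - 1L) + phase, phase = phase,
               protein_pos = protein_pos)
  } else {
    data.frame(start = integer(), end = integer(), length = integer(),
               donor = character(), acceptor = character(),
               coding_offset = integer(), phase = integer(),
               protein_pos = integer())
  }
  structure(list(id = id, genomic = "", introns = introns, cds = "",
                 protein = protein, ref_id = "ref", ref_start = 0L,
                 score = 0, identity = 1),
            class = "spliced_gene")
}

test_that("projection maps introns to alignment columns, gaps skipped", {
  g <- fake_gene("g1", "MKLVND", protein_pos = c(2L, 5L), phase = c(0L, 1L),
                 length = c(30L, 40L))
  # ungapped single-sequence alignment: columns equal codon indices
  proj <- project_to_alignment(g, c(g1 = "MKLVND"))
  expect_equal(proj$column, c(2L, 5L))
  expect_equal(proj$phase, c(0L, 1L))
  # a leading 3-column gap shifts every column by 3
  proj <- project_to_alignment(g, c(g1 = "---MKLVND"))
  expect_equal(proj$column, c(5L, 8L))
  expect_error(project_to_alignment(fake_gene("gX", "WWWW", 1L, 0L, 20L),
                                    c(g1 = "MKLVND")),
               "not found in alignment")
})

test_that("orthologs with an upstream insertion co-project to one column", {
  set.seed(5)
  # same planted intron after codon 60; one ortholog carries an upstream
  # 2-residue insertion, handled by the alignment gaps
  cds <- domain_cds()
  o <- 180L
  intr <- make_intron(30L, substr(cds, o - 5L, o), substr(cds, o + 1L, o + 6L))
  g1 <- infer_introns(paste0(substr(cds, 1L, o), intr,
                             substr(cds, o + 1L, nchar(cds))),
                      ghf5_domain_protein())
  cds2 <- paste0(substr(cds, 1L, 90L), "GCAGCA", substr(cds, 91L, nchar(cds)))
  o2 <- o + 6L
  g2 <- infer_introns(paste0(substr(cds2, 1L, o2), intr,
                             substr(cds2, o2 + 1L, nchar(cds2))),
                      paste0(substr(ghf5_domain_protein(), 1, 30), "AA",
                             substr(ghf5_domain_protein(), 31,
                                    nchar(ghf5_domain_protein()))))
  msa <- c(g1 = paste0(substr(g1$protein, 1, 30), "--",
                       substr(g1$protein, 31, nchar(g1$protein))),
           g2 = g2$protein)
  p1 <- project_to_alignment(g1, msa)
  p2 <- project_to_alignment(g2, msa)
  expect_equal(p1$column, p2$column)
  expect_equal(p1$phase, p2$phase)
})

test_that("identifier assignment matches canonical positions and mints halves", {
  map <- canonical_map(1:6, c(10L, 25L, 40L, 55L, 70L, 85L),
                       phase = list(0L, 0L, 1L, 0L, c(0L, 1L), 2L))
  # exactly at canonical 4
  expect_equal(as.numeric(assign_identifier(55L, 0L, map)), 4)
  # within tolerance, phase-compatible
  expect_equal(as.numeric(assign_identifier(56L, 0L, map)), 4)
  # same column, wrong phase: novel
  a <- assign_identifier(55L, 2L, map)
  expect_true(attr(a, "novel"))
  expect_equal(as.numeric(a), 3.5)
  # novel positions: between 1 and 2, before the first, after the last
  expect_equal(as.numeric(assign_identifier(17L, 0L, map)), 1.5)
  expect_equal(as.numeric(assign_identifier(3L, 0L, map)), 0.5)
  expect_equal(as.numeric(assign_identifier(99L, 0L, map)), 6.5)

  # ordering oracle: a random novel column sorts strictly between its
  # flanking canonical identifiers
  set.seed(17)
  for (i in 1:50) {
    col <- sample(setdiff(2:95, unlist(lapply(map$column, function(ct) (ct - 1):(ct + 1)))), 1L)
    id <- as.numeric(assign_identifier(col, 2L, map))
    below <- map$identifier[map$column < col]
    above <- map$identifier[map$column > col]
    if (length(below)) expect_gt(id, max(below))
    if (length(above)) expect_lt(id, min(above))
  }
})

test_that("identifier rendering is exact for machine and display styles", {
  expect_equal(format_identifier(c(2, 4.5)), c("2", "4.5"))
  expect_equal(format_identifier(c(2, 4.5, 0.5), "display"), c("2", "4½", "0½"))
})

test_that("phase_of is the coding offset modulo 3", {
  expect_equal(phase_of(0L), 0L)
  expect_equal(phase_of(7L), 1L)
  expect_equal(phase_of(14L), 2L)
  expect_equal(phase_of(data.frame(coding_offset = c(3L, 4L))), c(0L, 1L))
})

test_that("catalog assembly assigns slots and warns on crowded gaps", {
  map <- canonical_map(1:3, c(10L, 30L, 50L), phase = list(0L, 0L, 0L))
  g1 <- fake_gene("s1", paste(rep("A", 60), collapse = ""),
                  protein_pos = c(10L, 18L), phase = c(0L, 0L),
                  length = c(30L, 44L))
  g2 <- fake_gene("s2", paste(rep("A", 60), collapse = ""),
                  protein_pos = c(10L, 23L), phase = c(0L, 0L),
                  length = c(31L, 52L))
  expect_warning(cat12 <- build_catalog(list(g1, g2),
                                        c(s1 = paste(rep("A", 60), collapse = ""),
                                          s2 = paste(rep("A", 60), collapse = "")),
                                        map),
                 "distinct novel positions")
  labs <- cat12$introns$label
  expect_true(all(c("1", "1.5a", "1.5b") %in% labs))
})

test_that("phase summary counts positions, flags mixed, floors the percentage", {
  # single phase-0 intron: 100% phase 0, nothing mixed
  tab <- data.frame(seq_id = "s1", label = "2", phase = 0L, length = 50L)
  ph <- summarize_phases(tab)
  expect_equal(ph$phase0_percent, 100L)
  expect_equal(length(ph$mixed_positions), 0L)

  # simulated family: the summary equals the generator's bookkeeping
  tr <- simulate_family(sim_config(n_taxa = 6L, subst_rate = 0, seed = 23L))
  genes <- lapply(names(tr$taxa), function(tl) {
    g <- infer_introns(tr$taxa[[tl]]$genomic, ghf5_domain_protein())
    g$id <- tl
    g
  })
  msa <- setNames(vapply(genes, `[[`, "", "protein"), names(tr$taxa))
  map <- canonical_map(tr$slots$slot,
                       tr$slots$coding_offset %/% 3L + 1L,
                       phase = as.list(tr$slots$phase))
  catalog <- build_catalog(genes, msa, map)
  truth_tab <- do.call(rbind, lapply(names(tr$taxa), function(tl) {
    d <- tr$taxa[[tl]]$introns
    if (nrow(d)) data.frame(seq_id = tl, label = as.character(d$slot),
                            phase = d$phase, length = d$length)
  }))
  ph_got <- summarize_phases(catalog)
  ph_want <- summarize_phases(truth_tab)
  got <- ph_got$per_position
  want <- ph_want$per_position
  expect_equal(got[, c("label", "n", "phase0", "phase1", "phase2")],
               want[, c("label", "n", "phase0", "phase1", "phase2")])
  expect_equal(ph_got$phase0_percent, ph_want$phase0_percent)
})

test_that("fragments not spanning a canonical position yield unknown, not absent", {
  map <- canonical_map(1:3, c(10L, 30L, 50L), phase = list(0L, 0L, 0L))
  msa_row <- function(lo, hi) {
    paste0(paste(rep("-", lo - 1L), collapse = ""),
           paste(rep("A", hi - lo + 1L), collapse = ""),
           paste(rep("-", 60L - hi), collapse = ""))
  }
  full <- fake_gene("full", paste(rep("A", 60), collapse = ""),
                    protein_pos = 30L, phase = 0L, length = 40L)
  short <- fake_gene("short", paste(rep("A", 15), collapse = ""),
                     protein_pos = integer(), phase = integer(),
                     length = integer())
  catalog <- build_catalog(list(full, short),
                           c(full = msa_row(1L, 60L), short = msa_row(20L, 34L)),
                           map)
  m <- catalog_to_matrix(catalog)
  expect_equal(m["full", ], c(`1` = 0L, `2` = 1L, `3` = 0L))
  expect_equal(m["short", ], c(`1` = NA_integer_, `2` = 0L, `3` = NA_integer_))
})
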