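# Homology-guided intron inference: spliced alignment against a reference,
# splice-out arithmetic, and cDNA verification.

test_that("splice is the identity without introns and conserves length", {
  x <- "AAGTCCCTAGA"
  expect_equal(splice(x, NULL), x)
  expect_equal(splice(x, data.frame(start = integer(), end = integer())), x)

  intr <- data.frame(start = 1L, end = 10L)
  out <- splice("AAGTXXXXAGA"
                , intr)
  expect_equal(nchar(out), 11L - 9L)
  expect_equal(out, "AA")

  expect_error(splice(x, data.frame(start = c(1L, 4L), end = c(6L, 9L))),
               "overlap")
  expect_error(splice(x, data.frame(start = 5L, end = 50L)), "out of range")
})

test_that("an intronless gene identical to the reference yields zero introns", {
  cds <- domain_cds()
  fit <- infer_introns(cds, ghf5_domain_protein())
  expect_equal(nrow(fit$introns), 0L)
  expect_equal(fit$cds, cds)
  expect_equal(fit$identity, 1)
})

test_that("planted GT..AG introns are recovered with exact coordinates and phases", {
  set.seed(13)
  cds <- domain_cds()
  # plant 50/27/80 bp introns at coding offsets of phases 1, 0, 2
  offs <- c(100L, 300L, 500L)
  lens <- c(50L, 27L, 80L)
  seqs <- mapply(function(o, l) {
    make_intron(l, substr(cds, o - 5L, o), substr(cds, o + 1L, o + 6L))
  }, offs, lens)
  genomic <- cds
  for (j in 3:1) {
    genomic <- paste0(substr(genomic, 1L, offs[j]), seqs[j],
                      substr(genomic, offs[j] + 1L, nchar(genomic)))
  }
  fit <- infer_introns(genomic, ghf5_domain_protein())
  expect_equal(fit$introns$coding_offset, offs)
  expect_equal(fit$introns$length, lens)
  expect_equal(fit$introns$phase, offs %% 3L)
  expect_equal(fit$cds, cds)
  expect_true(all(fit$introns$donor == "GT" & fit$introns$acceptor == "AG"))
  # conservation
  expect_equal(nchar(genomic), nchar(fit$cds) + sum(fit$introns$length))
})

test_that("the best-scoring reference is selected automatically and recorded", {
  cds <- domain_cds()
  frag <- substr(cds, 1L, 400L)
  decoy <- paste(rep("MKLV", 60L), collapse = "")
  fit <- infer_introns(frag, list(decoy = decoy, domain = ghf5_domain_protein()))
  expect_equal(fit$ref_id, "domain")
})

test_that("phases are frame-anchored: invariant to fragment start shifts", {
  set.seed(29)
  cds <- domain_cds()
  o <- 240L
  intr <- make_intron(45L, substr(cds, o - 5L, o), substr(cds, o + 1L, o + 6L))
  genomic <- paste0(substr(cds, 1L, o), intr, substr(cds, o + 1L, nchar(cds)))
  ref <- ghf5_domain_protein()
  base <- infer_introns(genomic, ref)
  # codon-preserving shift (3 nt) and frame-breaking shift (1 nt) both leave
  # the phase unchanged because the phase is anchored in the reference frame
  for (shift in c(3L, 1L, 2L)) {
    fit <- infer_introns(substr(genomic, shift + 1L, nchar(genomic)), ref)
    expect_equal(fit$introns$phase, base$introns$phase, info = shift)
    expect_equal(fit$introns$length, base$introns$length, info = shift)
    expect_equal(fit$introns$phase, fit$introns$coding_offset %% 3L)
  }
})

test_that("a non-homologous fragment raises the no-splice error with its score", {
  set.seed(99)
  err <- tryCatch(infer_introns(random_dna(300L), ghf5_domain_protein(),
                                identity_floor = 0.9),
                  engevo_no_splice = function(e) e)
  expect_s3_class(err, "engevo_no_splice")
  expect_true(is.finite(err$best_score))
  expect_lt(err$identity, 0.9)
})

test_that("verify_against_cdna reports mismatch coordinates over the overlap", {
  a <- "ACGTACGTACGTACGT"
  r <- verify_against_cdna(a, a)
  expect_true(r$ok)
  expect_equal(nrow(r$mismatches), 0L)

  b <- a
  substr(b, 7L, 7L) <- "A"
  r <- verify_against_cdna(a, b)
  expect_false(r$ok)
  expect_equal(nrow(r$mismatches), 1L)
  expect_equal(r$mismatches$pos_spliced, 6L)

  # a cdna shifted/truncated relative to the splice product anchors at the
  # best offset; end trims ignore primer-derived ends
  cdna <- substr(a, 4L, 16L)
  r <- verify_against_cdna(a, cdna)
  expect_true(r$ok)
  expect_equal(r$offset, 3L)
  r2 <- verify_against_cdna(a, paste0(substr(cdna, 1, 12), "G"), end_trim = 1L)
  expect_true(r2$ok)
})

test_that("GC donors are found only when explicitly permitted", {
  set.seed(41)
  cds <- domain_cds()
  o <- 321L
  intr <- make_intron(40L, substr(cds, o - 5L, o), substr(cds, o + 1L, o + 6L))
  substr(intr, 2L, 2L) <- "C"   # GC donor
  genomic <- paste0(substr(cds, 1L, o), intr, substr(cds, o + 1L, nchar(cds)))
  fit_canon <- infer_introns(genomic, ghf5_domain_protein())
  expect_false(any(fit_canon$introns$coding_offset == o &
                     fit_canon$introns$length == 40L))
  fit_gc <- infer_introns(genomic, ghf5_domain_protein(), allow_gc_donor = TRUE)
  hit <- fit_gc$introns[fit_gc$introns$coding_offset == o, ]
  expect_equal(hit$length, 40L)
  expect_equal(hit$donor, "GC")
})
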