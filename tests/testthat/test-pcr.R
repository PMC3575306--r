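# In-silico PCR: binding-site search under IUPAC set-matching and amplicon
# extraction with both primer footprints included.

test_that("find_sites locates exact and inosine-wildcard sites", {
  s <- find_sites("ACGT", "TTACGTTT")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 2L)
  expect_equal(s$strand, "+")
  expect_equal(s$mismatches, 0L)

  s <- find_sites("ACIT", "TTACGTTT")
  expect_equal(s$start, 2L)   # I matches the G

  # a primer longer than the template is a valid zero-hit query
  expect_equal(nrow(find_sites("ACGTACGTACGT", "ACGT")), 0L)
})

test_that("site lists equal the brute-force scan on random templates", {
  set.seed(101)
  presets <- primer_presets()
  for (rep in 1:20) {
    tmpl <- random_dna(500L)
    p <- presets$pattern[sample(nrow(presets), 1L)]
    # plant an expansion of the primer (either strand) to guarantee signal
    inst <- sample(expand_pattern(p), 1L)
    if (runif(1) < 0.5) inst <- revcomp(inst)
    at <- sample(500L - nchar(inst), 1L)
    tmpl <- paste0(substr(tmpl, 1, at - 1L), inst,
                   substr(tmpl, at + nchar(inst), 500L))
    for (mm in 0:1) {
      got <- find_sites(p, tmpl, max_mismatch = mm)
      want <- oracle_sites(p, tmpl, max_mismatch = mm)
      expect_equal(got[, c("start", "end", "strand", "mismatches")],
                   want, ignore_attr = TRUE)
      expect_gte(nrow(got), 1L)
    }
  }
})

test_that("amplify extracts the fragment delimited by both footprints", {
  fwd <- "CCICCITACGGICAATTGTC"
  rev <- "GCCCAGTTGAGGTACGAA"
  inner <- random_dna(50L)
  tmpl <- paste0(sample(expand_pattern(fwd), 1L), inner, revcomp(rev))
  amp <- amplify(tmpl, fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, nchar(fwd) + 50L + nchar(rev))
  expect_equal(amp$sequence, tmpl)

  # zero products is a valid result
  expect_equal(nrow(amplify(random_dna(60L), fwd, rev)), 0L)
})

test_that("nested site pairs equal the exhaustive pairing oracle", {
  set.seed(7)
  f <- "ATGGCAT"
  r <- "TTGGCCA"
  rci <- revcomp(r)
  tmpl <- paste0(f, random_dna(30), f, random_dna(40), rci, random_dna(25), rci)
  amp <- amplify(tmpl, f, r, size_range = c(1, 500))
  fs <- oracle_sites(f, tmpl, 0); fs <- fs[fs$strand == "+", ]
  rs <- oracle_sites(r, tmpl, 0); rs <- rs[rs$strand == "-", ]
  pairs <- expand.grid(fi = seq_len(nrow(fs)), ri = seq_len(nrow(rs)))
  want <- sort(unlist(lapply(seq_len(nrow(pairs)), function(k) {
    st <- fs$start[pairs$fi[k]]; en <- rs$end[pairs$ri[k]]
    if (rs$start[pairs$ri[k]] >= st) en - st else NULL
  })))
  expect_equal(sort(amp$length), want)
  expect_equal(nrow(amp), 4L)
  # deterministic order: by start, then length
  expect_equal(amp$length, amp[order(amp$start, amp$length), "length"])

  # size_range filters the cross product
  amp2 <- amplify(tmpl, f, r, size_range = c(1, 60))
  expect_true(all(amp2$length <= 60))
})

test_that("strand symmetry: amplifying the reverse complement with swapped primers", {
  set.seed(31)
  f <- "CTCAAATGCAATTGGAACKC"
  r <- "TCCACATCTTGGCACCA"
  tmpl <- paste0(random_dna(20), sample(expand_pattern(f), 1L), random_dna(80),
                 revcomp(sample(expand_pattern(r), 1L)), random_dna(15))
  a1 <- amplify(tmpl, f, r)
  a2 <- amplify(revcomp(tmpl), r, f)
  expect_equal(nrow(a1), 1L)
  expect_equal(sort(a1$length), sort(a2$length))
  expect_setequal(vapply(a2$sequence, revcomp, ""), a1$sequence)
})

test_that("raising the mismatch tolerance never removes a site", {
  set.seed(53)
  p <- "TAYGTIATCGTIGAYTGGCA"
  for (rep in 1:10) {
    tmpl <- random_dna(400L)
    prev <- NULL
    for (mm in 0:3) {
      s <- find_sites(p, tmpl, max_mismatch = mm)
      key <- paste(s$start, s$strand)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
  }
})

test_that("variant screening reports which primer variant bound", {
  tmpl <- paste0(random_dna(10), sample(expand_pattern(get_primer("CD1bF")$pattern), 1L),
                 random_dna(10))
  hits <- screen_variants(c("CD1aF", "CD1bF", "CD1cF"), tmpl)
  expect_true("CD1bF" %in% hits$primer)
})
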