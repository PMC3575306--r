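# Parsimony superposition of intron presence/absence characters, diagnostic
# characters, and reference-based catalytic-domain typing.

random_states <- function(tips, p_na = 0.15) {
  s <- sample(0:1, length(tips), TRUE)
  s[runif(length(tips)) < p_na] <- NA_integer_
  setNames(as.integer(s), tips)
}

test_that("a constant character needs zero events", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  m <- character_matrix(matrix(1L, 4L, 1L, dimnames = list(letters[1:4], "5")))
  for (mode in c("fitch", "dollo")) {
    rec <- superpose(tree, m, mode = mode)
    expect_equal(unname(rec$counts), if (mode == "dollo") 1 else 0)
  }
  # all-absent: zero events in both modes
  m0 <- character_matrix(matrix(0L, 4L, 1L, dimnames = list(letters[1:4], "5")))
  expect_equal(unname(superpose(tree, m0, "dollo")$counts), 0)
})

test_that("fitch and dollo counts equal exhaustive enumeration with unknowns", {
  set.seed(301)
  for (n_tip in 4:7) {
    tree <- ape::rcoal(n_tip)
    for (rep in 1:25) {
      states <- random_states(tree$tip.label)
      m <- character_matrix(matrix(states, ncol = 1L,
                                   dimnames = list(names(states), "x")))
      expect_equal(unname(superpose(tree, m, "fitch")$counts),
                   oracle_parsimony(tree, states, "fitch"))
      expect_equal(unname(superpose(tree, m, "dollo")$counts),
                   oracle_parsimony(tree, states, "dollo"))
    }
  }
})

test_that("fitch agrees with phangorn and is invariant under re-rooting", {
  set.seed(99)
  tree <- ape::rcoal(8L)
  chars <- replicate(30, sample(0:1, 8L, TRUE))
  rownames(chars) <- tree$tip.label
  m <- character_matrix(chars)
  counts <- superpose(tree, m, "fitch")$counts
  pd <- phangorn::phyDat(chars, type = "USER", levels = c(0L, 1L))
  per_pattern <- phangorn::parsimony(tree, pd, site = "site", method = "fitch")
  expect_equal(unname(counts),
               as.numeric(per_pattern)[attr(pd, "index")])
  for (node in c(11L, 13L, 15L)) {
    ret <- ape::root(tree, node = node, resolve.root = TRUE)
    expect_equal(unname(superpose(ret, m, "fitch")$counts), unname(counts))
  }
})

test_that("a type-diagnostic intron loss maps to the clade stem under dollo", {
  # intron present in the outgroup and in type A, lost once on the stem of
  # the monophyletic B+C group (the intron-18 pattern of the catalytic-
  # domain types); the outgroup forces the gain above the root so a single
  # loss on the B+C stem is the only minimal dollo labelling
  tree <- ape::read.tree(
    text = "(Out,((A1,(A2,A3)),((B1,(B2,B3)),(C1,C2))));")
  taxa <- tree$tip.label
  states <- setNames(as.integer(grepl("^A|^Out", taxa)), taxa)
  m <- character_matrix(matrix(states, ncol = 1L,
                               dimnames = list(taxa, "18")))
  rec <- superpose(tree, m, "dollo")
  losses <- rec$events[rec$events$type == "loss", ]
  expect_equal(nrow(losses), 1L)
  stem <- ape::getMRCA(tree, c("B1", "B2", "B3", "C1", "C2"))
  expect_equal(losses$child, stem)
})

test_that("unknown states are free and never add events", {
  tree <- ape::rcoal(6L)
  tips <- tree$tip.label
  full <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L), tips)
  half <- full
  half[c(2L, 5L)] <- NA_integer_
  mk <- function(s) character_matrix(matrix(s, ncol = 1L,
                                            dimnames = list(names(s), "x")))
  expect_lte(unname(superpose(tree, mk(half), "fitch")$counts),
             unname(superpose(tree, mk(full), "fitch")$counts))
})

test_that("taxa missing from the tree are reported by name", {
  tree <- ape::read.tree(text = "((a,b),c);")
  m <- character_matrix(matrix(0L, 2L, 1L, dimnames = list(c("a", "zz"), "x")))
  expect_error(superpose(tree, m), "zz")
})

test_that("diagnostic characters are classified per clade", {
  taxa <- c("A1", "A2", "B1", "B2", "B3", "C1", "C2")
  m <- character_matrix(matrix(
    c( # intron 4: present only in type A (diagnostic for A)
      1L, 1L, 0L, 0L, 0L, 0L, 0L,
      # intron 2: present in C and in part of B (shared, not exclusive)
      0L, 0L, 1L, 1L, 0L, 1L, 1L,
      # constant absent: non-diagnostic
      0L, 0L, 0L, 0L, 0L, 0L, 0L,
      # unknowns ignored: diagnostic for A despite NA outside
      1L, 1L, NA, 0L, 0L, 0L, NA),
    ncol = 4L, dimnames = list(taxa, c("4", "2", "9", "14"))))
  clades <- list(A = c("A1", "A2"), B = c("B1", "B2", "B3"), C = c("C1", "C2"))
  rep <- diagnostic_characters(m, clades)
  get <- function(ch, cl) rep$status[rep$character == ch & rep$clade == cl]
  expect_equal(get("4", "A"), "diagnostic")
  expect_equal(get("2", "C"), "shared_not_exclusive")
  expect_equal(get("9", "A"), "non_diagnostic")
  expect_equal(get("9", "B"), "non_diagnostic")
  expect_equal(get("14", "A"), "diagnostic")
  expect_error(diagnostic_characters(m, list(A = character())), "empty clade")
})

test_that("classify_type recovers reference labels and simulated subfamilies", {
  set.seed(61)
  base <- ghf5_domain_protein()
  mutate <- function(p, frac) {
    ch <- strsplit(p, "")[[1]]
    idx <- sample(length(ch), round(frac * length(ch)))
    aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
    ch[idx] <- sample(aas, length(idx), TRUE)
    paste(ch, collapse = "")
  }
  ancestors <- setNames(lapply(1:3, function(i) mutate(base, 0.25)),
                        c("refA", "refB", "refC"))
  labels <- c("A", "B", "C")
  # a reference classified against the reference set gets its own label, score 1
  self <- classify_type(ancestors, ancestors, labels)
  expect_equal(self$label, labels)
  expect_equal(self$score, c(1, 1, 1))
  # subfamily members at 10% within-family divergence: 100% label recovery
  queries <- list()
  truth <- character()
  for (i in 1:3) {
    for (j in 1:4) {
      nm <- paste0("q", i, "_", j)
      queries[[nm]] <- mutate(ancestors[[i]], 0.10)
      truth[nm] <- labels[i]
    }
  }
  got <- classify_type(queries, ancestors, labels)
  expect_equal(setNames(got$label, got$id), truth)
  expect_error(classify_type(queries, character(), character()),
               "empty reference set")
})
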