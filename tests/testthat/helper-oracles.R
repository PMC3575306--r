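# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own implementation paths: the site
# scan is a position-by-position O(nm) sweep, and the parsimony oracle is
# exhaustive enumeration over ancestral (and unknown-tip) labellings.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N", I = "I")

oracle_revcomp_pattern <- function(p) {
  paste(rev(unname(ORACLE_COMP[strsplit(toupper(p), "")[[1]]])), collapse = "")
}

# compatibility lookup: pattern symbol x template symbol -> sets intersect
oracle_compat <- local({
  syms <- names(ORACLE_IUPAC)
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (a in syms) for (b in syms) {
    m[a, b] <- length(intersect(ORACLE_IUPAC[[a]], ORACLE_IUPAC[[b]])) > 0L
  }
  m
})

# brute-force scan of one strand: mismatch count at every offset
oracle_scan_strand <- function(pattern, template) {
  pc <- strsplit(toupper(pattern), "")[[1]]
  tc <- strsplit(toupper(template), "")[[1]]
  m <- length(pc); n <- length(tc)
  if (m > n) return(integer(0))
  mm <- integer(n - m + 1L)
  for (j in seq_len(m)) {
    mm <- mm + !oracle_compat[pc[j], tc[j:(n - m + j)]]
  }
  mm
}

oracle_sites <- function(pattern, template, max_mismatch = 0L) {
  m <- nchar(pattern)
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else oracle_revcomp_pattern(pattern)
    mm <- oracle_scan_strand(pat, template)
    hit <- which(mm <= max_mismatch)
    if (length(hit)) {
      rows[[strand]] <- data.frame(start = hit - 1L, end = hit - 1L + m,
                                   strand = strand, mismatches = mm[hit],
                                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               mismatches = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # same duplex-site convention as the implementation: a minus-strand hit
  # over a plus-strand footprint is one site
  dup <- out$strand == "-" &
    paste(out$start, out$end) %in% paste(out$start, out$end)[out$strand == "+"]
  out <- out[!dup, , drop = FALSE]
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# exhaustive small-parsimony oracle; states named by tip label (0/1/NA).
# Fitch: minimum edge changes over all labellings. Dollo: labellings with at
# most one gain (a 0->1 edge, or presence at the root counting as the gain),
# cost = gains + losses.
oracle_parsimony <- function(tree, states, mode = c("fitch", "dollo")) {
  mode <- match.arg(mode)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  s <- rep(NA_integer_, n_node)
  s[seq_len(n_tip)] <- states[tree$tip.label]
  vars <- which(is.na(s))                      # interior + unknown tips
  edges <- tree$edge
  n_var <- length(vars)
  masks <- 0:(2^n_var - 1L)
  assign <- matrix(rep(s, each = length(masks)), nrow = length(masks))
  for (k in seq_len(n_var)) {
    assign[, vars[k]] <- bitwAnd(masks %/% 2^(k - 1L), 1L)
  }
  changes <- rowSums(sapply(seq_len(nrow(edges)), function(e) {
    assign[, edges[e, 1L]] != assign[, edges[e, 2L]]
  }))
  if (mode == "fitch") return(min(changes))
  root <- setdiff(edges[, 1L], edges[, 2L])[1L]
  gains <- rowSums(sapply(seq_len(nrow(edges)), function(e) {
    assign[, edges[e, 1L]] == 0L & assign[, edges[e, 2L]] == 1L
  })) + (assign[, root] == 1L)
  losses <- rowSums(sapply(seq_len(nrow(edges)), function(e) {
    assign[, edges[e, 1L]] == 1L & assign[, edges[e, 2L]] == 0L
  }))
  ok <- gains <= 1L
  min((gains + losses)[ok])
}

# a GT..AG intron with interior chosen to avoid boundary-shift ambiguity
# against the given flanks (mirrors the generator's rejection rule)
make_intron <- function(len, left = "", right = "") {
  stopifnot(len >= 4L)
  for (t in 1:50) {
    x <- paste0("GT", random_dna(len - 4L), "AG")
    s <- paste0(left, x, right)
    nL <- nchar(left)
    ok <- TRUE
    for (k in 1:6) {
      if (substr(s, nL + 1L, nL + k) == substr(s, nL + len + 1L, nL + len + k) &&
          substr(s, nL + k + 1L, nL + k + 2L) == "GT" &&
          substr(s, nL + len + k - 1L, nL + len + k) == "AG") ok <- FALSE
      if (nL >= k &&
          substr(s, nL - k + 1L, nL) == substr(s, nL + len - k + 1L, nL + len) &&
          substr(s, nL - k + 1L, nL - k + 2L) == "GT" &&
          substr(s, nL + len - k - 1L, nL + len - k) == "AG") ok <- FALSE
    }
    if (ok) return(x)
  }
  x
}

# the simulator's intronless domain CDS (conserved scaffold, no events)
domain_cds <- function() {
  tr <- simulate_family(sim_config(n_taxa = 2L, subst_rate = 0,
                                   gain_rate = 0, loss_rate = 0,
                                   root_presence = 0, seed = 1L))
  tr$taxa[[1L]]$cds
}

intron_key <- function(d) paste(d$start, d$end, d$phase)
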