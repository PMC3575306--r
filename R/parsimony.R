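## Superposition of intron presence/absence characters onto a phylogeny.
## Fitch (minimum-change) counts are computed by a binary Sankoff dynamic
## programme that treats unknown tip states as free variables; Dollo
## reconstructions allow a single gain per character with unlimited
## subsequent losses. Both return branch-level event labellings achieving
## the minimum.

#' Construct an intron presence/absence character matrix
#'
#' @param states matrix or data.frame coercible to matrix: taxa in rows,
#'   canonical intron identifiers in columns; entries 1 (present), 0
#'   (absent) or NA (unknown: the fragment does not span the position and
#'   cannot testify)
#' @return integer matrix of class `character_matrix`
#' @export
character_matrix <- function(states) {
  m <- as.matrix(states)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) stop("character matrix needs taxon rownames")
  if (is.null(colnames(m))) colnames(m) <- paste0("chr", seq_len(ncol(m)))
  if (!all(m %in% c(0L, 1L, NA_integer_))) {
    stop("states must be 0, 1 or NA")
  }
  class(m) <- c("character_matrix", class(m))
  m
}

#' Presence/absence matrix from an intron catalog
#'
#' `present` where the catalog records the intron, `absent` where the
#' sequence spans the canonical position without it, `unknown` (NA) where
#' the fragment does not cover the position.
#'
#' @param catalog an `intron_catalog`
#' @return a [character_matrix()]
#' @export
catalog_to_matrix <- function(catalog) {
  labs <- unique(c(format_identifier(catalog$map$identifier),
                   catalog$introns$label))
  ord <- suppressWarnings(as.numeric(sub("([ab])$", "", labs)))
  labs <- labs[order(ord, labs)]
  cols <- setNames(rep(NA_integer_, length(labs)), labs)
  colpos <- setNames(rep(NA_integer_, length(labs)), labs)
  colpos[format_identifier(catalog$map$identifier)] <- catalog$map$column
  for (lb in setdiff(labs, names(which(!is.na(colpos))))) {
    colpos[lb] <- round(mean(catalog$introns$column[catalog$introns$label == lb]))
  }
  taxa <- catalog$span$seq_id
  m <- matrix(NA_integer_, length(taxa), length(labs),
              dimnames = list(taxa, labs))
  for (i in seq_along(taxa)) {
    sp <- catalog$span[i, ]
    covered <- colpos >= sp$col_start & colpos <= sp$col_end
    m[i, covered] <- 0L
    has <- catalog$introns$label[catalog$introns$seq_id == taxa[i]]
    m[i, has] <- 1L
  }
  character_matrix(m)
}

check_matrix_tree <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"))
  bad <- setdiff(rownames(matrix), tree$tip.label)
  if (length(bad)) {
    stop("matrix taxa absent from tree: ", paste(bad, collapse = ", "))
  }
}

# postorder edge matrix and child lists for a phylo tree
tree_structure <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    children[[p]] <- c(children[[p]], tree$edge[k, 2L])
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  list(tree = tree, n_tip = n_tip, n_node = n_node, children = children,
       root = root,
       postorder_nodes = unique(c(tree$edge[, 2L], root)))
}

# binary Sankoff for one character; returns min count and a minimal node
# labelling (ties: prefer absent at the root, keep the parent state down
# the tree)
fitch_one <- function(ts, states) {
  INF <- 1e9
  cost <- matrix(INF, ts$n_node, 2L)
  for (i in seq_len(ts$n_tip)) {
    s <- states[i]
    cost[i, ] <- if (is.na(s)) c(0, 0) else if (s == 0L) c(0, INF) else c(INF, 0)
  }
  for (v in ts$postorder_nodes) {
    kids <- ts$children[[v]]
    if (is.null(kids)) next
    for (s in 1:2) {
      tot <- 0
      for (ch in kids) {
        tot <- tot + min(cost[ch, s], cost[ch, 3L - s] + 1)
      }
      cost[v, s] <- tot
    }
  }
  assign <- integer(ts$n_node)
  rootcost <- cost[ts$root, ]
  assign[ts$root] <- if (rootcost[1L] <= rootcost[2L]) 0L else 1L
  # preorder: reverse postorder
  for (v in rev(ts$postorder_nodes)) {
    kids <- ts$children[[v]]
    if (is.null(kids)) next
    sv <- assign[v]
    for (ch in kids) {
      keep <- cost[ch, sv + 1L]
      flip <- cost[ch, (1L - sv) + 1L] + 1
      assign[ch] <- if (keep <= flip) sv else 1L - sv
    }
  }
  list(count = min(rootcost), assign = assign)
}

# Dollo: one gain allowed; minimise total events (the gain plus losses).
# DP2[v]: 0 if the subtree of v can be entirely absent (no constrained
# present tip below), else Inf. DP1[v]: min losses below v given v present.
dollo_one <- function(ts, states) {
  INF <- 1e9
  dp_absent <- numeric(ts$n_node)
  dp_present <- numeric(ts$n_node)
  for (i in seq_len(ts$n_tip)) {
    s <- states[i]
    dp_absent[i] <- if (!is.na(s) && s == 1L) INF else 0
    dp_present[i] <- if (!is.na(s) && s == 0L) INF else 0
  }
  choice <- matrix(0L, ts$n_node, max(lengths(ts$children), 1L))
  for (v in ts$postorder_nodes) {
    kids <- ts$children[[v]]
    if (is.null(kids)) next
    dp_absent[v] <- sum(dp_absent[kids])
    tot <- 0
    for (j in seq_along(kids)) {
      ch <- kids[j]
      keep <- dp_present[ch]
      lose <- 1 + dp_absent[ch]
      if (keep <= lose) {
        tot <- tot + keep
        choice[v, j] <- 1L
      } else {
        tot <- tot + lose
        choice[v, j] <- 0L
      }
    }
    dp_present[v] <- min(tot, INF)
  }
  # no gain at all (character absent everywhere it can be)
  best_cost <- dp_absent[ts$root]
  best_gain <- NA_integer_
  # gain on the edge above v (v = root: gain on the root stem)
  for (v in seq_len(ts$n_node)) {
    out_ok <- TRUE  # all present tips must be inside subtree(v)
    # feasibility is equivalent to: dp at root with v's subtree removed is 0;
    # simpler: cost = 1 + dp_present[v] + (absence feasible outside v)
    cost <- 1 + dp_present[v] + outside_absent_cost(ts, v, dp_absent)
    if (cost < best_cost) {
      best_cost <- cost
      best_gain <- v
    }
  }
  assign <- integer(ts$n_node)  # all absent by default
  if (!is.na(best_gain)) {
    # mark present along subtree of best_gain following loss choices
    stack <- best_gain
    assign[best_gain] <- 1L
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      kids <- ts$children[[v]]
      if (is.null(kids)) next
      for (j in seq_along(kids)) {
        if (choice[v, j] == 1L) {
          assign[kids[j]] <- 1L
          stack <- c(stack, kids[j])
        }
      }
    }
  }
  list(count = if (best_cost >= 1e8) NA_real_ else best_cost,
       assign = assign, gain_node = best_gain)
}

# cost of keeping everything outside subtree(v) absent: 0 or Inf
outside_absent_cost <- function(ts, v, dp_absent) {
  # tips outside subtree(v) that are constrained present make it infeasible
  inside <- logical(ts$n_node)
  inside[v] <- TRUE
  for (u in rev(ts$postorder_nodes)) {  # preorder
    kids <- ts$children[[u]]
    if (is.null(kids) || !inside[u]) next
    inside[kids] <- TRUE
  }
  tips_out <- which(!inside[seq_len(ts$n_tip)])
  if (any(dp_absent[tips_out] > 0)) 1e9 else 0
}

#' Superpose intron characters onto a phylogeny by parsimony
#'
#' For every character, computes the minimum number of state changes
#' (`fitch`: unordered binary parsimony, unknowns free) or the minimum
#' number of events given at most a single gain (`dollo`), together with a
#' branch-level gain/loss labelling achieving the minimum.
#'
#' @param tree `phylo` tree whose tips cover the matrix taxa; tips without
#'   data are treated as unknown
#' @param matrix a [character_matrix()]
#' @param mode `"fitch"` (default: the data show both gains and losses) or
#'   `"dollo"` (single-origin hypothesis)
#' @return object of class `event_reconstruction`: list with `counts`
#'   (named numeric, per character), `events` (data.frame: `character`,
#'   `parent`, `child`, `child_label`, `type`), `mode`, `tree`
#' @export
superpose <- function(tree, matrix, mode = c("fitch", "dollo")) {
  mode <- match.arg(mode)
  check_matrix_tree(tree, matrix)
  ts <- tree_structure(tree)
  tips <- ts$tree$tip.label
  counts <- setNames(numeric(ncol(matrix)), colnames(matrix))
  ev <- list()
  for (j in seq_len(ncol(matrix))) {
    states <- matrix[match(tips, rownames(matrix)), j]
    res <- if (mode == "fitch") fitch_one(ts, states) else dollo_one(ts, states)
    counts[j] <- res$count
    # events: edges where child state differs from parent state
    a <- res$assign
    for (k in seq_len(nrow(ts$tree$edge))) {
      p <- ts$tree$edge[k, 1L]
      ch <- ts$tree$edge[k, 2L]
      if (a[p] != a[ch]) {
        ev[[length(ev) + 1L]] <- data.frame(
          character = colnames(matrix)[j], parent = p, child = ch,
          child_label = if (ch <= ts$n_tip) tips[ch] else paste0("node_", ch),
          type = if (a[ch] == 1L) "gain" else "loss",
          stringsAsFactors = FALSE)
      }
    }
    if (mode == "dollo" && !is.na(res$gain_node) &&
        res$gain_node == ts$root && a[ts$root] == 1L) {
      ev[[length(ev) + 1L]] <- data.frame(
        character = colnames(matrix)[j], parent = NA_integer_, child = ts$root,
        child_label = "root", type = "gain", stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(character = character(), parent = integer(), child = integer(),
               child_label = character(), type = character())
  structure(list(counts = counts, events = events, mode = mode,
                 tree = ts$tree),
            class = "event_reconstruction")
}

#' @export
print.event_reconstruction <- function(x, ...) {
  cat(sprintf("<event_reconstruction> %s parsimony, %d characters, %d events total\n",
              x$mode, length(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Score characters as clade-diagnostic
#'
#' Each character is scored per clade (unknowns ignored):
#' `diagnostic` - state uniform inside the clade and its complement outside;
#' `shared_not_exclusive` - uniform inside but the same state also occurs
#' outside (alongside the other); `non_diagnostic` otherwise (including
#' constant characters).
#'
#' @param matrix a [character_matrix()]
#' @param clades named list: clade name -> character vector of taxa
#' @return data.frame: `character`, `clade`, `status`, `inside_state`;
#'   deterministic order (character, then clade)
#' @export
diagnostic_characters <- function(matrix, clades) {
  stopifnot(is.list(clades), length(clades) >= 1L, !is.null(names(clades)))
  for (nm in names(clades)) {
    if (!length(clades[[nm]])) stop("empty clade: ", nm)
    bad <- setdiff(clades[[nm]], rownames(matrix))
    if (length(bad)) stop("clade ", nm, " has taxa absent from matrix: ",
                          paste(bad, collapse = ", "))
  }
  out <- list()
  for (j in colnames(matrix)) {
    for (nm in names(clades)) {
      inside <- matrix[clades[[nm]], j]
      outside <- matrix[setdiff(rownames(matrix), clades[[nm]]), j]
      inside <- inside[!is.na(inside)]
      outside <- outside[!is.na(outside)]
      status <- "non_diagnostic"
      in_state <- NA_integer_
      if (length(inside) && length(unique(inside)) == 1L) {
        in_state <- inside[1L]
        if (!length(outside)) {
          status <- "non_diagnostic"
        } else if (!any(outside == in_state)) {
          status <- "diagnostic"
        } else if (any(outside != in_state)) {
          status <- "shared_not_exclusive"
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        character = j, clade = nm, status = status, inside_state = in_state,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$character, res$clade), ]
}

#' Classify catalytic-domain sequences by nearest labelled reference
#'
#' Assigns each query protein the catalytic-domain type (e.g. A/B/C) of its
#' nearest labelled reference by normalised local alignment score
#' (BLOSUM62; the score of a reference against itself is 1). Queries whose
#' best normalised score falls below the threshold stay unassigned. This is
#' a reference-based classifier, not a phylogenetic placement.
#'
#' @param seqs query proteins (`AAStringSet` or named character vector)
#' @param references labelled reference proteins (`AAStringSet` or named
#'   character vector)
#' @param labels character vector of type labels, one per reference
#' @param threshold minimum normalised score (default 0.4)
#' @return data.frame: `id`, `label` (`"unassigned"` below threshold),
#'   `score` between 0 and 1, `nearest_ref`
#' @export
classify_type <- function(seqs, references, labels, threshold = 0.4) {
  to_chr <- function(x) {
    if (inherits(x, "XStringSet")) setNames(as.character(x), names(x)) else x
  }
  seqs <- to_chr(seqs)
  references <- to_chr(references)
  if (!length(references)) stop("empty reference set")
  stopifnot(length(labels) == length(references))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  if (is.null(names(references))) names(references) <- paste0("ref_", seq_along(references))
  sm <- get_scoring()$submat
  align_score <- function(a, b) {
    Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                  substitutionMatrix = sm, gapOpening = 10,
                                  gapExtension = 0.5, type = "local",
                                  scoreOnly = TRUE)
  }
  out <- lapply(names(seqs), function(id) {
    selfsc <- align_score(seqs[[id]], seqs[[id]])
    scs <- vapply(references, function(r) align_score(seqs[[id]], r), numeric(1))
    best <- which.max(scs)
    score <- max(0, min(1, scs[best] / selfsc))
    data.frame(id = id,
               label = if (score >= threshold) labels[best] else "unassigned",
               score = score, nearest_ref = names(references)[best],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
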