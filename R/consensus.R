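# Consensus methods on embryo-rooted trees. All four methods work on
# clades (rooted tip sets), not unrooted splits: the ontogram reading of a
# node -- "every specimen above here is at least this mature" -- is rooted.

.check_tree_set <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees[-1]) {
    if (!identical(sort(tr$tip.label), tips))
      stop("trees have different tip sets")
  }
  trees
}

# list of clades (character vectors of tip labels) of a rooted tree,
# including the all-tips clade
.tree_clades <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], factor(tr$edge[, 1],
                                     levels = seq_len(ntip + tr$Nnode)))
  below <- vector("list", ntip + tr$Nnode)
  for (v in seq_len(ntip)) below[[v]] <- tr$tip.label[v]
  for (v in .node_order(tr$edge, ntip + 1L)) {
    below[[v]] <- sort(unlist(below[kids[[v]]], use.names = FALSE))
  }
  below[ntip + seq_len(tr$Nnode)]
}

.clade_key <- function(clade) paste(clade, collapse = "\x1f")

# count clades over a tree set -> named count vector + decoded sets
.clade_counts <- function(trees) {
  all <- unlist(lapply(trees, function(tr)
    unique(vapply(.tree_clades(tr), .clade_key, ""))))
  tab <- table(all)
  sets <- strsplit(names(tab), "\x1f", fixed = TRUE)
  list(count = as.integer(tab), sets = sets, key = names(tab))
}

# build a rooted (possibly multifurcating) phylo from a nested clade list
.clades_to_phylo <- function(clades, tips, labels = NULL) {
  keys <- vapply(clades, .clade_key, "")
  keep <- !duplicated(keys)
  clades <- clades[keep]
  if (!is.null(labels)) labels <- labels[keep]
  sizes <- lengths(clades)
  ord <- order(-sizes)
  clades <- clades[ord]
  if (!is.null(labels)) labels <- labels[ord]
  if (!length(clades) || length(clades[[1]]) != length(tips)) {
    clades <- c(list(sort(tips)), clades)
    if (!is.null(labels)) labels <- c(NA, labels)
  }
  build <- function(i) {
    inside <- clades[[i]]
    child_idx <- c()
    covered <- character()
    j <- i
    while (j < length(clades)) {
      j <- j + 1
      cl <- clades[[j]]
      if (all(cl %in% inside) && !any(cl %in% covered)) {
        child_idx <- c(child_idx, j)
        covered <- c(covered, cl)
      }
    }
    parts <- c(lapply(child_idx, build),
               as.list(setdiff(inside, covered)))
    lab <- if (!is.null(labels) && !is.na(labels[i])) labels[i] else ""
    paste0("(", paste(unlist(parts), collapse = ","), ")", lab)
  }
  txt <- paste0(build(1), ";")
  ape::read.tree(text = txt)
}

#' Strict consensus
#'
#' The tree containing exactly the clades present in every input tree.
#'
#' @param trees a list/`multiPhylo` of rooted trees over identical tips.
#' @return a rooted `phylo`, generally multifurcating.
#' @export
strict_consensus <- function(trees) {
  trees <- .check_tree_set(trees)
  cc <- .clade_counts(trees)
  keep <- cc$count == length(trees)
  .clades_to_phylo(cc$sets[keep], trees[[1]]$tip.label)
}

#' Semi-strict (combinable-components) consensus
#'
#' Retains every clade that occurs in at least one input tree and is
#' contradicted by none, i.e. is compatible with every input tree.
#'
#' @inheritParams strict_consensus
#' @return a rooted `phylo`.
#' @export
semistrict_consensus <- function(trees) {
  trees <- .check_tree_set(trees)
  cc <- .clade_counts(trees)
  per_tree <- lapply(trees, function(tr)
    lapply(.tree_clades(tr), identity))
  compat <- vapply(seq_along(cc$sets), function(i) {
    x <- cc$sets[[i]]
    all(vapply(per_tree, function(cls)
      all(vapply(cls, function(y) {
        ov <- sum(x %in% y)
        ov == 0 || ov == length(x) || ov == length(y)
      }, TRUE)), TRUE))
  }, TRUE)
  .clades_to_phylo(cc$sets[compat], trees[[1]]$tip.label)
}

#' Adams consensus
#'
#' Standard recursive construction: tips are partitioned by the product
#' (common refinement) of the root partitions of all input trees; each block
#' becomes a subtree, built recursively from the input trees restricted to
#' that block. Rogue tips slide towards the deepest position common to all
#' inputs rather than collapsing whole regions.
#'
#' @inheritParams strict_consensus
#' @return a rooted `phylo`.
#' @export
adams_consensus <- function(trees) {
  trees <- .check_tree_set(trees)
  rec <- function(trs) {
    tips <- trs[[1]]$tip.label
    if (length(tips) == 1) return(tips)
    if (length(tips) == 2) return(paste0("(", tips[1], ",", tips[2], ")"))
    # block id per tip: which root-child subtree it belongs to, per tree
    blk <- vapply(trs, function(tr) {
      ntip <- length(tr$tip.label)
      root_kids <- tr$edge[tr$edge[, 1] == ntip + 1L, 2]
      grp <- integer(ntip)
      names(grp) <- tr$tip.label
      for (i in seq_along(root_kids)) {
        v <- root_kids[i]
        members <- if (v <= ntip) tr$tip.label[v] else
          ape::extract.clade(tr, v)$tip.label
        grp[members] <- i
      }
      grp[tips]
    }, integer(length(tips)))
    key <- apply(matrix(blk, nrow = length(tips)), 1, paste, collapse = ".")
    blocks <- split(tips, key)
    parts <- lapply(blocks, function(b) {
      if (length(b) == 1) return(b)
      rec(lapply(trs, ape::keep.tip, tip = b))
    })
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(trees), ";"))
}

#' Majority-rule consensus with clade frequencies
#'
#' Builds the tree of clades occurring in more than `threshold_pct` percent
#' of the input trees (strictly greater, so incompatible 50/50 pairs cannot
#' both enter at the default threshold), annotates each retained node with
#' its percentage, and returns the full clade frequency table.
#'
#' @inheritParams strict_consensus
#' @param threshold_pct retention threshold, >= 50.
#' @return a list with `tree` (node labels = rounded percentages) and
#'   `frequencies`, a data frame of clade, count and percentage over the
#'   tree set (all clades observed, not only retained ones).
#' @export
majority_rule <- function(trees, threshold_pct = 50) {
  if (threshold_pct < 50)
    stop("threshold below 50% does not guarantee compatible clades")
  trees <- .check_tree_set(trees)
  cc <- .clade_counts(trees)
  pct <- 100 * cc$count / length(trees)
  keep <- pct > threshold_pct
  tree <- .clades_to_phylo(cc$sets[keep], trees[[1]]$tip.label,
                           labels = sprintf("%.4g", pct[keep]))
  freq <- data.frame(
    clade = vapply(cc$sets, paste, "", collapse = ","),
    size = lengths(cc$sets),
    count = cc$count,
    pct = pct, stringsAsFactors = FALSE)
  freq <- freq[order(-freq$size, -freq$pct), ]
  rownames(freq) <- NULL
  list(tree = tree, frequencies = freq)
}

#' Mean grouping frequency of a tree set
#'
#' Average majority-rule percentage over the non-trivial clades of the
#' majority-rule consensus: how consistently, on average, the groupings of
#' the consensus are present across the optimal trees.
#'
#' @inheritParams strict_consensus
#' @param threshold_pct majority threshold for the summarized tree.
#' @return mean percentage (scalar).
#' @export
mean_grouping_frequency <- function(trees, threshold_pct = 50) {
  trees <- .check_tree_set(trees)
  mr <- majority_rule(trees, threshold_pct)
  freq <- mr$frequencies
  ntip <- length(trees[[1]]$tip.label)
  nontrivial <- freq$size < ntip & freq$pct > threshold_pct
  mean(freq$pct[nontrivial])
}
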