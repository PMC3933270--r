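# Independent brute-force oracles and small fixture builders. The oracles
# never share code with the package's scoring path: they enumerate ancestral
# state assignments exhaustively.

# minimum number of state changes on `tree` by exhaustive enumeration of all
# internal-node (and missing-tip) assignments; cost_fn defaults to unordered
# (0/1) changes, pass function(a, b) abs(a - b) for ordered characters
oracle_length <- function(tree, m, cost_fn = function(a, b) a != b) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  cells <- m$cells[tree$tip.label, , drop = FALSE]
  nst <- m$characters$n_states
  total <- 0
  for (j in seq_len(ncol(cells))) {
    k <- nst[j]
    free <- c(which(is.na(cells[, j])), ntip + seq_len(tree$Nnode))
    assign0 <- integer(ntip + tree$Nnode)
    assign0[seq_len(ntip)] <- ifelse(is.na(cells[, j]), 0L, cells[, j])
    grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), length(free))))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      a <- assign0
      a[free] <- grid[r, ]
      best <- min(best, sum(cost_fn(a[edge[, 1]], a[edge[, 2]])))
    }
    total <- total + best
  }
  total
}

# random small character matrix (embryo optional)
random_matrix <- function(n = 6, k = 5, max_state = 2, na_frac = 0.1,
                          seed = 1, embryo = TRUE) {
  set.seed(seed)
  cells <- matrix(sample(0:max_state, n * k, TRUE), n, k,
                  dimnames = list(paste0("t", seq_len(n)), NULL))
  if (na_frac > 0) cells[sample(n * k, round(na_frac * n * k))] <- NA
  m <- character_matrix(cells)
  if (embryo) m <- add_hypothetical_embryo(m)
  m
}

# perfectly nested staircase: specimen i has acquired the first i characters
staircase_matrix <- function(n = 6, embryo = TRUE) {
  cells <- outer(seq_len(n), seq_len(n), ">=") * 1L
  dimnames(cells) <- list(paste0("t", seq_len(n)), NULL)
  m <- character_matrix(cells)
  if (embryo) m <- add_hypothetical_embryo(m)
  m
}

# embryo-rooted pectinate tree over the given tips, least mature first
pectinate_tree <- function(tips, embryo = "EMBRYO") {
  nest <- paste0(rev(tips)[1])
  for (t in rev(tips)[-1]) nest <- paste0("(", t, ",", nest, ")")
  ape::read.tree(text = paste0("(", embryo, ",", nest, ");"))
}

# random embryo-rooted binary tree over matrix specimens
random_tree <- function(m, seed = 1) {
  set.seed(seed)
  tips <- rownames(m$cells)
  tr <- ape::rtree(length(tips), tip.label = sample(tips))
  tr$edge.length <- NULL
  anchor <- if (!is.null(m$embryo)) m$embryo else tips[1]
  ape::root(ape::unroot(tr), outgroup = anchor, resolve.root = TRUE)
}

# embryo-rooted clade sets of a tree in any rooted/unrooted representation:
# each stored bipartition side is normalized to the half not containing the
# embryo, so arbitrary internal rootings agree
clade_sets <- function(tr, drop = c("EMBRYO", "ADULT")) {
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- lapply(pp, function(i) labs[i])
  out <- lapply(out, function(s)
    if ("EMBRYO" %in% s) setdiff(labs, s) else s)
  if (!is.null(drop)) out <- lapply(out, setdiff, y = drop)
  out <- lapply(out, sort)
  unique(out[lengths(out) >= 2])
}

clade_keys <- function(tr, ...) {
  sort(vapply(clade_sets(tr, ...), paste, "", collapse = ","))
}
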