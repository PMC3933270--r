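# Core parsimony scoring: equal-weight, unordered (Fitch) characters with
# missing data as full ambiguity. Binary nodes use the two-set Fitch rule;
# polytomies use Hartigan's minimum-mutation count rule, which is exact for
# hard multifurcations. State sets are bitmasks (<= 10 states), vectorized
# across characters, so one tree is scored in a handful of node-wise ops.

.bits <- bitwShiftL(1L, 0:9)

# tip-state bitmasks, rows = specimens, cols = characters; missing = all
# states the character declares
.state_masks <- function(m) {
  full <- bitwShiftL(1L, m$characters$n_states) - 1L
  cells <- m$cells
  masks <- bitwShiftL(1L, ifelse(is.na(cells), 0L, cells))
  masks[is.na(cells)] <- 0L
  masks <- masks + rep(full, each = nrow(cells)) * is.na(cells)
  dimnames(masks) <- dimnames(cells)
  masks
}

# processing order for internal nodes: children strictly before parents
.node_order <- function(edge, root) {
  maxn <- max(edge)
  par <- integer(maxn)
  par[edge[, 2]] <- edge[, 1]
  depth <- rep(NA_integer_, maxn)
  depth[root] <- 0L
  internal <- unique(edge[, 1])
  todo <- setdiff(internal, root)
  while (length(todo)) {
    ready <- todo[!is.na(depth[par[todo]])]
    if (!length(ready)) stop("edge matrix is not a rooted tree")
    depth[ready] <- depth[par[ready]] + 1L
    todo <- setdiff(todo, ready)
  }
  internal[order(depth[internal], decreasing = TRUE)]
}

# minimum-mutation score of a rooted tree given tip masks indexed by node id.
# Returns per-character step counts (and downpass state sets if sets = TRUE).
.pscore <- function(edge, root, tipmask, n_tips_total, weights = NULL,
                    per_char = FALSE, sets = FALSE) {
  nk <- ncol(tipmask)
  maxn <- max(edge)
  S <- matrix(0L, maxn, nk)
  S[seq_len(min(n_tips_total, maxn)), ] <-
    tipmask[seq_len(min(n_tips_total, maxn)), ]
  kids <- split(edge[, 2], factor(edge[, 1], levels = seq_len(maxn)))
  ord <- .node_order(edge, root)
  steps <- numeric(nk)
  for (v in ord) {
    ch <- kids[[v]]
    if (length(ch) == 2L) {
      A <- S[ch[1L], ]
      B <- S[ch[2L], ]
      I <- bitwAnd(A, B)
      z <- I == 0L
      if (any(z)) {
        steps[z] <- steps[z] + 1
        I[z] <- bitwOr(A, B)[z]
      }
      S[v, ] <- I
    } else if (length(ch) == 1L) {
      S[v, ] <- S[ch, ]
    } else {
      cnt <- matrix(0L, 10L, nk)
      for (c in ch)
        cnt <- cnt + (matrix(bitwAnd(rep(S[c, ], each = 10L), .bits),
                             10L, nk) > 0L)
      kmax <- apply(cnt, 2, max)
      H <- colSums(.bits * (cnt == rep(kmax, each = 10L)))
      steps <- steps + length(ch) - kmax
      S[v, ] <- as.integer(H)
    }
  }
  if (sets) return(list(steps = steps, sets = S))
  if (per_char) return(steps)
  if (is.null(weights)) sum(steps) else sum(steps * weights)
}

# score an ape phylo against a character matrix (weights: per-character
# resampling weights, used by the bootstrap)
.pscore_phylo <- function(tree, m, weights = NULL, per_char = FALSE) {
  masks <- .state_masks(m)
  idx <- match(tree$tip.label, rownames(masks))
  if (anyNA(idx))
    stop("tree tips not in matrix: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  ntip <- length(tree$tip.label)
  .pscore(tree$edge, ntip + 1L, masks[idx, , drop = FALSE], ntip,
          weights = weights, per_char = per_char)
}

#' Parsimony length of a tree
#'
#' Sum over characters of the minimum number of unordered state changes
#' required on the given topology (equal weights). Missing cells contribute
#' full ambiguity and never force changes. Multifurcating nodes are scored
#' as hard polytomies by the generalized minimum-mutation rule, so consensus
#' trees can be scored directly. The length is invariant to where the tree
#' is rooted along the embryo edge and to child order.
#'
#' @param tree an `ape::phylo` whose tips exactly match the matrix specimens.
#' @param m a `character_matrix`.
#' @param per_character if `TRUE`, return the per-character step vector.
#' @return integer total steps, or a per-character integer vector.
#' @export
tree_length <- function(tree, m, per_character = FALSE) {
  if (!setequal(tree$tip.label, rownames(m$cells)))
    stop("tree tips and matrix specimens differ")
  if (length(tree$tip.label) != nrow(m$cells))
    stop("tree tips and matrix specimens differ in number")
  s <- .pscore_phylo(tree, m, per_char = TRUE)
  if (per_character) as.integer(s) else as.integer(sum(s))
}

#' Theoretical minimum steps per character
#'
#' For an unordered character the minimum number of changes on any tree is
#' the number of distinct observed (non-missing) states minus one, floored
#' at zero. This is the numerator of the consistency index.
#'
#' @param m a `character_matrix`.
#' @return integer vector, one entry per character.
#' @export
min_steps <- function(m) {
  apply(m$cells, 2, function(v) max(0L, length(unique(v[!is.na(v)])) - 1L))
}

# parsimony-uninformative characters: at most one observed state is shared
# by two or more specimens, so the minimum is realized on every topology
.uninformative <- function(m) {
  apply(m$cells, 2, function(v) {
    tab <- table(v[!is.na(v)])
    sum(tab >= 2L) <= 1L
  })
}
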