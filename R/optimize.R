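# Ancestral-state optimization under ACCTRAN and DELTRAN.
#
# Per character, a unit-cost dynamic programme (Sankoff on unordered states,
# valid on multifurcations) yields for every node the minimal subtree cost
# of each state. States are then fixed in preorder: given the parent's fixed
# state p, a node may take any state s minimizing cost(subtree | s) + [s != p].
# When both a change and no-change resolution tie, ACCTRAN takes the change
# (pulling transformations rootward, favouring reversal over convergence)
# and DELTRAN keeps the parent state (pushing transformations tipward,
# favouring convergence). Residual ties resolve to the lowest state code and
# are flagged. Both flavours realize exactly tree_length() changes.

#' Optimize ancestral states on an embryo-rooted tree
#'
#' @param tree rooted `ape::phylo` (binary or multifurcating); tips must
#'   match the matrix specimens.
#' @param m a `character_matrix`.
#' @param flavor `"ACCTRAN"` or `"DELTRAN"`.
#' @return an `optimization_result`: `states` ((tips+nodes) x characters
#'   matrix of assigned states), `changes` (data frame: character, node at
#'   the child end of the branch carrying the change, from/to states,
#'   ambiguity flag), `total_changes`, `flavor`.
#' @export
optimize_states <- function(tree, m, flavor = c("ACCTRAN", "DELTRAN")) {
  flavor <- match.arg(flavor)
  if (!setequal(tree$tip.label, rownames(m$cells)))
    stop("tree tips and matrix specimens differ")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nn)))
  ord <- .node_order(tree$edge, root)          # children before parents
  pre <- rev(ord)                              # parents before children
  cells <- m$cells[tree$tip.label, , drop = FALSE]
  nst <- m$characters$n_states
  nchar_ <- ncol(cells)
  states <- matrix(NA_integer_, nn, nchar_)
  ambiguous <- matrix(FALSE, nn, nchar_)
  changes <- vector("list", nchar_)
  for (j in seq_len(nchar_)) {
    k <- nst[j]
    cost <- matrix(0, nn, k)
    obs <- cells[, j]
    for (v in seq_len(ntip)) {
      if (!is.na(obs[v])) {
        cost[v, ] <- Inf
        cost[v, obs[v] + 1L] <- 0
      }
    }
    for (v in ord) {
      for (c in kids[[v]]) {
        base <- min(cost[c, ])
        cost[v, ] <- cost[v, ] + pmin(cost[c, ] , base + 1)
      }
    }
    fix <- integer(nn)
    amb <- logical(nn)
    rmin <- which(cost[root, ] == min(cost[root, ]))
    fix[root] <- rmin[1] - 1L
    amb[root] <- length(rmin) > 1L
    for (v in pre) {
      p_state <- fix[v]
      for (c in kids[[v]]) {
        tot <- cost[c, ] + as.numeric(seq_len(k) != p_state + 1L)
        cand <- which(tot == min(tot)) - 1L
        if (length(cand) == 1L) {
          fix[c] <- cand
        } else if (flavor == "DELTRAN" && p_state %in% cand) {
          fix[c] <- p_state
        } else if (flavor == "ACCTRAN" && any(cand != p_state)) {
          ch <- cand[cand != p_state]
          fix[c] <- ch[1]
          amb[c] <- length(ch) > 1L
        } else {
          fix[c] <- cand[1]
          amb[c] <- TRUE
        }
      }
    }
    states[, j] <- fix
    ambiguous[, j] <- amb
    ce <- tree$edge[fix[tree$edge[, 1]] != fix[tree$edge[, 2]], ,
                    drop = FALSE]
    if (nrow(ce)) {
      changes[[j]] <- data.frame(
        character = m$characters$id[j],
        label = m$characters$label[j],
        node = ce[, 2],
        from = fix[ce[, 1]],
        to = fix[ce[, 2]],
        ambiguous = amb[ce[, 2]],
        stringsAsFactors = FALSE)
    }
  }
  changes <- do.call(rbind, changes[!vapply(changes, is.null, TRUE)])
  if (is.null(changes))
    changes <- data.frame(character = character(), label = character(),
                          node = integer(), from = integer(),
                          to = integer(), ambiguous = logical())
  rownames(changes) <- NULL
  structure(list(flavor = flavor, states = states, changes = changes,
                 total_changes = nrow(changes), tree = tree),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(x$flavor, " optimization: ", x$total_changes, " changes on ",
      nrow(x$tree$edge), " branches\n", sep = "")
  invisible(x)
}

#' Per-node synontomorphy table
#'
#' Lists, for every internal node, the character changes placed on the
#' branch leading to it under ACCTRAN and under DELTRAN, and their
#' intersection: the unambiguous synontomorphies -- growth features that
#' develop exactly once on the ontogram at the same position under both
#' optimization flavours, and are inherited by every more mature specimen.
#'
#' @param tree rooted `ape::phylo`.
#' @param m a `character_matrix`.
#' @return a `synontomorphy_table`: data frame with columns `node`, `clade`
#'   (tip labels above the branch), `character`, `label`, `from`, `to`,
#'   `flavor` (`ACCTRAN`/`DELTRAN`/`both`). Rows with flavor `"both"` are
#'   the unambiguous set. Internal nodes with no unambiguous changes are
#'   retained in the `nodes` attribute for reporting.
#' @export
synontomorphies <- function(tree, m) {
  acc <- optimize_states(tree, m, "ACCTRAN")
  del <- optimize_states(tree, m, "DELTRAN")
  ntip <- length(tree$tip.label)
  key <- function(d) paste(d$node, d$character, d$from, d$to)
  ka <- key(acc$changes); kd <- key(del$changes)
  both <- ka %in% kd
  addfl <- function(d, fl) { d$flavor <- rep(fl, nrow(d)); d }
  tab <- rbind(
    addfl(acc$changes[both, , drop = FALSE], "both"),
    addfl(acc$changes[!both, , drop = FALSE], "ACCTRAN"),
    addfl(del$changes[!(kd %in% ka), , drop = FALSE], "DELTRAN"))
  tab$ambiguous <- NULL
  # only branches leading to internal nodes define growth stages
  tab <- tab[tab$node > ntip, , drop = FALSE]
  clades <- .tree_clades(tree)
  tab$clade <- vapply(tab$node, function(v)
    paste(setdiff(clades[[v - ntip]], c(m$embryo, m$adult)),
          collapse = ","), "")
  tab <- tab[order(tab$node, tab$character), ]
  rownames(tab) <- NULL
  structure(tab, class = c("synontomorphy_table", "data.frame"),
            nodes = sort(unique(tree$edge[tree$edge[, 2] > ntip, 2])),
            acctran = acc, deltran = del)
}
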