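# Tree search under equal-weight unordered parsimony.
#
# Internally trees are binary and rooted on the edge leading to a fixed
# "anchor" tip (the hypothetical embryo when present): the root always has
# exactly two children, the first being the anchor. This is score-equivalent
# to the unrooted tree, and forbidding insertions on the root->anchor edge
# makes stepwise enumeration visit every unrooted topology exactly once.
# Node ids: tips keep their index in the full taxon vector; internal nodes
# are allocated from n_taxa + 1 upward.

.start_edge <- function(anchor, t2, t3, n) {
  root <- n + 1L
  v <- n + 2L
  matrix(c(root, anchor, root, v, v, t2, v, t3), ncol = 2, byrow = TRUE)
}

# insert `tip` on edge row `eidx`; `newnode` is the id for the new internal
.insert_tip_edge <- function(edge, eidx, tip, newnode) {
  p <- edge[eidx, 1]
  c <- edge[eidx, 2]
  edge[eidx, ] <- c(p, newnode)
  rbind(edge, c(newnode, c), c(newnode, tip))
}

# unrooted-topology signature: nontrivial splits normalized to the side not
# containing the anchor tip, so re-rootings of one topology collide
.tree_signature <- function(edge, root, n, anchor) {
  maxn <- max(edge)
  kids <- split(edge[, 2], factor(edge[, 1], levels = seq_len(maxn)))
  below <- vector("list", maxn)
  for (v in seq_len(min(n, maxn))) below[[v]] <- v
  for (v in .node_order(edge, root)) {
    below[[v]] <- sort(unlist(below[kids[[v]]], use.names = FALSE))
  }
  present <- sort(edge[edge[, 2] <= n, 2])
  splits <- lapply(unique(edge[, 1]), function(v) {
    s <- below[[v]]
    if (anchor %in% s) s <- setdiff(present, s)
    s
  })
  splits <- splits[lengths(splits) > 1 & lengths(splits) < length(present) - 1]
  paste(sort(unique(vapply(splits, paste, "", collapse = ","))),
        collapse = ";")
}

# re-root an edge-matrix tree on the edge leading to the anchor tip: the new
# root has exactly two children, the anchor first. Accepts any orientation
# and any old root degree; a degree-2 old root is suppressed.
.anchor_root <- function(edge, n, anchor) {
  root_old <- edge[!edge[, 1] %in% edge[, 2], 1][1]
  kids_root <- edge[edge[, 1] == root_old, 2]
  if (length(kids_root) == 2 && kids_root[1] == anchor) return(edge)
  und <- edge
  if (length(kids_root) == 2) {
    und <- und[und[, 1] != root_old, , drop = FALSE]
    und <- rbind(und, kids_root)
  }
  i <- which(und[, 1] == anchor | und[, 2] == anchor)
  p <- setdiff(und[i, ], anchor)
  und <- und[-i, , drop = FALSE]
  newroot <- max(edge) + 1L
  und <- rbind(und, c(newroot, anchor), c(newroot, p))
  # orient all edges away from the new root (BFS)
  both <- rbind(und, und[, 2:1])
  out <- matrix(0L, nrow(und), 2)
  visited <- newroot
  frontier <- newroot
  k <- 0L
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- setdiff(both[both[, 1] == v, 2], visited)
      nb <- if (v == newroot) c(anchor, setdiff(nb, anchor)) else nb
      for (w in nb) {
        k <- k + 1L
        out[k, ] <- c(v, w)
      }
      visited <- c(visited, nb)
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  out
}

# convert internal edge representation to an ape phylo rooted at the anchor
.edge_to_phylo <- function(edge, labels, present = NULL) {
  if (is.null(present)) present <- sort(unique(edge[, 2][edge[, 2] <=
                                                           length(labels)]))
  ntip <- length(present)
  tipmap <- integer(length(labels))
  tipmap[present] <- seq_len(ntip)
  internal <- unique(edge[, 1])
  intmap <- integer(max(edge))
  intmap[internal] <- ntip + seq_along(internal)
  new_edge <- edge
  is_tip <- edge[, 2] <= length(labels)
  new_edge[, 1] <- intmap[edge[, 1]]
  new_edge[is_tip, 2] <- tipmap[edge[is_tip, 2]]
  new_edge[!is_tip, 2] <- intmap[edge[!is_tip, 2]]
  # ape wants the root numbered ntip + 1 (internal[1] is the root by
  # construction of all builders in this file) and edges in cladewise
  # (preorder, depth-first) order
  kids <- split(seq_len(nrow(new_edge)),
                factor(new_edge[, 1], levels = seq_len(max(new_edge))))
  ord <- integer(nrow(new_edge))
  stack <- rev(kids[[ntip + 1L]])
  k <- 0L
  while (length(stack)) {
    e <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- e
    child <- new_edge[e, 2]
    if (child > ntip) stack <- c(stack, rev(kids[[child]]))
  }
  structure(list(edge = new_edge[ord, , drop = FALSE],
                 tip.label = labels[present],
                 Nnode = length(internal)),
            class = "phylo", order = "cladewise")
}

.search_result <- function(best_length, trees, cap_hit, replicates_run,
                           seed, method, extra = list()) {
  structure(c(list(best_length = as.integer(best_length), trees = trees,
                   cap_hit = cap_hit, replicates_run = replicates_run,
                   seed = seed, method = method), extra),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Parsimony search (", x$method, "): best length ", x$best_length,
      ", ", length(x$trees), " tree(s)",
      if (x$cap_hit) " [tree cap reached]", "\n", sep = "")
  invisible(x)
}

# shared pre-flight: returns anchor-first taxon bookkeeping
.search_setup <- function(m) {
  labels <- rownames(m$cells)
  masks <- .state_masks(m)
  anchor <- if (!is.null(m$embryo)) match(m$embryo, labels) else 1L
  list(labels = labels, masks = masks, anchor = anchor, n = length(labels))
}

.as_multiphylo <- function(trees) {
  class(trees) <- "multiPhylo"
  trees
}

#' Heuristic parsimony search
#'
#' Random-addition starting trees polished by branch swapping (NNI or SPR)
#' to a local optimum, one replicate per random addition sequence. All
#' distinct equally optimal topologies NNI-connected to the optima found
#' are then collected up to `maxtrees` (first-found retention, with a
#' `cap_hit` flag mirroring a saved-tree limit). Fully seed-reproducible;
#' insertion ties during stepwise addition are broken by the first
#' candidate in a deterministic edge ordering.
#'
#' @param m a `character_matrix` with at least 4 specimens.
#' @param nreps number of random-addition replicates.
#' @param swap branch-swapping move set: `"spr"` (default) or `"nni"`.
#' @param maxtrees cap on stored optimal trees (>= 1).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param weights optional per-character weights (used by the bootstrap).
#' @return a `search_result`: best length, the optimal trees (embryo-rooted
#'   `multiPhylo`), `cap_hit`, `replicates_run`, `seed`, plus a per-replicate
#'   search log (start and final length).
#' @export
heuristic_search <- function(m, nreps = 10, swap = c("spr", "nni"),
                             maxtrees = 100000L, seed = NULL,
                             weights = NULL) {
  swap <- match.arg(swap)
  if (maxtrees < 1) stop("maxtrees must be >= 1")
  if (nrow(m$cells) < 4)
    stop("heuristic search needs at least 4 specimens")
  su <- .search_setup(m)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  score <- function(edge) .pscore(edge, su$n + 1L, su$masks, su$n,
                                  weights = weights)
  best <- Inf
  pool <- list()      # edge matrices at best length
  sigs <- character() # their signatures
  cap_hit <- FALSE
  log <- data.frame(replicate = integer(), start_length = numeric(),
                    final_length = numeric())
  others <- setdiff(seq_len(su$n), su$anchor)
  for (rep_i in seq_len(nreps)) {
    ord <- sample(others)
    edge <- .start_edge(su$anchor, ord[1], ord[2], su$n)
    nextnode <- su$n + 3L
    for (t in ord[-(1:2)]) {
      cand <- 2:nrow(edge)  # never the root->anchor edge (row 1)
      sc <- vapply(cand, function(e)
        score(.insert_tip_edge(edge, e, t, nextnode)), 0)
      edge <- .insert_tip_edge(edge, cand[which.min(sc)], t, nextnode)
      nextnode <- nextnode + 1L
    }
    start_len <- score(edge)
    len <- start_len
    repeat {
      nb <- .swap_neighbors(edge, su$n, swap)
      if (!length(nb)) break
      sc <- vapply(nb, score, 0)
      if (min(sc) < len) {
        len <- min(sc)
        edge <- nb[[which.min(sc)]]
      } else break
    }
    log <- rbind(log, data.frame(replicate = rep_i, start_length = start_len,
                                 final_length = len))
    if (len < best) {
      best <- len
      pool <- list(edge)
      sigs <- .tree_signature(edge, su$n + 1L, su$n, su$anchor)
    } else if (len == best) {
      sg <- .tree_signature(edge, su$n + 1L, su$n, su$anchor)
      if (!sg %in% sigs && length(pool) < maxtrees) {
        pool <- c(pool, list(edge))
        sigs <- c(sigs, sg)
      } else if (!sg %in% sigs) cap_hit <- TRUE
    }
  }
  # explore the plateau: collect equal-length NNI-connected MPTs (NNI moves
  # regardless of the climb move set; SPR sweeps are too costly here)
  queue <- seq_along(pool)
  while (length(queue)) {
    e0 <- pool[[queue[1]]]
    queue <- queue[-1]
    for (nb in .swap_neighbors(e0, su$n, "nni")) {
      sc <- score(nb)
      if (sc < best) { # plateau walk found an improvement: restart from it
        best <- sc
        pool <- list(nb)
        sigs <- .tree_signature(nb, su$n + 1L, su$n, su$anchor)
        queue <- 1L
        break
      }
      if (sc == best) {
        sg <- .tree_signature(nb, su$n + 1L, su$n, su$anchor)
        if (!sg %in% sigs) {
          if (length(pool) >= maxtrees) { cap_hit <- TRUE; next }
          pool <- c(pool, list(nb))
          sigs <- c(sigs, sg)
          queue <- c(queue, length(pool))
        }
      }
    }
  }
  trees <- .as_multiphylo(lapply(pool, function(e)
    .edge_to_phylo(.anchor_root(e, su$n, su$anchor), su$labels)))
  .search_result(best, trees, cap_hit, nreps, seed, "heuristic",
                 extra = list(log = log, swap = swap))
}

# all NNI (and optionally SPR) neighbors of a binary anchor-rooted tree,
# as edge matrices
.swap_neighbors <- function(edge, n, swap) {
  maxn <- max(edge)
  kids <- split(edge[, 2], factor(edge[, 1], levels = seq_len(maxn)))
  par <- integer(maxn)
  par[edge[, 2]] <- edge[, 1]
  root <- n + 1L
  out <- list()
  # NNI: for each internal (non-root) node c with parent p: swap c's sibling
  # with each child of c
  internal <- setdiff(unique(edge[, 1]), root)
  for (c in internal) {
    p <- par[c]
    sib <- setdiff(kids[[p]], c)
    g <- kids[[c]]
    for (gc in g) {
      e <- edge
      e[e[, 1] == p & e[, 2] == sib, 2] <- gc
      e[e[, 1] == c & e[, 2] == gc, 2] <- sib
      out <- c(out, list(e))
    }
  }
  if (swap == "spr") {
    rows <- seq_len(nrow(edge))
    for (i in rows) {
      pr <- .prune_at(edge, i, root)
      if (is.null(pr)) next
      for (j in seq_len(nrow(pr$edge))) {
        if (pr$edge[j, 1] == root && j == pr$anchor_row) next
        e2 <- pr$edge
        p2 <- pr$freed
        e2[j, ] <- c(pr$edge[j, 1], p2)
        e2 <- rbind(e2, c(p2, pr$edge[j, 2]), c(p2, edge[i, 2]),
                    pr$sub_edges)
        out <- c(out, list(e2))
      }
    }
  }
  out
}

# nodes in the subtree below (and including) node v
.subtree_nodes <- function(edge, v) {
  res <- v
  frontier <- v
  repeat {
    nxt <- edge[edge[, 1] %in% frontier, 2]
    if (!length(nxt)) break
    res <- c(res, nxt)
    frontier <- nxt
  }
  res
}

# remove edge row i (parent p -> child c, pruning c's subtree) and suppress
# the now-degree-two node p; returns NULL for prunes that would detach the
# anchor side. `freed` is the suppressed node id, reusable for regrafting.
.prune_at <- function(edge, i, root) {
  p <- edge[i, 1]
  c <- edge[i, 2]
  if (p == root) return(NULL)  # would detach at the root edge
  sub <- .subtree_nodes(edge, c)
  in_sub <- edge[, 2] %in% sub
  sub_edges <- edge[in_sub & edge[, 1] %in% sub, , drop = FALSE]
  keep <- edge[!in_sub, , drop = FALSE]
  sib_row <- which(keep[, 1] == p)
  par_row <- which(keep[, 2] == p)
  sib <- keep[sib_row, 2]
  keep[par_row, 2] <- sib
  keep <- keep[-sib_row, , drop = FALSE]
  list(edge = keep, freed = p, sub_edges = sub_edges,
       anchor_row = which(keep[, 1] == root)[1])
}

#' Branch-and-bound parsimony search
#'
#' Exact search returning provably all optimal trees: depth-first stepwise
#' insertion, pruning any partial tree whose length already reaches the
#' current bound. The initial bound defaults to a quick heuristic-search
#' result. A node-expansion budget guards against runaway instances; when
#' exhausted the search aborts with an error rather than returning a
#' silently incomplete answer.
#'
#' @param m a `character_matrix`.
#' @param initial_bound optional known upper bound on the best length.
#' @param node_budget maximum number of partial-tree expansions.
#' @param keep_suboptimal also retain all complete trees within this many
#'   steps of the optimum (used by Bremer decay).
#' @param maxtrees cap on stored trees.
#' @return a `search_result`; when `keep_suboptimal > 0` the extra field
#'   `suboptimal` holds a list of `list(length, tree)` for all trees with
#'   length <= best + `keep_suboptimal`.
#' @export
branch_and_bound <- function(m, initial_bound = NULL, node_budget = 2e6,
                             keep_suboptimal = 0L, maxtrees = 100000L) {
  su <- .search_setup(m)
  if (su$n < 2) stop("need at least 2 specimens")
  score <- function(edge) .pscore(edge, su$n + 1L, su$masks, su$n)
  if (is.null(initial_bound)) {
    initial_bound <- if (su$n >= 4) {
      heuristic_search(m, nreps = 1, swap = "nni", seed = 0L)$best_length
    } else Inf
  }
  env <- new.env()
  env$bound <- initial_bound
  env$trees <- list()   # list(length=, edge=)
  env$expansions <- 0L
  env$cap_hit <- FALSE
  slack <- as.integer(keep_suboptimal)
  others <- setdiff(seq_len(su$n), su$anchor)
  if (length(others) < 2) {
    edge <- matrix(c(su$n + 1L, su$anchor, su$n + 1L, others), ncol = 2,
                   byrow = TRUE)
    env$trees <- list(list(length = score(edge), edge = edge))
    env$bound <- env$trees[[1]]$length
  } else {
    recurse <- function(edge, nextnode, remaining) {
      env$expansions <- env$expansions + 1L
      if (env$expansions > node_budget)
        stop("branch-and-bound node budget exhausted (incomplete search); ",
             "raise node_budget or use heuristic_search")
      len <- score(edge)
      if (len > env$bound + slack) return()
      if (!length(remaining)) {
        if (len < env$bound) {
          env$bound <- len
          env$trees <- Filter(function(t) t$length <= len + slack, env$trees)
        }
        if (length(env$trees) >= maxtrees) { env$cap_hit <- TRUE; return() }
        env$trees <- c(env$trees, list(list(length = len, edge = edge)))
        return()
      }
      t <- remaining[1]
      for (e in 2:nrow(edge)) {
        recurse(.insert_tip_edge(edge, e, t, nextnode), nextnode + 1L,
                remaining[-1])
      }
    }
    recurse(.start_edge(su$anchor, others[1], others[2], su$n),
            su$n + 3L, others[-(1:2)])
  }
  lens <- vapply(env$trees, `[[`, 0, "length")
  best <- min(lens)
  opt <- env$trees[lens == best]
  trees <- .as_multiphylo(lapply(opt, function(t)
    .edge_to_phylo(t$edge, su$labels)))
  extra <- list(expansions = env$expansions)
  if (slack > 0L) {
    extra$suboptimal <- lapply(env$trees, function(t)
      list(length = t$length, tree = .edge_to_phylo(t$edge, su$labels)))
  }
  .search_result(best, trees, env$cap_hit, 1L, NULL, "branch_and_bound",
                 extra = extra)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology (via [phangorn::allTrees()])
#' and scores each one; exact but only feasible for small tip counts. Used
#' as the reference optimum for the other searches.
#'
#' @param m a `character_matrix` with at most 9 specimens.
#' @return a `search_result` with extra field `n_enumerated`.
#' @export
exhaustive_search <- function(m) {
  su <- .search_setup(m)
  if (su$n > 9) stop("exhaustive search limited to 9 tips (got ", su$n, ")")
  if (su$n < 4) {
    tr <- ape::read.tree(text = paste0("(", paste(su$labels, collapse = ","),
                                       ");"))
    return(.search_result(tree_length(tr, m), .as_multiphylo(list(tr)),
                          FALSE, 1L, NULL, "exhaustive",
                          extra = list(n_enumerated = 1L)))
  }
  all_tr <- phangorn::allTrees(su$n, rooted = FALSE, tip.label = su$labels)
  lens <- vapply(all_tr, function(tr) .pscore_phylo(tr, m), 0)
  best <- min(lens)
  opt <- all_tr[lens == best]
  # allTrees numbers tips 1..n in tip.label order, matching su$labels
  trees <- .as_multiphylo(lapply(opt, function(tr)
    .edge_to_phylo(.anchor_root(tr$edge, su$n, su$anchor), su$labels)))
  .search_result(best, trees, FALSE, 1L, NULL, "exhaustive",
                 extra = list(n_enumerated = length(all_tr)))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
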