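# Node robustness: Bremer decay and nonparametric bootstrap.

# does an edge-representation tree contain the (sorted) tip-id clade under
# anchor rooting?
.contains_clade <- function(edge, n, anchor, clade_sorted) {
  maxn <- max(edge)
  kids <- split(edge[, 2], factor(edge[, 1], levels = seq_len(maxn)))
  below <- vector("list", maxn)
  for (v in seq_len(min(n, maxn))) below[[v]] <- v
  present <- sort(edge[edge[, 2] <= n, 2])
  for (v in .node_order(edge, n + 1L)) {
    below[[v]] <- sort(unlist(below[kids[[v]]], use.names = FALSE))
  }
  for (v in unique(edge[, 1])) {
    s <- below[[v]]
    if (anchor %in% s) s <- setdiff(present, s)
    if (length(s) == length(clade_sorted) && all(s == clade_sorted))
      return(TRUE)
  }
  FALSE
}

# best length over trees NOT containing the clade, by penalized heuristic
# search (reverse constraint)
.constrained_best <- function(m, clade_labels, nreps, swap, seed) {
  su <- .search_setup(m)
  clade_ids <- sort(match(clade_labels, su$labels))
  big <- sum(m$characters$n_states) * nrow(m$cells) # > any real length
  base <- function(edge) .pscore(edge, su$n + 1L, su$masks, su$n)
  score <- function(edge) {
    base(edge) + big * .contains_clade(edge, su$n, su$anchor, clade_ids)
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  best <- Inf
  others <- setdiff(seq_len(su$n), su$anchor)
  for (r in seq_len(nreps)) {
    ord <- sample(others)
    edge <- .start_edge(su$anchor, ord[1], ord[2], su$n)
    nextnode <- su$n + 3L
    for (t in ord[-(1:2)]) {
      cand <- 2:nrow(edge)
      sc <- vapply(cand, function(e)
        score(.insert_tip_edge(edge, e, t, nextnode)), 0)
      edge <- .insert_tip_edge(edge, cand[which.min(sc)], t, nextnode)
      nextnode <- nextnode + 1L
    }
    len <- score(edge)
    repeat {
      nb <- .swap_neighbors(edge, su$n, swap)
      if (!length(nb)) break
      sc <- vapply(nb, score, 0)
      if (min(sc) < len) {
        len <- min(sc)
        edge <- nb[[which.min(sc)]]
      } else break
    }
    best <- min(best, len)
  }
  best
}

#' Bremer decay index
#'
#' For each clade, the number of extra steps before the clade disappears
#' from the optimal set: (shortest length among trees lacking the clade)
#' minus the best length. A clade absent from some most parsimonious tree
#' has decay 0 by definition. For small matrices all trees within
#' `max_k` steps of the optimum are enumerated exactly by branch-and-bound;
#' larger matrices fall back to a reverse-constraint heuristic search per
#' clade. Decays exceeding `max_k` are reported as `">max_k"`.
#'
#' @param m a `character_matrix` (embryo present).
#' @param clades optional list of character vectors of tip labels; defaults
#'   to the non-trivial clades of the strict consensus of the MPTs.
#' @param max_k truncation for the suboptimal sweep.
#' @param method `"auto"` (exact below `exact_max_taxa` tips), `"exact"`,
#'   or `"constrained"`.
#' @param exact_max_taxa taxon-count ceiling for the exact route.
#' @param search_args settings for the heuristic searches (nreps, swap,
#'   seed).
#' @return a `support_table` data frame: `clade`, `bremer` (numeric,
#'   `Inf` when truncated), `display` (text, e.g. `">10"`).
#' @export
bremer_decay <- function(m, clades = NULL, max_k = 10L,
                         method = c("auto", "exact", "constrained"),
                         exact_max_taxa = 12L,
                         search_args = list(nreps = 2, swap = "spr",
                                            seed = 0L)) {
  method <- match.arg(method)
  n <- nrow(m$cells)
  if (method == "auto")
    method <- if (n <= exact_max_taxa) "exact" else "constrained"
  sa <- utils::modifyList(list(nreps = 2, swap = "spr", seed = 0L),
                          search_args)
  if (method == "exact") {
    bb <- branch_and_bound(m, keep_suboptimal = max_k)
    best <- bb$best_length
    mpts <- bb$trees
  } else {
    hs <- heuristic_search(m, nreps = sa$nreps, swap = sa$swap,
                           seed = sa$seed)
    best <- hs$best_length
    mpts <- hs$trees
  }
  if (is.null(clades)) {
    cons <- strict_consensus(mpts)
    cl <- .tree_clades(cons)
    cl <- lapply(cl, setdiff, y = c(m$embryo, m$adult))
    cl <- cl[lengths(cl) >= 2 &
               lengths(cl) < length(specimens(m, real = TRUE))]
    clades <- unique(lapply(cl, sort))
  }
  bremer <- vapply(clades, function(clade) {
    clade <- sort(clade)
    # decay 0 if some MPT lacks the clade
    lacking <- vapply(mpts, function(tr) {
      sets <- lapply(.tree_clades(tr), function(s)
        sort(setdiff(s, c(m$embryo, m$adult))))
      !any(vapply(sets, identical, TRUE, y = clade))
    }, TRUE)
    if (any(lacking)) return(0)
    if (method == "exact") {
      lens <- vapply(bb$suboptimal, function(t) {
        sets <- lapply(.tree_clades(t$tree), function(s)
          sort(setdiff(s, c(m$embryo, m$adult))))
        if (any(vapply(sets, identical, TRUE, y = clade))) Inf
        else t$length
      }, 0)
      if (all(is.infinite(lens))) Inf else min(lens) - best
    } else {
      alt <- .constrained_best(m, clade, sa$nreps, sa$swap, sa$seed)
      d <- alt - best
      if (d > max_k) Inf else d
    }
  }, 0)
  out <- data.frame(
    clade = vapply(clades, function(x) paste(sort(x), collapse = ","), ""),
    bremer = bremer,
    display = ifelse(is.infinite(bremer), paste0(">", max_k),
                     format(bremer, trim = TRUE)),
    stringsAsFactors = FALSE)
  class(out) <- c("support_table", "data.frame")
  out
}

#' Nonparametric bootstrap support
#'
#' Resamples characters with replacement, repeats a (reduced-effort)
#' heuristic search per replicate, and scores each clade by the share of
#' replicates whose MPT strict consensus contains it. Additive-binary
#' matrices are refused by default: their expansion columns are not
#' independent characters, so resampling them individually violates the
#' bootstrap's independence assumption. With `force = TRUE` a binary matrix
#' is resampled by linked source-character groups (never by individual
#' expansion columns).
#'
#' @param m a `character_matrix`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed driving the whole resampling/search stream.
#' @param search_args per-replicate search settings: `nreps`, `swap`,
#'   `maxtrees`.
#' @param force allow a binary matrix, resampling linked groups.
#' @return a `support_table` data frame: `clade`, `count`, `bootstrap_pct`,
#'   sorted by decreasing support; attribute `n_reps`.
#' @export
bootstrap_support <- function(m, n_reps = 1000L, seed = NULL,
                              search_args = list(nreps = 1, swap = "nni",
                                                 maxtrees = 20),
                              force = FALSE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  binary <- all(m$characters$n_states == 2L)
  if (binary && !force)
    stop("additive-binary matrices are excluded from the bootstrap: ",
         "expansion columns of one multistate character are not ",
         "independent, so column resampling violates the bootstrap's ",
         "character-independence assumption; pass force = TRUE to ",
         "resample linked groups instead")
  sa <- utils::modifyList(list(nreps = 1, swap = "nni", maxtrees = 20),
                          search_args)
  k <- ncol(m$cells)
  src <- m$characters$source_char
  units <- if (binary && any(!is.na(src))) {
    split(seq_len(k), ifelse(is.na(src), m$characters$id, src))
  } else {
    as.list(seq_len(k))
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(n_reps)) {
    draw <- sample.int(length(units), replace = TRUE)
    w <- numeric(k)
    for (u in draw) w[units[[u]]] <- w[units[[u]]] + 1
    hs <- heuristic_search(m, nreps = sa$nreps, swap = sa$swap,
                           maxtrees = sa$maxtrees, weights = w)
    cons <- if (length(hs$trees) > 1) strict_consensus(hs$trees) else
      hs$trees[[1]]
    cl <- lapply(.tree_clades(cons), function(s)
      sort(setdiff(s, c(m$embryo, m$adult))))
    cl <- unique(cl[lengths(cl) >= 2])
    for (key in vapply(cl, paste, "", collapse = ",")) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- ls(counts)
  out <- data.frame(
    clade = keys,
    count = vapply(keys, function(k) counts[[k]], 0),
    bootstrap_pct = 100 * vapply(keys, function(k) counts[[k]], 0) / n_reps,
    stringsAsFactors = FALSE)
  out <- out[order(-out$bootstrap_pct, out$clade), ]
  rownames(out) <- NULL
  attr(out, "n_reps") <- n_reps
  class(out) <- c("support_table", "data.frame")
  out
}
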