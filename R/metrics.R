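# Consistency indices, ontogenetic ranks, and the tied-rank Spearman
# correlation against a size proxy.

#' Consistency index report
#'
#' Per character: m = theoretical minimum steps (distinct observed states
#' minus one) and s = steps realized on the tree; ci = m/s. The ensemble CI
#' is the ratio of sums, sum(m)/sum(s). Both the conventional value (all
#' characters, matching the usual program default) and the value excluding
#' parsimony-uninformative characters are reported.
#'
#' @param tree rooted `ape::phylo` over the matrix specimens.
#' @param m a `character_matrix`.
#' @return a `ci_report`: list with `tree_steps`, `min_steps_total`,
#'   `ensemble_ci`, `ensemble_ci_informative`, and `per_character`
#'   (data frame: id, category, region, m, s, ci, informative).
#' @export
consistency_index <- function(tree, m) {
  s_i <- tree_length(tree, m, per_character = TRUE)
  m_i <- min_steps(m)
  if (sum(s_i) == 0)
    stop("CI undefined: no character changes on the tree (constant matrix)")
  inf_i <- !.uninformative(m)
  per <- data.frame(
    id = m$characters$id,
    category = m$characters$category,
    region = m$characters$region,
    m = m_i, s = s_i,
    ci = ifelse(s_i > 0, m_i / s_i, NA_real_),
    informative = inf_i,
    stringsAsFactors = FALSE)
  structure(list(
    tree_steps = sum(s_i),
    min_steps_total = sum(m_i),
    ensemble_ci = sum(m_i) / sum(s_i),
    ensemble_ci_informative =
      if (sum(s_i[inf_i]) > 0) sum(m_i[inf_i]) / sum(s_i[inf_i]) else NA,
    per_character = per), class = "ci_report")
}

#' @export
print.ci_report <- function(x, ...) {
  cat("Tree length ", x$tree_steps, " steps; minimum ", x$min_steps_total,
      "; ensemble CI ", sprintf("%.4f", x$ensemble_ci),
      " (informative only: ", sprintf("%.4f", x$ensemble_ci_informative),
      ")\n", sep = "")
  invisible(x)
}

#' Cumulative consistency index per category
#'
#' Partitions characters by a grouping label (by default the metadata
#' `category`) and reports, per group, the cumulative CI sum(m)/sum(s) --
#' the group analogue of the ensemble CI -- together with the mean of
#' per-character CIs as an alternative convention. Group sums of m and s
#' partition the ensemble totals exactly.
#'
#' @param tree rooted `ape::phylo`.
#' @param m a `character_matrix`.
#' @param groups optional character vector (one entry per character) or the
#'   name of a metadata column (`"category"` or `"region"`).
#' @return data frame: group, n_characters, m, s, cumulative_ci, mean_ci.
#' @export
cumulative_ci <- function(tree, m, groups = "category") {
  if (is.character(groups) && length(groups) == 1) {
    if (!groups %in% names(m$characters))
      stop("no metadata column '", groups, "'")
    groups <- m$characters[[groups]]
  }
  if (length(groups) != ncol(m$cells))
    stop("need one group label per character")
  if (anyNA(groups)) stop("unmapped characters: ",
                          paste(m$characters$id[is.na(groups)],
                                collapse = ", "))
  ci <- consistency_index(tree, m)$per_character
  out <- do.call(rbind, lapply(split(ci, groups), function(d) {
    data.frame(group = NA_character_, n_characters = nrow(d),
               m = sum(d$m), s = sum(d$s),
               cumulative_ci = if (sum(d$s) > 0) sum(d$m) / sum(d$s) else NA,
               mean_ci = mean(d$ci, na.rm = TRUE))
  }))
  out$group <- names(split(ci, groups))
  rownames(out) <- NULL
  out
}

#' Ontogenetic ranks from an ontogram
#'
#' Ranks specimens by their order of divergence from the embryo root: the
#' primary key is the depth (number of branching events from the root) at
#' which a tip's own branch splits off, so specimens diverging later --
#' having accumulated more growth changes -- rank higher. Tips diverging at
#' the same depth (sisters in a terminal cherry, members of a polytomy, or
#' tips of equally deep unresolved subtrees) carry no divergence order of
#' their own: with `tie_siblings = TRUE` they share the mid-rank of their
#' positions (the robust choice on consensus trees); otherwise they are
#' ordered by cumulative coded maturity (mean relative state) when the
#' data matrix is supplied, falling back to tip order, giving a full
#' 1..n ranking on a fully pectinate tree. Explicitly declared
#' `tie_groups` (e.g. an oversampled growth stage) always receive their
#' common mid-rank.
#'
#' @param tree rooted `ape::phylo`, embryo at the root.
#' @param tie_groups list of character vectors of tip labels to tie.
#' @param m optional `character_matrix` used to order equally deep tips.
#' @param exclude tips to drop from ranking (defaults to embryo/adult
#'   labels recorded in `m`, plus `"EMBRYO"`/`"ADULT"`).
#' @param tie_siblings tie all tips diverging at equal depth.
#' @return a `growth_ranking`: data frame `specimen`, `rank`.
#' @export
ontogenetic_ranks <- function(tree, tie_groups = NULL, m = NULL,
                              exclude = NULL, tie_siblings = FALSE) {
  if (is.null(exclude))
    exclude <- c("EMBRYO", "ADULT", if (!is.null(m)) c(m$embryo, m$adult))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  par <- integer(nn)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- integer(nn)
  for (v in rev(.node_order(tree$edge, root)))
    if (v != root) depth[v] <- depth[par[v]] + 1L
  tip_depth <- depth[par[seq_len(ntip)]]
  maturity <- if (!is.null(m)) {
    rel <- sweep(m$cells, 2, m$characters$n_states - 1L, "/")
    rowMeans(rel, na.rm = TRUE)[tree$tip.label]
  } else {
    seq_len(ntip)
  }
  keep <- which(!tree$tip.label %in% exclude)
  ord <- keep[order(tip_depth[keep], maturity[keep])]
  order_out <- tree$tip.label[ord]
  n <- length(ord)
  rk <- as.numeric(seq_len(n))
  if (tie_siblings) {
    for (d in unique(tip_depth[ord])) {
      idx <- which(tip_depth[ord] == d)
      if (length(idx) > 1) rk[idx] <- mean(rk[idx])
    }
  }
  names(rk) <- order_out
  if (!is.null(tie_groups)) {
    for (tg in tie_groups) {
      bad <- setdiff(tg, order_out)
      if (length(bad))
        stop("tie group members not among ranked tips: ",
             paste(bad, collapse = ", "))
      rk[tg] <- mean(rk[tg])
    }
  }
  structure(data.frame(specimen = order_out, rank = unname(rk),
                       stringsAsFactors = FALSE),
            class = c("growth_ranking", "data.frame"))
}

#' Spearman rank correlation, uncorrected form with mid-ranks
#'
#' Computes P = 1 - 6 * sum(D^2) / (n (n^2 - 1)) where D is the difference
#' between the ontogenetic rank and the rank of the size proxy. Raw proxy
#' values are converted to mid-ranks; tied values share their mid-rank. No
#' tie-correction term is applied, matching the classical hand-worked
#' arithmetic of growth-series studies.
#'
#' @param rank_a numeric vector of ontogenetic ranks (mid-ranks allowed).
#' @param values_b numeric vector of the size proxy (raw values or ranks),
#'   same length and order as `rank_a`.
#' @return a `spearman_result`: list with `n`, `d`, `d_squared`,
#'   `sum_d_squared`, `p`.
#' @export
spearman_rank <- function(rank_a, values_b) {
  if (length(rank_a) != length(values_b))
    stop("rank_a and values_b differ in length")
  n <- length(rank_a)
  if (n < 2) stop("need at least 2 observations")
  rank_b <- rank(values_b)
  d <- rank_a - rank_b
  structure(list(n = n, rank_a = rank_a, rank_b = rank_b,
                 d = d, d_squared = d^2, sum_d_squared = sum(d^2),
                 p = 1 - 6 * sum(d^2) / (n * (n^2 - 1))),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat("Spearman rank correlation (uncorrected, mid-ranks): n = ", x$n,
      ", sum D^2 = ", x$sum_d_squared,
      ", P = ", sprintf("%.3f", x$p), "\n", sep = "")
  invisible(x)
}
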