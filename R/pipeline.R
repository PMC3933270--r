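# End-to-end ontogram analysis: matrix -> search -> consensus ->
# optimization -> support -> metrics, with a machine-readable report.

#' Build an analysis configuration
#'
#' @param matrix a `character_matrix`, or a NEXUS path to load.
#' @param annotations sidecar TSV path when `matrix` is a path.
#' @param coding `"multistate"` (use the matrix as given) or `"binary"`
#'   (additive-binary recode before searching).
#' @param add_embryo inject the hypothetical embryo unless one is present.
#' @param add_adult append the artificial adult and re-run the search a
#'   posteriori to identify the most mature specimen.
#' @param subset optional specimen labels to restrict to (embryo kept).
#' @param search list: `mode` ("heuristic" or "branch_and_bound"), `nreps`,
#'   `swap`, `maxtrees`, `seed`.
#' @param consensus consensus methods to compute.
#' @param bremer list with `max_k` (or `NULL` to skip).
#' @param bootstrap list with `n_reps`, `search_args` (or `NULL` to skip).
#' @param ranks compute ontogenetic ranks from the reporting tree.
#' @param sizes optional data frame (`specimen`, `size`) for the Spearman
#'   correlation against the size proxy.
#' @param output_dir optional directory for trees/tables/report artifacts.
#' @return an `ontogram_config` list.
#' @export
ontogram_config <- function(matrix, annotations = NULL,
                            coding = c("multistate", "binary"),
                            add_embryo = TRUE, add_adult = FALSE,
                            subset = NULL,
                            search = list(mode = "heuristic", nreps = 10,
                                          swap = "spr", maxtrees = 100000,
                                          seed = 1),
                            consensus = c("strict", "semistrict", "adams",
                                          "majority"),
                            bremer = list(max_k = 10),
                            bootstrap = NULL,
                            ranks = TRUE, sizes = NULL,
                            output_dir = NULL) {
  structure(list(matrix = matrix, annotations = annotations,
                 coding = match.arg(coding), add_embryo = add_embryo,
                 add_adult = add_adult, subset = subset,
                 search = utils::modifyList(
                   list(mode = "heuristic", nreps = 10, swap = "spr",
                        maxtrees = 100000, seed = 1), search),
                 consensus = consensus, bremer = bremer,
                 bootstrap = bootstrap, ranks = ranks, sizes = sizes,
                 output_dir = output_dir),
            class = "ontogram_config")
}

#' Run the full ontogram analysis
#'
#' Stages: load -> embryo injection -> deduplication -> optional
#' additive-binary recoding -> optional specimen subset -> parsimony search
#' -> consensus set -> ACCTRAN/DELTRAN synontomorphies -> Bremer (and
#' optional bootstrap) support -> consistency indices -> optional
#' artificial-adult re-run -> optional ontogenetic ranks and Spearman
#' correlation against a size table. Any stage error aborts with the stage
#' name; artifacts already written are retained.
#'
#' @param config an [ontogram_config()].
#' @return an `ontogram_report` list with all headline numbers (best
#'   length, MPT count, cap flag, ensemble CI, mean grouping frequency,
#'   support tables, Spearman statistic) plus the trees and tables
#'   themselves.
#' @export
run_ontogram <- function(config) {
  stopifnot(inherits(config, "ontogram_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  m <- stage("load", {
    if (inherits(config$matrix, "character_matrix")) config$matrix
    else read_nexus(config$matrix, annotations = config$annotations)
  })
  if (config$add_embryo && is.null(m$embryo))
    m <- stage("embryo", add_hypothetical_embryo(m))
  dd <- stage("deduplicate", deduplicate_specimens(m))
  m <- dd$matrix
  if (config$coding == "binary")
    m <- stage("recode", to_additive_binary(m))
  if (!is.null(config$subset))
    m <- stage("subset", subset_specimens(m, config$subset))
  sr <- stage("search", {
    s <- config$search
    if (identical(s$mode, "branch_and_bound")) branch_and_bound(m)
    else heuristic_search(m, nreps = s$nreps, swap = s$swap,
                          maxtrees = s$maxtrees, seed = s$seed)
  })
  cons <- stage("consensus", {
    out <- list()
    for (meth in config$consensus) {
      out[[meth]] <- switch(meth,
        strict = strict_consensus(sr$trees),
        semistrict = semistrict_consensus(sr$trees),
        adams = adams_consensus(sr$trees),
        majority = majority_rule(sr$trees)$tree,
        stop("unknown consensus method: ", meth))
    }
    out
  })
  mean_freq <- if ("majority" %in% config$consensus)
    stage("consensus", mean_grouping_frequency(sr$trees)) else NA
  # reporting tree: the single MPT if unique, else the majority-rule tree
  report_tree <- if (length(sr$trees) == 1) sr$trees[[1]] else
    if (!is.null(cons$majority)) cons$majority else cons[[1]]
  syn <- stage("synontomorphies", synontomorphies(report_tree, m))
  ci <- stage("ci", consistency_index(report_tree, m))
  cci <- stage("ci", cumulative_ci(report_tree, m, "category"))
  brem <- if (!is.null(config$bremer))
    stage("bremer", bremer_decay(m, max_k = config$bremer$max_k,
                                 search_args = config$search))
  boot <- if (!is.null(config$bootstrap))
    stage("bootstrap", do.call(bootstrap_support,
                               c(list(m = m), config$bootstrap)))
  adult <- if (config$add_adult) stage("adult", {
    ma <- add_artificial_adult(m)
    s <- config$search
    sra <- if (identical(s$mode, "branch_and_bound")) branch_and_bound(ma)
    else heuristic_search(ma, nreps = s$nreps, swap = s$swap,
                          maxtrees = s$maxtrees, seed = s$seed)
    sisters <- unique(unlist(lapply(sra$trees, function(tr) {
      anc <- tr$edge[match(match(ma$adult, tr$tip.label), tr$edge[, 2]), 1]
      sibs <- tr$edge[tr$edge[, 1] == anc, 2]
      tips <- sibs[sibs <= length(tr$tip.label)]
      setdiff(tr$tip.label[tips], ma$adult)
    })))
    list(best_length = sra$best_length, added_steps = sra$best_length -
           sr$best_length, n_trees = length(sra$trees),
         most_mature = sisters)
  })
  rk <- sp <- NULL
  if (config$ranks) {
    rk <- stage("ranks", ontogenetic_ranks(report_tree, m = m,
                                           tie_siblings =
                                             length(sr$trees) > 1))
    if (!is.null(config$sizes)) {
      sp <- stage("spearman", {
        sz <- config$sizes
        common <- intersect(rk$specimen, sz$specimen)
        ra <- rank(rk$rank[match(common, rk$specimen)])
        spearman_rank(ra, sz$size[match(common, sz$specimen)])
      })
    }
  }
  report <- structure(list(
    coding = config$coding,
    n_specimens = nrow(m$cells), n_characters = ncol(m$cells),
    removed = dd$log,
    best_length = sr$best_length, n_mpt = length(sr$trees),
    cap_hit = sr$cap_hit, seed = config$search$seed,
    ensemble_ci = ci$ensemble_ci, mean_grouping_pct = mean_freq,
    search = sr, consensus = cons, synontomorphies = syn,
    ci = ci, cumulative_ci = cci, bremer = brem, bootstrap = boot,
    adult = adult, ranks = rk, spearman = sp,
    matrix = m), class = "ontogram_report")
  if (!is.null(config$output_dir))
    write_report(report, config$output_dir)
  report
}

#' @export
print.ontogram_report <- function(x, ...) {
  cat("Ontogram analysis (", x$coding, " coding): ", x$n_specimens,
      " specimens x ", x$n_characters, " characters\n", sep = "")
  cat("  best length ", x$best_length, " steps, ", x$n_mpt, " MPT(s)",
      if (x$cap_hit) " [cap hit]",
      ", ensemble CI ", sprintf("%.4f", x$ensemble_ci), "\n", sep = "")
  if (!is.na(x$mean_grouping_pct))
    cat("  mean grouping frequency ", sprintf("%.1f", x$mean_grouping_pct),
        "%\n", sep = "")
  if (!is.null(x$adult))
    cat("  artificial adult: +", x$adult$added_steps, " steps, sister to ",
        paste(x$adult$most_mature, collapse = ", "), "\n", sep = "")
  if (!is.null(x$spearman))
    cat("  Spearman vs size proxy: P = ", sprintf("%.3f", x$spearman$p),
        "\n", sep = "")
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' Newick trees (MPTs and consensus trees), TSV tables (synontomorphies,
#' CI, support, ranks, removal log) and a JSON summary of the headline
#' numbers.
#'
#' @param report an `ontogram_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(report$search$trees, file.path(dir, "mpts.nwk"))
  for (meth in names(report$consensus))
    ape::write.tree(report$consensus[[meth]],
                    file.path(dir, paste0("consensus_", meth, ".nwk")))
  tsv <- function(d, f) utils::write.table(d, file.path(dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  tsv(as.data.frame(report$synontomorphies), "synontomorphies.tsv")
  tsv(report$ci$per_character, "ci_per_character.tsv")
  tsv(report$cumulative_ci, "ci_cumulative.tsv")
  if (!is.null(report$bremer)) tsv(report$bremer, "bremer.tsv")
  if (!is.null(report$bootstrap)) tsv(report$bootstrap, "bootstrap.tsv")
  if (!is.null(report$ranks)) tsv(report$ranks, "ranks.tsv")
  if (nrow(report$removed)) tsv(report$removed, "removed_specimens.tsv")
  summary <- list(coding = report$coding,
                  n_specimens = report$n_specimens,
                  n_characters = report$n_characters,
                  best_length = report$best_length,
                  n_mpt = report$n_mpt, cap_hit = report$cap_hit,
                  seed = report$seed,
                  ensemble_ci = report$ensemble_ci,
                  mean_grouping_pct = report$mean_grouping_pct,
                  adult = report$adult,
                  spearman = if (!is.null(report$spearman))
                    list(n = report$spearman$n,
                         sum_d_squared = report$spearman$sum_d_squared,
                         p = report$spearman$p))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Compare multistate and additive-binary codings of one data set
#'
#' @param report_multi,report_binary `ontogram_report`s from the same
#'   specimen set under the two codings.
#' @return one-row-per-coding data frame: length, CI, MPT count, mean
#'   grouping frequency.
#' @export
compare_codings <- function(report_multi, report_binary) {
  sm <- setdiff(rownames(report_multi$matrix$cells),
                c(report_multi$matrix$embryo, report_multi$matrix$adult))
  sb <- setdiff(rownames(report_binary$matrix$cells),
                c(report_binary$matrix$embryo, report_binary$matrix$adult))
  if (!setequal(sm, sb))
    stop("reports cover different specimen sets")
  data.frame(
    coding = c(report_multi$coding, report_binary$coding),
    n_characters = c(report_multi$n_characters,
                     report_binary$n_characters),
    best_length = c(report_multi$best_length, report_binary$best_length),
    ensemble_ci = c(report_multi$ensemble_ci, report_binary$ensemble_ci),
    n_mpt = c(report_multi$n_mpt, report_binary$n_mpt),
    mean_grouping_pct = c(report_multi$mean_grouping_pct,
                          report_binary$mean_grouping_pct),
    stringsAsFactors = FALSE)
}
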