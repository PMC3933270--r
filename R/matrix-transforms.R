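#' Add the all-zero hypothetical embryo
#'
#' Polarizes every character by appending an artificial specimen scored 0
#' (the nascent state) for all characters. The embryo acts as the root of
#' the recovered ontogram.
#'
#' @param m a `character_matrix` without an embryo row.
#' @param label row label for the embryo.
#' @return the matrix with one extra all-zero row, flagged as embryo.
#' @export
add_hypothetical_embryo <- function(m, label = "EMBRYO") {
  if (!is.null(m$embryo))
    stop("matrix already contains an embryo row ('", m$embryo, "')")
  if (label %in% rownames(m$cells))
    stop("a specimen is already labelled '", label, "'")
  cells <- rbind(m$cells, matrix(0L, 1, ncol(m$cells),
                                 dimnames = list(label, NULL)))
  character_matrix(cells, m$characters, embryo = label, adult = m$adult)
}

#' Add an artificial adult scored for every mature state
#'
#' Appends a specimen carrying the mature condition of every character, used
#' a posteriori to identify the maturity axis of the tree (its sister is the
#' most mature real specimen). It is never part of the primary search.
#'
#' @param m a `character_matrix`.
#' @param mature_states optional integer vector (one state per character);
#'   defaults to each character's maximum state.
#' @param label row label for the adult.
#' @return the matrix with the adult row appended and flagged.
#' @export
add_artificial_adult <- function(m, mature_states = NULL, label = "ADULT") {
  if (!is.null(m$adult))
    stop("matrix already contains an adult row ('", m$adult, "')")
  if (label %in% rownames(m$cells))
    stop("a specimen is already labelled '", label, "'")
  if (is.null(mature_states)) {
    mature_states <- m$characters$n_states - 1L
  } else if (length(mature_states) != ncol(m$cells)) {
    stop("mature_states must supply one state per character (",
         ncol(m$cells), ")")
  }
  cells <- rbind(m$cells, matrix(as.integer(mature_states), 1,
                                 ncol(m$cells), dimnames = list(label, NULL)))
  character_matrix(cells, m$characters, embryo = m$embryo, adult = label)
}

#' Remove redundant specimens
#'
#' Drops (a) later members of groups with identical codings across all
#' characters, missing symbols included (missing is compared literally, not
#' wildcard-matched), and (b) specimens whose every coded cell is 0, which
#' are redundant with the hypothetical embryo.
#'
#' @param m a `character_matrix` with the embryo row present.
#' @return a list with `matrix` (the deduplicated `character_matrix`) and
#'   `log`, a data frame mapping each removed specimen to the retained
#'   representative and a reason (`duplicate` or `all_zero`).
#' @export
deduplicate_specimens <- function(m) {
  if (is.null(m$embryo))
    stop("add the hypothetical embryo before deduplicating")
  cells <- m$cells
  ids <- rownames(cells)
  keyed <- apply(cells, 1, function(r) {
    r[is.na(r)] <- "?"
    paste(r, collapse = "")
  })
  # the embryo is always the retained representative of its group
  ord <- order(ids != m$embryo)
  keep <- logical(length(ids))
  keep[ord] <- !duplicated(keyed[ord])
  retained_map <- ids[keep][match(keyed, keyed[keep])]
  log <- data.frame(removed = ids[!keep],
                    retained = retained_map[!keep],
                    reason = rep("duplicate", sum(!keep)),
                    stringsAsFactors = FALSE)
  # all-zero-coded rows (every non-missing cell 0) duplicate the embryo
  coded_zero <- apply(cells, 1, function(r) all(r[!is.na(r)] == 0L)) &
    apply(cells, 1, function(r) !all(is.na(r)))
  zero_drop <- keep & coded_zero & ids != m$embryo
  if (any(zero_drop)) {
    log <- rbind(log, data.frame(removed = ids[zero_drop],
                                 retained = m$embryo,
                                 reason = "all_zero",
                                 stringsAsFactors = FALSE))
    keep <- keep & !zero_drop
  }
  adult <- if (!is.null(m$adult) && m$adult %in% ids[keep]) m$adult
  out <- character_matrix(cells[keep, , drop = FALSE], m$characters,
                          embryo = m$embryo, adult = adult)
  list(matrix = out, log = log)
}

#' Expand multistate characters to additive binary coding
#'
#' A character with `k + 1` ordered states becomes `k` binary characters;
#' state `s` maps to `s` leading 1s followed by 0s, so partial fusion
#' precedes full fusion by construction. Characters flagged
#' `recode_policy = "branching"` instead yield one binary character per
#' alternative mature state, scored 1 only for specimens in that state, so
#' that alternative adult morphologies nullify one another on the tree.
#' Missing cells stay missing in every expansion column, and each new
#' character records its multistate source in `source_char`.
#'
#' @param m a `character_matrix`.
#' @return a binary `character_matrix` with the same specimens.
#' @export
to_additive_binary <- function(m) {
  ch <- m$characters
  multi <- ch$n_states > 2L
  if (any(multi & !ch$recode_policy %in% c("additive", "branching")))
    stop("multistate characters need recode_policy 'additive' or 'branching'")
  cols <- list(); meta <- list()
  for (j in seq_len(nrow(ch))) {
    v <- m$cells[, j]
    k <- ch$n_states[j] - 1L
    if (k == 1L) {
      cols[[length(cols) + 1L]] <- v
      meta[[length(meta) + 1L]] <-
        data.frame(id = ch$id[j], label = ch$label[j], n_states = 2L,
                   category = ch$category[j], region = ch$region[j],
                   recode_policy = "additive", source_char = ch$id[j],
                   stringsAsFactors = FALSE)
      next
    }
    for (s in seq_len(k)) {
      new <- if (ch$recode_policy[j] == "additive") {
        as.integer(v >= s)
      } else {
        as.integer(v == s)
      }
      new[is.na(v)] <- NA_integer_
      cols[[length(cols) + 1L]] <- new
      meta[[length(meta) + 1L]] <-
        data.frame(id = paste0(ch$id[j], ".", s),
                   label = paste0(ch$label[j], " [state ", s, "]"),
                   n_states = 2L, category = ch$category[j],
                   region = ch$region[j], recode_policy = "additive",
                   source_char = ch$id[j], stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  cells <- do.call(cbind, cols)
  dimnames(cells) <- list(rownames(m$cells), meta$id)
  character_matrix(cells, meta, embryo = m$embryo, adult = m$adult)
}

#' Restrict a matrix to a subset of specimens
#'
#' The embryo (and adult, if present among `keep_ids`) is always retained.
#' Characters are never dropped; those rendered constant by the subsetting
#' are flagged in the returned attribute `constant_chars`.
#'
#' @param m a `character_matrix`.
#' @param keep_ids specimen labels to retain.
#' @return the restricted `character_matrix`.
#' @export
subset_specimens <- function(m, keep_ids) {
  ids <- rownames(m$cells)
  unknown <- setdiff(keep_ids, ids)
  if (length(unknown))
    stop("unknown specimen ids: ", paste(unknown, collapse = ", "))
  keep <- union(m$embryo, keep_ids)
  out <- character_matrix(m$cells[ids[ids %in% keep], , drop = FALSE],
                          m$characters, embryo = m$embryo,
                          adult = if (!is.null(m$adult) &&
                                      m$adult %in% keep) m$adult)
  const <- apply(out$cells, 2, function(v) length(unique(v[!is.na(v)])) <= 1L)
  attr(out, "constant_chars") <- out$characters$id[const]
  out
}
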