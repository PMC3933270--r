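#' Growth-character matrices
#'
#' A `character_matrix` holds a specimens-by-characters table of small integer
#' state codes (0 = nascent/juvenile condition, higher codes = progressively
#' or alternatively mature conditions) together with per-character metadata.
#' Missing observations (uncodeable or unpreserved elements) are `NA`; the
#' inapplicable symbol "-" is treated identically to missing, so a single
#' ambiguity semantics applies throughout scoring.
#'
#' @param cells integer matrix, rows = specimens (rownames required),
#'   columns = characters. Values in `0:(n_states - 1)` or `NA`.
#' @param characters data frame of character metadata with columns
#'   `id`, `label`, `n_states`, `category`, `region`, `recode_policy`,
#'   `source_char`. Missing columns are filled with defaults
#'   (`n_states` from the observed maximum, category/region "other",
#'   policy "additive").
#' @param embryo label of the all-zero hypothetical embryo row, or `NULL`.
#' @param adult label of the artificial adult row, or `NULL`.
#'
#' @return an object of class `character_matrix`: a list with elements
#'   `cells`, `characters`, `embryo`, `adult`.
#' @export
character_matrix <- function(cells, characters = NULL, embryo = NULL,
                             adult = NULL) {
  if (!is.matrix(cells)) cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (is.null(rownames(cells)))
    stop("cells must have specimen rownames")
  if (anyDuplicated(rownames(cells)))
    stop("duplicate specimen labels: ",
         paste(unique(rownames(cells)[duplicated(rownames(cells))]),
               collapse = ", "))
  if (is.null(colnames(cells))) {
    ids <- if (!is.null(characters) && !is.null(characters[["id"]]) &&
               length(characters[["id"]]) == ncol(cells))
      as.character(characters[["id"]])
    colnames(cells) <- if (!is.null(ids)) ids else
      paste0("c", seq_len(ncol(cells)))
  }
  characters <- .complete_characters(characters, cells)
  m <- structure(list(cells = cells, characters = characters,
                      embryo = embryo, adult = adult),
                 class = "character_matrix")
  validate_character_matrix(m)
  m
}

.char_columns <- c("id", "label", "n_states", "category", "region",
                   "recode_policy", "source_char")

.complete_characters <- function(characters, cells) {
  k <- ncol(cells)
  if (is.null(characters)) characters <- data.frame(id = colnames(cells))
  characters <- as.data.frame(characters, stringsAsFactors = FALSE)
  if (is.null(characters$id)) characters$id <- colnames(cells)
  if (is.null(characters$label)) characters$label <- characters$id
  if (is.null(characters$n_states)) {
    obs_max <- suppressWarnings(apply(cells, 2, max, na.rm = TRUE))
    obs_max[!is.finite(obs_max)] <- 1L
    characters$n_states <- pmax(2L, as.integer(obs_max) + 1L)
  }
  if (is.null(characters$category)) characters$category <- "other"
  if (is.null(characters$region)) characters$region <- "other"
  if (is.null(characters$recode_policy)) characters$recode_policy <- "additive"
  if (is.null(characters$source_char)) characters$source_char <- NA_character_
  characters$n_states <- as.integer(characters$n_states)
  characters[, .char_columns]
}

#' Validate a character matrix
#'
#' Checks the structural invariants: metadata rows match columns, at least
#' two declared states per character, single-digit state codes, every cell
#' below its character's state count, and an all-zero embryo row if one is
#' flagged.
#'
#' @param m a `character_matrix`.
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_character_matrix <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  cells <- m$cells
  ch <- m$characters
  if (nrow(ch) != ncol(cells))
    stop("character metadata rows (", nrow(ch),
         ") do not match matrix columns (", ncol(cells), ")")
  if (!identical(ch$id, colnames(cells)))
    stop("character ids do not match matrix column names")
  if (any(ch$n_states < 2L))
    stop("characters must declare n_states >= 2: ",
         paste(ch$id[ch$n_states < 2L], collapse = ", "))
  if (any(ch$n_states > 10L))
    stop("state codes are limited to single digits 0-9")
  bad_pol <- !ch$recode_policy %in% c("additive", "branching")
  if (any(bad_pol & ch$n_states > 2L))
    stop("recode_policy must be 'additive' or 'branching' for ",
         paste(ch$id[bad_pol & ch$n_states > 2L], collapse = ", "))
  if (any(cells < 0L, na.rm = TRUE))
    stop("negative state codes are not allowed")
  over <- sweep(cells, 2, ch$n_states, ">=")
  if (any(over, na.rm = TRUE)) {
    j <- which(apply(over, 2, any, na.rm = TRUE))[1]
    stop("character ", ch$id[j], " has a cell >= its declared n_states (",
         ch$n_states[j], ")")
  }
  for (lab in c(m$embryo, m$adult)) {
    if (!is.null(lab) && !lab %in% rownames(cells))
      stop("flagged specimen '", lab, "' is not a row of the matrix")
  }
  if (!is.null(m$embryo)) {
    row <- cells[m$embryo, ]
    if (any(is.na(row)) || any(row != 0L))
      stop("embryo row must be all zeros with no missing cells")
  }
  invisible(m)
}

#' @export
print.character_matrix <- function(x, ...) {
  cells <- x$cells
  cat("Growth-character matrix: ", nrow(cells), " specimens x ",
      ncol(cells), " characters\n", sep = "")
  n_multi <- sum(x$characters$n_states > 2L)
  cat("  characters: ", ncol(cells) - n_multi, " binary, ", n_multi,
      " multistate; missing cells: ",
      sum(is.na(cells)), " (", round(100 * mean(is.na(cells)), 1), "%)\n",
      sep = "")
  if (!is.null(x$embryo)) cat("  embryo row: ", x$embryo, "\n", sep = "")
  if (!is.null(x$adult))  cat("  adult row:  ", x$adult, "\n", sep = "")
  invisible(x)
}

#' Specimen labels of a character matrix
#' @param m a `character_matrix`.
#' @param real if `TRUE`, drop the embryo/adult artificial rows.
#' @return character vector of specimen labels.
#' @export
specimens <- function(m, real = FALSE) {
  ids <- rownames(m$cells)
  if (real) ids <- setdiff(ids, c(m$embryo, m$adult))
  ids
}
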