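#' Read a growth-character matrix from a NEXUS file
#'
#' Reads a DATA or CHARACTERS block (digit symbols, `MISSING=?`; the
#' inapplicable symbol `-` is read as missing as well) and, optionally, a
#' sidecar tab-separated annotation table carrying per-character metadata
#' that NEXUS has no standard slot for. Rows labelled with the embryo or
#' adult label are recognised, so matrices deposited with these artificial
#' specimens already present are handled without double insertion.
#'
#' @param path NEXUS file path.
#' @param annotations optional path to a TSV with columns `id`, `label`,
#'   `n_states`, `category`, `region`, `recode_policy` (see
#'   [write_char_annotations()]).
#' @param embryo_label,adult_label row labels identifying artificial
#'   specimens if present in the file.
#' @return a [character_matrix()].
#' @export
read_nexus <- function(path, annotations = NULL,
                       embryo_label = "EMBRYO", adult_label = "ADULT") {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- tryCatch(ape::read.nexus.data(path),
                  error = function(e)
                    stop("malformed NEXUS block in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  n <- length(dat)
  k <- length(dat[[1]])
  if (any(lengths(dat) != k))
    stop("ragged matrix: specimens differ in character count")
  dims <- .nexus_declared_dims(path)
  if (!is.na(dims["ntax"]) && dims["ntax"] != n)
    stop("NTAX=", dims["ntax"], " but ", n, " specimens read")
  if (!is.na(dims["nchar"]) && dims["nchar"] != k)
    stop("NCHAR=", dims["nchar"], " but ", k, " characters read")
  syms <- unique(unlist(dat, use.names = FALSE))
  bad <- setdiff(syms, c(as.character(0:9), "?", "-"))
  if (length(bad))
    stop("unknown state symbols: ", paste(bad, collapse = " "))
  cells <- matrix(NA_integer_, n, k,
                  dimnames = list(names(dat), NULL))
  for (i in seq_len(n)) {
    v <- dat[[i]]
    v[v %in% c("?", "-")] <- NA
    cells[i, ] <- as.integer(v)
  }
  chars <- NULL
  if (!is.null(annotations)) {
    chars <- read_char_annotations(annotations)
    if (nrow(chars) != k)
      stop("annotation table has ", nrow(chars),
           " characters but matrix has ", k)
    colnames(cells) <- chars$id
  }
  character_matrix(
    cells, chars,
    embryo = if (embryo_label %in% names(dat)) embryo_label,
    adult = if (adult_label %in% names(dat)) adult_label)
}

.nexus_declared_dims <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  grab <- function(key) {
    mt <- regmatches(txt, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"),
                                  txt, perl = TRUE))
    if (!length(mt)) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", mt))
  }
  c(ntax = grab("NTAX"), nchar = grab("NCHAR"))
}

#' Write a character matrix to NEXUS (plus optional annotation sidecar)
#'
#' @param m a `character_matrix`.
#' @param path output NEXUS path.
#' @param annotations optional path for the sidecar metadata TSV.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path, annotations = NULL) {
  cells <- m$cells
  dat <- lapply(seq_len(nrow(cells)), function(i) {
    v <- as.character(cells[i, ])
    v[is.na(v)] <- "?"
    v
  })
  names(dat) <- rownames(cells)
  ape::write.nexus.data(dat, file = path, format = "standard",
                        interleaved = FALSE)
  if (!is.null(annotations)) write_char_annotations(m, annotations)
  invisible(path)
}

#' Read / write the sidecar character-annotation table
#'
#' The TSV carries one row per character: `id`, `label`, `n_states`,
#' `category` (fusion/texture/ornamentation/other), `region` (nasal,
#' supraorbital, frill, frontal, other), `recode_policy`
#' (additive/branching) and optional `source_char` linking a binary
#' expansion column back to its multistate source.
#'
#' @param path TSV path.
#' @return a data frame of character metadata.
#' @export
read_char_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"id" %in% names(tab)) stop("annotation TSV needs an 'id' column")
  if (!is.null(tab$n_states)) tab$n_states <- as.integer(tab$n_states)
  tab
}

#' @rdname read_char_annotations
#' @param m a `character_matrix` whose metadata should be written.
#' @export
write_char_annotations <- function(m, path) {
  utils::write.table(m$characters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
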