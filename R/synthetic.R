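# Synthetic growth matrices with known maturity ground truth.
#
# Specimens carry a latent maturity drawn uniformly on [0, 1]; each
# character acquires its states at fixed maturity thresholds, so a
# noise-free matrix is a perfect staircase whose unique most parsimonious
# tree is the true pectinate ontogram. Individual variability enters as
# +/- 1-state local deviations (mistimed acquisitions, not scoring
# blunders); taphonomy enters as block missingness, where an "isolated
# element" specimen retains only the characters of one skull region.

#' Define a synthetic growth model
#'
#' Defaults mirror a ceratopsid-skull study design: 47 specimens by 80
#' growth characters (38 two-state, 34 three-state of which 4 use
#' branching coding for alternative adult morphologies, 8 four-state,
#' expanding to 130 additive-binary characters), character regions sized
#' 11 nasal / 11 supraorbital / 34 frill / 4 frontal / 20 other and
#' categories 21 fusion / 6 texture / 12 ornamentation / 41 other, a 5%
#' per-cell deviation rate, 20% isolated-element specimens, and a frill
#' size proxy rising monotonically from 225 to 695 mm with Gaussian noise.
#'
#' @param n_specimens number of real specimens.
#' @param n_states integer vector of declared states per character (length
#'   = number of characters).
#' @param branching logical vector flagging characters whose non-nascent
#'   states are alternative adult morphologies rather than an ordered
#'   sequence.
#' @param regions,categories character vectors assigning each character to
#'   a skull region / proxy category.
#' @param deviation_rate per-cell probability of a +/- 1-state deviation.
#' @param isolated_fraction share of specimens preserved as isolated
#'   elements (all characters outside one region missing).
#' @param size_base,size_range,size_noise_sd size proxy: base value at
#'   maturity 0, span to maturity 1, and noise standard deviation (same
#'   units as the proxy, nominally mm).
#' @return a `growth_model` list.
#' @export
growth_model <- function(n_specimens = 47,
                         n_states = rep(c(2L, 3L, 4L), c(38, 34, 8)),
                         branching = seq_along(n_states) %in%
                           which(n_states == 3L)[1:4],
                         regions = NULL,
                         categories = NULL,
                         deviation_rate = 0.05,
                         isolated_fraction = 0.2,
                         size_base = 225, size_range = 470,
                         size_noise_sd = 30) {
  k <- length(n_states)
  if (any(n_states < 2)) stop("characters need at least 2 states")
  if (length(branching) != k) branching <- rep_len(branching, k)
  if (any(branching & n_states < 3))
    stop("branching coding requires alternative mature states (>= 3)")
  if (is.null(regions) || length(regions) != k) {
    counts <- round(k * c(nasal = 11, supraorbital = 11, frill = 34,
                          frontal = 4, other = 20) / 80)
    counts[length(counts)] <- k - sum(counts[-length(counts)])
    regions <- rep(names(counts), counts)
  }
  if (is.null(categories)) {
    counts <- round(k * c(fusion = 21, texture = 6, ornamentation = 12,
                          other = 41) / 80)
    counts[length(counts)] <- k - sum(counts[-length(counts)])
    categories <- rep(names(counts), counts)
  }
  structure(list(n_specimens = as.integer(n_specimens),
                 n_states = as.integer(n_states),
                 branching = branching,
                 regions = regions, categories = categories,
                 deviation_rate = deviation_rate,
                 isolated_fraction = isolated_fraction,
                 size_base = size_base, size_range = size_range,
                 size_noise_sd = size_noise_sd),
            class = "growth_model")
}

#' Preset growth models
#'
#' `"paper_scale"`: the full default design (47 x 80). `"toy6"`: 6
#' specimens x 12 binary characters, noise- and missingness-free -- binary
#' staircases are fully identifiable (every acquisition is an informative
#' split), so the true pectinate ontogram is the unique most parsimonious
#' tree. `"table3_scale"`: 11 specimens, clean characters, sized for
#' size-proxy correlation work.
#'
#' @param name preset name.
#' @return a `growth_model`.
#' @export
growth_preset <- function(name = c("paper_scale", "toy6", "table3_scale")) {
  switch(match.arg(name),
         paper_scale = growth_model(),
         toy6 = growth_model(n_specimens = 6,
                             n_states = rep(2L, 12),
                             branching = rep(FALSE, 12),
                             deviation_rate = 0, isolated_fraction = 0),
         table3_scale = growth_model(n_specimens = 11,
                                     n_states = rep(c(2L, 3L), c(12, 8)),
                                     branching = rep(FALSE, 20),
                                     deviation_rate = 0,
                                     isolated_fraction = 0))
}

#' Generate a synthetic growth matrix with ground truth
#'
#' @param model a [growth_model()].
#' @param seed integer seed (all generation is seed-deterministic).
#' @param add_embryo append the all-zero hypothetical embryo row.
#' @return list with `matrix` (a `character_matrix`) and `truth`
#'   (`maturity` per specimen, `order` = specimens sorted by maturity,
#'   `thresholds` per character, `alternatives` for branching characters).
#' @export
generate_growth_matrix <- function(model, seed = NULL, add_embryo = TRUE) {
  stopifnot(inherits(model, "growth_model"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- model$n_specimens
  k <- length(model$n_states)
  ids <- sprintf("sp%02d", seq_len(n))
  maturity <- stats::runif(n)
  names(maturity) <- ids
  thresholds <- lapply(seq_len(k), function(j) {
    nt <- if (model$branching[j]) 1L else model$n_states[j] - 1L
    sort(stats::runif(nt))
  })
  alternatives <- vector("list", k)
  cells <- matrix(0L, n, k, dimnames = list(ids, sprintf("chr%02d",
                                                         seq_len(k))))
  for (j in seq_len(k)) {
    if (model$branching[j]) {
      alts <- seq_len(model$n_states[j] - 1L)
      pick <- sample(alts, n, replace = TRUE)
      alternatives[[j]] <- pick
      cells[, j] <- ifelse(maturity > thresholds[[j]], pick, 0L)
    } else {
      cells[, j] <- vapply(maturity, function(u)
        sum(u > thresholds[[j]]), 0L)
    }
  }
  if (model$deviation_rate > 0) {
    dev <- matrix(stats::runif(n * k) < model$deviation_rate, n, k)
    sign <- matrix(sample(c(-1L, 1L), n * k, replace = TRUE), n, k)
    dn <- dimnames(cells)
    cells <- ifelse(dev, pmin(pmax(cells + sign, 0L),
                              rep(model$n_states - 1L, each = n)), cells)
    dimnames(cells) <- dn
  }
  storage.mode(cells) <- "integer"
  chars <- data.frame(
    id = colnames(cells),
    label = paste("growth character", seq_len(k)),
    n_states = model$n_states,
    category = model$categories,
    region = model$regions,
    recode_policy = ifelse(model$branching, "branching", "additive"),
    source_char = NA_character_,
    stringsAsFactors = FALSE)
  m <- character_matrix(cells, chars)
  if (add_embryo) m <- add_hypothetical_embryo(m)
  list(matrix = m,
       truth = list(maturity = maturity,
                    order = ids[order(maturity)],
                    thresholds = thresholds,
                    alternatives = alternatives))
}

#' Apply isolated-element block missingness
#'
#' A configurable fraction of specimens is turned into "isolated elements":
#' each retains the characters of a single skull region (drawn with
#' probability proportional to region size) and is missing everywhere else.
#' The embryo and adult rows are never masked.
#'
#' @param m a `character_matrix` whose characters carry region labels.
#' @param model a [growth_model()] providing `isolated_fraction`.
#' @param seed integer seed.
#' @return list with `matrix` (masked copy) and `isolated` (labels of the
#'   specimens reduced to isolated elements).
#' @export
apply_missingness <- function(m, model, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  frac <- model$isolated_fraction
  real <- specimens(m, real = TRUE)
  if (frac <= 0)
    return(list(matrix = m, isolated = character(0)))
  iso <- real[stats::runif(length(real)) < frac]
  regions <- m$characters$region
  cells <- m$cells
  for (sp in iso) {
    keep_region <- sample(regions, 1)  # proportional to region size
    cells[sp, regions != keep_region] <- NA_integer_
  }
  list(matrix = character_matrix(cells, m$characters, embryo = m$embryo,
                                 adult = m$adult),
       isolated = iso)
}

#' Generate the size proxy from ground truth
#'
#' Size = base + range * maturity + Gaussian noise: monotone in maturity up
#' to noise, mimicking a frill-length measurement.
#'
#' @param truth the `truth` element of [generate_growth_matrix()] output.
#' @param model a [growth_model()].
#' @param seed integer seed.
#' @return data frame: `specimen`, `size`, `size_rank` (mid-ranks).
#' @export
generate_size_proxy <- function(truth, model, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  mu <- truth$maturity
  size <- model$size_base + model$size_range * mu +
    stats::rnorm(length(mu), sd = model$size_noise_sd)
  data.frame(specimen = names(mu), size = size, size_rank = rank(size),
             stringsAsFactors = FALSE, row.names = NULL)
}
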