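test_that("a minimal two-taxon NEXUS matrix parses", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=1;",
               "FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"0123456789\";",
               "MATRIX", "A 0", "B 1", ";", "END;"), f)
  m <- read_nexus(f)
  expect_equal(dim(m$cells), c(2L, 1L))
  expect_equal(unname(m$cells[, 1]), c(0L, 1L))
})

test_that("declared dimensions and symbols are enforced", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=3 NCHAR=1;",
               "FORMAT DATATYPE=STANDARD MISSING=?;",
               "MATRIX", "A 0", "B 1", ";", "END;"), f)
  expect_error(read_nexus(f), "NTAX|malformed")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=1;",
               "FORMAT DATATYPE=STANDARD MISSING=?;",
               "MATRIX", "A X", "B 1", ";", "END;"), f)
  expect_error(read_nexus(f), "symbol")
})

test_that("write/read round-trips cells and metadata exactly", {
  for (seed in 1:3) {
    g <- generate_growth_matrix(
      growth_model(n_specimens = 10, n_states = rep(c(2L, 3L, 4L), 4),
                   branching = rep(FALSE, 12), deviation_rate = 0.1),
      seed = seed)
    m <- g$matrix
    f <- tempfile(fileext = ".nex"); a <- tempfile(fileext = ".tsv")
    write_nexus(m, f, annotations = a)
    m2 <- read_nexus(f, annotations = a)
    expect_identical(unname(m$cells), unname(m2$cells))
    expect_identical(m$characters, m2$characters)
    expect_identical(m2$embryo, m$embryo)
  }
})

test_that("the hypothetical embryo is an all-zero flagged row", {
  m <- random_matrix(5, 4, embryo = FALSE)
  me <- add_hypothetical_embryo(m)
  expect_equal(nrow(me$cells), nrow(m$cells) + 1L)
  expect_true(all(me$cells["EMBRYO", ] == 0L))
  expect_identical(me$embryo, "EMBRYO")
  expect_error(add_hypothetical_embryo(me), "embryo")
  # embryo plus an all-zero specimen cost nothing on any topology
  cells <- matrix(0L, 2, 6, dimnames = list(c("z1", "z2"), NULL))
  m0 <- add_hypothetical_embryo(character_matrix(cells))
  star <- ape::read.tree(text = "(EMBRYO,z1,z2);")
  expect_equal(tree_length(star, m0), 0L)
})

test_that("the artificial adult defaults to every maximum state", {
  m <- random_matrix(5, 4, max_state = 1, embryo = TRUE)
  ma <- add_artificial_adult(m)
  expect_true(all(ma$cells["ADULT", ] == 1L))
  expect_identical(ma$adult, "ADULT")
  expect_error(add_artificial_adult(ma), "adult")
  expect_error(add_artificial_adult(m, mature_states = c(1L, 1L)),
               "one state per character")
  m3 <- random_matrix(5, 4, max_state = 2, embryo = TRUE)
  expect_true(all(add_artificial_adult(m3)$cells["ADULT", ] == 2L))
})

test_that("deduplication removes identical and all-zero codings, once", {
  cells <- rbind(a = c(0L, 1L, NA, 2L),
                 b = c(0L, 1L, NA, 2L),   # duplicate of a, missing included
                 c = c(0L, 1L, 0L, 2L),   # distinct: ? is not a wildcard
                 d = c(0L, 0L, NA, 0L),   # all coded cells zero
                 e = c(1L, 0L, 0L, 0L))
  m <- add_hypothetical_embryo(character_matrix(cells))
  dd <- deduplicate_specimens(m)
  expect_setequal(rownames(dd$matrix$cells), c("a", "c", "e", "EMBRYO"))
  expect_equal(dd$log$retained[dd$log$removed == "b"], "a")
  expect_equal(dd$log$reason[dd$log$removed == "d"], "all_zero")
  # idempotent
  dd2 <- deduplicate_specimens(dd$matrix)
  expect_identical(dd2$matrix$cells, dd$matrix$cells)
  expect_equal(nrow(dd2$log), 0L)
  # no duplicates -> unchanged with empty log
  clean <- deduplicate_specimens(add_hypothetical_embryo(
    random_matrix(4, 5, embryo = FALSE)))
  expect_equal(nrow(clean$log), 0L)
})

test_that("additive recoding expands state s into s leading ones", {
  cells <- cbind(tri = c(0L, 1L, 2L, NA), bin = c(0L, 1L, 0L, 1L))
  rownames(cells) <- paste0("t", 1:4)
  m <- character_matrix(cells, data.frame(
    id = c("tri", "bin"), n_states = c(3L, 2L),
    recode_policy = "additive"))
  b <- to_additive_binary(m)
  expect_equal(ncol(b$cells), 3L)
  expect_equal(unname(b$cells[, "tri.1"]), c(0L, 1L, 1L, NA))
  expect_equal(unname(b$cells[, "tri.2"]), c(0L, 0L, 1L, NA))
  expect_equal(unname(b$cells[, "bin"]), unname(cells[, "bin"]))
  expect_equal(b$characters$source_char, c("tri", "tri", "bin"))
  expect_equal(nrow(b$cells), nrow(m$cells))
})

test_that("branching recoding scores each alternative mature state alone", {
  cells <- cbind(alt = c(0L, 1L, 2L, NA))
  rownames(cells) <- paste0("t", 1:4)
  m <- character_matrix(cells, data.frame(
    id = "alt", n_states = 3L, recode_policy = "branching"))
  b <- to_additive_binary(m)
  expect_equal(unname(b$cells[, "alt.1"]), c(0L, 1L, 0L, NA))
  expect_equal(unname(b$cells[, "alt.2"]), c(0L, 0L, 1L, NA))
})

test_that("the default design expands 80 multistate to 130 binary characters", {
  g <- generate_growth_matrix(growth_preset("paper_scale"), seed = 1)
  expect_equal(ncol(g$matrix$cells), 80L)
  b <- to_additive_binary(g$matrix)
  expect_equal(ncol(b$cells), 130L)
  expect_equal(nrow(b$cells), nrow(g$matrix$cells))
  expect_true(all(b$characters$n_states == 2L))
})

test_that("fully additive recoding preserves ordered tree length", {
  # binary length on a fixed tree equals the ordered-multistate length
  for (seed in 1:3) {
    set.seed(seed)
    cells <- matrix(sample(0:3, 6 * 4, TRUE), 6, 4,
                    dimnames = list(paste0("t", 1:6), NULL))
    m <- character_matrix(cells,
                          data.frame(id = paste0("c", 1:4), n_states = 4L,
                                     recode_policy = "additive"))
    tr <- random_tree(m, seed = seed)
    bin_len <- tree_length(tr, to_additive_binary(m))
    ordered_len <- oracle_length(tr, m, cost_fn = function(a, b) abs(a - b))
    expect_equal(bin_len, ordered_len)
  }
})

test_that("specimen subsetting keeps the embryo and all characters", {
  m <- staircase_matrix(6)
  s <- subset_specimens(m, c("t1", "t4"))
  expect_setequal(rownames(s$cells), c("t1", "t4", "EMBRYO"))
  expect_equal(ncol(s$cells), ncol(m$cells))
  expect_identical(s$cells["t4", ], m$cells["t4", ])
  expect_true(length(attr(s, "constant_chars")) > 0)
  expect_error(subset_specimens(m, "nope"), "unknown")
  # keep-all is the identity on cells
  all_ids <- specimens(m)
  expect_identical(subset_specimens(m, all_ids)$cells, m$cells)
})
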