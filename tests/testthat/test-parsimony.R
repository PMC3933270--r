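test_that("degenerate characters contribute no steps", {
  cells <- matrix(1L, 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  m <- character_matrix(cells)
  tr <- random_tree(m, seed = 1)
  expect_equal(tree_length(tr, m), 0L)
  # a character scored ? everywhere contributes nothing
  cells2 <- cbind(c(0L, 1L, 0L, 1L), NA_integer_)
  rownames(cells2) <- paste0("t", 1:4)
  m2 <- character_matrix(cells2, data.frame(id = c("a", "b"),
                                            n_states = 2L))
  per <- tree_length(random_tree(m2, seed = 2), m2, per_character = TRUE)
  expect_equal(per[2], 0L)
})

test_that("tree length equals the exhaustive assignment minimum", {
  for (seed in 1:8) {
    m <- random_matrix(6, 5, max_state = 2, na_frac = 0.15, seed = seed)
    tr <- random_tree(m, seed = seed + 100)
    expect_equal(tree_length(tr, m), oracle_length(tr, m),
                 info = paste("seed", seed))
  }
})

test_that("tree length matches an independent Fitch implementation", {
  for (seed in 1:4) {
    m <- random_matrix(7, 10, max_state = 3, na_frac = 0.1, seed = seed,
                       embryo = FALSE)
    tr <- random_tree(m, seed = seed)
    pd <- phangorn::phyDat(m$cells, type = "USER", levels = 0:3,
                           ambiguity = NA)
    expect_equal(tree_length(tr, m),
                 as.integer(phangorn::fitch(ape::unroot(tr), pd)))
  }
})

test_that("length is invariant to child order and embryo-edge rerooting", {
  m <- random_matrix(7, 6, seed = 3)
  tr <- random_tree(m, seed = 5)
  L <- tree_length(tr, m)
  expect_equal(tree_length(ape::ladderize(tr), m), L)
  expect_equal(tree_length(ape::ladderize(tr, right = FALSE), m), L)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "t3",
                        resolve.root = TRUE)
  expect_equal(tree_length(rerooted, m), L)
})

test_that("hard polytomies are scored by the minimum-mutation rule", {
  # star with tip states 0,0,1,1 needs two changes (sequential binary
  # Fitch along an arbitrary resolution would undercount)
  cells <- matrix(c(0L, 0L, 1L, 1L), 4, 1,
                  dimnames = list(paste0("t", 1:4), NULL))
  m <- character_matrix(cells)
  star <- ape::read.tree(text = "(t1,t2,t3,t4);")
  expect_equal(tree_length(star, m), 2L)
  expect_equal(oracle_length(star, m), 2)
  # random multifurcating trees against the oracle
  for (seed in 1:4) {
    m <- random_matrix(6, 4, max_state = 2, na_frac = 0.1, seed = seed,
                       embryo = FALSE)
    set.seed(seed)
    tr <- ape::rtree(6, tip.label = sample(rownames(m$cells)))
    # collapse a random internal edge to force a polytomy
    nt <- length(tr$tip.label)
    internal_edges <- which(tr$edge[, 2] > nt)
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr$edge.length[sample(internal_edges, 1)] <- 0
    tr <- ape::di2multi(tr)
    tr$edge.length <- NULL
    expect_equal(tree_length(tr, m), oracle_length(tr, m),
                 info = paste("seed", seed))
  }
})

test_that("minimum steps count distinct observed states minus one", {
  cells <- cbind(c(1L, 1L, 1L, NA),      # constant
                 c(0L, 1L, 2L, 2L),      # three states
                 c(NA, NA, NA, NA),      # all missing
                 c(0L, 3L, NA, 0L))      # two states observed
  rownames(cells) <- paste0("t", 1:4)
  m <- character_matrix(cells, data.frame(id = paste0("c", 1:4),
                                          n_states = 4L,
                                          recode_policy = "additive"))
  expect_equal(unname(min_steps(m)), c(0L, 2L, 0L, 1L))
})

test_that("per-character steps are bounded below by the minimum", {
  for (seed in 1:4) {
    m <- random_matrix(7, 8, max_state = 3, na_frac = 0.2, seed = seed)
    tr <- random_tree(m, seed = seed)
    s <- tree_length(tr, m, per_character = TRUE)
    expect_true(all(s >= min_steps(m)))
  }
})

test_that("tip/matrix mismatches are rejected", {
  m <- random_matrix(5, 4)
  tr <- ape::rtree(5, tip.label = paste0("x", 1:5))
  expect_error(tree_length(tr, m), "differ")
})
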