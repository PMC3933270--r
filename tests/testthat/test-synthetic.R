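test_that("generation is seed-deterministic", {
  gm <- growth_preset("paper_scale")
  a <- generate_growth_matrix(gm, seed = 5)
  b <- generate_growth_matrix(gm, seed = 5)
  expect_identical(a$matrix$cells, b$matrix$cells)
  expect_identical(a$truth, b$truth)
  c <- generate_growth_matrix(gm, seed = 6)
  expect_false(identical(a$matrix$cells, c$matrix$cells))
})

test_that("a noise-free model yields a staircase identifying the true order", {
  # binary characters: every acquisition is an informative split, so the
  # pectinate ontogram of the true maturity order is the unique MPT
  gm <- growth_model(n_specimens = 7, n_states = rep(2L, 14),
                     branching = rep(FALSE, 14), deviation_rate = 0,
                     isolated_fraction = 0)
  for (seed in c(2, 9)) {
    g <- generate_growth_matrix(gm, seed = seed)
    m <- g$matrix
    # cells are monotone along the true maturity order (perfect staircase)
    ordered <- m$cells[g$truth$order, ]
    expect_true(all(apply(ordered, 2, function(v) all(diff(v) >= 0))))
    dd <- deduplicate_specimens(m)
    bb <- branch_and_bound(dd$matrix)
    expect_equal(length(bb$trees), 1L)
    kept_order <- g$truth$order[g$truth$order %in%
                                  specimens(dd$matrix, real = TRUE)]
    expect_setequal(clade_keys(bb$trees[[1]]),
                    clade_keys(pectinate_tree(kept_order)))
    expect_equal(consistency_index(bb$trees[[1]], dd$matrix)$ensemble_ci, 1)
  }
  # with unordered multistate characters, intermediate states held by a
  # single specimen are uninformative, so ties can arise; the true
  # pectinate tree still attains the optimum and CI stays 1
  gmm <- growth_model(n_specimens = 7, n_states = rep(c(2L, 3L), c(6, 4)),
                      branching = rep(FALSE, 10), deviation_rate = 0,
                      isolated_fraction = 0)
  g <- generate_growth_matrix(gmm, seed = 2)
  dd <- deduplicate_specimens(g$matrix)
  bb <- branch_and_bound(dd$matrix)
  kept_order <- g$truth$order[g$truth$order %in%
                                specimens(dd$matrix, real = TRUE)]
  expect_equal(tree_length(pectinate_tree(kept_order), dd$matrix),
               bb$best_length)
  expect_equal(consistency_index(bb$trees[[1]], dd$matrix)$ensemble_ci, 1)
})

test_that("the realized deviation rate matches the configured rate", {
  base <- growth_model(n_specimens = 30,
                       n_states = rep(c(2L, 3L), c(20, 20)),
                       branching = rep(FALSE, 40), deviation_rate = 0,
                       isolated_fraction = 0)
  noisy <- base; noisy$deviation_rate <- 0.05
  # a +/-1 draw at a boundary state (0 or the maximum) clamps back to the
  # same value half the time, so the expected visible flip rate is
  # eps * (1 - 0.5 * P(boundary state)), computable from the clean cells
  obs <- exp <- numeric(10)
  for (s in 1:10) {
    gc_ <- generate_growth_matrix(base, seed = s)
    gd <- generate_growth_matrix(noisy, seed = s)
    real <- specimens(gc_$matrix, real = TRUE)
    clean <- gc_$matrix$cells[real, ]
    dirty <- gd$matrix$cells[real, ]
    top <- rep(base$n_states - 1L, each = nrow(clean))
    boundary <- clean == 0L | clean == top
    obs[s] <- mean(clean != dirty)
    exp[s] <- 0.05 * (1 - 0.5 * mean(boundary))
  }
  n_cells <- 30 * 40 * 10
  se <- sqrt(mean(exp) * (1 - mean(exp)) / n_cells)
  expect_gt(mean(obs), mean(exp) - 3 * se)
  expect_lt(mean(obs), mean(exp) + 3 * se)
})

test_that("isolated specimens retain exactly one region", {
  gm <- growth_preset("paper_scale")
  g <- generate_growth_matrix(gm, seed = 3)
  mm <- apply_missingness(g$matrix, gm, seed = 4)
  expect_gt(length(mm$isolated), 0)
  regions <- g$matrix$characters$region
  for (sp in mm$isolated) {
    coded <- !is.na(mm$matrix$cells[sp, ])
    expect_equal(length(unique(regions[coded])), 1L)
    expect_true(all(!coded | regions == unique(regions[coded])))
  }
  # untouched specimens keep their cells; fraction roughly as configured
  kept <- setdiff(specimens(g$matrix, real = TRUE), mm$isolated)
  expect_identical(mm$matrix$cells[kept, ], g$matrix$cells[kept, ])
  frac <- vapply(1:20, function(s)
    length(apply_missingness(g$matrix, gm, seed = s)$isolated) / 47, 0)
  expect_gt(mean(frac), 0.2 - 3 * sqrt(0.2 * 0.8 / (47 * 20)))
  expect_lt(mean(frac), 0.2 + 3 * sqrt(0.2 * 0.8 / (47 * 20)))
  # probability zero is the identity
  gm0 <- gm; gm0$isolated_fraction <- 0
  expect_identical(apply_missingness(g$matrix, gm0, seed = 1)$matrix$cells,
                   g$matrix$cells)
})

test_that("the size proxy is monotone in maturity up to noise", {
  gm <- growth_preset("table3_scale")
  g <- generate_growth_matrix(gm, seed = 8)
  gm0 <- gm; gm0$size_noise_sd <- 0
  sz <- generate_size_proxy(g$truth, gm0, seed = 1)
  expect_equal(spearman_rank(rank(g$truth$maturity), sz$size)$p, 1)
  expect_true(all(sz$size >= gm$size_base))
  expect_true(all(sz$size <= gm$size_base + gm$size_range))
  # rising noise degrades the expected correlation monotonically
  mean_rho <- vapply(c(0, 60, 400), function(sd) {
    gmx <- gm; gmx$size_noise_sd <- sd
    mean(vapply(1:15, function(s) {
      gg <- generate_growth_matrix(gm, seed = s)
      s2 <- generate_size_proxy(gg$truth, gmx, seed = s + 500)
      spearman_rank(rank(gg$truth$maturity), s2$size)$p
    }, 0))
  }, 0)
  expect_true(all(diff(mean_rho) < 0))
  expect_equal(mean_rho[1], 1)
})
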