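test_that("simulation is deterministic and dimensioned by its config", {
  s1 <- simulate_dataset(n_genes = 200, m_groups = 4, n_reps = 3,
                         n_regulated_sets = 2, set_size = 10,
                         n_corr_blocks = 2, block_size = 20, seed = 5)
  s2 <- simulate_dataset(n_genes = 200, m_groups = 4, n_reps = 3,
                         n_regulated_sets = 2, set_size = 10,
                         n_corr_blocks = 2, block_size = 20, seed = 5)
  expect_identical(s1$dataset$values, s2$dataset$values)
  expect_equal(dim(s1$dataset), c(200L, 12L))
  expect_equal(length(s1$regulated_sets), 2L)
  expect_equal(unname(group_sizes(s1$dataset)), rep(3L, 4))

  s3 <- simulate_dataset(n_genes = 200, m_groups = 4, n_reps = 3,
                          n_regulated_sets = 2, set_size = 10,
                          n_corr_blocks = 2, block_size = 20, seed = 6)
  expect_false(identical(s1$dataset$values[1, 1], s3$dataset$values[1, 1]))

  expect_error(simulate_dataset(n_genes = 50, n_regulated_sets = 10,
                                set_size = 10, n_corr_blocks = 0),
               "infeasible")
})

test_that("null configuration produces no group differences beyond chance", {
  sim <- simulate_dataset(n_genes = 4000, m_groups = 2, n_reps = 5,
                          effect_size = 0, n_regulated_sets = 0,
                          n_corr_blocks = 0, seed = 8)
  x <- sim$dataset$values
  a <- x[, 1:5]; b <- x[, 6:10]
  # per-gene Welch t; under Gaussian null the alpha=0.001 rejection rate
  # should sit at its nominal level
  tt <- (rowMeans(a) - rowMeans(b)) /
    sqrt(apply(a, 1, var) / 5 + apply(b, 1, var) / 5)
  df <- 8  # conservative (equal variances); exact Welch df is close
  rate <- mean(abs(tt) > qt(0.9995, df))
  expect_lt(rate, 0.005)
})

test_that("planted sets shift means only in their designated group", {
  sim <- simulate_dataset(n_genes = 300, m_groups = 3, n_reps = 50,
                          n_regulated_sets = 3, set_size = 20,
                          effect_size = 1, noise_sd = 1,
                          n_corr_blocks = 0, seed = 9)
  x <- sim$dataset$values
  for (nm in names(sim$regulated_sets)) {
    g <- sim$affected_group[[nm]]
    rows <- sim$regulated_sets$sets[[nm]]
    in_g <- mean(x[rows, sim$dataset$groups == g])
    out_g <- mean(x[rows, sim$dataset$groups != g])
    # 20 genes x 50 reps: the planted +1 shift is estimated within ~0.15
    expect_equal(in_g - out_g, 1, tolerance = 0.15)
  }
})

test_that("correlation blocks achieve the requested pairwise correlation", {
  sim <- simulate_dataset(n_genes = 200, m_groups = 20, n_reps = 3,
                          n_regulated_sets = 0, n_corr_blocks = 1,
                          block_size = 50, block_rho = 0.8, seed = 10)
  x <- sim$dataset$values
  blk <- x[151:200, ]  # blocks occupy the tail of the gene list
  cm <- cor(t(blk))
  mean_off <- mean(cm[upper.tri(cm)])
  expect_gt(mean_off, 0.7)
  expect_lt(mean_off, 0.9)
  # non-block genes stay essentially uncorrelated
  cm0 <- cor(t(x[1:50, ]))
  expect_lt(abs(mean(cm0[upper.tri(cm0)])), 0.1)
})

test_that("label randomization preserves the matrix and group sizes", {
  ds <- tiny_dataset(m_groups = 3, n_reps = 5)
  nd <- make_null_dataset(ds, seed = 3)
  expect_identical(nd$values, ds$values)
  expect_equal(group_sizes(nd), group_sizes(ds))
  expect_identical(make_null_dataset(ds, seed = 3)$groups, nd$groups)
  expect_error(make_null_dataset(
    expression_dataset(ds$values, rep("A", 15)), 1), "2 groups")
})

test_that("label randomization assigns labels uniformly across samples", {
  ds <- tiny_dataset(m_groups = 3, n_reps = 5)  # 15 samples, 5 per group
  hits <- numeric(ncol(ds$values))
  n_seeds <- 400
  for (s in seq_len(n_seeds)) {
    nd <- make_null_dataset(ds, seed = s)
    hits <- hits + (nd$groups == "G1")
  }
  freq <- hits / n_seeds
  # each sample receives label G1 with probability 5/15; 4 sigma tolerance
  tol <- 4 * sqrt((1 / 3) * (2 / 3) / n_seeds)
  expect_true(all(abs(freq - 1 / 3) < tol))
})

test_that("gene set dilution replaces the documented number of members", {
  specific <- sprintf("s%02d", 1:10)
  pool <- sprintf("p%02d", 1:50)
  expect_identical(dilute_gene_set(specific, 0, pool, 1), specific)
  d90 <- dilute_gene_set(specific, 90, pool, 2)
  expect_length(d90, 10)
  expect_length(intersect(d90, specific), 1)   # only 10% retained
  d50 <- dilute_gene_set(specific, 50, pool, 3)
  expect_length(d50, 10)
  expect_length(intersect(d50, specific), 5)
  expect_true(all(setdiff(d50, specific) %in% pool))
  expect_error(dilute_gene_set(specific, 90, pool[1:3], 1), "too small")
  expect_error(dilute_gene_set(specific, 50, c(pool, specific[1]), 1),
               "disjoint")
})

test_that("benchmark sets grade their co-regulated fraction from 0 to 1", {
  sim <- simulate_dataset(n_genes = 600, m_groups = 3, n_reps = 3,
                          n_regulated_sets = 0, n_corr_blocks = 4,
                          block_size = 30, block_rho = 0.4, seed = 13)
  bm <- benchmark_sets(sim, n_sets = 20, size_range = c(10, 30), seed = 14)
  expect_length(bm, 20)
  sz <- vapply(bm$sets, length, 1L)
  expect_true(all(sz >= 10 & sz <= 30))
  block_genes <- rownames(sim$dataset$values)[481:600]
  frac <- vapply(bm$sets, function(g) mean(g %in% block_genes), 1)
  expect_equal(unname(frac[1]), 0)
  expect_equal(unname(frac[20]), 1)
  expect_gt(cor(frac, seq_len(20)), 0.95)
})

test_that("simulations round-trip through the three standard files", {
  sim <- simulate_dataset(n_genes = 60, m_groups = 3, n_reps = 3,
                          n_regulated_sets = 1, set_size = 5,
                          n_corr_blocks = 0, seed = 15)
  dir <- tempfile(); paths <- write_simulation(sim, dir)
  back <- read_expression(paths["matrix"], paths["groups"])
  expect_equal(back$values, sim$dataset$values, tolerance = 1e-6)
  expect_identical(back$groups, sim$dataset$groups)
  gmt <- read_gmt(paths["gmt"])
  expect_equal(gmt$sets, sim$regulated_sets$sets)
})
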