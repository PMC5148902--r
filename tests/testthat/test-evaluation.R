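test_that("stratified splits have the documented sizes and are disjoint", {
  sim <- simulate_dataset(n_genes = 50, m_groups = 3, n_reps = 16,
                          n_regulated_sets = 0, n_corr_blocks = 0, seed = 71)
  sp <- split_dataset(sim$dataset, seed = 1)
  expect_equal(unname(group_sizes(sp$test)), rep(4L, 3))       # round(.25*16)
  expect_equal(unname(group_sizes(sp$reference)), rep(12L, 3))
  expect_length(intersect(colnames(sp$test$values),
                          colnames(sp$reference$values)), 0)
  expect_setequal(c(colnames(sp$test$values), colnames(sp$reference$values)),
                  colnames(sim$dataset$values))
  small <- tiny_dataset(m_groups = 2, n_reps = 2)  # round(0.25 * 2) = 0
  expect_error(split_dataset(small), "too small")
})

test_that("splits stratify test membership at the target fraction", {
  sim <- simulate_dataset(n_genes = 20, m_groups = 2, n_reps = 8,
                          n_regulated_sets = 0, n_corr_blocks = 0, seed = 72)
  counts <- numeric(16)
  n_seeds <- 60
  keys <- character(n_seeds)
  for (s in seq_len(n_seeds)) {
    sp <- split_dataset(sim$dataset, seed = s)
    idx <- match(colnames(sp$test$values), colnames(sim$dataset$values))
    counts[idx] <- counts[idx] + 1
    keys[s] <- paste(sort(idx), collapse = ",")
  }
  expect_gt(length(unique(keys)), n_seeds / 2)  # splits actually vary
  freq <- counts / n_seeds
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / n_seeds)))
})

test_that("reference sets are unions of top-n names", {
  r1 <- c("a", "b", "c", "d"); r2 <- c("x", "y", "z", "a")
  refs <- build_reference_sets(list(r1, r2), n_values = c(3, 5))
  expect_setequal(refs[["3"]], c("a", "b", "c", "x", "y", "z"))
  expect_setequal(build_reference_sets(list(r1), 3)[["3"]], c("a", "b", "c"))
  expect_setequal(build_reference_sets(list(r1, r1), 4)[["4"]], r1)
})

test_that("cumulative count curves count reference hits by rank", {
  ranking <- sprintf("s%02d", 1:60)
  expect_equal(cumulative_count_curve(ranking, ranking, 50), 1:50)
  expect_equal(cumulative_count_curve(ranking, c("zz"), 50), rep(0L, 50))
  # hand-built: hits at ranks 2, 3, 7 of a 10-item ranking
  cv <- cumulative_count_curve(sprintf("s%02d", 1:10),
                               c("s02", "s03", "s07", "s99"), 10)
  expect_equal(cv, c(0, 1, 2, 2, 2, 2, 3, 3, 3, 3))
  expect_warning(cumulative_count_curve(ranking[1:10], "s01", 50),
                 "truncated")
})

test_that("PR-AUC matches direct precision-recall integration", {
  # positives at ranks 2 and 5 of 6: AP = (1/2) (1/2 + 2/5)
  expect_equal(pr_auc(c("n1", "p1", "n2", "n3", "p2", "n4"), c("p1", "p2")),
               0.45)
  expect_equal(pr_auc(c("p1", "p2", "n1"), c("p1", "p2")), 1)
  expect_equal(pr_auc(c("n1", "n2"), c("p1")), 0)
  # positives missing from the ranking dilute the score
  expect_equal(pr_auc(c("p1", "n1"), c("p1", "p2")), 0.5)
})

test_that("the type-1 harness itself is calibrated", {
  ds <- tiny_dataset(m_groups = 2, n_reps = 3)
  unif <- function(nd, seed) { set.seed(seed); runif(300) }
  r <- type1_error_experiment(ds, NULL, "G1", "G2", n_repeats = 3,
                              seed = 5, pipeline_fun = unif)
  expect_gt(r$ks_p, 0.05)
  expect_lt(abs(r$frac_below_05 - 0.05), 0.03)
  const <- function(nd, seed) rep(0.01, 300)
  r2 <- type1_error_experiment(ds, NULL, "G1", "G2", n_repeats = 3,
                               seed = 5, pipeline_fun = const)
  expect_lt(r2$ks_p, 1e-6)
  boom <- function(nd, seed) stop("nope")
  expect_error(type1_error_experiment(ds, NULL, "G1", "G2", n_repeats = 2,
                                      seed = 5, pipeline_fun = boom),
               "repeat 1")
})

test_that("diluted planted sets separate from random sets under strong signal", {
  sim <- simulate_dataset(n_genes = 500, m_groups = 4, n_reps = 3,
                          n_regulated_sets = 4, set_size = 12,
                          effect_size = 3, n_corr_blocks = 2,
                          block_size = 25, seed = 73)
  r <- tissue_benchmark(sim, x_grid = c(0, 50), n_random_sets = 12,
                        seed = 1, pairs = list(c("G1", "G2")),
                        n_perm = 80, params = gsz_params(min_size = 3))
  expect_s3_class(r, "mgszm_tissue_eval")
  expect_true(all(diff(r$mean_curve) >= 0))
  expect_gt(r$mean_pr_auc, 0.8)   # 4 relevant sets, 2 dilution levels
  expect_equal(nrow(r$per_pair), 1)
  expect_equal(r$per_pair$n_relevant, 4)  # 2 planted sets x 2 dilutions
})

test_that("permutation-scheme concordance reports coherent metrics", {
  sim <- simulate_dataset(n_genes = 300, m_groups = 5, n_reps = 8,
                          n_regulated_sets = 0, n_corr_blocks = 4,
                          block_size = 25, block_rho = 0.4, seed = 74)
  bm <- benchmark_sets(sim, n_sets = 15, size_range = c(8, 25), seed = 75)
  cc <- validate_perm_concordance(sim$dataset, bm, "G1", "G2",
                                  n_perm = 150, seed = 1, half_size = 4)
  expect_s3_class(cc, "mgszm_concordance")
  expect_equal(cc$n_sets + cc$n_failed, 15)
  expect_true(abs(cc$cor_location) <= 1 && abs(cc$cor_scale) <= 1)
  expect_gte(cc$mre_location, 0)
  expect_gte(cc$mre_scale, 0)
  expect_equal(nrow(cc$per_set), cc$n_sets)
  # identical parameter vectors give perfect concordance metrics by
  # construction of the formulas (correlation 1, MRE 0)
  ps <- cc$per_set
  expect_equal(stats::cor(ps$loc_perm1, ps$loc_perm1), 1)
  expect_equal(mean(abs(ps$loc_perm1 - ps$loc_perm1) / abs(ps$loc_perm1)), 0)
})

test_that("the data-splitting driver produces averaged curves per config", {
  sim <- simulate_dataset(n_genes = 250, m_groups = 4, n_reps = 8,
                          n_regulated_sets = 4, set_size = 10,
                          effect_size = 1.5, n_corr_blocks = 0, seed = 76)
  genes <- rownames(sim$dataset$values)
  set.seed(77)
  rand <- stats::setNames(lapply(1:8, function(i) sample(genes, 10)),
                          sprintf("R%02d", 1:8))
  coll <- gene_set_collection(c(sim$regulated_sets$sets, rand))
  r <- suppressWarnings(split_eval(
    sim$dataset, coll, "G1", "G2",
    configs = list(perm4 = list(perm_method = "perm4"),
                   perm1 = list(perm_method = "perm1")),
    n_values = c(2, 3), n_repeats = 2, seed = 1, max_rank = 12,
    n_perm = 60, half_size = 2, params = gsz_params(min_size = 3)))
  expect_s3_class(r, "mgszm_split_eval")
  expect_named(r$mean_curves, c("perm4", "perm1"))
  for (cv in r$mean_curves) {
    expect_true(all(diff(cv) >= 0))
    expect_true(all(cv >= 0 & cv <= 12))
  }
})
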