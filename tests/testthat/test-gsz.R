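test_that("running null moments match exhaustive subset enumeration", {
  s <- c(3, 2, 1, 0, -1)
  mom <- running_null_moments(s, 2)
  oracle <- enum_running_moments(s, 2)
  expect_equal(mom$expectation, oracle$expectation, tolerance = 1e-10)
  expect_equal(mom$variance, oracle$variance, tolerance = 1e-10)
})

test_that("running null moments match enumeration across sizes and scores", {
  set.seed(41)
  for (N in c(5, 8, 12)) {
    s <- round(rnorm(N), 3)
    for (M in 1:min(4, N - 1)) {
      mom <- running_null_moments(s, M)
      oracle <- enum_running_moments(s, M)
      expect_equal(mom$expectation, oracle$expectation, tolerance = 1e-10)
      expect_equal(mom$variance, oracle$variance, tolerance = 1e-10)
    }
  }
})

test_that("running null moments handle degenerate and symmetric cases", {
  s <- rep(2, 6)
  mom <- running_null_moments(s, 3)
  expect_equal(mom$variance[6], 0, tolerance = 1e-12)  # constant subset sum
  s2 <- c(1.5, 0.2, -0.7, 2.2, 0.9)
  vM <- running_null_moments(s2, 2)$variance[5]
  vC <- running_null_moments(s2, 3)$variance[5]
  expect_equal(vM, vC, tolerance = 1e-12)  # complement symmetry at i = N
  expect_error(running_null_moments(s2, 5), "M < N")
  expect_error(running_null_moments(s2, 0), "1 <= M")
})

graded_scores <- function(N = 20) {
  stats::setNames(as.numeric(N:1), sprintf("g%02d", seq_len(N)))
}

test_that("a set of the top-k genes peaks exactly at the set boundary", {
  s <- graded_scores(20)
  prof <- gsz_score(s, names(s)[1:5], gsz_params(min_size = 2))
  expect_equal(prof$argmax_position, 5L)
  expect_equal(prof$direction, "up")
  expect_gt(prof$max_score, 0)
})

test_that("all-zero scores give an identically zero profile", {
  s <- stats::setNames(rep(0, 15), sprintf("g%02d", 1:15))
  prof <- gsz_score(s, names(s)[3:8], gsz_params(min_size = 2))
  expect_equal(prof$max_score, 0)
  expect_true(all(prof$z_up == 0) && all(prof$z_down == 0))
})

test_that("profile matches an independent position-by-position recomputation", {
  set.seed(43)
  s <- stats::setNames(round(rnorm(8), 3), sprintf("g%d", 1:8))
  members <- c("g2", "g5", "g7")
  lambda <- 0.5; eps <- 1e-3
  prof <- gsz_score(s, members, gsz_params(lambda = lambda, eps = eps,
                                           min_size = 2))
  expect_equal(prof$z_up, unname(oracle_gsz_profile(s, members, lambda, eps)),
               tolerance = 1e-10)
  # down direction == up direction of the negated scores
  expect_equal(prof$z_down,
               unname(oracle_gsz_profile(-s, members, lambda, eps)),
               tolerance = 1e-10)
})

test_that("negating scores swaps directions and preserves the max", {
  set.seed(44)
  s <- stats::setNames(rnorm(30), sprintf("g%02d", 1:30))
  members <- names(s)[c(2, 9, 15, 21, 28)]
  p <- gsz_params(min_size = 2, eps = 1e-3)
  a <- gsz_score(s, members, p)
  b <- gsz_score(-s, members, p)
  expect_equal(a$max_score, b$max_score, tolerance = 1e-12)
  expect_equal(a$z_up, b$z_down, tolerance = 1e-12)
  expect_equal(a$z_down, b$z_up, tolerance = 1e-12)
})

test_that("tied scores are resolved reproducibly by gene id", {
  s <- stats::setNames(c(3, 1, 1, 1, 1, 0, -2, 5, 1, 1),
                       sprintf("g%02d", 1:10))
  members <- c("g02", "g04", "g09")
  p <- gsz_params(min_size = 2, eps = 1e-3)
  a <- gsz_score(s, members, p)
  b <- gsz_score(s[sample(names(s))], members, p)  # input order irrelevant
  expect_equal(a$max_score, b$max_score, tolerance = 1e-14)
  expect_equal(a$argmax_position, b$argmax_position)
})

test_that("the smoothing weight changes the statistic when variance varies", {
  set.seed(45)
  s <- stats::setNames(rnorm(50, sd = seq(2, 0.2, length.out = 50)),
                       sprintf("g%02d", 1:50))
  members <- names(s)[c(1, 4, 11, 19, 33, 42)]
  m0 <- gsz_score(s, members, gsz_params(lambda = 0, eps = 1e-6))$max_score
  m1 <- gsz_score(s, members, gsz_params(lambda = 1, eps = 1e-6))$max_score
  expect_false(isTRUE(all.equal(m0, m1)))
  # lambda = 0 is the plain running z on the exact positional moments
  ord <- order(-s, names(s))
  so <- s[ord]
  mom <- running_null_moments(unname(so), length(members))
  X <- cumsum(unname(so) * (names(so) %in% members))
  z_plain <- (X - mom$expectation) / sqrt(mom$variance + 1e-6)
  ord_d <- order(s, names(s))
  sd_ <- -s[ord_d]
  mom_d <- running_null_moments(unname(sd_), length(members))
  Xd <- cumsum(unname(sd_) * (names(sd_) %in% members))
  z_plain_d <- (Xd - mom_d$expectation) / sqrt(mom_d$variance + 1e-6)
  expect_equal(m0, max(z_plain, z_plain_d), tolerance = 1e-10)
})

test_that("batch scoring equals per-set scoring and filters by size", {
  set.seed(46)
  s <- stats::setNames(rnorm(100), sprintf("g%03d", 1:100))
  coll <- gene_set_collection(list(
    BIG = names(s)[1:20], MID = names(s)[30:45], TINY = names(s)[1:2],
    GHOST = c("absent1", "absent2", "absent3", "absent4", "absent5")))
  p <- gsz_params(min_size = 5, eps = 1e-3)
  res <- suppressMessages(gsz_all_sets(s, coll, p))
  expect_setequal(names(res), c("BIG", "MID"))
  expect_setequal(names(attr(res, "skipped")), c("TINY", "GHOST"))
  for (nm in names(res))
    expect_equal(unname(res[nm]),
                 gsz_score(s, coll$sets[[nm]], p)$max_score,
                 tolerance = 1e-12)
  # order independence
  res2 <- suppressMessages(gsz_all_sets(s, coll[c(2, 1, 3, 4)], p))
  expect_equal(res[names(res)], res2[names(res)])
  # nothing survives -> error
  expect_error(suppressMessages(
    gsz_all_sets(s, coll["TINY"], p)), "no gene set survives")
})
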