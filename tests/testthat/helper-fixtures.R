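# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic dataset: values laid out by hand-controlled RNG
tiny_dataset <- function(n_genes = 30, m_groups = 3, n_reps = 3, seed = 99) {
  set.seed(seed)
  groups <- rep(sprintf("G%d", seq_len(m_groups)), each = n_reps)
  sids <- paste0(groups, "_", seq_along(groups))
  x <- matrix(rnorm(n_genes * length(sids), mean = 5),
              n_genes, length(sids),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), sids))
  expression_dataset(x, stats::setNames(groups, sids))
}

# write a GMT fixture from a named list, returning the path
write_gmt_fixture <- function(sets, descs = NULL) {
  path <- tempfile(fileext = ".gmt")
  if (is.null(descs)) descs <- rep("na", length(sets))
  writeLines(mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                    names(sets), descs, sets), path)
  path
}

# exhaustive-subset oracle for the running null moments: mean and variance
# of X(i) = sum_{j<=i} s_j 1[j in subset] over all M-subsets of 1..N
enum_running_moments <- function(scores, M) {
  N <- length(scores)
  subsets <- utils::combn(N, M)
  X <- matrix(0, ncol(subsets), N)
  for (k in seq_len(ncol(subsets))) {
    ind <- numeric(N)
    ind[subsets[, k]] <- 1
    X[k, ] <- cumsum(scores * ind)
  }
  list(expectation = colMeans(X),
       variance = apply(X, 2, function(v) mean((v - mean(v))^2)))
}

# enumeration oracle for perm1: unique equal splits of 2n items, mirrors merged
enum_perm1_count <- function(n) {
  z <- 2 * n
  subsets <- utils::combn(z, n)
  keys <- apply(subsets, 2, function(a) {
    b <- setdiff(seq_len(z), a)
    paste(min(paste(a, collapse = ","), paste(b, collapse = ",")),
          max(paste(a, collapse = ","), paste(b, collapse = ",")))
  })
  length(unique(keys))
}

# enumeration oracle for perm2: unordered pairs of disjoint n-subsets of y items
enum_perm2_count <- function(y, n) {
  combn_safe <- function(x, m)   # combn(scalar, m) would expand seq_len(x)
    if (length(x) == m) list(x) else utils::combn(x, m, simplify = FALSE)
  a_sets <- combn_safe(seq_len(y), n)
  keys <- character(0)
  for (a in a_sets) {
    rest <- setdiff(seq_len(y), a)
    if (length(rest) < n) next
    for (b in combn_safe(rest, n)) {
      ka <- paste(a, collapse = ","); kb <- paste(b, collapse = ",")
      keys <- c(keys, paste(min(ka, kb), max(ka, kb)))
    }
  }
  length(unique(keys))
}

# independent position-by-position GSZ profile recomputation (test oracle)
oracle_gsz_profile <- function(scores, member_names, lambda, eps) {
  ord <- order(-scores, names(scores))
  so <- scores[ord]
  memb <- names(so) %in% member_names
  N <- length(so); M <- sum(memb)
  X <- cumsum(so * memb)
  mom <- enum_running_moments(so, M)
  v <- mom$variance
  (X - mom$expectation) / sqrt((1 - lambda) * v + lambda * mean(v) + eps)
}
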