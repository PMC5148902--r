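#' Size of the naive two-group permutation space
#'
#' Number of unique label permutations when only the `z = 2n` samples of the
#' two analyzed groups are shuffled: `(1/2) * z! / (n! (z - n)!)`. The factor
#' 1/2 excludes permutations that are mirror images of one another (e.g.
#' `(1,1,0,0)` and `(0,0,1,1)` give identical results). With 5 replicates per
#' group this is only 126 — the core reason naive permutation fails with few
#' replicates.
#'
#' @param z Total samples in the two analyzed groups (must equal `2 * n`).
#' @param n Replicates per group.
#' @return Exact count (numeric; exact for all practical designs). If the
#'   halved binomial is not an integer the value is floored with a warning.
#' @export
count_perm1 <- function(z, n) {
  stopifnot(n >= 1)
  if (z != 2 * n)
    stop("count_perm1 requires z = 2n (unequal two-group designs are out of scope)")
  tot <- choose(z, n)
  half <- tot / 2
  if (half != floor(half)) {
    warning("permutation count is not an even integer; rounding down")
    half <- floor(half)
  }
  half
}

#' Size of the unconstrained all-sample permutation space
#'
#' All `y` samples of the dataset are eligible: choose an ordered pair of
#' disjoint `n`-subsets, modulo mirror images:
#' `(1/2) * y! / (n! n! (y - 2n)!)`.
#'
#' @param y Total samples in all groups.
#' @param n Replicates per group.
#' @return Exact count (numeric).
#' @export
count_perm2 <- function(y, n) {
  stopifnot(n >= 1)
  if (y < 2 * n) stop("count_perm2 requires y >= 2n")
  choose(y, n) * choose(y - n, n) / 2
}

#' Lower bound on the two-stage constrained permutation space
#'
#' For the two-stage scheme (group selection, then one sample per selected
#' group), a lower bound on the number of unique permutations:
#' `(1/2) * n^n * (n-1)^n * ((m-2)! / ((n-2)! (m-n)!))^2`, valid when
#' `m > n`.
#'
#' @param m Number of groups.
#' @param n Replicates per group (half size), `n >= 2`.
#' @return Exact count (numeric).
#' @export
count_perm4_lower <- function(m, n) {
  stopifnot(n >= 2)
  if (m <= n)
    stop("the lower-bound formula applies only when m > n; ",
         "for m <= n use the unconstrained scheme (perm2)")
  n^n * (n - 1)^n * choose(m - 2, n - 2)^2 / 2
}

#' Permutation-space sizes for a balanced multi-group design
#'
#' Convenience wrapper evaluating all three closed-form counts for a design
#' with `m` groups of `n` replicates.
#'
#' @param m Number of groups.
#' @param n Replicates per group.
#' @return Named numeric vector `c(perm1 = , perm2 = , perm4 = )`.
#' @export
perm_space_sizes <- function(m, n) {
  c(perm1 = count_perm1(2 * n, n),
    perm2 = count_perm2(m * n, n),
    perm4 = if (m > n && n >= 2) count_perm4_lower(m, n) else NA_real_)
}

#' Generate permuted two-group comparisons
#'
#' Draws `n_perm` permuted comparisons — ordered pairs of disjoint
#' equal-sized sample-index lists standing in for "group A vs group B" — by
#' one of three schemes:
#' \describe{
#'   \item{`perm1`}{naive: a random equal split of the `2n` samples of the
#'     two analyzed groups (which must have equal size `n`).}
#'   \item{`perm2`}{unconstrained: `2n` distinct samples drawn uniformly from
#'     all samples, split into halves; a draw may contain no sample at all
#'     from the analyzed groups.}
#'   \item{`perm4`}{two-stage constrained: per half, the two analyzed groups
#'     plus `half_size - 2` further groups are selected (groups sampled
#'     without replacement), then one sample is picked uniformly from each
#'     selected group; the second half re-selects groups independently, with
#'     the first half's samples explicitly filtered out of every group's
#'     candidates. Each half therefore contains exactly one sample from each
#'     of `half_size` distinct groups, always including both analyzed
#'     groups, and no original group dominates a half.}
#' }
#' Draws are independent samples with replacement from the permutation space
#' (duplicates across draws are allowed, never deduplicated); both mirror
#' orientations may occur. The stream is a deterministic function of `seed`.
#'
#' @param dataset An [expression_dataset()].
#' @param group_a,group_b The two analyzed group labels (distinct).
#' @param method One of `"perm1"`, `"perm2"`, `"perm4"`.
#' @param n_perm Number of comparisons to draw.
#' @param seed Integer seed.
#' @param half_size Half size for `perm4`; defaults to the minimum group
#'   size. Must satisfy `half_size >= 2`, `half_size < number of groups`,
#'   and every group must have >= 2 samples. Ignored by perm1/perm2 (their
#'   half size is the analyzed group size).
#' @return List of length `n_perm`; each element is `list(a = , b = )` of
#'   disjoint sample column indices.
#' @export
generate_permutations <- function(dataset, group_a, group_b,
                                  method = c("perm4", "perm2", "perm1"),
                                  n_perm = 500, seed = 1, half_size = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"), n_perm >= 1)
  method <- match.arg(method)
  if (group_a == group_b) stop("group_a and group_b must differ")
  ia <- group_index(dataset, group_a)
  ib <- group_index(dataset, group_b)
  y <- ncol(dataset$values)

  if (method == "perm1") {
    if (length(ia) != length(ib))
      stop("perm1 requires the two analyzed groups to have equal size")
    n <- length(ia)
    pool <- c(ia, ib)
    return(with_seed(seed, lapply(seq_len(n_perm), function(i) {
      s <- sample(pool)
      list(a = s[seq_len(n)], b = s[n + seq_len(n)])
    })))
  }

  if (method == "perm2") {
    if (length(ia) != length(ib))
      stop("perm2 requires the two analyzed groups to have equal size")
    n <- length(ia)
    if (y < 2 * n) stop("need at least 2n samples in total")
    return(with_seed(seed, lapply(seq_len(n_perm), function(i) {
      s <- sample.int(y, 2 * n)
      list(a = s[seq_len(n)], b = s[n + seq_len(n)])
    })))
  }

  # perm4
  sizes <- group_sizes(dataset)
  labs <- names(sizes)
  m <- length(labs)
  n4 <- if (is.null(half_size)) min(sizes) else as.integer(half_size)
  if (n4 < 2) stop("perm4 requires a half size of at least 2")
  if (m <= n4)
    stop("perm4 requires more groups than the half size (m > n); ",
         "use perm2 for this design")
  if (any(sizes < 2)) stop("perm4 requires every group to have >= 2 samples")
  members <- lapply(labs, function(g) which(dataset$groups == g))
  names(members) <- labs
  others <- setdiff(labs, c(group_a, group_b))

  draw_half <- function(excluded) {
    gs <- c(group_a, group_b, sample_safe(others, n4 - 2L))
    vapply(gs, function(g) {
      cand <- setdiff(members[[g]], excluded)
      if (!length(cand))
        stop("internal error: group ", g, " exhausted in second half")
      sample_safe(cand, 1L)
    }, 1L, USE.NAMES = FALSE)
  }

  with_seed(seed, lapply(seq_len(n_perm), function(i) {
    a <- draw_half(integer(0))
    b <- draw_half(a)
    list(a = a, b = b)
  }))
}
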