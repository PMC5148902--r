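#' Tuning parameters for the Gene Set Z-score
#'
#' @param lambda Variance-smoothing weight in `[0, 1]`: the positional null
#'   variance is mixed as `(1 - lambda) * Var(i) + lambda * mean(Var)`.
#'   `lambda = 0` gives a plain running z; larger values damp the unstable
#'   early positions of the profile. Default 0.5.
#' @param eps Small positive variance floor added inside the square root.
#'   `NULL` (default) resolves, at scoring time, to `1e-4` times the median
#'   over sets of the mean positional variance (floored at 1e-12 so that an
#'   all-zero score vector yields zero profiles rather than 0/0).
#' @param min_size,max_size Effective set size bounds (after intersection
#'   with the measured genes); sets outside are skipped. Defaults 5 and
#'   2000, conventional for curated collections.
#' @return A list of class `gsz_params`.
#' @export
gsz_params <- function(lambda = 0.5, eps = NULL, min_size = 5,
                       max_size = 2000) {
  stopifnot(lambda >= 0, lambda <= 1,
            is.null(eps) || eps > 0,
            min_size >= 1, max_size >= min_size)
  structure(list(lambda = lambda, eps = eps,
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size)),
            class = "gsz_params")
}

#' Running null moments of a weighted hypergeometric prefix sum
#'
#' For genes ordered by score, consider the running sum
#' `X(i) = sum_{j <= i} s_j * 1[gene_j in set]` where the set is a uniformly
#' random `M`-subset of all `N` genes (the competitive null). This returns
#' the exact expectation and variance of `X(i)` at every prefix position:
#' with `p = M/N`, `A1(i) = sum_{j<=i} s_j`, `A2(i) = sum_{j<=i} s_j^2` and
#' `c = M(N-M) / (N^2 (N-1))`,
#' `E(i) = p A1(i)` and `Var(i) = p(1-p) A2(i) - c (A1(i)^2 - A2(i))`.
#' At `i = N` these equal the exact mean and variance of the score sum over
#' a random `M`-subset.
#'
#' @param ordered_scores Numeric vector of scores in list order (length `N`).
#' @param set_size Set size `M`, with `1 <= M < N`.
#' @return List with numeric vectors `expectation` and `variance` (variance
#'   clamped at 0 against rounding).
#' @export
running_null_moments <- function(ordered_scores, set_size) {
  s <- as.numeric(ordered_scores)
  N <- length(s)
  M <- as.integer(set_size)
  if (M < 1L || M >= N)
    stop("set_size must satisfy 1 <= M < N")
  A1 <- cumsum(s)
  A2 <- cumsum(s * s)
  p <- M / N
  cc <- M * (N - M) / (N^2 * (N - 1))
  v <- p * (1 - p) * A2 - cc * (A1 * A1 - A2)
  v[v < 0] <- 0
  list(expectation = p * A1, variance = v)
}

# Precompute everything shared across sets for one score vector:
# both orderings (descending for "up", ascending == negated-descending for
# "down"), prefix sums, and gene -> position maps. Ties broken by gene id
# (ascending) for reproducibility.
gsz_prepare <- function(scores, gene_ids) {
  N <- length(scores)
  prep_dir <- function(ord) {
    so <- scores[ord]
    pos <- integer(N); pos[ord] <- seq_len(N)
    A1 <- cumsum(so)
    A2 <- cumsum(so * so)
    list(s = so, pos = pos, A1 = A1, A2 = A2, D = A1 * A1 - A2)
  }
  up <- prep_dir(order(-scores, gene_ids))
  down_ord <- order(scores, gene_ids)
  down <- prep_dir(down_ord)
  down$s <- -down$s; down$A1 <- -down$A1   # negated scores, A2/D unchanged
  list(N = N, up = up, down = down)
}

# mean positional variance (descending direction) for one set size
gsz_varbar <- function(prep, M) {
  N <- prep$N
  p <- M / N
  cc <- M * (N - M) / (N^2 * (N - 1))
  v <- p * (1 - p) * prep$up$A2 - cc * prep$up$D
  v[v < 0] <- 0
  mean(v)
}

# directional profile: z over positions
gsz_profile_dir <- function(dirprep, N, member_pos, lambda, eps) {
  M <- length(member_pos)
  p <- M / N
  cc <- M * (N - M) / (N^2 * (N - 1))
  x <- numeric(N)
  x[member_pos] <- dirprep$s[member_pos]
  X <- cumsum(x)
  v <- p * (1 - p) * dirprep$A2 - cc * dirprep$D
  v[v < 0] <- 0
  (X - p * dirprep$A1) / sqrt((1 - lambda) * v + lambda * mean(v) + eps)
}

# max over both directions; fast path for the permutation loop
gsz_max_one <- function(prep, member_idx, lambda, eps) {
  zu <- gsz_profile_dir(prep$up, prep$N, prep$up$pos[member_idx], lambda, eps)
  zd <- gsz_profile_dir(prep$down, prep$N, prep$down$pos[member_idx], lambda, eps)
  max(max(zu), max(zd))
}

resolve_eps <- function(params, varbars) {
  if (!is.null(params$eps)) return(params$eps)
  max(1e-4 * stats::median(varbars), 1e-12)
}

#' Gene Set Z-score of one gene set
#'
#' Orders genes by descending score (ties broken by gene id), forms the
#' running member-score sum `X(i)`, standardizes it by the exact
#' hypergeometric prefix moments (see [running_null_moments()]) with
#' lambda-smoothed variance, and takes the maximum over positions; the
#' "down" direction repeats this on the ascending order (equivalently with
#' negated scores). The set score is the larger directional maximum.
#'
#' @param scores A `gene_scores` vector from [score_genes()], or any named
#'   numeric vector of per-gene scores.
#' @param members Character vector of member gene ids; genes absent from
#'   `scores` are dropped, and the effective size must lie within the
#'   `params` bounds.
#' @param params A [gsz_params()] object.
#' @return Object of class `gsz_profile`: list with `z_up`, `z_down`
#'   (profiles over positions in their respective orderings), `max_score`,
#'   `argmax_position`, `direction` (`"up"` or `"down"`), `set_size`
#'   (effective), and `n_genes`.
#' @export
gsz_score <- function(scores, members, params = gsz_params()) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  gene_ids <- names(scores)
  idx <- match(unique(as.character(members)), gene_ids)
  idx <- idx[!is.na(idx)]
  M <- length(idx)
  if (M < params$min_size || M > params$max_size)
    stop(sprintf("effective set size %d outside bounds [%d, %d]",
                 M, params$min_size, params$max_size))
  N <- length(scores)
  if (M >= N) stop("set must be a proper subset of the scored genes")
  prep <- gsz_prepare(as.numeric(scores), gene_ids)
  eps <- resolve_eps(params, gsz_varbar(prep, M))
  zu <- gsz_profile_dir(prep$up, N, prep$up$pos[idx], params$lambda, eps)
  zd <- gsz_profile_dir(prep$down, N, prep$down$pos[idx], params$lambda, eps)
  if (max(zu) >= max(zd)) {
    direction <- "up"; arg <- which.max(zu); mx <- max(zu)
  } else {
    direction <- "down"; arg <- which.max(zd); mx <- max(zd)
  }
  structure(list(z_up = zu, z_down = zd, max_score = mx,
                 argmax_position = arg, direction = direction,
                 set_size = M, n_genes = N),
            class = "gsz_profile")
}

#' @export
print.gsz_profile <- function(x, ...) {
  cat(sprintf(
    "gsz_profile: max score %.4f (%s) at position %d; set size %d of %d genes\n",
    x$max_score, x$direction, x$argmax_position, x$set_size, x$n_genes))
  invisible(x)
}

#' Gene Set Z-scores for a whole collection
#'
#' Batch driver sharing the ordering and prefix sums across sets. Sets whose
#' effective size (members present among the scored genes) falls outside the
#' `params` bounds are omitted; their names and reasons are returned in the
#' `skipped` attribute and reported via `message()`.
#'
#' @inheritParams gsz_score
#' @param collection A [gene_set_collection()].
#' @param quiet Suppress the skip message.
#' @return Named numeric vector of max GSZ scores, with attributes `skipped`
#'   (named character vector of reasons) and `set_size` (named integer
#'   vector of effective sizes).
#' @export
gsz_all_sets <- function(scores, collection, params = gsz_params(),
                         quiet = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"),
            is.numeric(scores), !is.null(names(scores)))
  if (!length(collection)) stop("empty gene set collection")
  gene_ids <- names(scores)
  N <- length(scores)
  idx_list <- lapply(collection$sets, function(g) {
    i <- match(g, gene_ids); i[!is.na(i)]
  })
  sizes <- vapply(idx_list, length, 1L)
  ok <- sizes >= params$min_size & sizes <= params$max_size & sizes < N
  skipped <- stats::setNames(
    sprintf("effective size %d outside [%d, %d]", sizes[!ok],
            params$min_size, min(params$max_size, N - 1L)),
    names(collection$sets)[!ok])
  if (!any(ok)) stop("no gene set survives the size filter")
  if (length(skipped) && !quiet)
    message(length(skipped), " gene set(s) skipped by size filter")
  prep <- gsz_prepare(as.numeric(scores), gene_ids)
  varbars <- vapply(sizes[ok], function(M) gsz_varbar(prep, M), 1)
  eps <- resolve_eps(params, varbars)
  out <- vapply(idx_list[ok], function(i)
    gsz_max_one(prep, i, params$lambda, eps), 1)
  structure(out, skipped = skipped,
            set_size = sizes[ok], eps = eps)
}
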