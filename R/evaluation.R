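#' Stratified test/reference split of a dataset
#'
#' Splits the samples of every group into a test partition (25% by default,
#' rounded per group) and a reference partition (the remainder), keeping
#' partitions disjoint and both non-empty in every group.
#'
#' @param dataset An [expression_dataset()].
#' @param seed Integer seed.
#' @param test_fraction Fraction of each group assigned to the test
#'   partition (default 0.25).
#' @return List with `test` and `reference`, both [expression_dataset()]s.
#' @export
split_dataset <- function(dataset, seed = 1, test_fraction = 0.25) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sizes <- group_sizes(dataset)
  n_test <- round(test_fraction * sizes)
  bad <- names(sizes)[n_test < 1 | n_test >= sizes]
  if (length(bad))
    stop("group(s) too small for a ", test_fraction,
         " split (need >= 1 sample in each partition): ",
         paste(bad, collapse = ", "))
  with_seed(seed, {
    test_idx <- unlist(lapply(names(sizes), function(g) {
      idx <- which(dataset$groups == g)
      sample_safe(idx, n_test[[g]])
    }), use.names = FALSE)
    test_idx <- sort(test_idx)
    ref_idx <- setdiff(seq_along(dataset$groups), test_idx)
    list(
      test = expression_dataset(dataset$values[, test_idx, drop = FALSE],
                                dataset$groups[test_idx]),
      reference = expression_dataset(dataset$values[, ref_idx, drop = FALSE],
                                     dataset$groups[ref_idx]))
  })
}

#' Reference gene sets from ranked lists
#'
#' For each `n`, the union over all rankings of their top-`n` set names —
#' the "reference gene sets" a test-partition ranking is scored against.
#'
#' @param reference_rankings List of character vectors, each a ranked list
#'   of set names (most significant first).
#' @param n_values Integer vector of top-list depths (e.g. `c(3, 5, 7)`).
#' @return Named list, one character vector per `n`.
#' @export
build_reference_sets <- function(reference_rankings, n_values = c(3, 5, 7)) {
  stopifnot(is.list(reference_rankings), length(reference_rankings) >= 1,
            all(vapply(reference_rankings, length, 1L) >= 1))
  out <- lapply(n_values, function(n)
    Reduce(union, lapply(reference_rankings, utils::head, n)))
  names(out) <- as.character(n_values)
  out
}

#' Cumulative count of reference sets along a ranking
#'
#' Entry `r` is the number of reference set names among the top `r` of the
#' test ranking, for ranks 1..`max_rank` (50 by default). Rankings shorter
#' than `max_rank` yield a truncated curve with a warning.
#'
#' @param test_ranking Character vector of set names, ranked.
#' @param reference Character vector (or set) of reference set names.
#' @param max_rank Curve length.
#' @return Integer vector of cumulative counts.
#' @export
cumulative_count_curve <- function(test_ranking, reference, max_rank = 50) {
  if (length(test_ranking) < max_rank) {
    warning(sprintf("ranking has only %d entries; curve truncated",
                    length(test_ranking)))
    max_rank <- length(test_ranking)
  }
  cumsum(utils::head(test_ranking, max_rank) %in% reference)
}

#' Precision-recall area under curve of a ranked list
#'
#' Step-wise interpolation of the precision-recall curve over the ranked
#' list (equivalently, average precision): the mean of the precision at each
#' positive's rank, over all positives (positives missing from the ranking
#' contribute zero). A random ranking gives approximately the prevalence of
#' positives; perfect separation gives 1.
#'
#' @param ranked_names Character vector of item names, best first.
#' @param positives Character vector of positive item names.
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(ranked_names, positives) {
  n_pos <- length(unique(positives))
  if (n_pos == 0) stop("no positives supplied")
  hits <- ranked_names %in% positives
  if (!any(hits)) return(0)
  prec <- cumsum(hits) / seq_along(hits)
  sum(prec[hits]) / n_pos
}

# rank set names of an mgszm fit (already sorted: p asc, score desc, name)
ranking_of <- function(fit) as.data.frame(fit)$set_name

#' Type-1 error experiment on null data
#'
#' Repeatedly randomizes the sample labels of a dataset (so there is no true
#' differential expression), runs the full pipeline on each null replicate,
#' and pools the resulting p-values. On null data the p-values should follow
#' a Uniform(0,1) distribution; the report carries the Kolmogorov-Smirnov
#' statistic against that uniform and the fraction of p below 0.05 (the
#' nominal-level check).
#'
#' @param dataset An [expression_dataset()] (typically from
#'   [simulate_dataset()] with `effect_size = 0`, or any real dataset).
#' @param sets A [gene_set_collection()].
#' @param group_a,group_b Labels of the pair analyzed in each replicate.
#' @param n_repeats Number of label randomizations.
#' @param seed Integer seed (each repeat derives its own sub-seed).
#' @param pipeline_fun Optional override: a `function(null_dataset, seed)`
#'   returning a p-value vector. Used to calibrate the harness itself
#'   (e.g. by injecting known-uniform p-values); default runs [mgszm()].
#' @param ... Further arguments passed to [mgszm()].
#' @return Object of class `mgszm_type1`: list with pooled `p_values`,
#'   `ks_statistic`, `ks_p`, `frac_below_05`, `n_repeats`.
#' @export
type1_error_experiment <- function(dataset, sets, group_a, group_b,
                                   n_repeats = 5, seed = 1,
                                   pipeline_fun = NULL, ...) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(unique(dataset$groups)) < 2L) stop("need >= 2 groups")
  if (is.null(pipeline_fun))
    pipeline_fun <- function(nd, sub_seed)
      as.data.frame(mgszm(nd, sets, group_a, group_b, seed = sub_seed,
                          quiet = TRUE, ...))$p_value
  ps <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sub_seed <- seed * 1000L + r
    nd <- make_null_dataset(dataset, seed = sub_seed)
    ps[[r]] <- tryCatch(pipeline_fun(nd, sub_seed),
                        error = function(e)
                          stop("pipeline failed in repeat ", r, ": ",
                               conditionMessage(e)))
  }
  p <- unlist(ps, use.names = FALSE)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  structure(list(p_values = p,
                 ks_statistic = unname(ks$statistic),
                 ks_p = ks$p.value,
                 frac_below_05 = mean(p < 0.05),
                 n_repeats = n_repeats),
            class = "mgszm_type1")
}

#' @export
print.mgszm_type1 <- function(x, ...) {
  cat(sprintf(
    "type-1 error experiment: %d pooled p-values from %d null repeats\n",
    length(x$p_values), x$n_repeats))
  cat(sprintf("  KS vs Uniform(0,1): D = %.4f, p = %.4g\n",
              x$ks_statistic, x$ks_p))
  cat(sprintf("  fraction p < 0.05: %.4f (nominal 0.05)\n", x$frac_below_05))
  invisible(x)
}

#' Benchmark ranking of diluted relevant sets against random sets
#'
#' For each pairwise comparison of groups carrying planted signal, builds
#' "relevant" gene sets by diluting every planted set of the pair over a
#' grid of replacement percentages (see [dilute_gene_set()]), mixes them
#' with size-matched random sets, ranks everything with the pipeline and
#' reports the cumulative relevant-set count over the top of the ranking
#' plus the precision-recall AUC (relevant sets as positives).
#'
#' @param truth An `mgszm_sim` from [simulate_dataset()] with planted sets.
#' @param x_grid Dilution percentages (default `seq(0, 90, 10)`).
#' @param n_random_sets Random sets added per comparison.
#' @param seed Integer seed.
#' @param pairs Optional list of 2-vectors of group labels to compare;
#'   default: all pairs of groups that carry at least one planted set.
#' @param max_rank Length of the cumulative-count curve.
#' @param ... Passed to [mgszm()] (e.g. `n_perm`, `perm_method`).
#' @return Object of class `mgszm_tissue_eval`: list with `mean_curve`,
#'   `mean_pr_auc`, `per_pair` (data frame), `n_ties` (p-value ties seen).
#' @export
tissue_benchmark <- function(truth, x_grid = seq(0, 90, 10),
                             n_random_sets = 30, seed = 1, pairs = NULL,
                             max_rank = 50, ...) {
  stopifnot(inherits(truth, "mgszm_sim"))
  ds <- truth$dataset
  all_genes <- rownames(ds$values)
  planted_genes <- unique(unlist(truth$regulated_sets$sets))
  pool <- setdiff(all_genes, planted_genes)
  groups_with_signal <- unique(truth$affected_group)
  if (length(groups_with_signal) < 2L)
    stop("need planted sets in at least 2 groups")
  if (is.null(pairs)) {
    pairs <- utils::combn(sort(groups_with_signal), 2, simplify = FALSE)
  }
  curves <- list(); aucs <- numeric(0); ties <- 0L
  per_pair <- data.frame()
  for (k in seq_along(pairs)) {
    ga <- pairs[[k]][1]; gb <- pairs[[k]][2]
    rel_names <- names(truth$affected_group)[truth$affected_group %in% c(ga, gb)]
    if (!length(rel_names)) next
    relevant <- list()
    for (nm in rel_names) {
      for (x in x_grid) {
        relevant[[sprintf("%s_x%02d", nm, x)]] <-
          dilute_gene_set(truth$regulated_sets$sets[[nm]], x, pool,
                          seed = seed * 10000L + k * 100L + x)
      }
    }
    sz <- vapply(relevant, length, 1L)
    random <- with_seed(seed * 10000L + k, {
      stats::setNames(lapply(seq_len(n_random_sets), function(i)
        sample_safe(all_genes, sz[(i - 1L) %% length(sz) + 1L])),
        sprintf("RANDOM_%02d", seq_len(n_random_sets)))
    })
    coll <- gene_set_collection(c(relevant, random))
    fit <- mgszm(ds, coll, ga, gb, seed = seed + k, quiet = TRUE, ...)
    rk <- ranking_of(fit)
    ties <- ties + sum(duplicated(as.data.frame(fit)$p_value))
    curves[[k]] <- cumulative_count_curve(rk, names(relevant),
                                          min(max_rank, length(rk)))
    aucs[k] <- pr_auc(rk, names(relevant))
    per_pair <- rbind(per_pair,
                      data.frame(group_a = ga, group_b = gb,
                                 n_relevant = length(relevant),
                                 n_random = n_random_sets,
                                 pr_auc = aucs[k]))
  }
  len <- min(vapply(curves, length, 1L))
  mean_curve <- Reduce(`+`, lapply(curves, utils::head, len)) / length(curves)
  structure(list(mean_curve = mean_curve, mean_pr_auc = mean(aucs),
                 per_pair = per_pair, n_ties = ties),
            class = "mgszm_tissue_eval")
}

#' @export
print.mgszm_tissue_eval <- function(x, ...) {
  cat(sprintf(
    "diluted-set benchmark: %d pairwise comparisons, mean PR-AUC %.3f\n",
    nrow(x$per_pair), x$mean_pr_auc))
  cat(sprintf("  mean cumulative relevant count at rank %d: %.1f\n",
              length(x$mean_curve), x$mean_curve[length(x$mean_curve)]))
  if (x$n_ties > 0) cat(sprintf("  %d tied p-value(s) observed\n", x$n_ties))
  invisible(x)
}

#' Concordance of naive and constrained permutation nulls
#'
#' Builds, for every gene set, a permutation null of GSZ scores under the
#' naive scheme (perm1, valid here because the analyzed groups have many
#' replicates) and under the constrained scheme (perm4), fits a Gumbel to
#' each, and reports the Pearson correlation across sets of the fitted
#' locations and scales together with the mean relative error
#' `mean(|perm4_i - perm1_i| / |perm1_i|)` per parameter (perm1 is the
#' reference arm, which makes the MRE asymmetric by construction).
#'
#' @param dataset An [expression_dataset()]; the analyzed pair should have
#'   ample replicates (>= 15 each) so perm1 itself is trustworthy, with
#'   additional groups available for perm4.
#' @param collection A [gene_set_collection()].
#' @param group_a,group_b The two analyzed group labels.
#' @param n_perm Permutations per arm.
#' @param seed Integer seed.
#' @param gene_stat Per-gene statistic.
#' @param params GSZ parameters.
#' @param half_size Perm4 half size override.
#' @return Object of class `mgszm_concordance`: list with `cor_location`,
#'   `cor_scale`, `mre_location`, `mre_scale`, `n_sets`, `n_failed`,
#'   `per_set` (data frame of both arms' parameters).
#' @export
validate_perm_concordance <- function(dataset, collection, group_a, group_b,
                                      n_perm = 2000, seed = 1,
                                      gene_stat = "moderated_t",
                                      params = gsz_params(),
                                      half_size = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(collection, "gene_set_collection"))
  gene_ids <- rownames(dataset$values)
  ia <- group_index(dataset, group_a)
  obs_scores <- score_matrix(dataset$values, ia,
                             group_index(dataset, group_b), gene_stat)
  names(obs_scores) <- gene_ids
  probe <- gsz_all_sets(obs_scores, collection, params, quiet = TRUE)
  eps_fixed <- attr(probe, "eps")
  kept <- names(probe)
  idx_list <- lapply(collection$sets[kept], function(g) {
    i <- match(g, gene_ids); i[!is.na(i)]
  })

  null_arm <- function(method, arm_seed) {
    perms <- generate_permutations(dataset, group_a, group_b,
                                   method = method, n_perm = n_perm,
                                   seed = arm_seed, half_size = half_size)
    out <- matrix(NA_real_, length(kept), n_perm,
                  dimnames = list(kept, NULL))
    for (j in seq_len(n_perm)) {
      s <- score_matrix(dataset$values, perms[[j]]$a, perms[[j]]$b, gene_stat)
      prep <- gsz_prepare(s, gene_ids)
      out[, j] <- vapply(idx_list, function(i)
        gsz_max_one(prep, i, params$lambda, eps_fixed), 1)
    }
    out
  }
  n1 <- null_arm("perm1", seed)
  n4 <- null_arm("perm4", seed + 1L)

  fit_arm <- function(nulls) {
    lapply(kept, function(nm)
      tryCatch(fit_gumbel(nulls[nm, ]), error = function(e) NULL))
  }
  f1 <- fit_arm(n1); f4 <- fit_arm(n4)
  ok <- !vapply(f1, is.null, TRUE) & !vapply(f4, is.null, TRUE)
  n_failed <- sum(!ok)
  loc1 <- vapply(f1[ok], `[[`, 1, "location")
  loc4 <- vapply(f4[ok], `[[`, 1, "location")
  sc1 <- vapply(f1[ok], `[[`, 1, "scale")
  sc4 <- vapply(f4[ok], `[[`, 1, "scale")
  mre <- function(hat, ref) mean(abs(hat - ref) / abs(ref))
  structure(list(cor_location = stats::cor(loc1, loc4),
                 cor_scale = stats::cor(sc1, sc4),
                 mre_location = mre(loc4, loc1),
                 mre_scale = mre(sc4, sc1),
                 n_sets = sum(ok), n_failed = n_failed,
                 per_set = data.frame(set_name = kept[ok],
                                      loc_perm1 = loc1, loc_perm4 = loc4,
                                      scale_perm1 = sc1, scale_perm4 = sc4)),
            class = "mgszm_concordance")
}

#' @export
print.mgszm_concordance <- function(x, ...) {
  cat(sprintf(
    "perm1/perm4 EV concordance over %d sets (%d fit failures excluded)\n",
    x$n_sets, x$n_failed))
  cat(sprintf("  location: r = %.4f, MRE = %.4f\n",
              x$cor_location, x$mre_location))
  cat(sprintf("  scale:    r = %.4f, MRE = %.4f\n",
              x$cor_scale, x$mre_scale))
  invisible(x)
}

#' Data-splitting evaluation of pipeline configurations
#'
#' The cross-validation-style protocol: split the data into reference (75%)
#' and test (25%) partitions; run every configuration on the reference
#' partition and take, for each `n` in `n_values`, the union of each
#' configuration's top-`n` sets as the reference gene sets; re-run every
#' configuration on the test partition and record the cumulative count of
#' reference sets over the top of its ranking, averaged over `n` values;
#' repeat over splits and average. A configuration is a named list of
#' [mgszm()] arguments (e.g. `list(perm_method = "perm4")`).
#'
#' @param dataset An [expression_dataset()]; every group needs enough
#'   samples to place one in each partition.
#' @param sets A [gene_set_collection()].
#' @param group_a,group_b Labels of the analyzed pair.
#' @param configs Named list of configuration lists.
#' @param n_values Reference top-list depths.
#' @param n_repeats Number of splits.
#' @param seed Integer seed.
#' @param max_rank Curve length.
#' @param ... Shared [mgszm()] arguments applied to every configuration.
#' @return Object of class `mgszm_split_eval`: list with `mean_curves`
#'   (one averaged curve per configuration) and `n_repeats`.
#' @export
split_eval <- function(dataset, sets, group_a, group_b,
                       configs = list(perm4 = list(perm_method = "perm4"),
                                      perm1 = list(perm_method = "perm1")),
                       n_values = c(3, 5, 7), n_repeats = 20, seed = 1,
                       max_rank = 50, ...) {
  shared <- list(...)
  run_cfg <- function(cfg, ds, sub_seed) {
    args <- c(list(dataset = ds, sets = sets, group_a = group_a,
                   group_b = group_b, seed = sub_seed, quiet = TRUE),
              cfg, shared)
    ranking_of(do.call(mgszm, args[!duplicated(names(args))]))
  }
  acc <- stats::setNames(vector("list", length(configs)), names(configs))
  for (r in seq_len(n_repeats)) {
    sp <- split_dataset(dataset, seed = seed * 100L + r)
    ref_rankings <- lapply(configs, run_cfg, ds = sp$reference,
                           sub_seed = seed * 100L + r)
    refs <- build_reference_sets(ref_rankings, n_values)
    for (cf in names(configs)) {
      test_rk <- run_cfg(configs[[cf]], sp$test, seed * 100L + r)
      cv <- lapply(refs, function(ref)
        cumulative_count_curve(test_rk, ref, min(max_rank, length(test_rk))))
      len <- min(vapply(cv, length, 1L))
      avg <- Reduce(`+`, lapply(cv, utils::head, len)) / length(cv)
      acc[[cf]] <- c(acc[[cf]], list(avg))
    }
  }
  mean_curves <- lapply(acc, function(lst) {
    len <- min(vapply(lst, length, 1L))
    Reduce(`+`, lapply(lst, utils::head, len)) / length(lst)
  })
  structure(list(mean_curves = mean_curves, n_repeats = n_repeats),
            class = "mgszm_split_eval")
}

#' @export
print.mgszm_split_eval <- function(x, ...) {
  cat(sprintf("data-splitting evaluation over %d splits\n", x$n_repeats))
  for (nm in names(x$mean_curves)) {
    cv <- x$mean_curves[[nm]]
    cat(sprintf("  %s: mean cumulative reference count %.2f (final rank %d: %.2f)\n",
                nm, mean(cv), length(cv), cv[length(cv)]))
  }
  invisible(x)
}
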