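# Cross-phenotype eGene overlap: all k-way intersections, a bootstrap null
# over a background gene set (10,000 draws by default), and an analytic
# hypergeometric oracle for pairwise overlaps.

#' Inclusive k-way intersection counts for every phenotype combination
#'
#' For every combination of size >= 2, the size of the plain intersection
#' of the member sets (inclusive convention: an element shared by all four
#' sets also counts in every pairwise and triple intersection). Counts are
#' symmetric under permutation of the combination.
#'
#' @param sets Named list (phenotype -> character vector).
#' @param exclusive Use the exclusive (UpSet-style) convention instead:
#'   count elements in every member set and in none of the remaining sets.
#'   The bootstrap null is defined for the inclusive convention only.
#' @return List with `sizes` (named per-phenotype set sizes) and `combos`
#'   (data.table: combination, k, observed).
#' @export
compute_intersections <- function(sets, exclusive = FALSE) {
  if (length(sets) < 2L) stop("need at least two sets", call. = FALSE)
  sets <- lapply(sets, unique)
  combos <- all_combinations(names(sets))
  count_one <- function(m) {
    inter <- Reduce(intersect, sets[m])
    if (exclusive) {
      others <- setdiff(names(sets), m)
      if (length(others)) inter <- setdiff(inter, unlist(sets[others]))
    }
    length(inter)
  }
  dt <- data.table::data.table(
    combination = vapply(combos, combo_label, character(1L)),
    k = lengths(combos),
    observed = vapply(combos, count_one, integer(1L)))
  list(sizes = lengths(sets), combos = dt)
}

#' Exact upper-tail hypergeometric overlap probability
#'
#' P(X >= observed) for the overlap X of two uniform random subsets of
#' sizes `n1`, `n2` drawn without replacement from a background of `N`
#' elements: X ~ Hypergeometric(N, n1, n2).
#'
#' @param n1,n2 Set sizes (each <= N).
#' @param N Background size.
#' @param observed Observed overlap.
#' @return The exact tail probability.
#' @export
hypergeom_overlap_p <- function(n1, n2, N, observed) {
  assert_count(N, "N")
  if (n1 > N || n2 > N) stop("set sizes must not exceed N", call. = FALSE)
  lo <- max(0L, n1 + n2 - N)
  if (observed > min(n1, n2) || observed < lo) {
    stop(sprintf("observed overlap %d impossible for sizes (%d, %d, N=%d)",
                 observed, n1, n2, N), call. = FALSE)
  }
  stats::phyper(observed - 1L, n1, N - n1, n2, lower.tail = FALSE)
}

#' Bootstrap null for a k-way set overlap
#'
#' Each of `n_boot` replicates draws, independently for each phenotype, a
#' uniform random subset of the background without replacement of the
#' matching size, and records the intersection size of the combination.
#' The empirical p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_boot)` (inclusive ties), so it is
#' never exactly zero; with 10,000 replicates the smallest reportable value
#' is just under 1e-4. The RNG stream is derived from `seed` and the sorted
#' combination label via [stable_hash()], making results invariant to
#' evaluation order.
#'
#' @param set_sizes Named integer vector: one draw size per phenotype in
#'   the combination.
#' @param background Character vector of background element ids (genes or
#'   pathway ids).
#' @param observed Observed intersection size.
#' @param n_boot Number of replicates (default 10000).
#' @param seed Master seed.
#' @param background_label Annotation stored on the result.
#' @return An `overlap_result`: combination, observed, background_label,
#'   background_size, n_boot, null_counts, empirical_p, seed.
#' @export
bootstrap_overlap <- function(set_sizes, background, observed,
                              n_boot = 10000L, seed = 1L,
                              background_label = "background") {
  if (is.null(names(set_sizes)) || length(set_sizes) < 2L) {
    stop("`set_sizes` must be a named vector with >= 2 entries",
         call. = FALSE)
  }
  N <- length(unique(background))
  if (any(set_sizes > N)) {
    stop(sprintf("set size %d exceeds background size %d",
                 max(set_sizes), N), call. = FALSE)
  }
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  k <- length(set_sizes)
  label <- combo_label(sort(names(set_sizes)))
  set.seed(stable_hash(seed, paste0("overlap|", label)))
  null_counts <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    drawn <- unlist(lapply(set_sizes, function(s) sample.int(N, s)),
                    use.names = FALSE)
    null_counts[b] <- sum(tabulate(drawn, nbins = N) == k)
  }
  structure(list(
    combination = names(set_sizes), observed = as.integer(observed),
    background_label = background_label, background_size = N,
    n_boot = as.integer(n_boot), null_counts = null_counts,
    empirical_p = (1 + sum(null_counts >= observed)) / (1 + n_boot),
    seed = as.integer(seed)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %s | observed %d | background %s (N=%d) | p = %.4g\n",
    combo_label(x$combination), x$observed, x$background_label,
    x$background_size, x$empirical_p))
  invisible(x)
}

#' Evaluate every combination against two background definitions
#'
#' Runs the bootstrap for each combination of the supplied eGene sets under
#' each background (typically "all eGenes" and "spatially contacted
#' genes"), adds the analytic hypergeometric p for pairwise combinations,
#' and flags combinations whose significance verdict differs between
#' backgrounds.
#'
#' @param sets Named list (phenotype -> gene ids); every set must be a
#'   subset of every background.
#' @param backgrounds Named list of background gene vectors (two entries in
#'   the standard analysis).
#' @param n_boot,seed Bootstrap parameters.
#' @param alpha Significance level for the verdict flag (default 0.05).
#' @return List with `table` (one row per combination x background) and
#'   `results` (the underlying `overlap_result` objects, keyed
#'   "combination|background").
#' @export
run_both_backgrounds <- function(sets, backgrounds, n_boot = 10000L,
                                 seed = 1L, alpha = 0.05) {
  sets <- lapply(sets, unique)
  for (bl in names(backgrounds)) {
    for (ph in names(sets)) {
      extra <- setdiff(sets[[ph]], backgrounds[[bl]])
      if (length(extra)) {
        stop(sprintf(
          "set '%s' contains %d element(s) missing from background '%s'",
          ph, length(extra), bl), call. = FALSE)
      }
    }
  }
  ci <- compute_intersections(sets)
  results <- list()
  rows <- list()
  for (i in seq_len(nrow(ci$combos))) {
    members <- parse_combo(ci$combos$combination[i])
    obs <- ci$combos$observed[i]
    for (bl in names(backgrounds)) {
      res <- bootstrap_overlap(ci$sizes[members], backgrounds[[bl]], obs,
                               n_boot = n_boot, seed = seed,
                               background_label = bl)
      key <- paste(ci$combos$combination[i], bl, sep = "|")
      results[[key]] <- res
      analytic <- if (length(members) == 2L) {
        hypergeom_overlap_p(ci$sizes[[members[1L]]],
                            ci$sizes[[members[2L]]],
                            res$background_size, obs)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.table::data.table(
        combination = ci$combos$combination[i], k = length(members),
        background = bl, background_size = res$background_size,
        observed = obs, empirical_p = res$empirical_p,
        analytic_p = analytic, significant = res$empirical_p < alpha)
    }
  }
  tab <- data.table::rbindlist(rows)
  tab[, sig_differs := length(unique(significant)) > 1L, by = combination]
  list(table = tab[], results = results)
}
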