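#' Subsampling stability selection over IDA effects
#'
#' Repeats the whole causal analysis on random subsamples of the paired
#' design: in each run a subsample of paired columns is drawn without
#' replacement (a stromal sample and the tumor sample its conditioned medium
#' stimulated are inseparable), both matrices are re-standardized on the
#' subsample, the CPDAG is re-estimated, IDA lower-bound effects are computed
#' for every (secreted, target) pair, and all pairs are ranked jointly by
#' absolute effect. A pair scores a run when it lands in the top
#' `top_fraction` of that ranking (ties at the cutoff included). Pairs whose
#' relative frequency reaches `freq_threshold` (`>=`) are retained; the
#' median lower bound across *all* runs is reported for every pair.
#'
#' @param stromal stromal network-gene matrix (raw, un-standardized).
#' @param tumor tumor target-gene matrix, columns paired with `stromal`.
#' @param secreted secreted candidate genes (subset of `rownames(stromal)`).
#' @param targets tumor target genes (subset of `rownames(tumor)`).
#' @param alpha PC test level.
#' @param n_runs number of subsampling runs.
#' @param subsample_size paired samples drawn per run; default
#'   `floor(0.8 * n)` (12 of 15 in the reference design).
#' @param top_fraction fraction `q` of top-ranked pairs scored per run.
#' @param freq_threshold retention threshold `pi` on the relative frequency.
#' @param max_cond_size optional cap on the PC conditioning-set size.
#' @param seed integer seed; per-run seeds are derived from it so runs are
#'   reproducible.
#' @param keep_ranks if `TRUE` (default) store the per-run rank fractions,
#'   enabling re-thresholding at other `(q, pi)` without re-running
#'   (see [calibrate()]).
#' @return object of class `stable_effects`: list with `table` (data frame
#'   `x`, `y`, `frequency`, `median_effect`, `retained`), `params`, and
#'   optionally `rank_frac` (pairs x runs matrix of rank fractions).
#' @export
stability_selection <- function(stromal, tumor, secreted, targets,
                                alpha = 0.2, n_runs = 100,
                                subsample_size = NULL, top_fraction = 0.30,
                                freq_threshold = 0.7, max_cond_size = Inf,
                                seed = NULL, keep_ranks = TRUE) {
  stopifnot(is.matrix(stromal), is.matrix(tumor),
            all(secreted %in% rownames(stromal)),
            all(targets %in% rownames(tumor)))
  if (ncol(stromal) != ncol(tumor))
    stop("unpaired samples: matrices must have the same number of columns")
  n <- ncol(stromal)
  if (is.null(subsample_size)) subsample_size <- floor(0.8 * n)
  if (subsample_size > n || subsample_size < 4)
    stop("'subsample_size' must be between 4 and the number of paired samples")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("'top_fraction' must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  pairs <- data.frame(x = rep(secreted, each = length(targets)),
                      y = rep(targets, length(secreted)),
                      stringsAsFactors = FALSE)
  N <- nrow(pairs)
  k_top <- ceiling(top_fraction * N)
  counts <- numeric(N)
  effects_runs <- matrix(NA_real_, N, n_runs)
  rank_frac <- if (keep_ranks) matrix(NA_real_, N, n_runs)

  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    idx <- sample.int(n, subsample_size)
    s_sub <- standardize(stromal[, idx, drop = FALSE])
    t_sub <- standardize(tumor[targets, idx, drop = FALSE])
    graph <- pc(s_sub, alpha = alpha, max_cond_size = max_cond_size)
    ida <- ida_lower_bounds(s_sub, t_sub, graph, secreted, targets)
    v <- abs(ida$lower_bound)
    cutoff <- sort(v, decreasing = TRUE)[k_top]
    counts <- counts + (v >= cutoff)
    effects_runs[, r] <- ida$lower_bound
    if (keep_ranks) rank_frac[, r] <- rank(-v, ties.method = "min") / N
  }

  tab <- data.frame(pairs,
                    frequency = counts / n_runs,
                    median_effect = apply(effects_runs, 1, median),
                    stringsAsFactors = FALSE)
  tab$retained <- stable_retain(tab$frequency, freq_threshold)
  structure(list(table = tab,
                 params = list(alpha = alpha, n_runs = n_runs,
                               subsample_size = subsample_size,
                               top_fraction = top_fraction,
                               freq_threshold = freq_threshold,
                               n_pairs = N, seed = seed),
                 rank_frac = if (keep_ranks) rank_frac,
                 run_seeds = run_seeds),
            class = "stable_effects")
}

#' Retention rule of stability selection
#'
#' A pair is retained iff its relative frequency is greater than *or equal
#' to* the threshold (a frequency of exactly 0.7 is kept at the default
#' threshold; 0.69999 is not).
#'
#' @param frequency numeric vector of relative frequencies in `[0, 1]`.
#' @param threshold retention threshold `pi`.
#' @return logical vector.
#' @export
stable_retain <- function(frequency, threshold) {
  stopifnot(all(frequency >= 0 & frequency <= 1))
  frequency >= threshold
}

#' @export
print.stable_effects <- function(x, ...) {
  cat("Stability selection over ", x$params$n_pairs, " (secreted, target) ",
      "pairs\n  runs: ", x$params$n_runs, ", subsample ",
      x$params$subsample_size, ", top fraction ", x$params$top_fraction,
      ", retention >= ", x$params$freq_threshold, "\n  retained pairs: ",
      sum(x$table$retained), "\n", sep = "")
  invisible(x)
}

#' Retained rows of a stability-selection result
#'
#' @param x a `stable_effects` object.
#' @param freq_threshold optionally re-threshold at a different `pi`.
#' @return data frame of retained `(x, y, frequency, median_effect)` rows.
#' @export
retained_effects <- function(x, freq_threshold = NULL) {
  stopifnot(inherits(x, "stable_effects"))
  thr <- freq_threshold %||% x$params$freq_threshold
  x$table[stable_retain(x$table$frequency, thr),
          c("x", "y", "frequency", "median_effect")]
}
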