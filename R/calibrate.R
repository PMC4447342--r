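#' Median rank aggregation across rankings
#'
#' @param rankings list of character vectors, each ordered best-first.
#' @return data frame `regulator`, `median_rank` over the union of entries
#'   (absence from a ranking counts as `length(ranking) + 1`), sorted by
#'   median rank then name.
#' @export
median_rank_aggregate <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 1)
  all_regs <- sort(unique(unlist(rankings)))
  ranks <- vapply(rankings, function(rk) {
    r <- match(all_regs, rk)
    r[is.na(r)] <- length(rk) + 1L
    r
  }, numeric(length(all_regs)))
  ranks <- matrix(ranks, nrow = length(all_regs))
  med <- apply(ranks, 1, median)
  out <- data.frame(regulator = all_regs, median_rank = med,
                    stringsAsFactors = FALSE)
  out[order(out$median_rank, out$regulator), , drop = FALSE]
}

#' Known-positive calibration of the retention parameters
#'
#' Sweeps the stability-selection retention parameters the way the study's
#' sensitivity analysis does: for each retention threshold `pi` in `pi_grid`,
#' the top-fraction parameter `q` is integrated out over `q_grid` — for every
#' pair the per-run top-`q` frequency is computed at each `q` and the median
#' frequency across the grid is compared against `pi`. Each `pi` yields a
#' retained pair set, target-set collection and MGSA ranking; regulators are
#' aggregated by median rank across the `pi` settings, and the settings in
#' which the known positive clears the posterior threshold `b` are reported.
#'
#' Requires a [stability_selection()] result built with `keep_ranks = TRUE`
#' (the per-run rank fractions allow re-thresholding without re-running the
#' causal analysis).
#'
#' @param stab a `stable_effects` object with stored rank fractions.
#' @param universe tumor gene universe for MGSA (the DE target list).
#' @param known_positive regulator gene that must appear in the final list;
#'   must be among the secreted candidates of `stab`.
#' @param pi_grid retention thresholds (default 0.80, 0.85, 0.90).
#' @param q_step step of the top-fraction grid on (0, 1].
#' @param b posterior threshold for "in the final list".
#' @param params optional `mgsa_params` shared by all MGSA runs.
#' @return list of class `calibration`: `per_pi` (per-setting results),
#'   `median_ranks`, `settings_with_positive` (pi values whose list contains
#'   the known positive), `known_positive`.
#' @export
calibrate <- function(stab, universe, known_positive,
                      pi_grid = c(0.80, 0.85, 0.90), q_step = 0.02,
                      b = 0.5, params = NULL) {
  stopifnot(inherits(stab, "stable_effects"))
  if (is.null(stab$rank_frac))
    stop("calibration needs a stability result with keep_ranks = TRUE")
  if (!known_positive %in% stab$table$x)
    stop("known positive '", known_positive,
         "' is not among the secreted candidates")
  q_grid <- seq(q_step, 1, by = q_step)
  # median over the q grid of the per-pair top-q frequency
  med_freq <- apply(stab$rank_frac, 1, function(rf) {
    median(vapply(q_grid, function(q) mean(rf <= q), numeric(1)))
  })
  per_pi <- lapply(pi_grid, function(pi) {
    keep <- stable_retain(med_freq, pi)
    rows <- stab$table[keep, c("x", "y", "frequency", "median_effect")]
    if (!nrow(rows))
      return(list(pi = pi, retained = rows, ranking = character(),
                  result = NULL, selected = character()))
    coll <- build_target_sets(rows, universe = universe)
    prm <- params %||% mgsa_params(n_sets = length(coll$sets))
    res <- mgsa_mcmc(coll, observed = universe, params = prm)
    list(pi = pi, retained = rows, ranking = res$regulator, result = res,
         selected = select_regulators(res, b = b))
  })
  names(per_pi) <- sprintf("pi_%0.2f", pi_grid)
  rankings <- lapply(per_pi, `[[`, "ranking")
  med_ranks <- median_rank_aggregate(rankings)
  hit <- vapply(per_pi, function(z) known_positive %in% z$selected,
                logical(1))
  structure(list(per_pi = per_pi, median_ranks = med_ranks,
                 settings_with_positive = pi_grid[hit],
                 known_positive = known_positive, b = b),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("Known-positive calibration (", x$known_positive, ", b = ", x$b,
      ")\n  settings retaining it: ",
      if (length(x$settings_with_positive))
        paste(x$settings_with_positive, collapse = ", ") else "none",
      "\n", sep = "")
  print(head(x$median_ranks, 10))
  invisible(x)
}
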