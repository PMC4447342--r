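#' Reorganize stable effects into regulator target sets
#'
#' Inverts the retained (secreted gene, tumor gene) pairs into one gene set
#' per regulator: `sets[[x]]` holds every tumor gene on which `x` exerts a
#' stable causal effect. Regulators with empty sets are omitted.
#'
#' @param stable a `stable_effects` object or a data frame with columns `x`,
#'   `y` (retained rows only).
#' @param universe tumor gene universe; defaults to the union of targets in
#'   the retained rows.
#' @return object of class `target_sets`: list with `sets` (named list of
#'   character vectors) and `universe`.
#' @export
build_target_sets <- function(stable, universe = NULL) {
  rows <- if (inherits(stable, "stable_effects")) retained_effects(stable)
          else stable
  stopifnot(all(c("x", "y") %in% names(rows)))
  if (!nrow(rows)) {
    warning("no retained effects: empty target-set collection")
    return(structure(list(sets = list(),
                          universe = universe %||% character()),
                     class = "target_sets"))
  }
  sets <- lapply(split(rows$y, rows$x), function(v) sort(unique(v)))
  sets <- sets[order(names(sets))]
  universe <- universe %||% sort(unique(rows$y))
  extra <- setdiff(unlist(sets), universe)
  if (length(extra))
    stop("target set members outside the universe: ",
         paste(head(extra, 5), collapse = ", "))
  structure(list(sets = sets, universe = universe), class = "target_sets")
}

#' @export
print.target_sets <- function(x, ...) {
  cat("Target-set collection: ", length(x$sets), " regulator sets over ",
      length(x$universe), " tumor genes\n", sep = "")
  invisible(x)
}

#' Log-likelihood of the set-activation observation model
#'
#' With hidden item state `h_i = 1` iff item `i` belongs to at least one
#' active set, observations flip with false-positive rate `alpha_fp`
#' (`P(on | h = 0)`) and false-negative rate `beta_fn` (`P(off | h = 1)`);
#' the returned value is the sum of `log P(obs_i | h_i)` over the universe.
#'
#' @param active character vector of active regulator names.
#' @param coll a `target_sets` collection.
#' @param observed character vector of observed-on tumor genes (subset of the
#'   universe).
#' @param alpha_fp,beta_fn rates strictly inside (0, 1).
#' @return log-likelihood (a non-positive number).
#' @export
mgsa_log_likelihood <- function(active, coll, observed, alpha_fp, beta_fn) {
  stopifnot(inherits(coll, "target_sets"),
            all(active %in% names(coll$sets)),
            all(observed %in% coll$universe))
  if (alpha_fp <= 0 || alpha_fp >= 1 || beta_fn <= 0 || beta_fn >= 1)
    stop("rates must lie strictly inside (0, 1)")
  h <- coll$universe %in% unlist(coll$sets[active])
  on <- coll$universe %in% observed
  sum(log(ifelse(h, ifelse(on, 1 - beta_fn, beta_fn),
                 ifelse(on, alpha_fp, 1 - alpha_fp))))
}

#' MGSA parameter settings
#'
#' Grids follow the spirit of the reference defaults: 10 points each for the
#' false-positive rate on (0.01, 0.3), the false-negative rate on
#' (0.05, 0.8), and the activation prior on (1/m, 0.5) where `m` is the
#' number of sets. Singleton grids fix a parameter.
#'
#' @param alpha_fp,beta_fn,p_active numeric grids strictly inside (0, 1), or
#'   `NULL` for the defaults (the `p_active` default needs `n_sets`).
#' @param n_sets number of sets, used for the default `p_active` grid.
#' @param n_iter,burnin MCMC sweeps and burn-in per restart.
#' @param n_restarts independent restarts averaged in the reported posterior.
#' @param seed optional integer seed.
#' @return list of class `mgsa_params`.
#' @export
mgsa_params <- function(alpha_fp = NULL, beta_fn = NULL, p_active = NULL,
                        n_sets = NULL, n_iter = 2e5, burnin = NULL,
                        n_restarts = 5, seed = NULL) {
  alpha_fp <- alpha_fp %||% seq(0.01, 0.3, length.out = 10)
  beta_fn <- beta_fn %||% seq(0.05, 0.8, length.out = 10)
  if (is.null(p_active)) {
    if (is.null(n_sets)) stop("'n_sets' is required for the default p grid")
    lo <- min(1 / n_sets, 0.45)
    p_active <- seq(lo, 0.5, length.out = 10)
  }
  for (g in list(alpha_fp, beta_fn, p_active))
    if (!length(g) || any(g <= 0) || any(g >= 1))
      stop("parameter grids must be nonempty and strictly inside (0, 1)")
  burnin <- burnin %||% max(1L, floor(n_iter / 5))
  if (n_iter <= burnin) stop("'n_iter' must exceed 'burnin'")
  structure(list(alpha_fp = alpha_fp, beta_fn = beta_fn,
                 p_active = p_active, n_iter = as.integer(n_iter),
                 burnin = as.integer(burnin),
                 n_restarts = as.integer(n_restarts), seed = seed),
            class = "mgsa_params")
}

#' Exact MGSA posteriors by exhaustive enumeration
#'
#' Sums prior times likelihood over all `2^m` activation states (and over the
#' parameter grids with uniform weights) to obtain exact marginal activation
#' posteriors. Feasible for small collections only; the exact oracle for
#' [mgsa_mcmc()].
#'
#' @param coll a `target_sets` collection with at most `max_sets` sets.
#' @param observed observed-on tumor genes.
#' @param params an `mgsa_params` object (grids may be singletons).
#' @param max_sets enumeration cap.
#' @return data frame of class `mgsa_result`: `regulator`, `set_size`,
#'   `posterior`, sorted by decreasing posterior.
#' @export
mgsa_exhaustive <- function(coll, observed, params, max_sets = 20) {
  stopifnot(inherits(coll, "target_sets"))
  m <- length(coll$sets)
  if (m == 0) stop("empty collection")
  if (m > max_sets)
    stop("too many sets to enumerate (", m, " > ", max_sets, ")")
  on <- coll$universe %in% observed
  n_on <- sum(on); n_off <- sum(!on)
  member <- vapply(coll$sets, function(s) coll$universe %in% s,
                   logical(length(coll$universe)))
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  k_active <- rowSums(states)
  # per-state counts of covered items among observed-on / observed-off
  H <- states %*% t(member * 1) > 0           # state x item coverage
  h1_on <- drop(H %*% on)
  h1_off <- drop(H %*% (!on))
  h0_on <- n_on - h1_on; h0_off <- n_off - h1_off

  # two passes: global log-sum-exp over (state, alpha, beta, p) with uniform
  # grid priors, so each parameter triple enters with its marginal likelihood
  M <- -Inf
  for (a in params$alpha_fp) for (b in params$beta_fn) {
    ll <- h0_on * log(a) + h0_off * log1p(-a) +
      h1_off * log(b) + h1_on * log1p(-b)
    for (p in params$p_active) {
      lp <- k_active * log(p) + (m - k_active) * log1p(-p)
      M <- max(M, max(ll + lp))
    }
  }
  weight <- numeric(nrow(states))
  for (a in params$alpha_fp) for (b in params$beta_fn) {
    ll <- h0_on * log(a) + h0_off * log1p(-a) +
      h1_off * log(b) + h1_on * log1p(-b)
    for (p in params$p_active) {
      lp <- k_active * log(p) + (m - k_active) * log1p(-p)
      weight <- weight + exp(ll + lp - M)
    }
  }
  post <- colSums(states * weight) / sum(weight)
  res <- data.frame(regulator = names(coll$sets),
                    set_size = vapply(coll$sets, length, integer(1)),
                    posterior = unname(post), stringsAsFactors = FALSE)
  res <- res[order(-res$posterior, res$regulator), ]
  rownames(res) <- NULL
  class(res) <- c("mgsa_result", "data.frame")
  res
}

#' MGSA marginal posteriors by MCMC
#'
#' Metropolis-Gibbs sampling over the set-activation bit vector (single-bit
#' toggles and active/inactive swaps) with Metropolis moves of the
#' false-positive rate, false-negative rate and activation prior over their
#' grids. Marginal posteriors are post-burn-in activation frequencies,
#' averaged over independent restarts; the restart-to-restart spread is
#' attached as attribute `"restart_spread"`.
#'
#' @inheritParams mgsa_exhaustive
#' @return data frame of class `mgsa_result` as in [mgsa_exhaustive()].
#' @export
mgsa_mcmc <- function(coll, observed, params = NULL) {
  stopifnot(inherits(coll, "target_sets"))
  m <- length(coll$sets)
  if (m == 0) stop("empty collection")
  params <- params %||% mgsa_params(n_sets = m)
  stopifnot(inherits(params, "mgsa_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  on <- coll$universe %in% observed
  idx_sets <- lapply(coll$sets, function(s)
    match(s, coll$universe) - 1L)
  draws <- matrix(NA_real_, m, params$n_restarts)
  for (r in seq_len(params$n_restarts)) {
    fit <- mgsa_mcmc_cpp(idx_sets, length(coll$universe), on,
                         params$alpha_fp, params$beta_fn, params$p_active,
                         params$n_iter, params$burnin)
    draws[, r] <- fit$posterior
  }
  post <- rowMeans(draws)
  res <- data.frame(regulator = names(coll$sets),
                    set_size = vapply(coll$sets, length, integer(1)),
                    posterior = post, stringsAsFactors = FALSE)
  res <- res[order(-res$posterior, res$regulator), ]
  rownames(res) <- NULL
  attr(res, "restart_spread") <-
    setNames(apply(draws, 1, function(v) diff(range(v))),
             names(coll$sets))
  class(res) <- c("mgsa_result", "data.frame")
  res
}

#' Declare the most important regulators
#'
#' @param result an `mgsa_result`.
#' @param b posterior probability threshold (strict `>`).
#' @return character vector of regulators with posterior above `b`, ranked by
#'   decreasing posterior.
#' @export
select_regulators <- function(result, b = 0.5) {
  stopifnot(inherits(result, "mgsa_result"))
  res <- result[result$posterior > b, ]
  res$regulator[order(-res$posterior, res$regulator)]
}
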