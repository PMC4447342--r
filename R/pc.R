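#' Partial correlation via precision of the sub-correlation matrix
#'
#' Computes `rho(x, y | S)` by inverting the correlation submatrix on
#' `{x, y} union S`: `rho = -P_xy / sqrt(P_xx * P_yy)` with `P` the inverse.
#' If the submatrix is numerically singular (reciprocal condition number below
#' `tol`) an SVD pseudo-inverse is used; if the effective rank leaves the
#' diagonal of `P` non-positive a numerical-rank error is raised.
#'
#' @param corr symmetric correlation matrix.
#' @param x,y node names or indices.
#' @param S conditioning set (names or indices), excluding `x`, `y`.
#' @param tol singularity tolerance.
#' @return partial correlation, clamped to `[-1, 1]`.
#' @export
partial_correlation <- function(corr, x, y, S = NULL, tol = 1e-10) {
  idx <- resolve_nodes(corr, c(x, y, S))
  if (anyDuplicated(idx)) stop("'x', 'y' and 'S' must be distinct nodes")
  if (length(idx) == 2L) return(max(-1, min(1, corr[idx[1], idx[2]])))
  sub <- corr[idx, idx, drop = FALSE]
  P <- tryCatch({
    if (rcond(sub) < tol) stop("singular") else solve(sub)
  }, error = function(e) pseudo_inverse(sub, tol))
  if (P[1, 1] <= 0 || P[2, 2] <= 0)
    stop("numerical-rank error: conditioning set leaves no residual variance")
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  max(-1, min(1, r))
}

resolve_nodes <- function(corr, nodes) {
  if (is.character(nodes)) {
    idx <- match(nodes, rownames(corr))
    if (anyNA(idx)) stop("unknown node(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(nodes)
}

pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) stop("numerical-rank error: submatrix has rank 0")
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fisher-z conditional-independence decision
#'
#' Declares `x` and `y` dependent given a conditioning set of size `s` iff
#' `sqrt(n - s - 3) * |atanh(r)| > qnorm(1 - alpha / 2)`.
#'
#' @param r (partial) correlation in `[-1, 1]`.
#' @param n sample count.
#' @param s conditioning set size.
#' @param alpha significance level in (0, 1).
#' @return `"independent"` or `"dependent"`.
#' @export
fisher_z_decision <- function(r, n, s, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (n - s - 3 <= 0)
    stop("insufficient samples for Fisher-z at conditioning size ", s)
  if (abs(r) >= 1) return("dependent")
  z <- 0.5 * log((1 + r) / (1 - r))
  if (sqrt(n - s - 3) * abs(z) > qnorm(1 - alpha / 2)) "dependent"
  else "independent"
}

#' PC-stable skeleton from data
#'
#' Order-independent (PC-stable) skeleton search with Fisher-z
#' partial-correlation tests: starting from the complete graph, at level
#' `l = 0, 1, ...` every remaining edge `(x, y)` is tested against every
#' size-`l` subset of the level-start adjacency of `x` and of `y`; the edge is
#' removed on the first declared independence and the separating set recorded.
#' Levels where the Fisher-z test is undefined (`n - l - 3 <= 0`) are not
#' entered, so small samples bound the search depth implicitly.
#'
#' @param data standardized genes x samples matrix (rows are variables).
#' @param alpha test level (the spec default for the full pipeline is 0.2).
#' @param max_cond_size optional cap on the conditioning-set size.
#' @return list with logical adjacency matrix `adj` and `sepsets` (a named
#'   list keyed `"a|b"` with node-name vectors).
#' @export
estimate_skeleton <- function(data, alpha = 0.2, max_cond_size = Inf) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  n <- ncol(data)
  if (n < 4) stop("at least 4 samples are required")
  corr <- cor(t(data))
  lmax <- min(max_cond_size, n - 4)
  res <- pc_skeleton_cpp(corr, n, alpha, as.integer(lmax))
  nodes <- rownames(data)
  adj <- res$adj
  dimnames(adj) <- list(nodes, nodes)
  seps <- lapply(res$sep_sets, function(ix) nodes[ix])
  names(seps) <- paste(nodes[res$sep_i], nodes[res$sep_j], sep = "|")
  list(adj = adj, sepsets = seps, nodes = nodes)
}

#' Reference PC-stable skeleton engine with a pluggable independence test
#'
#' Pure-R engine used for population-oracle runs and as an independent
#' cross-check of the compiled search. `indep_test(i, j, S)` must return
#' `TRUE` (independent), `FALSE` (dependent) or `NA` (not testable; the edge
#' is kept).
#'
#' @param nodes character vector of variable names.
#' @param indep_test function of `(i, j, S)` over integer indices.
#' @param max_cond_size cap on conditioning-set size.
#' @return as [estimate_skeleton()].
#' @export
skeleton_engine <- function(nodes, indep_test, max_cond_size = Inf) {
  p <- length(nodes)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  seps <- list()
  l <- 0
  repeat {
    snapshot <- adj
    for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
      if (!adj[i, j]) next
      found <- FALSE
      for (side in 1:2) {
        a <- if (side == 1) i else j
        b <- if (side == 1) j else i
        nb <- setdiff(which(snapshot[a, ]), b)
        if (length(nb) < l) next
        subsets <- if (l == 0) list(integer(0))
                   else if (length(nb) == 1) list(nb)  # combn(n, l) pitfall
                   else combn(nb, l, simplify = FALSE)
        for (S in subsets) {
          verdict <- indep_test(a, b, S)
          if (isTRUE(verdict)) {
            adj[i, j] <- adj[j, i] <- FALSE
            seps[[paste(nodes[i], nodes[j], sep = "|")]] <- nodes[S]
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
    l <- l + 1
    if (l > max_cond_size) break
    # continue only if some edge still has a large enough neighborhood
    deg <- rowSums(adj)
    if (!any(adj & (deg - 1 >= l))) break
  }
  dimnames(adj) <- list(nodes, nodes)
  list(adj = adj, sepsets = seps, nodes = nodes)
}

#' Population-oracle CPDAG (faithfulness oracle)
#'
#' Runs the PC search with exact population partial correlations derived from
#' a covariance matrix: independence is declared iff `|rho(x, y | S)| < tol`.
#' Under faithfulness this recovers the true CPDAG exactly.
#'
#' @param sigma population covariance (e.g. [sem_covariance()]).
#' @param tol zero threshold for population partial correlations.
#' @param max_cond_size cap on conditioning-set size.
#' @return a `cpdag` object.
#' @export
pc_population <- function(sigma, tol = 1e-8, max_cond_size = Inf) {
  stopifnot(is.matrix(sigma), !is.null(rownames(sigma)))
  corr <- cov2cor(sigma)
  nodes <- rownames(corr)
  test <- function(i, j, S) {
    abs(partial_correlation(corr, i, j, S)) < tol
  }
  sk <- skeleton_engine(nodes, test, max_cond_size)
  orient_cpdag(sk)
}

#' PC algorithm: CPDAG estimate from standardized expression data
#'
#' [estimate_skeleton()] followed by [orient_cpdag()]; deterministic and
#' order-independent given the data (PC-stable with a conservative conflict
#' rule).
#'
#' @inheritParams estimate_skeleton
#' @return a `cpdag` object.
#' @export
pc <- function(data, alpha = 0.2, max_cond_size = Inf) {
  orient_cpdag(estimate_skeleton(data, alpha = alpha,
                                 max_cond_size = max_cond_size))
}
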