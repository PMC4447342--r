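#' Local adjustment sets of a node in a CPDAG
#'
#' Enumerates the adjustment sets of the local IDA method: with `pa` the
#' certain parents of `x` and `sib` its undirected neighbors, every subset
#' `S` of `sib` whose members are pairwise adjacent (and adjacent to every
#' certain parent) is locally valid — orienting `S -> x` then creates no new
#' v-structure pointing at `x` — and yields the adjustment set `pa union S`.
#' For a Meek-closed CPDAG the parent-adjacency clause is automatic; it only
#' bites on estimated graphs carrying orientation conflicts.
#'
#' @param cpdag a `cpdag` object.
#' @param x node name.
#' @return list of character vectors (possibly containing the empty set),
#'   deduplicated, in deterministic order.
#' @export
local_adjustment_sets <- function(cpdag, x) {
  stopifnot(inherits(cpdag, "cpdag"))
  xi <- match(x, cpdag$nodes)
  if (is.na(xi)) stop("node not in CPDAG: ", x)
  a <- cpdag$amat
  pa <- which(a[, xi] == 1L & a[xi, ] == 0L)
  sib <- which(a[, xi] == 1L & a[xi, ] == 1L)
  adjacent <- (a == 1L) | (t(a) == 1L)
  # siblings incompatible with some certain parent can never enter S
  if (length(pa))
    sib <- sib[vapply(sib, function(s) all(adjacent[s, pa]), logical(1))]
  # enumerate all cliques (incl. empty) among the surviving siblings
  cliques <- list(integer(0))
  expand <- function(cur, cand) {
    for (k in seq_along(cand)) {
      v <- cand[k]
      cliques[[length(cliques) + 1L]] <<- c(cur, v)
      rest <- cand[-seq_len(k)]
      rest <- rest[adjacent[v, rest]]
      if (length(rest)) expand(c(cur, v), rest)
    }
  }
  if (length(sib)) expand(integer(0), sib)
  lapply(cliques, function(S) cpdag$nodes[sort(c(pa, S))])
}

#' Covariate-adjusted causal effect of one gene on one target
#'
#' Least-squares regression of `y` on `x` and the adjustment set (with
#' intercept); on standardized data the returned coefficient of `x` is the
#' expected change of `y` under a one-standard-unit intervention on `x`.
#'
#' @param stromal stromal genes x paired-samples matrix.
#' @param tumor tumor genes x paired-samples matrix (same sample count,
#'   paired by position).
#' @param x stromal gene; must not be in `adjust`.
#' @param y tumor gene.
#' @param adjust character vector of stromal adjustment genes.
#' @return the regression coefficient of `x`.
#' @export
adjusted_effect <- function(stromal, tumor, x, y, adjust = character()) {
  if (ncol(stromal) != ncol(tumor))
    stop("unpaired samples: matrices must have the same number of columns")
  if (x %in% adjust) stop("'x' must not be in the adjustment set")
  X <- cbind(`(Intercept)` = 1, t(stromal[c(x, adjust), , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient (collinear) design for genes: ",
         paste(c(x, adjust), collapse = ", "))
  unname(qr.coef(qx, tumor[y, ])[2])
}

#' IDA lower-bound effects of secreted genes on tumor targets
#'
#' For every pair (secreted gene `x`, tumor gene `y`) computes the multiset
#' of adjusted effects, one per local adjustment set of `x`, and summarizes it
#' by the member with minimum absolute value, sign preserved — a conservative
#' lower bound over the Markov equivalence class.
#'
#' Batch regressions use pivoted QR least squares: adjustment sets larger than
#' the sample size yield rank-deficient designs whose excess covariates are
#' dropped by pivoting while the coefficient of `x` (entered first) is kept.
#'
#' @param stromal standardized stromal (network gene) matrix.
#' @param tumor standardized tumor target matrix (paired columns).
#' @param cpdag `cpdag` over the stromal genes.
#' @param secreted secreted candidate genes (subset of CPDAG nodes).
#' @param targets tumor target genes (rows of `tumor`).
#' @param keep_all if `TRUE`, attach the full per-set effect matrices as
#'   attribute `"effects"` (a list over `secreted`).
#' @return data frame with columns `x`, `y`, `lower_bound`, `n_sets`, ordered
#'   by `secreted` then `targets`.
#' @export
ida_lower_bounds <- function(stromal, tumor, cpdag, secreted, targets,
                             keep_all = FALSE) {
  stopifnot(inherits(cpdag, "cpdag"),
            all(secreted %in% cpdag$nodes),
            all(targets %in% rownames(tumor)))
  if (ncol(stromal) != ncol(tumor))
    stop("unpaired samples: matrices must have the same number of columns")
  Y <- t(tumor[targets, , drop = FALSE])
  all_eff <- if (keep_all) vector("list", length(secreted))
  out <- vector("list", length(secreted))
  for (si in seq_along(secreted)) {
    x <- secreted[si]
    sets <- local_adjustment_sets(cpdag, x)
    eff <- matrix(NA_real_, length(sets), length(targets),
                  dimnames = list(NULL, targets))
    for (k in seq_along(sets)) {
      X <- cbind(1, t(stromal[c(x, sets[[k]]), , drop = FALSE]))
      cf <- qr.coef(qr(X), Y)
      eff[k, ] <- cf[2, ]
    }
    eff[is.na(eff)] <- 0  # aliased coefficient (degenerate subsample)
    pick <- apply(abs(eff), 2, which.min)
    lb <- eff[cbind(pick, seq_along(targets))]
    out[[si]] <- data.frame(x = x, y = targets, lower_bound = lb,
                            n_sets = length(sets),
                            stringsAsFactors = FALSE)
    if (keep_all) all_eff[[si]] <- eff
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (keep_all) {
    names(all_eff) <- secreted
    attr(res, "effects") <- all_eff
  }
  res
}

#' Exhaustive IDA oracle over all DAG extensions of a CPDAG
#'
#' Enumerates every consistent DAG extension of the CPDAG (all orientations
#' of the undirected edges that are acyclic and create no v-structure beyond
#' those of the class) and computes the adjusted effect of `x` on `y` using
#' that DAG's parent set. Intended as a testing oracle for the local method.
#'
#' @param cpdag a `cpdag` with at most `max_undirected` undirected edges.
#' @param stromal,tumor paired standardized matrices.
#' @param x stromal gene; `y` tumor gene.
#' @param max_undirected enumeration cap.
#' @return numeric vector of effects, one per DAG extension.
#' @export
global_ida_oracle <- function(cpdag, stromal, tumor, x, y,
                              max_undirected = 12) {
  stopifnot(inherits(cpdag, "cpdag"))
  a <- cpdag$amat
  p <- nrow(a)
  und <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  u <- nrow(und)
  if (u > max_undirected)
    stop("too many undirected edges to enumerate (", u, " > ",
         max_undirected, ")")
  vs0 <- v_structures(a)
  xi <- match(x, cpdag$nodes)
  effects <- numeric(0)
  for (mask in seq_len(2^u) - 1L) {
    b <- a
    for (k in seq_len(u)) {
      i <- und[k, 1]; j <- und[k, 2]
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L))) b[j, i] <- 0L  # i -> j
      else b[i, j] <- 0L                                        # j -> i
    }
    E <- (b == 1L) & (t(b) == 0L)
    if (is.null(topological_order(E))) next
    if (!identical(v_structures(b), vs0)) next
    pa <- cpdag$nodes[which(E[, xi])]
    effects <- c(effects,
                 adjusted_effect(stromal, tumor, x, y, adjust = pa))
  }
  effects
}
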