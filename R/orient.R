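#' @title CPDAG objects
#' @description A `cpdag` holds nodes, an adjacency code matrix `amat`
#'   (`amat[i, j] == 1 && amat[j, i] == 0` encodes the directed edge i -> j;
#'   both 1 encodes an undirected edge), the separating sets recorded during
#'   skeleton search, and any conflicting v-structure orientations (left
#'   undirected, conservatively).
#' @param nodes character vector of node names.
#' @param amat integer 0/1 adjacency code matrix.
#' @param sepsets named list of separating sets.
#' @param conflicts character vector of contested edges ("a|b").
#' @return an object of class `cpdag`.
#' @export
cpdag <- function(nodes, amat, sepsets = list(), conflicts = character()) {
  stopifnot(is.matrix(amat), nrow(amat) == length(nodes))
  dimnames(amat) <- list(nodes, nodes)
  if (any(diag(amat) != 0)) stop("self-loops are not allowed")
  structure(list(nodes = nodes, amat = amat, sepsets = sepsets,
                 conflicts = conflicts),
            class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  ed <- cpdag_edges(x)
  cat("CPDAG with ", length(x$nodes), " nodes, ",
      sum(ed$type == "directed"), " directed and ",
      sum(ed$type == "undirected"), " undirected edges\n", sep = "")
  if (length(x$conflicts))
    cat("  ", length(x$conflicts),
        " conflicting v-structure edge(s) left undirected\n", sep = "")
  invisible(x)
}

#' Edge list of a CPDAG
#'
#' @param x a `cpdag`.
#' @return data frame with columns `source`, `target`,
#'   `type` (`"directed"`/`"undirected"`); undirected edges appear once with
#'   `source < target` lexicographically.
#' @export
cpdag_edges <- function(x) {
  a <- x$amat
  D <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  U <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  out <- data.frame(
    source = c(x$nodes[D[, 1]], pmin(x$nodes[U[, 1]], x$nodes[U[, 2]])),
    target = c(x$nodes[D[, 2]], pmax(x$nodes[U[, 1]], x$nodes[U[, 2]])),
    type = rep(c("directed", "undirected"), c(nrow(D), nrow(U))),
    stringsAsFactors = FALSE)
  out[order(out$type, out$source, out$target), , drop = FALSE]
}

#' Orient a skeleton into a CPDAG (v-structures + Meek closure)
#'
#' Unshielded triples `x - z - y` are oriented as the collider `x -> z <- y`
#' iff `z` is absent from the recorded separating set of `(x, y)`; edges whose
#' two endpoints are demanded as arrowheads by different triples are left
#' undirected (conservative conflict rule, recorded in `$conflicts`). Meek
#' rules R1-R4 are then applied to closure in a fixed deterministic order.
#'
#' @param skeleton list with `adj` (logical adjacency), `sepsets`, `nodes`,
#'   as returned by [estimate_skeleton()] or [skeleton_engine()].
#' @return a `cpdag` object.
#' @export
orient_cpdag <- function(skeleton) {
  adj <- skeleton$adj
  nodes <- skeleton$nodes
  p <- length(nodes)
  amat <- matrix(as.integer(adj), p, p, dimnames = list(nodes, nodes))

  # --- v-structures ----------------------------------------------------
  sepenv <- list2env(skeleton$sepsets, hash = TRUE,
                     parent = emptyenv())  # hashed lookup
  head_at <- matrix(FALSE, p, p)  # head_at[i, j]: some triple demands i -> j
  for (z in seq_len(p)) {
    nb <- which(adj[z, ])
    if (length(nb) < 2) next
    for (a in nb) for (b in nb) {
      if (a >= b || adj[a, b]) next
      key <- paste(nodes[a], nodes[b], sep = "|")
      # a triple is only orientable when the pair's removal was recorded;
      # without a separating set nothing can be concluded about z
      if (!exists(key, envir = sepenv, inherits = FALSE)) next
      if (!nodes[z] %in% get(key, envir = sepenv)) {
        head_at[a, z] <- TRUE
        head_at[b, z] <- TRUE
      }
    }
  }
  conflicts <- character()
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (!adj[i, j]) next
    if (head_at[i, j] && head_at[j, i]) {
      conflicts <- c(conflicts, paste(nodes[i], nodes[j], sep = "|"))
    } else if (head_at[i, j]) {
      amat[j, i] <- 0L
    } else if (head_at[j, i]) {
      amat[i, j] <- 0L
    }
  }

  amat <- meek_closure(amat)
  cpdag(nodes, amat, sepsets = skeleton$sepsets, conflicts = conflicts)
}

# Meek rules R1-R4 applied to a partially directed graph until fixpoint.
# Rules only orient currently-undirected edges; directed edges are never
# flipped. R4 (sound without the classical background-knowledge chain
# requirement: a-b, a-c, c->d, d->b, c and b non-adjacent => a->b) is inert
# when orientation starts from v-structures only, but kept for completeness.
meek_closure <- function(amat) {
  p <- nrow(amat)
  repeat {
    D <- (amat == 1L) & (t(amat) == 0L)   # D[i, j]: i -> j
    U <- (amat == 1L) & (t(amat) == 1L)   # undirected
    A <- amat == 1L | t(amat) == 1L       # any adjacency
    nonadj <- !A; diag(nonadj) <- FALSE

    # demand[i, j] == TRUE requests orienting i -> j
    # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
    demand <- U & (crossprod(D * 1, nonadj * 1) > 0)
    # R2: a - b with a directed path a -> c -> b  =>  a -> b
    demand <- demand | (U & ((D %*% D) > 0))
    # R3: a - b; a - c, a - d; c -> b, d -> b; c, d non-adjacent  =>  a -> b
    # R4: a - b; a - c; c -> d -> b; c, b non-adjacent            =>  a -> b
    DD <- (D %*% D) > 0
    und <- which(U, arr.ind = TRUE)
    for (k in seq_len(nrow(und))) {
      a <- und[k, 1]; b <- und[k, 2]
      if (demand[a, b]) next
      cand <- which(U[a, ] & D[, b])
      if (length(cand) >= 2 && any(nonadj[cand, cand])) {
        demand[a, b] <- TRUE
        next
      }
      if (any(U[a, ] & nonadj[, b] & DD[, b])) demand[a, b] <- TRUE
    }

    idx <- which(demand, arr.ind = TRUE)
    if (nrow(idx)) idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    changed <- FALSE
    for (k in seq_len(nrow(idx))) {
      a <- idx[k, 1]; b <- idx[k, 2]
      if (amat[a, b] == 1L && amat[b, a] == 1L) {  # still undirected
        amat[b, a] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  amat
}

#' CPDAG of a ground-truth DAG
#'
#' Builds the Markov-equivalence-class representative of a DAG: its skeleton
#' with the DAG's v-structures oriented, completed by Meek closure.
#'
#' @param W weighted (or logical) adjacency matrix of the DAG, `W[i, j] != 0`
#'   meaning i -> j.
#' @return a `cpdag` object.
#' @export
dag_to_cpdag <- function(W) {
  stopifnot(is.matrix(W), !is.null(rownames(W)))
  nodes <- rownames(W)
  p <- length(nodes)
  E <- W != 0
  if (is.null(topological_order(E))) stop("input is not a DAG")
  amat <- matrix(as.integer(E | t(E)), p, p, dimnames = list(nodes, nodes))
  for (z in seq_len(p)) {
    pa <- which(E[, z])
    if (length(pa) < 2) next
    for (a in pa) for (b in pa) {
      if (a >= b || E[a, b] || E[b, a]) next
      amat[z, a] <- 0L
      amat[z, b] <- 0L
    }
  }
  cpdag(nodes, meek_closure(amat))
}

#' Structural Hamming distance between two CPDAGs
#'
#' Counts node pairs whose edge mark differs (absent / undirected / each
#' direction counted as distinct states); one unit per differing pair.
#'
#' @param x,y `cpdag` objects over the same node set.
#' @return non-negative integer.
#' @export
shd <- function(x, y) {
  stopifnot(setequal(x$nodes, y$nodes))
  a <- x$amat
  b <- y$amat[x$nodes, x$nodes]
  d <- 0L
  p <- nrow(a)
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    sa <- paste(a[i, j], a[j, i])
    sb <- paste(b[i, j], b[j, i])
    if (sa != sb) d <- d + 1L
  }
  d
}

# v-structures of a directed graph or CPDAG as a character set "a->z<-b".
v_structures <- function(amat) {
  p <- nrow(amat)
  nodes <- rownames(amat)
  D <- (amat == 1L) & (t(amat) == 0L)
  A <- amat == 1L | t(amat) == 1L
  out <- character()
  for (z in seq_len(p)) {
    pa <- which(D[, z])
    if (length(pa) < 2) next
    for (a in pa) for (b in pa) {
      if (a >= b || A[a, b]) next
      out <- c(out, paste0(nodes[a], ">", nodes[z], "<", nodes[b]))
    }
  }
  sort(out)
}
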