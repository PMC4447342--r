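#' Draw a random sparse DAG with edge weights
#'
#' Nodes are taken in a fixed topological order and each forward edge is
#' included independently with probability `expected_degree / (n_nodes - 1)`,
#' so the graph is acyclic by construction and the expected number of edges is
#' `n_nodes * expected_degree / 2`. Edge weights are drawn uniformly from
#' `weight_range` in magnitude with random sign.
#'
#' @param n_nodes number of stromal genes (>= 2).
#' @param expected_degree expected number of neighbors per node; must be
#'   positive and smaller than `n_nodes - 1`.
#' @param weight_range length-2 numeric, `0 < min <= max`; magnitudes of the
#'   structural coefficients.
#' @param seed optional integer seed for reproducibility.
#' @param node_labels optional character vector of gene labels.
#' @return A `ground_truth` model holding the weighted adjacency matrix `W`
#'   (`W[i, j]` is the coefficient of edge i -> j) and unit noise standard
#'   deviations; downstream fields (secreted mask, planted effects) are empty.
#' @seealso [simulate_study()] for the full paired-design generator.
#' @export
make_random_dag <- function(n_nodes, expected_degree, weight_range = c(0.5, 1.5),
                            seed = NULL, node_labels = NULL) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2)
    stop("'n_nodes' must be a single integer >= 2")
  n_nodes <- as.integer(n_nodes)
  if (!is.numeric(expected_degree) || expected_degree <= 0 ||
      expected_degree >= n_nodes - 1 + 1e-12)
    stop("'expected_degree' must lie in (0, n_nodes - 1)")
  if (length(weight_range) != 2L || any(!is.finite(weight_range)) ||
      weight_range[1] <= 0 || weight_range[1] > weight_range[2])
    stop("'weight_range' must satisfy 0 < min <= max (magnitudes; sign is random)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(node_labels)) node_labels <- sprintf("g%03d", seq_len(n_nodes))
  stopifnot(length(node_labels) == n_nodes, !anyDuplicated(node_labels))

  p_edge <- expected_degree / (n_nodes - 1)
  W <- matrix(0, n_nodes, n_nodes, dimnames = list(node_labels, node_labels))
  idx <- which(upper.tri(W))
  present <- idx[runif(length(idx)) < p_edge]
  if (length(present)) {
    mag <- runif(length(present), weight_range[1], weight_range[2])
    sgn <- sample(c(-1, 1), length(present), replace = TRUE)
    W[present] <- mag * sgn
  }
  ground_truth_model(W = W, noise_sd = rep(1, n_nodes))
}

#' Construct (and validate) a ground-truth structural model
#'
#' @param W weighted adjacency matrix over stromal genes; `W[i, j]` is the
#'   linear coefficient of edge i -> j. Must describe an acyclic graph.
#' @param noise_sd per-node positive noise standard deviation.
#' @param baseline per-gene mean expression on the log2 scale (defaults to 0).
#' @param secreted character vector of stromal genes flagged secreted.
#' @param regulator_effects data frame with columns `x` (secreted stromal
#'   gene), `y` (tumor gene) and `beta` (linear effect).
#' @param null_targets tumor genes with no stromal driver.
#' @param control_shift named per-tumor-gene baseline offset shared by
#'   stimulated and control samples.
#' @param flags optional gene-annotation data frame (see [simulate_study()]).
#' @return An object of class `ground_truth`.
#' @export
ground_truth_model <- function(W, noise_sd, baseline = NULL,
                               secreted = character(),
                               regulator_effects = NULL,
                               null_targets = character(),
                               control_shift = NULL, flags = NULL) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), !is.null(rownames(W)))
  nodes <- rownames(W)
  ord <- topological_order(W != 0)
  if (is.null(ord)) stop("'W' contains a directed cycle")
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, nrow(W))
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0))
    stop("'noise_sd' must be positive for all nodes")
  names(noise_sd) <- nodes
  if (is.null(baseline)) baseline <- rep(0, nrow(W))
  if (length(baseline) == 1L) baseline <- rep(baseline, nrow(W))
  names(baseline) <- nodes
  if (is.null(regulator_effects))
    regulator_effects <- data.frame(x = character(), y = character(),
                                    beta = numeric())
  stopifnot(all(c("x", "y", "beta") %in% names(regulator_effects)))
  if (!all(regulator_effects$x %in% secreted))
    stop("every regulator in 'regulator_effects' must be in the secreted mask")
  if (!all(secreted %in% nodes))
    stop("secreted genes must be stromal nodes")
  tumor_genes <- sort(unique(c(regulator_effects$y, null_targets)))
  if (is.null(control_shift)) control_shift <- setNames(rep(0, length(tumor_genes)),
                                                        tumor_genes)
  structure(list(nodes = nodes, W = W, noise_sd = noise_sd,
                 baseline = baseline, secreted = secreted,
                 regulator_effects = regulator_effects,
                 null_targets = null_targets, tumor_genes = tumor_genes,
                 control_shift = control_shift, flags = flags,
                 topo_order = ord),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth structural model\n",
      "  stromal genes: ", length(x$nodes),
      " (", sum(x$W != 0), " edges)\n",
      "  secreted: ", length(x$secreted),
      "; planted regulators: ", length(unique(x$regulator_effects$x)), "\n",
      "  tumor genes: ", length(x$tumor_genes),
      " (", length(x$null_targets), " null)\n", sep = "")
  invisible(x)
}

# Kahn topological sort on a logical adjacency matrix; NULL if cyclic.
topological_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  out <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    ch <- which(adj[v, ])
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (!is.na(indeg[c]) && indeg[c] == 0L) {
        avail <- c(avail, c)
        indeg[c] <- NA
      }
    }
  }
  if (length(out) < n) NULL else out
}

#' Population covariance implied by the structural model
#'
#' Closed form `(I - W')^{-1} D (I - W)^{-1}` with `W` the weight matrix and
#' `D` the diagonal of noise variances; useful as an oracle for tests and for
#' population-level (faithfulness) analyses.
#'
#' @param model a `ground_truth` model.
#' @return Covariance matrix over stromal genes.
#' @export
sem_covariance <- function(model) {
  n <- length(model$nodes)
  A <- solve(diag(n) - t(model$W))
  S <- A %*% diag(model$noise_sd^2, n) %*% t(A)
  dimnames(S) <- list(model$nodes, model$nodes)
  S
}

#' Sample stromal expression from the structural model
#'
#' Each sample is drawn by the topological-order recursion
#' `x_j = baseline_j + sum_parents w * (x_parent - baseline_parent) + eps_j`,
#' `eps_j ~ N(0, noise_sd_j^2)`, i.e. the centred process follows the
#' linear-Gaussian structural equations exactly.
#'
#' @param model a `ground_truth` model.
#' @param n_samples number of donors (columns) to draw.
#' @param seed optional integer seed.
#' @return genes x samples numeric matrix with sample ids `hsc_01, ...` and a
#'   `sample_role` attribute (`"stromal"`).
#' @export
sample_stromal_expression <- function(model, n_samples, seed = NULL) {
  stopifnot(inherits(model, "ground_truth"))
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("'n_samples' must be >= 1")
  n_samples <- as.integer(n_samples)
  if (!is.null(seed)) set.seed(seed)
  n <- length(model$nodes)
  eps <- matrix(rnorm(n * n_samples), n, n_samples) * model$noise_sd
  x <- solve(diag(n) - t(model$W), eps) + model$baseline
  dimnames(x) <- list(model$nodes,
                      sprintf("hsc_%02d", seq_len(n_samples)))
  attr(x, "sample_role") <- rep("stromal", n_samples)
  x
}

#' Sample tumor response to conditioned medium
#'
#' Stimulated tumor samples respond linearly to the secreted expression of the
#' paired stromal donor: `y = shift_y + sum effects beta * x_secreted + eps`;
#' unstimulated controls receive `shift_y + eps` only (the stromal term is
#' zeroed). Null target genes carry shift plus noise in both groups.
#'
#' @param model a `ground_truth` model with tumor genes defined.
#' @param stromal stromal expression matrix from
#'   [sample_stromal_expression()]; must contain every secreted regulator.
#' @param n_controls number of unstimulated control samples (>= 0).
#' @param target_noise_sd positive tumor noise standard deviation.
#' @param seed optional integer seed.
#' @return list with `stimulated` (genes x paired samples) and `controls`
#'   (genes x n_controls) matrices; both carry a `sample_role` attribute.
#' @export
sample_tumor_response <- function(model, stromal, n_controls = 4,
                                  target_noise_sd = 1, seed = NULL) {
  stopifnot(inherits(model, "ground_truth"), is.matrix(stromal))
  if (n_controls < 0) stop("'n_controls' must be >= 0")
  if (target_noise_sd <= 0) stop("'target_noise_sd' must be positive")
  regs <- unique(model$regulator_effects$x)
  missing <- setdiff(regs, rownames(stromal))
  if (length(missing))
    stop("stromal matrix is missing secreted regulator(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  genes <- model$tumor_genes
  n_stim <- ncol(stromal)
  B <- matrix(0, length(genes), length(regs),
              dimnames = list(genes, regs))
  if (nrow(model$regulator_effects))
    B[cbind(model$regulator_effects$y, model$regulator_effects$x)] <-
      model$regulator_effects$beta
  shift <- model$control_shift[genes]
  stim <- shift + (if (length(regs)) B %*% stromal[regs, , drop = FALSE] else 0) +
    matrix(rnorm(length(genes) * n_stim, sd = target_noise_sd),
           length(genes), n_stim)
  stim <- matrix(stim, length(genes), n_stim,
                 dimnames = list(genes, sub("^hsc", "hcc", colnames(stromal))))
  ctrl <- shift + matrix(rnorm(length(genes) * n_controls, sd = target_noise_sd),
                         length(genes), n_controls)
  ctrl <- matrix(ctrl, length(genes), n_controls,
                 dimnames = list(genes, if (n_controls) sprintf("ctrl_%02d", seq_len(n_controls))))
  attr(stim, "sample_role") <- rep("tumor_stimulated", n_stim)
  attr(ctrl, "sample_role") <- rep("tumor_control", n_controls)
  list(stimulated = stim, controls = ctrl)
}

#' Simulate a complete paired stromal/tumor study with planted regulators
#'
#' Generates the full desk-scale emulation of the conditioned-medium design:
#' a sparse linear-Gaussian stromal network, a designated secreted subset with
#' annotation flags (secreted, receptor, growth factor, detected in
#' conditioned medium), a small set of planted secreted regulators driving
#' responsive tumor genes, null tumor genes, paired stimulated samples and
#' unstimulated controls.
#'
#' Defaults mirror the study shape at desk scale: 150 stromal network genes,
#' 40 secreted, 5 planted regulators, 60 responsive plus 40 null tumor genes,
#' 15 paired samples and 4 controls. Planted regulators receive a larger donor
#' noise standard deviation (1.5) than other genes (0.8-1.2): a paracrine
#' signal is only identifiable if it varies across donors, and this keeps true
#' regulators clear of the low-variability exclusion filter. One planted
#' regulator is an undetected growth factor (exercising the detection-rescue
#' rule) and a few secreted-annotated genes are receptors (cascade decoys).
#'
#' @param n_genes,n_secreted,n_regulators,n_responsive,n_null fixture
#'   dimensions (stromal genes; secreted subset; planted regulators;
#'   responsive and null tumor genes).
#' @param n_pairs number of paired stromal/stimulated-tumor samples.
#' @param n_controls number of unstimulated tumor controls.
#' @param expected_degree expected stromal network degree.
#' @param weight_range magnitudes of stromal edge weights (random sign).
#' @param effect_range magnitudes of planted regulator -> target effects
#'   (random sign).
#' @param targets_per_gene integer vector; how many planted regulators may
#'   drive one responsive gene (drawn uniformly).
#' @param noise_sd_range donor noise sd range for ordinary stromal genes.
#' @param regulator_noise_sd donor noise sd of planted regulators.
#' @param target_noise_sd tumor-side noise sd.
#' @param baseline_range stromal baseline (log2) expression range.
#' @param shift_range tumor baseline (log2) offset range.
#' @param n_receptors number of secreted-annotated receptor decoys.
#' @param detect_prob probability that a non-planted secreted gene product is
#'   detected in conditioned medium.
#' @param seed integer seed (required: the fixture is a reproducible object).
#' @return list with elements `model` (`ground_truth`), `stromal`,
#'   `tumor` (stimulated), `controls` (matrices), and `flags` (data frame with
#'   gene_id + four logical columns covering all genes).
#' @export
simulate_study <- function(n_genes = 150, n_secreted = 40, n_regulators = 5,
                           n_responsive = 60, n_null = 40,
                           n_pairs = 15, n_controls = 4,
                           expected_degree = 2, weight_range = c(0.5, 1.5),
                           effect_range = c(0.8, 1.5), targets_per_gene = 1:2,
                           noise_sd_range = c(0.8, 1.2),
                           regulator_noise_sd = 1.5,
                           target_noise_sd = 1,
                           baseline_range = c(6, 10), shift_range = c(6, 10),
                           n_receptors = 4, detect_prob = 0.85,
                           seed = 1L) {
  stopifnot(n_secreted <= n_genes, n_regulators <= n_secreted - n_receptors)
  set.seed(seed)
  graph <- make_random_dag(n_genes, expected_degree, weight_range)
  nodes <- graph$nodes
  noise_sd <- runif(n_genes, noise_sd_range[1], noise_sd_range[2])
  baseline <- runif(n_genes, baseline_range[1], baseline_range[2])

  secreted <- sort(sample(nodes, n_secreted))
  receptors <- sort(sample(secreted, n_receptors))
  regulators <- sort(sample(setdiff(secreted, receptors), n_regulators))
  names(noise_sd) <- nodes
  noise_sd[regulators] <- regulator_noise_sd

  # detection flags: planted regulators are present in the medium by design,
  # except one that emulates a growth factor too small for MS detection.
  undetected_reg <- regulators[1]
  growth_factors <- unique(c(undetected_reg,
                             sample(setdiff(secreted, c(receptors, regulators)),
                                    min(2, n_secreted - n_receptors - n_regulators))))
  detected <- setdiff(secreted, receptors)
  keep <- runif(length(detected)) < detect_prob
  detected <- union(setdiff(detected[keep], undetected_reg),
                    setdiff(regulators, undetected_reg))

  tumor_resp <- sprintf("t%03d", seq_len(n_responsive))
  tumor_null <- sprintf("n%03d", seq_len(n_null))
  eff <- do.call(rbind, lapply(tumor_resp, function(y) {
    k <- targets_per_gene[sample.int(length(targets_per_gene), 1)]
    xs <- regulators[sample.int(length(regulators), k)]
    data.frame(x = xs, y = y,
               beta = runif(k, effect_range[1], effect_range[2]) *
                 sample(c(-1, 1), k, replace = TRUE))
  }))
  shift <- setNames(runif(n_responsive + n_null, shift_range[1], shift_range[2]),
                    c(tumor_resp, tumor_null))

  flags <- data.frame(
    gene_id = c(nodes, tumor_resp, tumor_null),
    secreted_annotation = c(nodes %in% secreted,
                            rep(FALSE, n_responsive + n_null)),
    receptor = c(nodes %in% receptors, rep(FALSE, n_responsive + n_null)),
    growth_factor = c(nodes %in% growth_factors,
                      rep(FALSE, n_responsive + n_null)),
    detected_in_cm = c(nodes %in% detected, rep(FALSE, n_responsive + n_null)),
    stringsAsFactors = FALSE)

  model <- ground_truth_model(W = graph$W, noise_sd = noise_sd,
                              baseline = baseline, secreted = secreted,
                              regulator_effects = eff,
                              null_targets = tumor_null,
                              control_shift = shift, flags = flags)
  model$regulators <- regulators
  stromal <- sample_stromal_expression(model, n_pairs)
  tum <- sample_tumor_response(model, stromal, n_controls = n_controls,
                               target_noise_sd = target_noise_sd)
  list(model = model, stromal = stromal, tumor = tum$stimulated,
       controls = tum$controls, flags = flags)
}
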