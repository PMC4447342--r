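#' Empirical-Bayes moderated two-sample t-test
#'
#' Gene-wise two-group comparison with variance moderation: residual variances
#' are shrunk toward a pooled prior variance fitted by moment matching of
#' log variances against a scaled F distribution (the classical moderated-t
#' construction), giving `t = dmean / (s_post * sqrt(1/n1 + 1/n2))` on
#' `df_residual + df_prior` degrees of freedom.
#'
#' @param case genes x samples matrix of the stimulated group (log2 scale).
#' @param control genes x samples matrix of the control group; must cover the
#'   same genes (rows are aligned by name).
#' @param prior_df `NULL` (default) to estimate the prior degrees of freedom
#'   from the data; `0` gives the ordinary pooled-variance t-test; `Inf` fully
#'   pools all gene variances.
#' @return data frame with one row per gene: `gene_id`, `log2_fold_change`
#'   (mean(case) - mean(control)), `moderated_t`, `p_value`, `q_value`
#'   (Benjamini-Hochberg). The variance fit (`df_prior`, `s2_prior`,
#'   `s2_posterior`) is attached as attribute `"fit"`.
#' @export
moderated_t_test <- function(case, control, prior_df = NULL) {
  stopifnot(is.matrix(case), is.matrix(control))
  if (ncol(case) < 2 || ncol(control) < 2)
    stop("insufficient replication: each group needs >= 2 samples")
  if (is.null(rownames(case)) || is.null(rownames(control)) ||
      !setequal(rownames(case), rownames(control)))
    stop("'case' and 'control' must cover identical gene sets")
  control <- control[rownames(case), , drop = FALSE]
  if (anyNA(case) || anyNA(control)) stop("missing values are not allowed")

  n1 <- ncol(case); n2 <- ncol(control)
  m1 <- rowMeans(case); m2 <- rowMeans(control)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((control - m2)^2) / (n2 - 1)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  lfc <- m1 - m2

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2, d)
  } else if (prior_df == 0) {
    fit <- list(df_prior = 0, s2_prior = NA_real_)
  } else if (is.infinite(prior_df)) {
    fit <- list(df_prior = Inf, s2_prior = fit_variance_prior(s2, d)$s2_target)
  } else {
    fit <- list(df_prior = prior_df,
                s2_prior = fit_variance_prior(s2, d)$s2_prior)
  }
  if (fit$df_prior == 0) {
    s2_post <- s2
  } else if (is.infinite(fit$df_prior)) {
    s2_post <- rep(fit$s2_prior, length(s2))
  } else {
    s2_post <- (fit$df_prior * fit$s2_prior + d * s2) / (fit$df_prior + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d + fit$df_prior
  pv <- 2 * pt(-abs(tt), df = df_total)
  pv[se == 0 & lfc == 0] <- 1
  res <- data.frame(gene_id = rownames(case), log2_fold_change = lfc,
                    moderated_t = tt, p_value = pv,
                    q_value = bh_adjust(pv), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "fit") <- list(df_prior = fit$df_prior, s2_prior = fit$s2_prior,
                           s2_posterior = unname(s2_post), df_residual = d)
  res
}

# Moment-matching fit of the scaled inverse-chi-square variance prior:
# z = log s^2; E z = log sigma^2 + digamma(d/2) - log(d/2),
# Var z = trigamma(d/2) + trigamma(d0/2); solve for d0, then back out s0^2.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) return(list(df_prior = Inf, s2_prior = 0, s2_target = 0))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- if (sum(ok) > 1) var(e) else 0
  excess <- evar - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    list(df_prior = Inf, s2_prior = mean(s2[ok]), s2_target = mean(s2[ok]))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    list(df_prior = d0,
         s2_prior = exp(emean + digamma(d0 / 2) - log(d0 / 2)),
         s2_target = exp(emean))
  }
}

# Newton solve of trigamma(y) = x (vectorized), monotone decreasing branch.
trigamma_inverse <- function(x) {
  if (any(x <= 0)) stop("trigamma_inverse needs positive input")
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values (BH-adjusted p-values), capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must be numeric in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Select differentially expressed target genes
#'
#' Strict thresholds on both significance and effect size: a gene is kept iff
#' `q_value < q_max` and `|log2_fold_change| > lfc_min`.
#'
#' @param de result of [moderated_t_test()].
#' @param q_max FDR threshold (strict `<`).
#' @param lfc_min absolute log2 fold-change threshold (strict `>`).
#' @return character vector of selected gene ids (input order).
#' @export
select_target_genes <- function(de, q_max = 0.001, lfc_min = 1.0) {
  stopifnot(all(c("gene_id", "log2_fold_change", "q_value") %in% names(de)))
  de$gene_id[de$q_value < q_max & abs(de$log2_fold_change) > lfc_min]
}

# Global expression percentile over all (gene, sample) entries.
global_percentile <- function(mat, prob) {
  quantile(as.vector(mat), probs = prob, names = FALSE, type = 7)
}

#' Select candidate secreted regulators (annotation + expression cascade)
#'
#' Ordered filter cascade over stromal genes:
#' (1) annotated secreted/extracellular; (2) not a receptor; (3) expressed:
#' maximum over samples above the global `expr_quantile` percentile computed
#' over all matrix entries; (4) drop the lowest `iqr_drop_frac` fraction (by
#' count, floor) of inter-quartile range among survivors of (3); (5) gene
#' product detected in conditioned medium, or annotated growth factor
#' (too-small-for-detection rescue).
#'
#' @param stromal genes x samples stromal expression matrix (log2).
#' @param flags gene-annotation data frame with columns `gene_id`,
#'   `secreted_annotation`, `receptor`, `growth_factor`, `detected_in_cm`;
#'   genes without a row default to all-false.
#' @param expr_quantile global expression percentile for filter (3).
#' @param iqr_drop_frac fraction of lowest-IQR survivors dropped in (4).
#' @return character vector of candidate genes (matrix row order); per-filter
#'   survivor counts are attached as attribute `"audit"`. Ties in the IQR
#'   ranking are broken by gene-id lexicographic order.
#' @export
select_secreted_candidates <- function(stromal, flags, expr_quantile = 0.4,
                                       iqr_drop_frac = 0.2) {
  stopifnot(is.matrix(stromal), !is.null(rownames(stromal)))
  fl <- align_flags(flags, rownames(stromal))
  s1 <- rownames(stromal)[fl$secreted_annotation]
  s2 <- s1[!fl[s1, "receptor"]]
  thr <- global_percentile(stromal, expr_quantile)
  s3 <- s2[apply(stromal[s2, , drop = FALSE], 1, max) > thr]
  if (length(s3)) {
    iqr <- apply(stromal[s3, , drop = FALSE], 1, IQR, type = 7)
    n_drop <- floor(iqr_drop_frac * length(s3))
    ord <- order(iqr, s3)
    s4 <- s3[!s3 %in% s3[ord[seq_len(n_drop)]]]
  } else s4 <- s3
  s5 <- s4[fl[s4, "detected_in_cm"] | fl[s4, "growth_factor"]]
  if (!length(s5)) warning("secreted-candidate cascade produced an empty set")
  out <- rownames(stromal)[rownames(stromal) %in% s5]
  attr(out, "audit") <- c(secreted_annotation = length(s1),
                          non_receptor = length(s2),
                          expressed = length(s3), variable = length(s4),
                          detected_or_growth_factor = length(s5))
  out
}

# Align a flags table to a gene universe; absent genes get all-FALSE rows.
align_flags <- function(flags, genes) {
  cols <- c("secreted_annotation", "receptor", "growth_factor",
            "detected_in_cm")
  stopifnot(is.data.frame(flags), "gene_id" %in% names(flags),
            all(cols %in% names(flags)))
  if (anyDuplicated(flags$gene_id)) stop("duplicate gene ids in flags table")
  out <- matrix(FALSE, length(genes), length(cols),
                dimnames = list(genes, cols))
  hit <- intersect(genes, flags$gene_id)
  rows <- match(hit, flags$gene_id)
  for (cl in cols) out[hit, cl] <- as.logical(flags[[cl]][rows])
  as.data.frame(out)
}

#' Select the stromal network gene set
#'
#' The network over which the CPDAG is estimated: all secreted candidates plus
#' the `total - length(secreted)` non-secreted genes that are expressed (at
#' least 3 samples above the global 40th percentile) with the highest
#' inter-quartile range (ties broken lexicographically). If fewer qualify the
#' shortfall is recorded in attribute `"shortfall"`.
#'
#' @param stromal genes x samples stromal expression matrix.
#' @param secreted character vector of secreted candidate genes.
#' @param total requested total network size (>= length(secreted)).
#' @param expr_quantile global expression percentile for the expression filter.
#' @param min_expressed_samples required number of samples above threshold.
#' @return character vector of network genes (secreted candidates first).
#' @export
select_network_genes <- function(stromal, secreted, total = 2000,
                                 expr_quantile = 0.4,
                                 min_expressed_samples = 3) {
  stopifnot(is.matrix(stromal), all(secreted %in% rownames(stromal)))
  if (total < length(secreted))
    stop("'total' must be at least the number of secreted candidates")
  thr <- global_percentile(stromal, expr_quantile)
  rest <- setdiff(rownames(stromal), secreted)
  qual <- rest[rowSums(stromal[rest, , drop = FALSE] > thr) >=
                 min_expressed_samples]
  k <- total - length(secreted)
  if (length(qual) > k) {
    iqr <- apply(stromal[qual, , drop = FALSE], 1, IQR, type = 7)
    qual <- qual[order(-iqr, qual)][seq_len(k)]
  }
  out <- c(secreted, sort(qual))
  attr(out, "shortfall") <- as.integer(max(0, total - length(out)))
  out
}

#' Standardize expression rows
#'
#' Centers each gene to mean 0 and scales to sample standard deviation 1
#' (denominator `n - 1`), making causal effects comparable across genes.
#'
#' @param mat genes x samples numeric matrix.
#' @param tol genes with standard deviation below `tol` are an error.
#' @return standardized matrix with the same dimnames.
#' @export
standardize <- function(mat, tol = 1e-12) {
  stopifnot(is.matrix(mat))
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  bad <- which(s < tol | !is.finite(s))
  if (length(bad))
    stop("zero-variance gene(s): ",
         paste(rownames(mat)[bad] %||% bad, collapse = ", "))
  (mat - mu) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Naive correlation baseline
#'
#' For each secreted stromal gene, counts the tumor genes whose expression has
#' `|Pearson r| > cutoff` across paired samples. This is the association-only
#' screen that causal analysis is designed to improve on: high counts can be
#' driven by shared upstream regulators rather than direct influence.
#'
#' @param secreted_data secreted-gene x paired-sample matrix.
#' @param target_data tumor-gene x paired-sample matrix (same sample count,
#'   paired by column position).
#' @param cutoff absolute correlation threshold (strict `>`).
#' @return named integer vector of counts, sorted decreasing (ties broken
#'   lexicographically).
#' @export
correlation_baseline <- function(secreted_data, target_data, cutoff = 0.7) {
  stopifnot(is.matrix(secreted_data), is.matrix(target_data))
  if (ncol(secreted_data) != ncol(target_data))
    stop("unpaired samples: the matrices must have the same number of columns")
  cc <- cor(t(secreted_data), t(target_data))
  counts <- rowSums(abs(cc) > cutoff)
  counts[order(-counts, names(counts))]
}

#' Highest-variance gene subset
#'
#' @param mat genes x samples matrix.
#' @param top_n number of genes to keep (<= gene count).
#' @return the `top_n` genes by sample variance, ties broken
#'   lexicographically, in decreasing-variance order.
#' @export
high_variance_subset <- function(mat, top_n = 200) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (top_n > nrow(mat)) stop("'top_n' exceeds the gene count")
  v <- apply(mat, 1, var)
  rownames(mat)[order(-v, rownames(mat))][seq_len(top_n)]
}
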