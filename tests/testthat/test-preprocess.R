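test_that("moderated t reduces to the ordinary pooled t at prior df 0", {
  set.seed(101)
  case <- matrix(rnorm(50 * 5), 50, 5,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("a", 1:5)))
  ctrl <- matrix(rnorm(50 * 4), 50, 4,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("b", 1:4)))
  de <- moderated_t_test(case, ctrl, prior_df = 0)
  ref <- vapply(1:50, function(i) pooled_t_reference(case[i, ], ctrl[i, ]),
                numeric(1))
  expect_equal(de$moderated_t, ref, tolerance = 1e-12)
  # gene with identical values in both groups: lfc 0, t 0, p 1
  case["g01", ] <- 3; ctrl["g01", ] <- 3
  de0 <- moderated_t_test(case, ctrl)
  row <- de0[de0$gene_id == "g01", ]
  expect_equal(row$log2_fold_change, 0)
  expect_equal(row$moderated_t, 0)
  expect_equal(row$p_value, 1)
  expect_error(moderated_t_test(case[, 1, drop = FALSE], ctrl),
               "insufficient replication")
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(102)
  g <- 300
  case <- matrix(rnorm(g * 6, sd = rep(sqrt(rchisq(g, 4) / 4), 6)), g, 6,
                 dimnames = list(sprintf("g%03d", 1:g), paste0("a", 1:6)))
  ctrl <- matrix(rnorm(g * 4), g, 4,
                 dimnames = list(sprintf("g%03d", 1:g), paste0("b", 1:4)))
  de <- moderated_t_test(case, ctrl)
  fit <- limma::eBayes(limma::lmFit(cbind(case, ctrl),
                                    cbind(1, c(rep(1, 6), rep(0, 4)))))
  expect_equal(de$moderated_t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(de$p_value, unname(fit$p.value[, 2]), tolerance = 1e-10)
  expect_equal(attr(de, "fit")$df_prior, fit$df.prior, tolerance = 1e-8)
})

test_that("prior df Inf pools every gene's variance", {
  set.seed(103)
  case <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(paste0("g", 1:40), NULL))
  ctrl <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(paste0("g", 1:40), NULL))
  colnames(case) <- paste0("a", 1:4); colnames(ctrl) <- paste0("b", 1:4)
  de <- moderated_t_test(case, ctrl, prior_df = Inf)
  s2p <- attr(de, "fit")$s2_posterior
  expect_lt(diff(range(s2p)), 1e-14)
})

test_that("null p-values are approximately uniform", {
  set.seed(104)
  g <- 2000
  case <- matrix(rnorm(g * 8), g, 8, dimnames = list(paste0("g", 1:g), paste0("a", 1:8)))
  ctrl <- matrix(rnorm(g * 8), g, 8, dimnames = list(paste0("g", 1:g), paste0("b", 1:8)))
  de <- moderated_t_test(case, ctrl)
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(105)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("target-gene selection uses strict thresholds on both axes", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2_fold_change = c(1.5, 1.0, -2, 0.2),
                   q_value = c(0.0005, 0.0005, 0.001, 1e-6))
  expect_identical(select_target_genes(de), "a")           # b: lfc == 1; c: q == 0.001
  expect_identical(select_target_genes(de, q_max = 0.0011), c("a", "c"))
})

test_that("planted responsive genes are selected at high power", {
  sim <- simulate_study(n_pairs = 100, seed = 31)
  de <- moderated_t_test(sim$tumor, sim$controls)
  sel <- select_target_genes(de)
  expect_true(all(grepl("^t", sel)))        # no null gene selected
  expect_gt(length(sel), 30)                # most planted genes found
})

test_that("the secreted-candidate cascade follows the documented order", {
  # 10 genes; engineered so exactly 6 pass filters 1-3, the IQR-lowest of
  # the 6 is dropped, 4 of the remaining 5 are detected and the undetected
  # one is rescued as a growth factor -> 5 candidates.
  genes <- sprintf("g%02d", 1:10)
  m <- matrix(8, 10, 8, dimnames = list(genes, paste0("s", 1:8)))
  m["g01", ] <- c(10, 12, 9, 11, 10, 12, 9, 11)
  m["g02", ] <- c(6, 14, 7, 13, 6, 14, 7, 13)
  m["g03", ] <- c(9, 10, 9, 10, 9, 10, 9, 10)
  m["g04", ] <- c(8, 12, 8, 12, 8, 12, 8, 12)
  m["g05", ] <- c(7, 13, 9, 11, 7, 13, 9, 11)
  m["g06", ] <- 8 + seq(0, 3.5, 0.5)
  m["g07", ] <- 2          # secreted but fails the expression filter
  m["g08", ] <- c(9, 11, 9, 11, 9, 11, 9, 11)   # receptor: removed at (2)
  m["g09", ] <- 1; m["g10", ] <- 1.5            # not secreted
  flags <- data.frame(
    gene_id = genes,
    secreted_annotation = c(rep(TRUE, 8), FALSE, FALSE),
    receptor = c(rep(FALSE, 7), TRUE, FALSE, FALSE),
    growth_factor = c(FALSE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 5)),
    detected_in_cm = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                       FALSE, FALSE))
  out <- select_secreted_candidates(m, flags)
  # g07 fails expression; g08 is a receptor; g03 has the lowest IQR of the
  # six survivors and is dropped; g05 is rescued as a growth factor.
  expect_identical(as.character(out), c("g01", "g02", "g04", "g05", "g06"))
  expect_identical(unname(attr(out, "audit")),
                   c(8L, 7L, 6L, 5L, 5L))
  # receptor flag dominates regardless of expression
  flags2 <- flags; flags2$receptor[1] <- TRUE
  expect_false("g01" %in% select_secreted_candidates(m, flags2))
  # all flags false: empty with a warning
  flags3 <- flags; flags3$secreted_annotation <- FALSE
  expect_warning(out3 <- select_secreted_candidates(m, flags3), "empty")
  expect_length(out3, 0)
})

test_that("cascade output is invariant to gene order", {
  sim <- simulate_study(seed = 32)
  base <- select_secreted_candidates(sim$stromal, sim$flags)
  set.seed(1)
  perm <- sample(nrow(sim$stromal))
  shuf <- select_secreted_candidates(sim$stromal[perm, ], sim$flags)
  expect_setequal(as.character(base), as.character(shuf))
})

test_that("network-gene selection honours the total and breaks ties by id", {
  genes <- sprintf("g%02d", 1:30)
  set.seed(106)
  m <- matrix(rnorm(30 * 10, mean = 8), 30, 10,
              dimnames = list(genes, paste0("s", 1:10)))
  secreted <- genes[1:5]
  out <- select_network_genes(m, secreted, total = 12)
  expect_length(out, 12)
  expect_identical(out[1:5], secreted)
  expect_identical(attr(out, "shortfall"), 0L)
  expect_error(select_network_genes(m, secreted, total = 3), "at least")
  # shortfall recorded when too few qualify
  out2 <- select_network_genes(m, secreted, total = 500)
  expect_identical(attr(out2, "shortfall"), 500L - length(out2))
  # IQR ties resolved lexicographically
  m2 <- matrix(rep(c(5, 9, 5, 9), 4), 4, 4, byrow = TRUE,
               dimnames = list(c("b", "a", "d", "c"), paste0("s", 1:4)))
  out3 <- select_network_genes(m2, character(0), total = 2,
                               min_expressed_samples = 1)
  expect_identical(as.character(out3), c("a", "b"))
})

test_that("standardization is exact, idempotent, and rejects constants", {
  set.seed(107)
  m <- matrix(rnorm(60, sd = 4), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  z <- standardize(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  m["g3", ] <- 7
  expect_error(standardize(m), "g3")
})

test_that("correlation baseline counts and ranks as documented", {
  set.seed(108)
  x <- matrix(rnorm(3 * 15), 3, 15,
              dimnames = list(c("s1", "s2", "s3"), paste0("p", 1:15)))
  y <- rbind(t1 = x["s1", ], t2 = rnorm(15), t3 = -x["s2", ])
  colnames(y) <- colnames(x)
  counts <- correlation_baseline(x, y)
  expect_equal(unname(counts["s1"]), 1)  # t1 = s1 exactly
  expect_gte(unname(counts["s2"]), 1)    # t3 = -s2
  expect_error(correlation_baseline(x, y[, 1:10]), "unpaired")
  # null calibration: expected count ~ n_targets * P(|r| > 0.7 | rho = 0)
  n <- 15; r0 <- 0.7
  p_exceed <- 2 * pt(-r0 * sqrt((n - 2) / (1 - r0^2)), n - 2)
  set.seed(109)
  reps <- vapply(1:300, function(i) {
    xx <- matrix(rnorm(n), 1, n, dimnames = list("x", NULL))
    yy <- matrix(rnorm(100 * n), 100, n,
                 dimnames = list(paste0("t", 1:100), NULL))
    unname(correlation_baseline(xx, yy))
  }, numeric(1))
  expected <- 100 * p_exceed
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 4 * se + 0.05)
})

test_that("high-variance subset reproduces a hand-ranked order", {
  m <- rbind(a = c(0, 0, 0, 0), b = c(1, -1, 1, -1), c = c(5, -5, 5, -5),
             d = c(2, -2, 2, -2), e = c(0.1, -0.1, 0.1, -0.1))
  colnames(m) <- paste0("s", 1:4)
  expect_identical(high_variance_subset(m, 3), c("c", "d", "b"))
  expect_setequal(high_variance_subset(m, 5), rownames(m))
  expect_false("a" %in% high_variance_subset(m, 4))
  expect_error(high_variance_subset(m, 6), "exceeds")
})
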