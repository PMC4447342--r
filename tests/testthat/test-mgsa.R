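test_that("target sets are rebuilt from retained pairs", {
  rows <- data.frame(x = c("a", "a", "b"), y = c("y1", "y2", "y1"))
  coll <- build_target_sets(rows, universe = c("y1", "y2", "y3"))
  expect_identical(coll$sets, list(a = c("y1", "y2"), b = "y1"))
  expect_warning(empty <- build_target_sets(
    data.frame(x = character(), y = character())), "empty")
  expect_length(empty$sets, 0)
  expect_error(build_target_sets(rows, universe = "y1"), "outside")
})

test_that("set-activation log-likelihood matches closed forms", {
  uni <- paste0("t", 1:10)
  coll <- toy_collection(list(A = uni[1:4], B = uni[3:6], C = uni[7:8]), uni)
  # empty active set: k on-genes among N
  obs <- uni[1:3]
  a <- 0.1; b <- 0.3
  expect_equal(mgsa_log_likelihood(character(), coll, obs, a, b),
               3 * log(a) + 7 * log(1 - a))
  # perfect explanation: ll -> 0 as rates -> 0
  obs2 <- uni[1:4]
  expect_gt(mgsa_log_likelihood("A", coll, obs2, 1e-12, 1e-12), -1e-9)
  # 3-set toy against an independently enumerated sum
  act <- c("A", "C")
  h <- uni %in% c(uni[1:4], uni[7:8])
  on <- uni %in% obs
  ref <- sum(log(ifelse(h & on, 1 - b, ifelse(h & !on, b,
                        ifelse(!h & on, a, 1 - a)))))
  expect_equal(mgsa_log_likelihood(act, coll, obs, a, b), ref)
  expect_error(mgsa_log_likelihood("A", coll, obs, 0, 0.5), "inside")
})

test_that("exhaustive posteriors behave like a set-cover prior", {
  uni <- paste0("t", 1:12)
  prm <- mgsa_params(alpha_fp = 0.05, beta_fn = 0.2, p_active = 0.5,
                     n_iter = 1000)
  # one set covering all observed genes: posterior ~ 1
  coll1 <- toy_collection(list(A = uni[1:8]), uni)
  ex1 <- mgsa_exhaustive(coll1, uni[1:8], prm)
  expect_gt(ex1$posterior, 0.99)
  # duplicate sets split the evidence (explaining-away)
  coll2 <- toy_collection(list(A = uni[1:8], B = uni[1:8]), uni)
  ex2 <- mgsa_exhaustive(coll2, uni[1:8], prm)
  expect_equal(ex2$posterior[1], ex2$posterior[2], tolerance = 1e-12)
  expect_lt(ex2$posterior[1], ex1$posterior)
  # nothing observed: every posterior below the prior
  prm2 <- mgsa_params(alpha_fp = 0.01, beta_fn = 0.2, p_active = 0.3,
                      n_iter = 1000)
  ex3 <- mgsa_exhaustive(coll2, character(0), prm2)
  expect_true(all(ex3$posterior < 0.3))
  # posterior of a fully-covered set is nonincreasing in alpha_fp
  post_at <- function(a) {
    p <- mgsa_params(alpha_fp = a, beta_fn = 0.2, p_active = 0.3,
                     n_iter = 1000)
    mgsa_exhaustive(coll1, uni[1:8], p)$posterior
  }
  alphas <- c(0.01, 0.05, 0.1, 0.2, 0.4)
  vals <- vapply(alphas, post_at, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("MCMC matches exhaustive enumeration and is reproducible", {
  worst <- 0
  for (s in 1:10) {
    inst <- random_mgsa_instance(4 + s %% 6, seed = 700 + s)
    prm <- mgsa_params(alpha_fp = 0.1, beta_fn = 0.25, p_active = 0.25,
                       n_iter = 1e5, burnin = 2e4, n_restarts = 2,
                       seed = 800 + s)
    ex <- mgsa_exhaustive(inst$coll, inst$observed, prm)
    mc <- mgsa_mcmc(inst$coll, inst$observed, prm)
    err <- max(abs(ex$posterior[match(mc$regulator, ex$regulator)] -
                     mc$posterior))
    worst <- max(worst, err)
  }
  expect_lt(worst, 0.02)
  # fixed seed: identical result
  inst <- random_mgsa_instance(6, seed = 900)
  prm <- mgsa_params(n_sets = 6, n_iter = 2e4, n_restarts = 2, seed = 1)
  expect_identical(mgsa_mcmc(inst$coll, inst$observed, prm),
                   mgsa_mcmc(inst$coll, inst$observed, prm))
  # symmetric instance: interchangeable sets get equal posteriors
  uni <- paste0("t", 1:10)
  coll <- toy_collection(list(A = uni[1:5], B = uni[6:10]), uni)
  prm2 <- mgsa_params(alpha_fp = 0.1, beta_fn = 0.2, p_active = 0.3,
                      n_iter = 2e5, burnin = 2e4, n_restarts = 2, seed = 2)
  mc2 <- mgsa_mcmc(coll, uni, prm2)
  expect_lt(abs(mc2$posterior[1] - mc2$posterior[2]), 0.02)
})

test_that("regulator selection thresholds and orders by posterior", {
  res <- data.frame(regulator = c("a", "b", "c"),
                    set_size = c(3L, 2L, 1L),
                    posterior = c(0.9, 0.4, 0.95))
  class(res) <- c("mgsa_result", "data.frame")
  expect_identical(select_regulators(res, b = 0), c("c", "a", "b"))
  expect_identical(select_regulators(res, b = 1), character(0))
  expect_identical(select_regulators(res, b = 0.5), c("c", "a"))
})

test_that("median-rank aggregation reproduces the hand example", {
  rk <- list(c("r1", "r2", "r3"), c("r2", "r1", "r3"), c("r1", "r3", "r2"))
  out <- median_rank_aggregate(rk)
  expect_identical(out$regulator, c("r1", "r2", "r3"))
  expect_identical(out$median_rank, c(1, 2, 3))
})

test_that("calibration reduces to a plain run on singleton grids and finds a planted positive", {
  sim <- simulate_study(n_genes = 40, n_secreted = 12, n_regulators = 3,
                        n_responsive = 15, n_null = 10, n_pairs = 40,
                        n_receptors = 2, seed = 71)
  cand <- select_secreted_candidates(sim$stromal, sim$flags)
  net <- select_network_genes(sim$stromal, cand, total = 40)
  targets <- select_target_genes(moderated_t_test(sim$tumor, sim$controls))
  stab <- stability_selection(sim$stromal[net, ], sim$tumor, cand, targets,
                              n_runs = 20, seed = 9)
  kp <- intersect(sim$model$regulators, cand)[1]
  prm <- mgsa_params(n_sets = 10, n_iter = 5e4, n_restarts = 2, seed = 3)
  cal <- calibrate(stab, universe = targets, known_positive = kp,
                   pi_grid = c(0.6, 0.7, 0.8), params = prm)
  expect_s3_class(cal, "calibration")
  expect_true(length(cal$settings_with_positive) >= 1)
  expect_true(kp %in% head(cal$median_ranks$regulator, 5))
  # single-element grid: same retained set as one plain pipeline run at the
  # median-q rule with one q value
  cal1 <- calibrate(stab, universe = targets, known_positive = kp,
                    pi_grid = 0.7, q_step = 1, params = prm)
  keep_manual <- stable_retain(rowMeans(stab$rank_frac <= 1), 0.7)
  expect_identical(nrow(cal1$per_pi[[1]]$retained), sum(keep_manual))
  expect_error(calibrate(stab, targets, known_positive = "not_a_gene"),
               "not among")
})
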