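test_that("partial correlation matches closed forms", {
  # S empty returns the plain correlation entry
  set.seed(201)
  x <- matrix(rnorm(4 * 100), 4, 100, dimnames = list(letters[1:4], NULL))
  corr <- cor(t(x))
  expect_identical(partial_correlation(corr, "a", "b"), corr["a", "b"])
  # 3x3 textbook recursion to machine precision
  ref <- (corr[1, 2] - corr[1, 3] * corr[2, 3]) /
    sqrt((1 - corr[1, 3]^2) * (1 - corr[2, 3]^2))
  expect_equal(partial_correlation(corr, 1, 2, 3), ref, tolerance = 1e-12)
  # chain a -> z -> y in population: rho(a, y | z) = 0 exactly
  W <- matrix(0, 3, 3, dimnames = list(c("a", "z", "y"), c("a", "z", "y")))
  W["a", "z"] <- 0.9; W["z", "y"] <- -0.7
  S <- cov2cor(sem_covariance(ground_truth_model(W, 1)))
  expect_lt(abs(partial_correlation(S, "a", "y", "z")), 1e-12)
  expect_error(partial_correlation(corr, "a", "b", "a"), "distinct")
})

test_that("Fisher-z decisions follow the closed form", {
  expect_identical(fisher_z_decision(0, 100, 0, 0.2), "independent")
  expect_identical(fisher_z_decision(1, 100, 0, 0.2), "dependent")
  # sqrt(12) * atanh(0.5) = 1.903 > qnorm(0.9) = 1.2816
  expect_identical(fisher_z_decision(0.5, 15, 0, 0.2), "dependent")
  # same statistic, stricter level
  expect_identical(fisher_z_decision(0.5, 15, 0, 2 * (1 - pnorm(1.91))),
                   "independent")
  expect_error(fisher_z_decision(0.5, 5, 2, 0.2), "insufficient")
  expect_error(fisher_z_decision(0.5, 15, 0, 1.2), "alpha")
})

test_that("compiled skeleton equals the pure-R reference engine", {
  for (s in 1:6) {
    g <- make_random_dag(8 + (s %% 3), 2, seed = 300 + s)
    x <- standardize(sample_stromal_expression(g, 50, seed = 310 + s))
    for (alpha in c(0.05, 0.2)) {
      skC <- estimate_skeleton(x, alpha = alpha)
      skR <- skeleton_engine(rownames(x), fisher_test_closure(x, alpha),
                             max_cond_size = ncol(x) - 4)
      expect_identical(skC$adj, skR$adj)
      expect_identical(skC$sepsets[sort(names(skC$sepsets))],
                       skR$sepsets[sort(names(skR$sepsets))])
    }
  }
})

test_that("population-oracle skeleton recovers the true skeleton", {
  g <- make_random_dag(6, 2, seed = 320)
  cp <- pc_population(sem_covariance(g))
  truth <- (g$W != 0) | t(g$W != 0)
  expect_identical(cp$amat > 0, truth)
  # two independent genes: empty skeleton at large n with prob ~ 1 - alpha
  set.seed(321)
  hits <- vapply(1:40, function(i) {
    x <- matrix(rnorm(2 * 5000), 2, 5000, dimnames = list(c("a", "b"), NULL))
    sum(estimate_skeleton(standardize(x), alpha = 0.05)$adj) == 0
  }, logical(1))
  expect_gt(mean(hits), 0.80)
})

test_that("orientation implements v-structures and leaves chains undirected", {
  nodes <- c("a", "b", "c")
  # chain skeleton a - b - c with sepset(a, c) = {b}: stays undirected
  adj <- matrix(FALSE, 3, 3, dimnames = list(nodes, nodes))
  adj["a", "b"] <- adj["b", "a"] <- TRUE
  adj["b", "c"] <- adj["c", "b"] <- TRUE
  cp <- orient_cpdag(list(adj = adj, sepsets = list(`a|c` = "b"),
                          nodes = nodes))
  expect_identical(unique(cpdag_edges(cp)$type), "undirected")
  # collider truth: sepset(a, c) empty -> a -> b <- c
  cp2 <- orient_cpdag(list(adj = adj, sepsets = list(`a|c` = character()),
                           nodes = nodes))
  expect_identical(cp2$amat["a", "b"], 1L)
  expect_identical(cp2$amat["b", "a"], 0L)
  expect_identical(cp2$amat["c", "b"], 1L)
  expect_identical(cp2$amat["b", "c"], 0L)
  # empty skeleton -> empty CPDAG
  cp3 <- orient_cpdag(list(adj = adj & FALSE, sepsets = list(),
                           nodes = nodes))
  expect_identical(sum(cp3$amat), 0L)
})

test_that("Meek closure orients the compelled edges of known graphs", {
  # a -> b <- c plus b - d: R1 compels b -> d
  nodes <- letters[1:4]
  adj <- matrix(FALSE, 4, 4, dimnames = list(nodes, nodes))
  adj["a", "b"] <- adj["b", "a"] <- TRUE
  adj["c", "b"] <- adj["b", "c"] <- TRUE
  adj["b", "d"] <- adj["d", "b"] <- TRUE
  cp <- orient_cpdag(list(adj = adj, sepsets = list(`a|c` = character()),
                          nodes = nodes))
  expect_identical(cp$amat["b", "d"], 1L)
  expect_identical(cp$amat["d", "b"], 0L)
  # a fully connected 3-chain DAG is Markov-equivalent to its undirected class
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 1; W["b", "c"] <- 1
  cp2 <- dag_to_cpdag(W)
  expect_identical(unique(cpdag_edges(cp2)$type), "undirected")
  # collider DAG keeps its arrows
  W2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W2["a", "c"] <- 1; W2["b", "c"] <- 1
  cp3 <- dag_to_cpdag(W2)
  expect_identical(cp3$amat["a", "c"], 1L)
  expect_identical(cp3$amat["c", "a"], 0L)
})

test_that("pc is invariant to gene order and monotone in alpha", {
  g <- make_random_dag(8, 2, seed = 330)
  x <- standardize(sample_stromal_expression(g, 60, seed = 331))
  cp <- pc(x, alpha = 0.1)
  set.seed(332)
  perm <- sample(nrow(x))
  cp_perm <- pc(x[perm, ], alpha = 0.1)
  expect_identical(cp_perm$amat[rownames(x), rownames(x)], cp$amat)
  # alpha near 1 keeps essentially every edge
  cp_all <- pc(x, alpha = 1 - 1e-9)
  expect_identical(sum(cp_all$amat > 0 | t(cp_all$amat) > 0),
                   8L * 7L)
})

test_that("structural Hamming distance counts differing pair marks", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "c"] <- 1; W["b", "c"] <- 1
  cp <- dag_to_cpdag(W)
  expect_identical(shd(cp, cp), 0L)
  W2 <- W; W2["a", "c"] <- 0
  expect_identical(shd(cp, dag_to_cpdag(W2)), 2L)  # edge gone + orientation
})
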