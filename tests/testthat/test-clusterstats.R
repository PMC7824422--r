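test_that("paired t map matches hand computation and its symmetries", {
  a <- cbind(c(2, 3, 4, 5), c(1, 1, 1, 1), c(0.5, 0.5, 0.5, 0.5))
  b <- cbind(c(1, 1, 1, 1), c(1, 1, 1, 1), c(0, 0, 0, 0))
  tm <- paired_t_map(a, b)
  # d = (1,2,3,4): mean 2.5, sd 1.2910, t = 2.5/(1.2910/2) = 3.873
  expect_equal(tm$t[1], 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(tm$t[2], 0)                      # a = b
  expect_equal(tm$df, 3)
  expect_true(tm$zero_variance[3])              # constant nonzero diff
  expect_equal(tm$t[3], 0)
  tm_sw <- paired_t_map(b, a)
  expect_equal(tm_sw$t, -tm$t)
  expect_error(paired_t_map(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "at least 2 subjects")
})

test_that("distance neighbours are symmetric with an empty diagonal", {
  m <- make_montage()
  g <- build_neighbors(m, threshold = 0.35)
  expect_true(isSymmetric(g$adjacency))
  expect_false(any(diag(g$adjacency)))
  # two electrodes closer than the threshold are adjacent
  expect_true(g$adjacency["PPO1h", "POO1"])
  expect_true(g$adjacency["POO1", "POO2"])
  # an over-tight threshold warns about isolated electrodes
  expect_warning(build_neighbors(m, threshold = 0.05), "isolated")
  gk <- build_neighbors(m, method = "knn", k = 3)
  expect_true(isSymmetric(gk$adjacency))
})

test_that("cluster finding matches an exhaustive graph-components oracle", {
  set.seed(71)
  for (rep in 1:25) {
    ne <- sample(4:10, 1)
    adj <- matrix(runif(ne * ne) < 0.35, ne, ne)
    adj <- adj | t(adj); diag(adj) <- FALSE
    t_vals <- rnorm(ne, sd = 3)
    tmap <- list(t = t_vals, df = 15)
    got <- find_clusters(tmap, list(adjacency = adj))
    tcrit <- qt(0.975, 15)
    expected <- list()
    for (sgn in c(1, -1))
      for (comp in oracle_components(which(sgn * t_vals > tcrit), adj))
        expected <- c(expected, list(comp))
    got_sets <- lapply(got, `[[`, "electrodes")
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(expected, paste, collapse = ","))
    for (cl in got) {
      expect_equal(cl$mass, sum(t_vals[cl$electrodes]))
      expect_true(all(sign(t_vals[cl$electrodes]) == cl$sign))
    }
  }
})

test_that("sub-threshold maps give no clusters; opposite signs split", {
  adj <- matrix(TRUE, 2, 2); diag(adj) <- FALSE
  none <- find_clusters(list(t = c(0.5, -1), df = 10),
                        list(adjacency = adj))
  expect_length(none, 0)
  two <- find_clusters(list(t = c(5, -5), df = 10),
                       list(adjacency = adj))
  expect_length(two, 2)
  expect_setequal(vapply(two, `[[`, numeric(1), "sign"), c(1, -1))
})

test_that("exact enumeration at n = 4 matches a brute-force oracle", {
  set.seed(72)
  ne <- 6
  pos <- cbind(seq_len(ne) / ne, 0.1 * seq_len(ne))
  adj <- as.matrix(dist(pos)) < 0.4
  diag(adj) <- FALSE
  a <- matrix(rnorm(4 * ne, mean = 0.8), 4)
  b <- matrix(rnorm(4 * ne), 4)
  res <- permutation_test(a, b, list(adjacency = adj), n_perm = 1000)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 16)
  # oracle: full enumeration from first principles
  d <- a - b
  tcrit <- qt(0.975, 3)
  null_max <- apply(as.matrix(expand.grid(rep(list(c(1, -1)), 4))), 1,
                    function(s) {
    ds <- s * d
    m <- colMeans(ds); sdev <- apply(ds, 2, sd)
    t_vals <- ifelse(sdev > 0, m / (sdev / 2), 0)
    oracle_max_mass(t_vals, tcrit, adj)
  })
  for (cl in res$clusters) {
    p_oracle <- mean(null_max >= abs(cl$mass) - 1e-12)
    expect_equal(cl$p_corrected, p_oracle, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo and exact modes agree within sampling error", {
  set.seed(73)
  ne <- 8
  adj <- matrix(TRUE, ne, ne); diag(adj) <- FALSE
  a <- matrix(rnorm(10 * ne, mean = 0.5), 10)
  b <- matrix(rnorm(10 * ne), 10)
  exact <- permutation_test(a, b, list(adjacency = adj), n_perm = 5000)
  expect_true(exact$exact)
  mc <- permutation_test(a, b, list(adjacency = adj), n_perm = 999,
                         seed = 9)
  expect_false(mc$exact)
  for (i in seq_along(exact$clusters)) {
    pe <- exact$clusters[[i]]$p_corrected
    pm <- mc$clusters[[i]]$p_corrected
    se <- sqrt(pe * (1 - pe) / 999)
    expect_lt(abs(pe - pm), 3 * se + 2 / 999)
  }
})

test_that("a strong consistent effect is detected as a significant cluster", {
  set.seed(74)
  m <- make_montage()
  g <- build_neighbors(m)
  ne <- length(m$labels)
  target <- match(c("P3", "P4", "PPO1h", "PPO2h", "POO1", "POO2"),
                  m$labels)
  a <- matrix(rnorm(16 * ne, sd = 0.1), 16)
  b <- matrix(rnorm(16 * ne, sd = 0.1), 16)
  a[, target] <- a[, target] + 1                  # d = 1 +- ~0.14
  res <- permutation_test(a, b, g, n_perm = 1000, seed = 75)
  sig <- Filter(function(cl) cl$significant, res$clusters)
  expect_gte(length(sig), 1)
  expect_true(any(vapply(sig, function(cl)
    all(target %in% cl$electrodes) && cl$sign > 0, logical(1))))
})

test_that("permutation results are reproducible and electrode-relabeling invariant", {
  set.seed(76)
  m <- make_montage()
  g <- build_neighbors(m)
  ne <- length(m$labels)
  a <- matrix(rnorm(12 * ne), 12); b <- matrix(rnorm(12 * ne), 12)
  r1 <- permutation_test(a, b, g, n_perm = 500, seed = 42)
  r2 <- permutation_test(a, b, g, n_perm = 500, seed = 42)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(lapply(r1$clusters, `[[`, "p_corrected"),
                   lapply(r2$clusters, `[[`, "p_corrected"))
  # permute electrodes together with the graph: p-values unchanged
  perm <- sample(ne)
  gp <- list(adjacency = g$adjacency[perm, perm])
  rp <- permutation_test(a[, perm], b[, perm], gp, n_perm = 500, seed = 42)
  expect_equal(sort(vapply(rp$clusters, `[[`, numeric(1), "p_corrected")),
               sort(vapply(r1$clusters, `[[`, numeric(1), "p_corrected")))
})

test_that("the permutation count defaults to 1000", {
  expect_equal(eval(formals(permutation_test)$n_perm), 1000)
})
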