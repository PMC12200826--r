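test_that("adjacency is built from montage geometry", {
  line <- data.frame(channel = c("a", "b", "c"),
                     x = c(0, 1, 2), y = 0)
  adj <- build_adjacency(line, radius = 1.1)
  expect_equal(nrow(adj$edges), 2)
  expect_equal(sort(paste(adj$edges[, 1], adj$edges[, 2])),
               c("1 2", "2 3"))
  full <- build_adjacency(line, radius = 10)
  expect_equal(nrow(full$edges), 3)
  expect_error(build_adjacency(line, radius = 0), "positive")
  # the default scoring montage leaves no channel isolated
  adj8 <- build_adjacency(default_montage())
  deg <- tabulate(c(adj8$edges), nbins = 8)
  expect_true(all(deg >= 1))
})

test_that("identical group data produce no clusters", {
  set.seed(4)
  half <- array(rnorm(10 * 8 * 5), c(10, 8, 5))
  data <- array(0, c(20, 8, 5))
  data[1:10, , ] <- half
  data[11:20, , ] <- half
  res <- cluster_permutation_test(data, rep(c("a", "b"), each = 10),
                                  "t", build_adjacency(default_montage()),
                                  n_perm = 50, seed = 1)
  expect_equal(nrow(res$clusters), 0)
})

test_that("group-size and group-count contracts are enforced", {
  adj <- build_adjacency(default_montage())
  data <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  expect_error(cluster_permutation_test(data, rep(c("a", "b", "c"), 2),
                                        "t", adj), "exactly 2")
  expect_error(cluster_permutation_test(data, rep(c("a", "b"), 3),
                                        "F", adj), "exactly 3")
  expect_error(cluster_permutation_test(
    data, c("a", rep("b", 5)), "t", adj), "at least 2")
})

test_that("injected effects are detected and localised", {
  set.seed(9)
  adj <- build_adjacency(default_montage())
  hits <- overlap <- logical(10)
  for (r in 1:10) {
    data <- array(rnorm(40 * 8 * 10), c(40, 8, 10))
    g <- rep(c("a", "b"), each = 20)
    # F3, F4, C3, C4 (mutually adjacent) over bins 3:6, d = 1.5
    data[g == "a", 1:4, 3:6] <- data[g == "a", 1:4, 3:6] + 1.5
    res <- cluster_permutation_test(data, g, "t", adj, n_perm = 300,
                                    seed = r)
    sig <- which(res$clusters$p <= 0.05)
    hits[r] <- length(sig) > 0
    if (hits[r]) {
      mem <- res$members[[sig[1]]]
      inj <- paste(rep(c("F3", "F4", "C3", "C4"), each = 4),
                   rep(3:6, 4))
      got <- paste(mem$channel, mem$bin)
      overlap[r] <- mean(inj %in% got) >= 0.75
    }
  }
  expect_gte(mean(hits), 0.9)
  expect_gte(mean(overlap[hits]), 0.75)
})

test_that("swapping the two group labels flips signs but not p-values", {
  set.seed(12)
  adj <- build_adjacency(default_montage())
  data <- array(rnorm(24 * 8 * 6), c(24, 8, 6))
  g <- rep(c("a", "b"), each = 12)
  data[g == "a", 3:5, 2:4] <- data[g == "a", 3:5, 2:4] + 1.2
  r1 <- cluster_permutation_test(data, factor(g, c("a", "b")), "t", adj,
                                 n_perm = 200, seed = 5)
  r2 <- cluster_permutation_test(data, factor(g, c("b", "a")), "t", adj,
                                 n_perm = 200, seed = 5)
  expect_equal(r1$clusters$mass, -r2$clusters$mass)
  expect_equal(r1$clusters$p, r2$clusters$p)
})

test_that("permutation p-values are invariant to element reordering", {
  set.seed(3)
  mont <- default_montage()
  data <- array(rnorm(16 * 8 * 4), c(16, 8, 4))
  g <- rep(c("a", "b"), each = 8)
  data[g == "a", 5:8, ] <- data[g == "a", 5:8, ] + 1
  adj <- build_adjacency(mont)
  r1 <- cluster_permutation_test(data, g, "t", adj, n_perm = 200, seed = 2)
  # reorder channels consistently in data, montage
  ord <- c(3, 1, 4, 2, 8, 6, 7, 5)
  r2 <- cluster_permutation_test(data[, ord, ], g,
                                 build_adjacency(mont[ord, ]),
                                 stat = "t",
                                 n_perm = 200, seed = 2)
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass))
  expect_equal(r1$clusters$p[order(r1$clusters$mass)],
               r2$clusters$p[order(r2$clusters$mass)])
})

test_that("permutation p approaches the exhaustive enumeration p", {
  set.seed(21)
  mont <- default_montage()[1:4, ]
  adj <- build_adjacency(mont)
  data <- array(rnorm(8 * 4 * 3), c(8, 4, 3))
  data[1:4, 1:2, ] <- data[1:4, 1:2, ] + 1.6
  res <- cluster_permutation_test(data, rep(c("a", "b"), each = 4), "t",
                                  adj, n_perm = 4000, seed = 7)
  expect_gt(nrow(res$clusters), 0) # the injected effect forms a cluster
  exact <- exhaustive_cluster_p(data, 4, adj, cluster_alpha = 0.05)
  # exhaustive_cluster_p returns p per observed cluster in its own
  # (unsorted) order; match on |mass| ordering
  perm_p <- res$clusters$p[order(-abs(res$clusters$mass))]
  exact_p <- sort(exact)
  expect_equal(length(perm_p), length(exact_p))
  expect_lt(max(abs(perm_p - exact_p)), 0.02)
})

test_that("post-hoc pairwise contrasts recover directional clusters", {
  set.seed(30)
  adj <- build_adjacency(default_montage())
  n <- 36
  g <- rep(c("Wake", "N1", "N2"), each = 12)
  data <- array(rnorm(n * 8 * 8, sd = 0.8), c(n, 8, 8))
  # N1 has extra "alpha" power on bins 3:5 everywhere
  data[g == "N1", , 3:5] <- data[g == "N1", , 3:5] + 1.2
  res <- posthoc_pairwise(data, g, list(c("N1", "N2")), adjacency = adj,
                          n_perm = 300, seed = 4)
  expect_named(res, "N1_vs_N2")
  top <- res$N1_vs_N2$clusters[1, ]
  expect_equal(top$sign, "+")
  expect_lt(top$p, 0.05)
  expect_true(all(res$N1_vs_N2$members[[1]]$bin %in% 2:6))
  # identical pair members give an empty result
  same <- array(rep(rnorm(8 * 8), each = 8), c(8, 8, 8))
  r0 <- posthoc_pairwise(same, rep(c("x", "y"), 4), list(c("x", "y")),
                         adjacency = adj, n_perm = 50, seed = 1)
  expect_equal(nrow(r0$`x_vs_y`$clusters), 0)
})
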