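rand_profiles <- function(n, centers, sd = 0.05, seed = 1L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(rnorm(n * 3L, mean = rep(centers[k, ], each = n), sd = sd),
           n, 3L)))
  colnames(X) <- c("p10", "00", "m10")
  rownames(X) <- sprintf("r%03d", seq_len(nrow(X)))
  X
}

test_that("k-means MSE equals its brute-force recomputation", {
  centers <- rbind(c(0.7, 0.5, 0.3), c(0, 0, 0), c(-0.5, -0.5, -0.5))
  X <- rand_profiles(30L, centers, sd = 0.1, seed = 2L)
  for (k in c(2L, 3L, 5L)) {
    cl <- kmeans_profiles(X, k, n_restarts = 20L, seed = 4L)
    brute <- mean(vapply(seq_len(nrow(X)), function(i)
      sum((X[i, ] - cl$centroids[cl$assignments[i], ])^2), numeric(1L)))
    expect_equal(cl$mse, brute)
  }
})

test_that("k-means degenerate cases: k = N and identical profiles", {
  X <- rand_profiles(4L, rbind(c(0.5, 0, -0.5)), sd = 0.2, seed = 9L)
  cl <- kmeans_profiles(X, nrow(X), n_restarts = 30L, seed = 1L)
  expect_equal(cl$mse, 0)
  same <- matrix(rep(c(0.3, 0.2, 0.1), each = 6L), 6L, 3L)
  rownames(same) <- sprintf("s%d", 1:6)
  cl1 <- kmeans_profiles(same, 1L, seed = 1L)
  expect_equal(cl1$mse, 0)
  expect_equal(unname(cl1$centroids[1L, ]), c(0.3, 0.2, 0.1))
  expect_error(kmeans_profiles(same[1:2, ], 3L), "fewer profiles")
})

test_that("well-separated blobs are recovered exactly and k=1 MSE is the variance", {
  centers <- rbind(c(0.8, 0.8, 0.8), c(-0.2, -0.2, -0.2))
  X <- rand_profiles(25L, centers, sd = 0.05, seed = 3L)
  cl <- kmeans_profiles(X, 2L, n_restarts = 20L, seed = 5L)
  planted <- rep(1:2, each = 25L)
  # same partition up to label swap
  expect_equal(length(unique(paste(planted, cl$assignments))), 2L)
  cl1 <- kmeans_profiles(X, 1L, seed = 1L)
  expect_equal(cl1$mse,
               mean(rowSums(sweep(X, 2L, colMeans(X))^2)))
})

test_that("elbow curve is nonincreasing and flags the planted cluster count", {
  arch_centers <- rbind(
    c(0.55, 0.4, 0.2), c(0.3, 0.1, -0.05), c(0.5, -0.1, -0.5),
    c(0, 0, 0), c(-0.45, -0.45, -0.45))
  X <- rand_profiles(40L, arch_centers, sd = 0.05, seed = 6L)
  ec <- elbow_curve(X, k_range = 1:8, n_restarts = 30L, seed = 2L)
  expect_true(all(diff(ec$mse) <= 1e-12))
  ratios <- ec$mse[-1L] / ec$mse[-nrow(ec)]
  # successive-ratio elbow: the drop into k=5 clearly beats the drop after
  expect_lt(ratios[4L], ratios[5L])
  # single blob: no comparable elbow at 5
  X1 <- rand_profiles(200L, rbind(c(0, 0, 0)), sd = 0.2, seed = 7L)
  ec1 <- elbow_curve(X1, k_range = 1:8, n_restarts = 20L, seed = 2L)
  r1 <- ec1$mse[-1L] / ec1$mse[-nrow(ec1)]
  expect_gt(r1[4L], ratios[4L])
})

test_that("cluster labelling follows the documented centroid rule", {
  cents <- rbind(c(0.8, 0.7, 0.3), c(0.4, 0.3, 0.1), c(0.6, 0.1, -0.4),
                 c(0.05, 0.0, -0.05), c(-0.3, -0.3, -0.2))
  expect_equal(label_clusters(cents),
               c("signal-like", "signal-dominated", "balanced",
                 "insensitive", "masker-like"))
  # permutation invariance: each centroid keeps its label
  perm <- c(4L, 1L, 5L, 2L, 3L)
  expect_equal(label_clusters(cents[perm, ]),
               label_clusters(cents)[perm])
  # duplicated centroids: deterministic, no crash, all five labels used
  dup <- rbind(cents[1:4, ], cents[4, ])
  expect_setequal(label_clusters(dup), category_levels())
  expect_error(label_clusters(cents[1:4, ]), "k = 5")
  expect_equal(label_clusters(cents[1:3, ], named = FALSE),
               c("cluster_1", "cluster_2", "cluster_3"))
})

test_that("bootstrap stability is 100/100 for zero-variability recordings", {
  p <- quick_protocol(5L)
  d <- make_dataset(generator_config(p, n_per_category = c("signal-like" = 1L),
                                     seed = 14L))
  r <- d$recordings[[1L]]
  # duplicate one trial across every condition: resampling is a no-op
  for (cid in names(r$blocks)) {
    tr <- r$blocks[[cid]]$trains
    r$blocks[[cid]]$trains <- rep(tr[1L], length(tr))
  }
  cents <- rbind(c(0.6, 0.5, 0.4), c(0.3, 0.2, 0.1), c(0.5, 0, -0.5),
                 c(0, 0, 0), c(-0.4, -0.4, -0.4))
  lm <- label_clusters(cents)
  bs <- bootstrap_stability(r, p, "stationary", cents, lm, n_boot = 100L,
                            seed = 3L)
  expect_equal(bs$bootstrap_mode_count, 100L)
  expect_true(bs$reliable)
  expect_equal(bs$mode_category, bs$category)
})

test_that("borderline noisy profiles are not reliable and reruns are identical", {
  p <- quick_protocol(5L)
  # sparse, noisy recording whose EI sits between two nearby centroids
  arch <- category_archetype("insensitive", c(0.3, 0.3, 0.3),
                             c(0.3, 0.3, 0.3), 2, 6, 0.6, 0.01)
  cfg <- generator_config(p, n_per_category = c(insensitive = 1L),
                          archetypes = stats::setNames(
                            rep(list(arch), 5L), category_levels()),
                          seed = 33L)
  d <- make_dataset(cfg)
  r <- d$recordings[[1L]]
  own <- ei_profile(r, p)$ei["stationary", ]
  delta <- c(0.08, 0.08, 0.08)
  cents <- rbind(own + delta, own - delta, c(1, 1, 1), c(-1, -1, -1),
                 c(1, 0, -1))
  lm <- sprintf("cluster_%d", 1:5)
  b1 <- bootstrap_stability(r, p, "stationary", cents, lm, n_boot = 100L,
                            seed = 7L)
  expect_lt(b1$bootstrap_mode_count, 95L)
  expect_false(b1$reliable)
  b2 <- bootstrap_stability(r, p, "stationary", cents, lm, n_boot = 100L,
                            seed = 7L)
  expect_identical(b1$boot_categories, b2$boot_categories)
})
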