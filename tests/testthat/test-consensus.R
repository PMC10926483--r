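# Fixtures: well-separated Gaussian blobs with planted labels.
make_blobs <- function(n_per = 20, centers = rbind(c(0, 0), c(10, 0), c(5, 9)),
                       sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
          centers[i, ], "+")))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("z-scoring centers and scales each feature column", {
  expect_equal(zscore_features(cbind(a = c(1, 2, 3), b = c(4, 8, 12))),
               cbind(c(-1, 0, 1), c(-1, 0, 1)), ignore_attr = TRUE)
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  Z <- zscore_features(X)
  expect_equal(colMeans(Z), rep(0, 4), tolerance = 1e-8)
  expect_equal(apply(Z, 2, sd), rep(1, 4), tolerance = 1e-8)
  expect_equal(zscore_features(Z), Z, tolerance = 1e-8,
               ignore_attr = TRUE)  # idempotent
  expect_error(zscore_features(cbind(a = c(1, 2, 3), b = rep(2, 3))),
               "zero-variance")
})

test_that("rows with undefined features are excluded before z-scoring", {
  X <- data.frame(ymax = c(1, 2, NA, 4), rotation_asymmetry = c(0, 1, 0.5, 0.2),
                  tortuosity = c(0.9, 0.8, 0.7, 0.6),
                  walking_pace = c(1, 2, 3, 4),
                  abs_turning_velocity = c(0, 0.1, 0.2, 0.3))
  Z <- zscore_features(X)
  expect_equal(nrow(Z), 3L)
  expect_equal(attr(Z, "n_excluded"), 1L)
  expect_equal(attr(Z, "kept_rows"), c(1L, 2L, 4L))
})

test_that("consensus on two point-masses is exactly block 0/1", {
  X <- rbind(matrix(0, 10, 2), matrix(5, 10, 2)) +
    matrix(rnorm(40, 0, 1e-6), 20)
  M <- consensus_run(X, k = 2, reps = 50, seed = 1)
  grp <- rep(1:2, each = 10)
  same <- outer(grp, grp, "==")
  expect_equal(unclass(M)[same], rep(1, sum(same)))
  expect_equal(unclass(M)[!same], rep(0, sum(!same)))
})

test_that("without resampling the consensus reproduces one k-means partition", {
  b <- make_blobs(n_per = 10, seed = 2)
  M <- consensus_run(b$X, k = 3, reps = 1, item_frac = 1, feature_frac = 1,
                     seed = 3)
  expect_true(all(unclass(M) %in% c(0, 1)))
  expect_equal(unclass(M), outer(b$labels, b$labels, function(a, b)
    as.numeric(a == b)), ignore_attr = TRUE)
})

test_that("consensus matrices are symmetric, bounded, seeded, permutation-equivariant", {
  b <- make_blobs(n_per = 8, sd = 1.5, seed = 4)
  M1 <- consensus_run(b$X, k = 3, reps = 60, seed = 9)
  M2 <- consensus_run(b$X, k = 3, reps = 60, seed = 9)
  expect_identical(unclass(M1), unclass(M2))      # bitwise determinism
  M <- unclass(M1)
  expect_equal(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(diag(M) == 1))
  # permuting rows permutes the consensus matrix accordingly (same seed
  # stream, so compare partitions via the hierarchical cut, not entries)
  perm <- sample(nrow(b$X))
  Mp <- consensus_run(b$X[perm, ], k = 3, reps = 60, seed = 9)
  lab <- assign_clusters(M1, 3)
  labp <- assign_clusters(Mp, 3)
  expect_gt(mclust::adjustedRandIndex(labp, lab[perm]), 0.99)
})

test_that("PAC counts the ambiguous window correctly", {
  stable <- matrix(sample(c(0, 1), 64, TRUE), 8); diag(stable) <- 1
  expect_equal(pac(stable), 0)
  fuzzy <- matrix(0.5, 8, 8); diag(fuzzy) <- 1
  expect_equal(pac(fuzzy), 1)
  m <- matrix(1, 8, 8)
  off <- which(row(m) != col(m))
  m[off[seq(1, length(off), 2)]] <- 0.5   # half the off-diagonal at 0.5
  expect_equal(pac(m, 0.1, 0.9), 0.5)
  expect_error(pac(m, 0.9, 0.1), "lower < upper")
})

test_that("PAC falls as two blobs separate", {
  # gaps start at the point where the blobs begin to disentangle: at
  # near-complete overlap a k=2 partition is just a stable hyperplane split,
  # so PAC only discriminates once real separation exists
  pacs <- vapply(c(2, 3, 6), function(gap) {
    set.seed(5)
    X <- rbind(matrix(rnorm(60, 0, 1), 30), matrix(rnorm(60, gap, 1), 30))
    pac(consensus_run(X, k = 2, reps = 80, seed = 6))
  }, numeric(1))
  expect_true(all(diff(pacs) <= 0))   # non-increasing with separation
  expect_lt(pacs[3], pacs[1])         # and strictly lower overall
})

test_that("Monte-Carlo reference surrogates match the source covariance", {
  set.seed(8)
  X <- matrix(rnorm(500 * 4), 500, 4)          # spherical standard normal
  refs <- monte_carlo_reference(X, B = 40, seed = 11)
  expect_length(refs, 40L)
  pooled <- do.call(rbind, refs)
  # surrogates are matched to the *empirical* covariance of X, which itself
  # sits within sampling error of the identity here
  expect_equal(cov(pooled), cov(X), tolerance = 0.05, ignore_attr = TRUE)
  expect_lt(max(abs(cov(pooled) - diag(4))), 0.15)
  expect_identical(monte_carlo_reference(X, B = 3, seed = 2),
                   monte_carlo_reference(X, B = 3, seed = 2))
  expect_error(monte_carlo_reference(X, B = 0), "B must be")
  # correlated source: surrogates reproduce the correlation
  Y <- cbind(X[, 1], X[, 1] * 0.9 + 0.45 * X[, 2], X[, 3], X[, 4])
  refs2 <- monte_carlo_reference(Y, B = 40, seed = 12)
  pooled2 <- do.call(rbind, refs2)
  expect_equal(cov(pooled2), cov(Y), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("select_k recovers the planted cluster count on separable data", {
  b <- make_blobs(n_per = 20, sd = 0.1, seed = 13)   # 3 blobs, n = 60
  ks <- select_k(b$X, k_range = 2:6, reps = 100, B = 8, seed = 14)
  expect_equal(ks$chosen_k, 3)
  expect_lt(ks$pac[ks$k_range == 3], 0.01)

  masses <- rbind(matrix(0, 15, 2), matrix(8, 15, 2)) +
    matrix(rnorm(60, 0, 1e-4), 30)
  ks2 <- select_k(masses, k_range = 2:5, reps = 100, B = 8, seed = 15)
  expect_equal(ks2$chosen_k, 2)
  expect_equal(ks2$pac[ks2$k_range == 2], 0)
})

test_that("a single Gaussian shows no stability support for any k", {
  set.seed(16)
  X <- matrix(rnorm(60 * 3), 60, 3)
  ks <- select_k(X, k_range = 2:6, reps = 100, B = 8, seed = 17)
  # real data are themselves a draw from the reference model: RCSI ~ 0,
  # nowhere near the strong support (RCSI >> 1) seen for genuine structure
  expect_lt(max(ks$rcsi), 1)
})

test_that("assign_clusters cuts consensus blocks and renumbers by size", {
  grp <- rep(1:3, times = c(10, 6, 4))
  M <- outer(grp, grp, function(a, b) as.numeric(a == b))
  lab <- assign_clusters(M, 3)
  expect_equal(lab, grp)                       # already size-ordered
  # permuted input recovers the same partition
  perm <- sample(20)
  labp <- assign_clusters(M[perm, perm], 3)
  expect_equal(labp, grp[perm])
  # noisy blocks at 0.9 / 0.1
  set.seed(18)
  noisy <- ifelse(M == 1, 0.9, 0.1) + matrix(runif(400, -0.05, 0.05), 20)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 1
  expect_equal(assign_clusters(noisy, 3), grp)
})

test_that("cluster proportions sum to one per treatment-stimulus cell", {
  md <- data.frame(treatment = rep(c("CTL", "IMD"), each = 6),
                   stimulus_label = rep(rep(c("s1", "s2"), each = 3), 2))
  lab <- rep(1L, 12)
  pr <- cluster_proportions(lab, md)
  expect_true(all(pr$proportion == 1))
  md <- data.frame(treatment = rep(c("CTL", "IMD"), each = 4),
                   stimulus_label = rep(rep(c("s1", "s2"), each = 2), 2))
  lab <- rep(1L, 8)
  lab2 <- rep(c(1L, 2L), 4)                    # planted 50/50 in every cell
  pr2 <- cluster_proportions(lab2, md)
  expect_true(all(pr2$proportion == 0.5))
  agg <- aggregate(proportion ~ treatment + stimulus_label, pr2, sum)
  expect_true(all(abs(agg$proportion - 1) < 1e-12))
  expect_error(cluster_proportions(lab, md[1:3, ]), "must match")
})

test_that("cluster recovery on the default synthetic cohort is near-perfect", {
  ft <- default_cohort_features()
  Z <- zscore_features(ft)
  M <- consensus_run(Z, k = 3, reps = 200, seed = 19)
  lab <- assign_clusters(M, 3)
  ari <- mclust::adjustedRandIndex(lab, ft$archetype[attr(Z, "kept_rows")])
  expect_gte(ari, 0.9)
  # treatment-dependent mixtures are visible in the cluster proportions:
  # the follower-dominated control carries more of the follower cluster
  pr <- cluster_proportions(lab, ft[attr(Z, "kept_rows"), ])
  arch_by_cluster <- table(ft$archetype[attr(Z, "kept_rows")], lab)
  follower_cl <- which.max(arch_by_cluster["FOLLOWER", ])
  mean_prop <- function(tr) {
    rows <- pr[pr$treatment == tr & pr$cluster == follower_cl, ]
    sum(rows$n) / sum(pr$n[pr$treatment == tr])
  }
  expect_gt(mean_prop("CTL"), mean_prop("SFX"))
})
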