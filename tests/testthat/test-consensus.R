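test_that("subsampling draws the right number of distinct indices", {
  set.seed(1)
  s <- subsample(10, 0.8)
  expect_length(s, 8)
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s %in% 1:10))
  expect_identical(subsample(5, 1), 1:5)
  expect_error(subsample(10, 0), "fraction")
  expect_error(subsample(10, 0.2, k = 3), "cannot support")
  set.seed(42); a <- subsample(100, 0.8)
  set.seed(42); b <- subsample(100, 0.8)
  expect_identical(a, b)
})

test_that("the base clusterer recovers well-separated groups exactly", {
  x <- two_group_matrix(n1 = 4, n2 = 4, seed = 2)
  lab <- base_cluster(x, 2)
  oracle <- best_2partition(x)
  expect_equal(adjusted_rand(lab, oracle), 1)
  # K = n gives singletons
  expect_equal(sort(unique(base_cluster(x, 8))), 1:8)
  # duplicated samples always co-assigned
  y <- rbind(x, x[1, ])
  for (k in 2:5) {
    l <- base_cluster(y, k)
    expect_equal(l[1], l[9])
  }
  expect_error(base_cluster(x[1:2, ], 3), "at least")
})

test_that("zero-variance samples get distance 1 with a message", {
  x <- rbind(c(1, 2, 3), c(2, 4, 6), c(5, 5, 5))
  expect_message(d <- pearson_dist(x), "zero-variance")
  m <- as.matrix(d)
  expect_equal(m[1, 3], 1)
  expect_equal(m[1, 2], 0, tolerance = 1e-12)
})

test_that("consensus matrix equals direct co-clustering counts", {
  # 2 samples co-sampled 4 times, co-clustered 3 of them -> 0.75
  runs <- list(
    list(subset = c(1L, 2L), labels = c(1L, 1L)),
    list(subset = c(1L, 2L), labels = c(1L, 1L)),
    list(subset = c(1L, 2L), labels = c(1L, 2L)),
    list(subset = c(1L, 2L, 3L), labels = c(1L, 1L, 2L)))
  M <- suppressWarnings(consensus_matrix(runs, 4))
  expect_equal(M[1, 2], 0.75)
  expect_equal(M[2, 1], 0.75)
  expect_equal(diag(M), rep(1, 4))
  # sample 4 never drawn: consensus 0 and a warning
  expect_warning(consensus_matrix(runs, 4), "never co-sampled")
  expect_equal(M[1, 4], 0)
  # single iteration: entries in {0, 1}
  M1 <- suppressWarnings(consensus_matrix(runs[4], 3))
  expect_true(all(M1 %in% c(0, 1)))
  expect_equal(M1[1, 2], 1); expect_equal(M1[1, 3], 0)
})

test_that("consensus matrix matches a brute-force recount on a full run", {
  set.seed(7)
  x <- two_group_matrix(n1 = 4, n2 = 4, seed = 7)
  res <- run_consensus(x, k_range = 2:4, iters = 20, seed = 3,
                       keep_runs = TRUE)
  for (k in 2:4) {
    M <- res$matrices[[as.character(k)]]
    expect_identical(M, consensus_recount(res$runs[[as.character(k)]], 8))
    expect_true(isSymmetric(M))
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(diag(M), rep(1, 8))
  }
  # perfectly separated pairs at K=2: within-group 1, cross-group 0
  M2 <- res$matrices[["2"]]
  expect_true(all(M2[1:4, 1:4] == 1))
  expect_true(all(M2[1:4, 5:8] == 0))
})

test_that("consensus CDF areas match hand-computed Riemann sums", {
  M <- diag(3)  # upper triangle all zero
  cc <- consensus_cdf(M)
  expect_equal(cc$area, 1)
  M1 <- matrix(1, 3, 3)
  expect_equal(consensus_cdf(M1)$area, 0)
  # entries {0, 0.5, 1} equally: integral of step CDF = 1/3*0.5 + 2/3*0.5
  M3 <- diag(3); M3[1, 2] <- M3[2, 1] <- 0; M3[1, 3] <- M3[3, 1] <- 0.5
  M3[2, 3] <- M3[3, 2] <- 1
  cc3 <- consensus_cdf(M3)
  expect_equal(cc3$area, 0.5, tolerance = 1e-12)
  expect_equal(cc3$area, cdf_area_hand(c(0, 0.5, 1)), tolerance = 1e-12)
  # CDF is non-decreasing, ends at 1
  expect_true(all(diff(cc3$cdf$cdf) >= 0))
  expect_equal(max(cc3$cdf$cdf), 1)
  # random case vs hand integral
  set.seed(8)
  v <- round(runif(45), 2)
  Mr <- matrix(0, 10, 10); Mr[upper.tri(Mr)] <- v
  Mr <- Mr + t(Mr); diag(Mr) <- 1
  expect_equal(consensus_cdf(Mr)$area, cdf_area_hand(v), tolerance = 1e-12)
})

test_that("the delta-area rule picks the elbow K", {
  areas <- c(`2` = 0.2, `3` = 0.5, `4` = 0.9, `5` = 0.92, `6` = 0.93)
  sel <- select_k(areas, tau = 0.1)
  expect_equal(sel$k, 4L)
  expect_equal(unname(sel$deltas[["4"]]), 0.8, tolerance = 1e-12)
  expect_equal(unname(sel$deltas[["5"]]), 0.02 / 0.9, tolerance = 1e-12)
  # flat areas: fall back to K = 2 with a warning
  expect_warning(sel2 <- select_k(c(`2` = 0.05, `3` = 0.051, `4` = 0.052)),
                 "falling back")
  expect_equal(sel2$k, 2L)
  # manual override
  expect_equal(select_k(areas, override = 6)$k, 6L)
  expect_error(select_k(areas, override = 11), "not in K range")
  expect_error(select_k(areas[1:2]), "at least 3")
})

test_that("final labels split block-diagonal consensus exactly and are stable", {
  M <- matrix(0, 6, 6)
  M[1:4, 1:4] <- 1; M[5:6, 5:6] <- 1
  lab <- final_labels(M, 2, prefix = "T")
  expect_equal(as.character(lab$subtype), c(rep("T1", 4), rep("T2", 2)))
  # largest cluster gets index 1
  expect_equal(levels(lab$subtype), c("T1", "T2"))
  # permuting sample order permutes labels consistently
  perm <- c(5, 1, 6, 2, 3, 4)
  lab2 <- final_labels(M[perm, perm], 2, sample_ids = paste0("s", perm),
                       prefix = "T")
  expect_equal(as.character(lab2$subtype[match(paste0("s", 1:6), lab2$sample_id)]),
               as.character(lab$subtype))
})

test_that("run_consensus is deterministic and honest about iters = 1", {
  x <- two_group_matrix(6, 6, seed = 4)
  r1 <- run_consensus(x, k_range = 2:4, iters = 25, seed = 5)
  r2 <- run_consensus(x, k_range = 2:4, iters = 25, seed = 5)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  r3 <- suppressWarnings(run_consensus(x, k_range = 2:4, iters = 1, seed = 5))
  for (M in r3$matrices) expect_true(all(M %in% c(0, 1)))
})

test_that("K selection is stable between reduced and longer runs", {
  ks <- vapply(1:5, function(s) {
    cfg <- synth_config(n_patients = 60, n_metabolites = 40,
                        grid_shape = c(4, 4), seed = s)
    d <- generate_discovery_cohort(cfg)
    co <- suppressMessages(build_cohort(d$grids, d$if_images, d$patient_ids,
                                        min_pixels = 2))
    k_small <- run_consensus(co$tumor, k_range = 2:6, iters = 40, seed = s)$k
    k_big <- run_consensus(co$tumor, k_range = 2:6, iters = 400, seed = s)$k
    k_small == k_big
  }, logical(1))
  expect_gte(sum(ks), 4)
})

test_that("label ordering convention is invariant to sample order", {
  cfg <- synth_config(n_patients = 50, n_metabolites = 40,
                      grid_shape = c(4, 4), seed = 12)
  d <- generate_discovery_cohort(cfg)
  co <- suppressMessages(build_cohort(d$grids, d$if_images, d$patient_ids,
                                      min_pixels = 2))
  r1 <- run_consensus(co$tumor, k_range = 2:5, iters = 60, seed = 2)
  set.seed(99); perm <- sample(nrow(co$tumor$x))
  co2 <- cohort_matrix(co$tumor$x[perm, ], "tumor",
                       co$tumor$sample_ids[perm])
  r2 <- run_consensus(co2, k_range = 2:5, iters = 60, seed = 2)
  expect_equal(r1$k, r2$k)
  s1 <- assignment_summary(r1$assignment)
  s2 <- assignment_summary(r2$assignment)
  expect_equal(s1$n, s2$n)
})

test_that("assignment summaries reproduce printed count arithmetic", {
  tum <- rep(paste0("T", 1:4), times = c(91, 64, 81, 77))
  expect_equal(assignment_summary(tum)$percent, c(29L, 20L, 26L, 25L))
  str <- rep(paste0("S", 1:4), times = c(100, 71, 22, 75))
  expect_equal(assignment_summary(str)$percent, c(37L, 27L, 8L, 28L))
  expect_equal(sum(assignment_summary(str)$percent), 100L)
  one <- assignment_summary(rep("T1", 10))
  expect_equal(one$percent, 100L)
  expect_error(assignment_summary(character()), "empty")
})

test_that("silhouette separation behaves at its extremes", {
  # identical duplicated points per group -> silhouette 1
  x <- rbind(matrix(rep(c(1, 2, 3), 3), 3, byrow = TRUE),
             matrix(rep(c(3, 2, 1), 3), 3, byrow = TRUE))
  expect_equal(separation_score(x, rep(c("a", "b"), each = 3)), 1)
  # well-separated planted groups scored high
  y <- two_group_matrix(8, 8, seed = 6)
  expect_gte(separation_score(y, rep(1:2, each = 8)), 0.5)
  # random labels on structureless data: near zero
  set.seed(10)
  z <- matrix(rnorm(200 * 10), 200, 10)
  expect_lte(abs(separation_score(z, sample(1:4, 200, TRUE))), 0.1)
  expect_error(separation_score(y, rep(1, 16)), "at least 2")
})
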