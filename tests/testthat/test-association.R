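test_that("Spearman with mid-rank ties matches hand computation", {
  sr <- spearman_rho(c(0, 0, 1, 1), c(1, 2, 3, 4))
  # mid-ranks of the indicator: (1.5, 1.5, 3.5, 3.5); Pearson with (1,2,3,4)
  expect_equal(sr$rho, 4 / sqrt(20), tolerance = 1e-3)
  expect_equal(sr$rho, cor(c(0, 0, 1, 1), 1:4, method = "spearman"),
               tolerance = 1e-12)
  # constant input -> missing
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)$rho))
})

test_that("Spearman equals Pearson on mid-ranks across random vectors", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, TRUE)  # heavy ties
    y <- rnorm(n)
    expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y)$rho, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("subtype-marker correlations find planted signs and control the null", {
  cfg <- synth_config(n_patients = 300, n_metabolites = 10,
                      grid_shape = c(2, 2), seed = 14)
  d <- generate_discovery_cohort(cfg)
  assign <- data.frame(sample_id = d$patient_ids,
                       subtype = factor(paste0("T", d$truth$z_tumor)))
  res <- subtype_marker_correlation(assign, d$markers)
  expect_true(all(res$rho >= -1 & res$rho <= 1, na.rm = TRUE))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  # planted immune-cold subtype 1: negative with all four markers
  t1 <- res[res$subtype == "T1", ]
  expect_true(all(t1$rho < 0))
  expect_true(all(t1$q < 0.05))
  # planted immune-hot subtype 2: positive
  t2 <- res[res$subtype == "T2", ]
  expect_true(all(t2$rho > 0))
  # degenerate: all samples one subtype -> missing rho
  one <- data.frame(sample_id = d$patient_ids,
                    subtype = factor(rep("T1", nrow(d$markers))))
  res1 <- subtype_marker_correlation(one, d$markers)
  expect_true(all(is.na(res1$rho)))
})

test_that("marker correlations are calibrated under the null", {
  set.seed(22)
  ps <- replicate(200, {
    n <- 100
    ind <- as.numeric(sample(1:4, n, TRUE) == 1)
    spearman_rho(ind, rnorm(n))$p
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.12)
  expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  # at n = 500 the null |rho| is typically small
  rhos <- replicate(50, spearman_rho(as.numeric(sample(1:4, 500, TRUE) == 1),
                                     rnorm(500))$rho)
  expect_lt(stats::quantile(abs(rhos), 0.9), 0.1)
})

test_that("Kruskal-Wallis H matches the rank-sum formula and Dunn is sane", {
  kd <- kruskal_dunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                     rep(c("a", "b", "c"), each = 3))
  # H = 12/(N(N+1)) * sum n_g (rbar_g - (N+1)/2)^2 = 7.2 without ties
  expect_equal(kd$H, 7.2, tolerance = 1e-12)
  expect_equal(kd$df, 2)
  expect_equal(kd$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # the extreme pair has the largest |z|
  pairs <- kd$pairs
  expect_equal(pairs$q, p.adjust(pairs$p, "BH"))
  ac <- pairs[pairs$group1 == "a" & pairs$group2 == "c", ]
  expect_equal(abs(ac$z), max(abs(pairs$z)))

  # identical values: H = 0, p = 1
  kd0 <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(kd0$H, 0)
  expect_equal(kd0$p, 1)

  # permuting group order leaves H unchanged
  v <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  g <- rep(c("x", "y", "z"), 4)
  expect_equal(kruskal_dunn(v, g)$H,
               kruskal_dunn(v, factor(g, levels = c("z", "x", "y")))$H,
               tolerance = 1e-12)

  # Dunn z agrees with kruskal.test's tie correction machinery on tied data
  kt <- kruskal.test(v, factor(g))
  expect_equal(kruskal_dunn(v, g)$H, unname(kt$statistic), tolerance = 1e-12)
})

test_that("clinicopathological tests choose Fisher vs chi-square correctly", {
  assign <- data.frame(sample_id = paste0("P", 1:16),
                       subtype = factor(rep(c("T1", "T2"), each = 8)))
  clinical <- data.frame(patient_id = paste0("P", 1:16),
                         time = rep(10, 16), event = rep(1, 16),
                         uicc = rep("I", 16), pT = rep("T1", 16),
                         pN = rep("N0", 16), M = rep("M0", 16),
                         grade = rep("G2", 16),
                         sex = c(rep("male", 10), rep("female", 6)),
                         age = rep(60, 16), resection = rep("R0", 16),
                         stringsAsFactors = FALSE)
  # sex table [[8,0],[2,6]] has small expected counts -> Fisher
  res <- suppressMessages(clinicopath_tests(assign, clinical,
                                            columns = c("sex", "uicc")))
  expect_equal(res$test[res$column == "sex"], "fisher")
  # single-level column skipped
  expect_false("uicc" %in% res$column)
})

test_that("null clinicopathological associations are rarely significant", {
  set.seed(23)
  hits <- replicate(100, {
    assign <- data.frame(sample_id = paste0("P", 1:120),
                         subtype = factor(sample(paste0("T", 1:4), 120, TRUE)))
    sex <- sample(c("male", "female"), 120, TRUE, prob = c(0.85, 0.15))
    tab <- table(assign$subtype, sex)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    p <- if (any(expected < 5)) fisher.test(tab)$p.value
         else chisq.test(tab, correct = FALSE)$p.value
    p <= 0.05
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("tumor-stroma cross-tabulation counts co-membership", {
  ta <- data.frame(sample_id = paste0("P", 1:6),
                   subtype = factor(paste0("T", c(1, 1, 2, 2, 3, 4))))
  sa <- data.frame(sample_id = paste0("P", c(1:5, 7)),
                   subtype = factor(paste0("S", c(2, 2, 3, 3, 4, 1))))
  tab <- crosstab_subtypes(ta, sa)
  expect_equal(sum(tab), 5)  # overlap size
  expect_equal(unname(tab["T1", "S2"]), 2L)
  expect_equal(rowSums(tab)[["T3"]], 1)
  # identical mappings give a diagonal table
  tb <- crosstab_subtypes(ta, ta)
  expect_true(all(tb[row(tb) != col(tb)] == 0))
  expect_error(crosstab_subtypes(ta, data.frame(sample_id = "X",
                                                subtype = "S1")),
               "no patients")
})

test_that("planted tumor-stroma coupling shows up as row maxima", {
  cfg <- synth_config(n_patients = 200, n_metabolites = 10,
                      grid_shape = c(2, 2), stroma_coupling = 0.8, seed = 17)
  d <- generate_discovery_cohort(cfg)
  ta <- data.frame(sample_id = d$patient_ids,
                   subtype = factor(paste0("T", d$truth$z_tumor)))
  sa <- data.frame(sample_id = d$patient_ids,
                   subtype = factor(paste0("S", d$truth$z_stroma)))
  tab <- crosstab_subtypes(ta, sa)
  # planted map: tumor k -> stroma k+1 (mod 4); check the T1 row peaks at S2
  expect_equal(which.max(tab["T1", ]), c(S2 = 2L))
  expect_equal(which.max(tab["T3", ]), c(S4 = 4L))
})
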