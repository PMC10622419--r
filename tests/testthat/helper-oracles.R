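# Independent oracles used to verify the implementation. Each one recomputes
# the target quantity by a route the implementation never takes (enumeration,
# closed forms, direct formula evaluation).

# two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration: sum probabilities of all tables (given margins) no more
# probable than the observed one
fisher_2x2_enum <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-group log-rank chi-square by the textbook O-E formula over pooled
# distinct event times
logrank_2group_hand <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Cox partial log-likelihood for a single covariate, tie-free data;
# maximized by golden-section search (stats::optimize)
cox_beta_bruteforce <- function(x, time, event) {
  stopifnot(!anyDuplicated(time[event == 1]))
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  negpl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    -ll
  }
  stats::optimize(negpl, c(-10, 10), tol = 1e-9)$minimum
}

# brute-force recount of a consensus matrix from the logged iteration
# outputs: explicit pair loops, no matrix algebra
consensus_recount <- function(runs, n) {
  co <- matrix(0, n, n); both <- matrix(0, n, n)
  for (r in runs) {
    for (a in seq_along(r$subset)) {
      for (b in seq_along(r$subset)) {
        i <- r$subset[a]; j <- r$subset[b]
        both[i, j] <- both[i, j] + 1
        if (r$labels[a] == r$labels[b]) co[i, j] <- co[i, j] + 1
      }
    }
  }
  M <- matrix(0, n, n)
  nz <- both > 0
  M[nz] <- co[nz] / both[nz]
  diag(M) <- 1
  M
}

# exhaustive best 2-partition of <= 12 samples minimizing total within-group
# 1 - Pearson distance
best_2partition <- function(x) {
  n <- nrow(x)
  d <- as.matrix(1 - cor(t(x)))
  best <- NULL; best_cost <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    g <- c(1L, as.integer(intToBits(code)[1:(n - 1)]) + 1L)
    cost <- 0
    for (grp in 1:2) {
      idx <- which(g == grp)
      if (length(idx) > 1) cost <- cost + sum(d[idx, idx]) / 2
    }
    if (cost < best_cost) { best_cost <- cost; best <- g }
  }
  best
}

# left-Riemann integral of the empirical CDF of v over [0, 1], by hand
cdf_area_hand <- function(v) {
  br <- sort(unique(c(0, v, 1)))
  sum(vapply(seq_len(length(br) - 1), function(i)
    mean(v <= br[i]) * (br[i + 1] - br[i]), numeric(1)))
}

# small synthetic cohorts used across tests
tiny_cfg <- function(...) {
  synth_config(n_patients = 40, n_metabolites = 30, grid_shape = c(6, 6),
               ...)
}

# planted two-group matrix: rows 1..n1 around center1, rest around center2
two_group_matrix <- function(n1 = 5, n2 = 5, m = 20, sep = 5, sd = 0.3,
                             seed = 1) {
  set.seed(seed)
  c1 <- rnorm(m); c2 <- c1 + sep * seq(-1, 1, length.out = m)
  rbind(matrix(rnorm(n1 * m, sd = sd), n1, m, byrow = TRUE) + rep(c1, each = n1),
        matrix(rnorm(n2 * m, sd = sd), n2, m, byrow = TRUE) + rep(c2, each = n2))
}

map_to_truth <- function(labels, truth) {
  # majority-map cluster labels onto planted labels
  tab <- table(labels, truth)
  map <- colnames(tab)[apply(tab, 1, which.max)]
  names(map) <- rownames(tab)
  map[as.character(labels)]
}
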