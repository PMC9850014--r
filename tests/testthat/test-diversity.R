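test_that("Ho, Hs and Fis follow Nei's unbiased small-sample arithmetic", {
  # two individuals {AA, Aa}: p = 0.75, Ho = 0.5,
  # Hs = 2 * (1 - 0.5625 - 0.0625 - 0.5/4) = 0.5, Fis = 0
  g <- gm(cbind(c(0, 1)))
  hh <- ho_hs_fis(g)
  expect_equal(hh$per_locus$Hs, 0.5)
  expect_equal(hh$per_locus$Fis, 0)
  # all-homozygous locus at p = 0.5: Ho = 0, Fis = 1
  g2 <- gm(cbind(c(0, 2, 0, 2)))
  hh2 <- ho_hs_fis(g2)
  expect_equal(hh2$per_locus$Ho, 0)
  expect_equal(hh2$per_locus$Fis, 1)
  # loci with < 2 typed genotypes are skipped
  g3 <- gm(cbind(c(0, 1, 2), c(NA, NA, 1)))
  expect_equal(nrow(ho_hs_fis(g3)$per_locus), 1L)
})

test_that("Fis is centred on zero under Hardy-Weinberg simulation", {
  g <- hwe_genotypes(200, runif(300, 0.1, 0.9), seed = 77)
  fis <- ho_hs_fis(g)$per_locus$Fis
  se <- sd(fis) / sqrt(length(fis))
  expect_lt(abs(mean(fis)), 3 * se)
})

test_that("Hs converges to expected heterozygosity for large samples", {
  p <- c(0.2, 0.35, 0.5)
  g <- hwe_genotypes(20000, p, seed = 5)
  hh <- ho_hs_fis(g)
  expect_true(all(abs(hh$per_locus$Hs - 2 * p * (1 - p)) < 1e-2))
  # and the small-sample correction term itself is below 1e-3 at this n
  expect_true(all(abs(hh$per_locus$Hs -
                        (1 - hh$per_locus$p^2 - (1 - hh$per_locus$p)^2)) < 1e-3))
})

test_that("MLH counts heterozygous sites among typed loci", {
  g <- gm(rbind(rep(1, 6), c(1, 1, 1, 0, 2, 0), c(0, NA, 1, NA, 1, 0)))
  m <- mlh(g)
  expect_equal(unname(m), c(1, 0.5, 0.5))
  # identity: mean MLH = mean Ho with no missing data
  gg <- hwe_genotypes(50, runif(40, 0.1, 0.9), seed = 3)
  expect_equal(mean(mlh(gg)), mean(ho_hs_fis(gg)$per_locus$Ho))
})

test_that("IR equals a brute-force evaluation with both-copies frequency summation", {
  codes <- rbind(c(0, 1, 2), c(2, 1, 0), c(1, 1, 1), c(0, 0, 2))
  g <- gm(codes)
  p_alt <- colMeans(codes) / 2
  brute <- apply(codes, 1, function(row) {
    H <- sum(row != 1)
    sum_f <- 0
    for (l in seq_along(row)) {
      if (row[l] == 0) sum_f <- sum_f + 2 * (1 - p_alt[l])
      if (row[l] == 2) sum_f <- sum_f + 2 * p_alt[l]
    }
    (2 * H - sum_f) / (2 * length(row) - sum_f)
  })
  expect_equal(unname(ir(g)), unname(brute))
  # fully heterozygous individual: IR = 0 / (2N) = 0
  expect_equal(unname(ir(g))[3], 0)
})

test_that("the paired Wilcoxon test matches exact signed-rank enumeration", {
  set.seed(9)
  a <- round(runif(12, 0.1, 0.5), 3)
  d <- round(runif(12, -0.1, 0.2), 4)
  d[d == 0] <- 0.01
  b <- a + d
  res <- paired_wilcoxon_by_locus(a, b)
  # exact null distribution of V by dynamic programming over sign flips
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  max_v <- sum(r)
  counts <- c(1, rep(0, max_v))          # counts[v + 1] = #assignments with sum v
  for (ri in r) {
    shifted <- c(rep(0, ri), counts[seq_len(max_v + 1 - ri)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r)
  p_exact <- 2 * min(sum(probs[seq_len(v_obs + 1)]),
                     sum(probs[(v_obs + 1):(max_v + 1)]))
  expect_equal(unname(res$statistic), v_obs)
  expect_equal(res$p_value, min(1, p_exact))
  # degenerate and extreme cases
  expect_error(paired_wilcoxon_by_locus(a, a), "degenerate")
  expect_lt(paired_wilcoxon_by_locus(seq(0, 1, length.out = 40),
                                     seq(0, 1, length.out = 40) + 0.05)$p_value,
            0.001)
})

test_that("the randomization test reproduces exhaustive enumeration on a tiny case", {
  values <- c(1.2, 3.4, 2.1, 9.8, 8.7)
  groups <- c("a", "a", "a", "b", "b")
  obs <- mean(values[4:5]) - mean(values[1:3])
  combos <- combn(5, 2)
  perm <- apply(combos, 2, function(i) mean(values[i]) - mean(values[-i]))
  p_exact <- mean(abs(perm) >= abs(obs))
  res <- permutation_mean_diff(values, groups, n_perm = 5000, seed = 123)
  expect_equal(res$statistic, obs)
  se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-4)
  # p respects the permutation lower bound
  expect_gte(res$p_value, 1 / 5001)
})

test_that("the randomization test behaves under the designs it is meant for", {
  set.seed(55)
  # strongly unbalanced groups, shared distribution: p should be well-defined
  vals <- rnorm(203)
  grp <- rep(c("historical", "contemporary"), c(8, 195))
  res <- permutation_mean_diff(vals, grp, n_perm = 2000, seed = 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # identical group means at scale: p near 1
  v2 <- rep(c(1, 2), 50)
  g2 <- rep(c("x", "y"), each = 50)
  res2 <- permutation_mean_diff(v2, g2, n_perm = 2000, seed = 2)
  expect_gt(res2$p_value, 0.5)
  expect_error(permutation_mean_diff(vals, rep("one", 203)), "two groups")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(202)
  pvals <- replicate(500, {
    v <- rnorm(24)
    g <- rep(c("a", "b"), each = 12)
    permutation_mean_diff(v, g, n_perm = 99)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Weir-Cockerham theta matches a step-by-step hand computation", {
  # two populations, two loci, no missing data
  codes <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 2), c(2, 1), c(2, 2), c(2, 1), c(1, 2))
  pops <- rep(c("p1", "p2"), each = 4)
  fit <- weir_cockerham_fst(gm(codes), pops, n_boot = 50, seed = 1)
  # independent scalar evaluation of the 1984 variance components
  hand_components <- function(n1, n2, p1, p2, h1, h2) {
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }
  l1 <- hand_components(4, 4, mean(codes[1:4, 1]) / 2, mean(codes[5:8, 1]) / 2,
                        mean(codes[1:4, 1] == 1), mean(codes[5:8, 1] == 1))
  l2 <- hand_components(4, 4, mean(codes[1:4, 2]) / 2, mean(codes[5:8, 2]) / 2,
                        mean(codes[1:4, 2] == 1), mean(codes[5:8, 2] == 1))
  theta_hand <- (l1[1] + l2[1]) / sum(l1 + l2)
  expect_equal(fit$theta, theta_hand, tolerance = 1e-10)
})

test_that("theta is near zero for identical populations and near one under fixation", {
  set.seed(71)
  freqs <- runif(400, 0.2, 0.8)
  g <- hwe_genotypes(400, freqs)
  pops <- rep(c("a", "b"), each = 200)
  fit <- weir_cockerham_fst(g, pops, n_boot = 200, seed = 2)
  per_locus_theta <- fit$per_locus$a / (fit$per_locus$a + fit$per_locus$b + fit$per_locus$c)
  se <- sd(per_locus_theta, na.rm = TRUE) / sqrt(nrow(fit$per_locus))
  expect_lt(abs(fit$theta), 3 * se)
  expect_true(fit$ci_low <= fit$theta && fit$theta <= fit$ci_high)
  fixed <- gm(rbind(matrix(0L, 10, 20), matrix(2L, 10, 20)))
  fit2 <- weir_cockerham_fst(fixed, pops = rep(c("a", "b"), each = 10),
                             n_boot = 50, seed = 3)
  expect_gt(fit2$theta, 0.95)
  expect_error(weir_cockerham_fst(g, rep("one", 400)), "two populations")
})
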