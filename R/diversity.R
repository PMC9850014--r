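#' Per-locus observed heterozygosity, gene diversity and Fis
#'
#' Per locus, with n the non-missing sample size: Ho is the heterozygote
#' fraction; Hs is Nei's unbiased gene diversity,
#' Hs = n/(n-1) * (1 - sum(p^2) - Ho/(2n)); Fis = 1 - Ho/Hs (NA when Hs = 0).
#' Loci with fewer than two non-missing genotypes are skipped.
#'
#' @param g a \code{\link{geno_matrix}}
#' @return list with \code{per_locus} (data.frame: snp_id, n, p, Ho, Hs, Fis)
#'   and \code{means} (unweighted means of Ho, Hs and Fis over loci)
#' @export
ho_hs_fis <- function(g) {
  stopifnot(is_geno_matrix(g))
  n <- colSums(!is.na(g$codes))
  keep <- n >= 2
  if (!any(keep)) stop("no locus with >= 2 non-missing genotypes")
  x <- g$codes[, keep, drop = FALSE]
  n <- n[keep]
  p <- colMeans(x, na.rm = TRUE) / 2
  ho <- colMeans(x == 1L, na.rm = TRUE)
  hs <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
  fis <- ifelse(hs > 0, 1 - ho / hs, NA_real_)
  per_locus <- data.frame(snp_id = colnames(x), n = n, p = p,
                          Ho = ho, Hs = hs, Fis = fis,
                          row.names = NULL, stringsAsFactors = FALSE)
  list(per_locus = per_locus,
       means = c(Ho = mean(ho), Hs = mean(hs), Fis = mean(fis, na.rm = TRUE)))
}

#' Multilocus heterozygosity per individual
#'
#' Number of heterozygous SNPs divided by the number of SNPs genotyped in that
#' individual. Individuals with zero typed loci are returned as NA.
#'
#' @param g a \code{\link{geno_matrix}}
#' @return named numeric vector in [0, 1]
#' @export
mlh <- function(g) {
  stopifnot(is_geno_matrix(g))
  typed <- rowSums(!is.na(g$codes))
  out <- rowSums(g$codes == 1L, na.rm = TRUE) / typed
  out[typed == 0] <- NA_real_
  out
}

#' Internal relatedness per individual
#'
#' IR = (2H - sum f_i) / (2N - sum f_i), where H is the number of homozygous
#' loci, N the number of typed loci, and sum f_i the summed sample frequencies
#' of the alleles carried at the individual's homozygous loci, both copies
#' counted (2 * f(allele) per homozygous locus). Positive values indicate
#' inbreeding, negative values outbreeding. Allele frequencies come from the
#' full sample.
#'
#' @param g a \code{\link{geno_matrix}}
#' @return named numeric vector
#' @export
ir <- function(g) {
  stopifnot(is_geno_matrix(g))
  p_alt <- geno_allele_freq(g)
  x <- g$codes
  typed <- rowSums(!is.na(x))
  hom_ref <- x == 0L
  hom_alt <- x == 2L
  H <- rowSums(hom_ref, na.rm = TRUE) + rowSums(hom_alt, na.rm = TRUE)
  sum_f <- 2 * (rowSums(sweep(hom_ref, 2, 1 - p_alt, `*`), na.rm = TRUE) +
                  rowSums(sweep(hom_alt, 2, p_alt, `*`), na.rm = TRUE))
  out <- (2 * H - sum_f) / (2 * typed - sum_f)
  out[typed == 0] <- NA_real_
  out
}

#' Paired Wilcoxon signed-rank test over loci
#'
#' Two-sided signed-rank test of per-locus metric differences between two
#' groups (e.g. historical vs contemporary Ho at the same loci). Zero
#' differences are dropped, as in the classical test.
#'
#' @param a,b numeric vectors of the same per-locus metric over an identical
#'   locus set
#' @return list(statistic, p_value, n_pairs, method)
#' @export
paired_wilcoxon_by_locus <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must cover the same locus set")
  d <- b - a
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) stop("degenerate test: all per-locus differences are zero")
  use_exact <- length(nz) < 50 && !anyDuplicated(abs(nz))
  wt <- wilcox.test(nz, exact = use_exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = length(nz), method = "Wilcoxon signed-rank (paired by locus)")
}

#' Permutation test for a difference in group means
#'
#' Two-sided randomization test: group labels are shuffled \code{n_perm}
#' times; p = (1 + #\{permuted |diff| >= observed |diff|\}) / (n_perm + 1).
#' Designed for strongly unbalanced group sizes where parametric tests are
#' unreliable.
#'
#' @param values numeric per-individual metric
#' @param groups two-level factor/character vector aligned with \code{values}
#' @param n_perm number of permutations
#' @param seed optional integer seed
#' @return list(statistic = observed mean difference (group2 - group1),
#'   p_value, n_permutations, method)
#' @export
permutation_mean_diff <- function(values, groups, n_perm = 5000, seed = NULL) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  n1 <- sum(groups == lev[1])
  if (n1 < 2 || sum(groups == lev[2]) < 2) stop("each group needs >= 2 members")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(values[groups == lev[2]]) - mean(values[groups == lev[1]])
  n <- length(values)
  total <- sum(values)
  perm <- replicate(n_perm, {
    s1 <- sum(values[sample.int(n, n1)])
    (total - s1) / (n - n1) - s1 / n1
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_permutations = n_perm,
       method = sprintf("permutation test of mean(%s) - mean(%s)", lev[2], lev[1]))
}

#' Multi-locus Weir-Cockerham Fst with bootstrap CI
#'
#' Weir & Cockerham's theta for biallelic SNPs: per-locus variance components
#' a (among populations), b (among individuals within populations) and c
#' (within individuals), combined across loci as sum(a) / sum(a + b + c).
#' The 95\% confidence interval is a percentile bootstrap over loci.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param pops factor/character of population labels per individual
#' @param n_boot bootstrap resamples over loci
#' @param seed optional integer seed
#' @return list(theta, ci_low, ci_high, per_locus data.frame, n_boot)
#' @export
weir_cockerham_fst <- function(g, pops, n_boot = 1000, seed = NULL) {
  stopifnot(is_geno_matrix(g))
  pops <- as.character(pops)
  if (length(pops) != nrow(g$codes)) stop("pops must align with individuals")
  lev <- sort(unique(pops))
  r <- length(lev)
  if (r < 2) stop("need at least two populations")
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(g$codes)
  a <- b <- cc <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    x <- g$codes[, l]
    ok <- !is.na(x)
    ni <- tapply(ok, pops, sum)[lev]
    if (any(ni < 1) || sum(ni) < 2) next
    pi <- vapply(lev, function(k) mean(x[ok & pops == k]) / 2, 0)
    hi <- vapply(lev, function(k) mean(x[ok & pops == k] == 1L), 0)
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a[l] <- nbar / nc * (s2 - 1 / (nbar - 1) *
                           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b[l] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[l] <- hbar / 2
  }
  use <- which(!is.na(a))
  if (!length(use)) stop("no usable locus for Fst")
  theta <- sum(a[use]) / sum(a[use] + b[use] + cc[use])
  boot <- replicate(n_boot, {
    i <- sample(use, length(use), replace = TRUE)
    sum(a[i]) / sum(a[i] + b[i] + cc[i])
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  list(theta = theta, ci_low = ci[1], ci_high = ci[2],
       per_locus = data.frame(snp_id = colnames(g$codes)[use],
                              a = a[use], b = b[use], c = cc[use],
                              row.names = NULL, stringsAsFactors = FALSE),
       n_boot = n_boot)
}

#' Diversity summary by group
#'
#' Convenience wrapper: per-group Ho/Hs/Fis means and per-individual MLH/IR.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param groups group label per individual (e.g. era)
#' @return list(population = data.frame per group, individual = data.frame)
#' @export
diversity_table <- function(g, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  pop <- do.call(rbind, lapply(lev, function(k) {
    hh <- ho_hs_fis(g[groups == k, ])
    data.frame(group = k, n = sum(groups == k), t(hh$means))
  }))
  ind <- data.frame(sample_id = rownames(g$codes), group = groups,
                    MLH = mlh(g), IR = ir(g),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(population = pop, individual = ind)
}
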