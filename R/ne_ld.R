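#' Burrows composite linkage disequilibrium across locus pairs
#'
#' For every pair of loci passing the allele-frequency screen (minor allele
#' frequency >= \code{pcrit}; \code{pcrit = 0} keeps all polymorphic loci),
#' estimates the composite Burrows disequilibrium from unphased diploid
#' genotypes over the individuals non-missing at both loci:
#' Delta = cov(X, Y) / 2 with X, Y the 0/1/2 allele counts (sample covariance,
#' S/(S-1) corrected), and r^2 = Delta^2 / (pA (1-pA) pB (1-pB)), clipped to
#' [0, 1].
#'
#' @param g a \code{\link{geno_matrix}}
#' @param pcrit minor-allele-frequency exclusion threshold
#' @param return_pairs also return the per-pair table (quadratic in loci)
#' @return list(mean_r2, n_comparisons, harmonic_mean_S, n_loci,
#'   r2_by_locus = mean r^2 of pairs involving each locus, pairs = optional
#'   data.frame)
#' @export
burrows_r2 <- function(g, pcrit = 0, return_pairs = FALSE) {
  stopifnot(is_geno_matrix(g))
  maf <- geno_maf(g)
  keep <- which(!is.na(maf) & maf > 0 & maf >= pcrit)
  if (length(keep) < 2) stop("fewer than 2 loci pass the Pcrit screen")
  x <- g$codes[, keep, drop = FALSE]
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0L
  storage.mode(x0) <- "double"
  obs_n <- matrix(as.double(obs), nrow(obs))
  n_ij <- crossprod(obs_n)
  sxy <- crossprod(x0)
  sx <- crossprod(x0, obs_n)         # sum of X over individuals shared with Y
  sxx <- crossprod(x0 * x0, obs_n)   # sum of X^2 over shared individuals
  mx <- sx / n_ij
  covm <- (sxy / n_ij - mx * t(mx)) * n_ij / pmax(n_ij - 1, 1)
  p <- mx / 2
  het <- p * (1 - p)
  den <- het * t(het)
  r2 <- (covm / 2)^2 / den
  r2[!is.finite(r2)] <- NA
  r2 <- pmin(pmax(r2, 0), 1)
  ut <- upper.tri(r2)
  valid <- ut & !is.na(r2) & n_ij >= 2
  mean_r2 <- mean(r2[valid])
  hm_s <- 1 / mean(1 / n_ij[valid])
  r2v <- r2
  r2v[!valid & !t(valid)] <- NA
  out <- list(mean_r2 = mean_r2, n_comparisons = sum(valid),
              harmonic_mean_S = hm_s, n_loci = length(keep),
              r2_by_locus = rowMeans(r2v, na.rm = TRUE),
              locus_ids = colnames(g$codes)[keep])
  if (return_pairs) {
    idx <- which(valid, arr.ind = TRUE)
    out$pairs <- data.frame(
      locus_a = colnames(g$codes)[keep][idx[, 1]],
      locus_b = colnames(g$codes)[keep][idx[, 2]],
      S = n_ij[valid], delta = (covm / 2)[valid], r2 = r2[valid],
      stringsAsFactors = FALSE)
  }
  out
}

#' Effective population size from mean composite r-squared
#'
#' Waples (2006) bias-corrected LD method under random mating: the expected
#' sample-size contribution E[r^2 | S] is subtracted from the observed mean
#' r^2 and the published quadratic drift relation is inverted to Ne. For
#' harmonic mean sample size S >= 30: E[r^2] = 1/S + 3.19/S^2 and
#' Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2'); for S < 30:
#' E[r^2] = 0.0018 + 0.907/S + 4.44/S^2 and
#' Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2'). A non-positive drift
#' residual r2' yields Ne = Inf (no drift signal resolvable).
#'
#' @param mean_r2 mean composite r^2 over locus pairs
#' @param harmonic_mean_S harmonic mean per-pair sample size (>= 10)
#' @param mating currently only "random"
#' @return list(ne_point, r2_drift, expected_r2_sample)
#' @export
ne_from_r2 <- function(mean_r2, harmonic_mean_S, mating = "random") {
  if (mating != "random") stop("only random mating is implemented")
  S <- harmonic_mean_S
  if (S < 10)
    stop("harmonic mean sample size below 10: LD-Ne is unreliable; ",
         "pool samples or use more individuals")
  if (S >= 30) {
    er2 <- 1 / S + 3.19 / S^2
    r2d <- mean_r2 - er2
    ne <- if (r2d <= 0) Inf else
      (1 / 3 + sqrt(max(0, 1 / 9 - 2.76 * r2d))) / (2 * r2d)
  } else {
    er2 <- 0.0018 + 0.907 / S + 4.44 / S^2
    r2d <- mean_r2 - er2
    ne <- if (r2d <= 0) Inf else
      (0.308 + sqrt(max(0, 0.308^2 - 2.08 * r2d))) / (2 * r2d)
  }
  list(ne_point = ne, r2_drift = r2d, expected_r2_sample = er2)
}

#' LD effective population size across a Pcrit sweep
#'
#' One estimate per allele-exclusion threshold: loci with minor allele
#' frequency below Pcrit are excluded (for biallelic SNPs allele exclusion
#' degenerates to locus exclusion), Burrows composite r^2 is averaged over
#' locus pairs, bias-corrected, and inverted to Ne. The 95\% CI is a
#' delete-one-locus jackknife on mean r^2 mapped through the Ne relation.
#' Stability of Ne across Pcrit values is summarized as the maximum relative
#' spread, a diagnostic separating stable isolated populations (small spread)
#' from populations with an excess of rare alleles (migration, expansion).
#'
#' @param g a \code{\link{geno_matrix}}
#' @param pcrit_list vector of Pcrit thresholds
#' @return data.frame with one row per Pcrit: pcrit, n_loci, n_comparisons,
#'   mean_r2, harmonic_mean_S, ne_point, ci_low, ci_high, ci_method; attribute
#'   \code{max_relative_spread} over finite point estimates. A Pcrit level
#'   leaving fewer than two usable loci yields an all-NA row with a warning
#'   rather than aborting the sweep.
#' @export
ne_ld_estimate <- function(g, pcrit_list = c(0, 0.1, 0.2, 0.5)) {
  na_row <- function(pc) data.frame(
    pcrit = pc, n_loci = NA_integer_, n_comparisons = NA_integer_,
    mean_r2 = NA_real_, harmonic_mean_S = NA_real_, ne_point = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, ci_method = NA_character_,
    stringsAsFactors = FALSE)
  rows <- lapply(pcrit_list, function(pc) {
    b <- tryCatch(burrows_r2(g, pc), error = function(e) NULL)
    if (is.null(b) || !is.finite(b$mean_r2)) {
      warning("Pcrit = ", pc, ": fewer than 2 usable loci; returning NA row")
      return(na_row(pc))
    }
    fit <- ne_from_r2(b$mean_r2, b$harmonic_mean_S)
    # jackknife over loci: drop all pairs involving locus l
    L <- b$n_loci
    x <- g$codes[, b$locus_ids, drop = FALSE]
    r2l <- b$r2_by_locus
    pairs_per_locus <- L - 1
    tot <- b$mean_r2 * b$n_comparisons
    loo <- (tot - r2l * pairs_per_locus) / (b$n_comparisons - pairs_per_locus)
    loo <- loo[is.finite(loo)]
    if (length(loo) >= 3) {
      se <- sqrt((length(loo) - 1) / length(loo) * sum((loo - mean(loo))^2))
      lo_r2 <- b$mean_r2 - 1.96 * se
      hi_r2 <- b$mean_r2 + 1.96 * se
      ci_hi <- ne_from_r2(lo_r2, b$harmonic_mean_S)$ne_point
      ci_lo <- ne_from_r2(hi_r2, b$harmonic_mean_S)$ne_point
    } else {
      ci_lo <- ci_hi <- NA_real_  # too few loci for a delete-one jackknife
    }
    data.frame(pcrit = pc, n_loci = b$n_loci, n_comparisons = b$n_comparisons,
               mean_r2 = b$mean_r2, harmonic_mean_S = b$harmonic_mean_S,
               ne_point = fit$ne_point, ci_low = ci_lo, ci_high = ci_hi,
               ci_method = "jackknife over loci", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  finite <- out$ne_point[is.finite(out$ne_point)]
  attr(out, "max_relative_spread") <-
    if (length(finite) >= 2) diff(range(finite)) / min(finite) else NA_real_
  out
}
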