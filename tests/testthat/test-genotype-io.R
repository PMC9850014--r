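toy_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    lines), p)
  p
}

test_that("VCF genotypes parse to 0/1/2 codes with a missing mask", {
  p <- toy_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "loc1\t5\tsnp1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "loc1\t9\tsnp2\tC\tG\t.\tPASS\t.\tGT\t./.\t0/1\t0/0"))
  g <- read_vcf(p)
  expect_equal(unname(g$codes[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(g$codes[1, 2]))
  expect_equal(g$locus_tag, c("loc1", "loc1"))
  expect_equal(g$position, c(5L, 9L))
})

test_that("multi-allelic records are excluded with a warning", {
  p <- toy_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "loc1\t5\tsnp1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "loc2\t2\tsnp2\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t1/2"))
  expect_warning(g <- read_vcf(p), "multi-allelic")
  expect_equal(ncol(g$codes), 1L)
})

test_that("the iterative missingness filter matches a brute-force replay", {
  set.seed(10)
  codes <- matrix(rbinom(60 * 40, 2, 0.3), 60, 40)
  # planted gradient: some terrible loci and individuals
  miss <- matrix(runif(60 * 40) < outer(seq(0, 0.5, length.out = 60),
                                        seq(0, 0.6, length.out = 40)), 60, 40)
  codes[miss] <- NA
  g <- gm(codes)
  out <- iterative_missingness_filter(g)
  # brute force: replay the documented schedule with naive loops
  schedule <- sort(unique(c(0.9, 0.7, 0.5, 0.3, 0.3)), decreasing = TRUE)
  m <- codes
  for (s in c(schedule, 0.3)) {
    repeat {
      done <- TRUE
      ml <- colMeans(is.na(m))
      if (any(ml > s)) { m <- m[, ml <= s, drop = FALSE]; done <- FALSE }
      mi <- rowMeans(is.na(m))
      if (any(mi > s)) { m <- m[mi <= s, , drop = FALSE]; done <- FALSE }
      if (s > 0.3 || done) break
    }
  }
  expect_equal(dim(out$codes), dim(m))
  # final thresholds hold simultaneously and rerunning changes nothing
  expect_true(all(colMeans(is.na(out$codes)) <= 0.3))
  expect_true(all(rowMeans(is.na(out$codes)) <= 0.3))
  again <- iterative_missingness_filter(out)
  expect_identical(again$codes, out$codes)
  # a fully missing individual goes first
  codes2 <- matrix(rbinom(20, 2, 0.5), 4, 5)
  codes2[2, ] <- NA
  f2 <- iterative_missingness_filter(gm(codes2))
  expect_equal(nrow(f2$codes), 3L)
  # purity: input untouched
  expect_identical(g$codes, codes_before <- {
    gg <- gm(codes); gg$codes
  })
})

test_that("MAC filtering drops rare and monomorphic loci exactly", {
  codes <- cbind(c(0, 0, 1), c(0, 1, 1), c(0, 0, 0), c(2, 2, 2), c(1, 1, 0))
  g <- gm(codes)
  out <- mac_filter(g, min_mac = 2)
  # MAC per locus: 1, 2, 0(mono), 0(mono), 2
  expect_equal(ncol(out$codes), 2L)
  set.seed(4)
  rnd <- matrix(rbinom(50 * 30, 2, runif(30, 0.02, 0.5)), 50, 30, byrow = TRUE)
  rnd[sample(length(rnd), 100)] <- NA
  g2 <- gm(rnd)
  out2 <- mac_filter(g2, 2)
  brute <- sum(vapply(seq_len(30), function(j) {
    x <- rnd[, j][!is.na(rnd[, j])]
    alt <- sum(x); tot <- 2 * length(x)
    min(alt, tot - alt) >= 2
  }, TRUE))
  expect_equal(ncol(out2$codes), brute)
})

test_that("HDplot H and D follow the allele-balance z-score arithmetic", {
  # 4 heterozygotes with balanced depths (10, 10): A = B = 40, D = 0
  codes <- matrix(1, 4, 1)
  g <- gm(codes, ref_depth = matrix(10L, 4, 1), alt_depth = matrix(10L, 4, 1))
  qc <- hdplot(g)
  expect_equal(qc$D, 0)
  expect_equal(qc$H, 1)
  # A = 49, B = 15 -> D = 34 / sqrt(64) = 4.25; retained at |D| <= 7
  codes2 <- rbind(1, 1, 0)
  g2 <- gm(codes2, ref_depth = rbind(25L, 24L, 12L), alt_depth = rbind(8L, 7L, 0L))
  qc2 <- hdplot(g2)
  expect_equal(qc2$D, (49 - 15) / sqrt(64))
  # h_max raised so the D criterion is what decides here (H = 2/3)
  expect_equal(ncol(filter_hdplot(g2, h_max = 0.8, d_max = 7)$codes), 1L)
  expect_equal(ncol(filter_hdplot(g2, h_max = 0.8, d_max = 4)$codes), 0L)
  # depths are mandatory
  expect_error(hdplot(gm(codes)), "depth")
})

test_that("HDplot separates injected paralogs from true SNPs", {
  dem <- demography(0, 800)
  sch <- sampling_scheme(0, 60)
  ds <- simulate_snp_dataset(dem, sch, 300, seed = 14)
  ds <- add_read_depths(ds, depth_mean = 100, paralog_fraction = 0.2, seed = 15)
  is_par <- attr(ds$genotypes, "paralog")
  kept <- filter_hdplot(ds$genotypes)
  kept_ids <- colnames(kept$codes)
  all_ids <- colnames(ds$genotypes$codes)
  removed <- !(all_ids %in% kept_ids)
  expect_gte(mean(removed[is_par]), 0.9)   # >= 90% of paralogs caught
  expect_lte(mean(removed[!is_par]), 0.1)  # <= 10% of true SNPs lost
})

test_that("one SNP per locus keeps the highest-MAF site, ties to lowest position", {
  codes <- cbind(c(0, 0, 1, 0), c(0, 1, 1, 1), c(0, 1, 0, 1), c(1, 0, 1, 0))
  g <- gm(codes, locus_tag = c("A", "A", "B", "B"), position = c(1L, 7L, 2L, 9L))
  # locus A: MAF 0.125 vs 0.375 -> site 2; locus B: tie 0.25/0.25 -> position 2
  out <- select_one_snp_per_locus(g)
  expect_equal(out$position, c(7L, 2L))
  expect_equal(out$locus_tag, c("A", "B"))
  single <- gm(cbind(c(0, 1)), locus_tag = "Z")
  expect_equal(dim(select_one_snp_per_locus(single)), c(2L, 1L))
})

test_that("relatedness recovers clones, parent-offspring pairs and unrelateds", {
  set.seed(30)
  freqs <- runif(1000, 0.1, 0.9)
  base <- hwe_genotypes(40, freqs)
  dup <- gm(rbind(base$codes, base$codes[1, , drop = FALSE]))
  r <- pairwise_relatedness(dup)
  expect_gt(r[41, 1], 0.9)  # clone pair
  # gamete-constructed parent-offspring pairs
  n_pairs <- 100
  parents <- vapply(freqs, function(p) rbinom(n_pairs, 2, p), numeric(n_pairs))
  gamete <- function(g_row) ifelse(g_row == 1, rbinom(length(g_row), 1, 0.5),
                                   g_row / 2)
  other <- vapply(freqs, function(p) rbinom(n_pairs, 1, p), numeric(n_pairs))
  offspring <- t(apply(parents, 1, gamete)) + other
  codes <- rbind(parents, offspring)
  rpo <- pairwise_relatedness(gm(codes))
  po <- vapply(seq_len(n_pairs), function(i) rpo[i, n_pairs + i], 0)
  expect_lt(abs(mean(po) - 0.5), 0.05)
  unrel <- rpo[1:50, 51:100]
  expect_lt(abs(mean(unrel[upper.tri(unrel)])), 0.05)
  expect_error(pairwise_relatedness(gm(cbind(c(0, 1))[, 0, drop = FALSE])), "empty|locus")
})

test_that("the filter cascade is pure and reproduces brute-force counts", {
  dem <- demography(0, 500)
  sch <- sampling_scheme(0, 50)
  ds <- simulate_snp_dataset(dem, sch, 150, seed = 44)
  ds$genotypes$codes[sample(length(ds$genotypes$codes), 400)] <- NA
  ds <- add_read_depths(ds, 80, paralog_fraction = 0.1, seed = 45)
  snapshot <- ds$genotypes$codes
  out <- filter_cascade(ds$genotypes)
  expect_identical(ds$genotypes$codes, snapshot)  # purity
  log <- attr(out, "cascade_log")
  expect_true(all(c("missingness", "mac", "hdplot", "one_snp_per_locus") %in%
                    names(log)))
  # independent replay of the same cascade
  g1 <- iterative_missingness_filter(ds$genotypes)
  g2 <- mac_filter(g1)
  g3 <- filter_hdplot(g2)
  g4 <- select_one_snp_per_locus(g3)
  expect_identical(out$codes, g4$codes)
})
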