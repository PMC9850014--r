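# one moderately structured river fixture shared across the file
ibd_ds <- simulate_river_population(20, 25, 0.25, 150, 120, 5,
                                    deme_spacing_km = 20, seed = 77)
ibd_g <- mac_filter(ibd_ds$genotypes)
ibd_d <- river_distances(ibd_ds)

test_that("distance matrices load, validate and round-trip", {
  md <- data.frame(sample_id = c("a", "b", "c"), era = "contemporary")
  dir <- withr::local_tempdir()
  m <- matrix(c(0, 10, 20, 10, 0, 10, 20, 10, 0), 3,
              dimnames = list(md$sample_id, md$sample_id))
  p <- file.path(dir, "d.tsv")
  write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE), p,
              sep = "\t", quote = FALSE, row.names = FALSE)
  d <- load_distances(p, ids = md$sample_id)
  expect_equal(unname(d["a", c("b", "c")]), c(10, 20))
  expect_error(load_distances(p, ids = c("a", "zz")), "zz")
  asym <- m; asym[1, 2] <- 99
  p2 <- file.path(dir, "bad.tsv")
  write.table(data.frame(sample_id = rownames(asym), asym, check.names = FALSE),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_distances(p2), "asymmetric")
  expect_warning(
    d2 <- load_distances(metadata = data.frame(sample_id = c("x", "y"),
                                               lon = c(0, 1), lat = c(0, 0))),
    "haversine")
  expect_gt(d2["x", "y"], 100)  # ~111 km per degree at the equator
})

test_that("nMDS embeds Euclidean-compatible and river-line distances faithfully", {
  set.seed(80)
  pts <- matrix(rnorm(30), 15, 2)
  d <- as.matrix(dist(pts))
  fit <- nmds_project(d, seed = 81)
  expect_lt(fit$stress, 0.05)
  km <- seq(0, 380, 20)
  dr <- abs(outer(km, km, `-`))
  fit2 <- nmds_project(dr, seed = 82)
  emb <- as.matrix(dist(fit2$coords))
  expect_gt(cor(emb[upper.tri(emb)], dr[upper.tri(dr)], method = "spearman"),
            0.95)
  expect_error(nmds_project(dr[1:3, 1:3], dims = 3), "dims")
})

test_that("sPCA finds the river cline and rejects degenerate graphs", {
  proj <- nmds_project(ibd_d, seed = 1)
  sp <- spca(ibd_g, proj$coords, n_perm = 199, seed = 2)
  expect_lte(sp$global_test$p_value, 0.05)
  expect_gt(abs(cor(sp$scores[, 1], ibd_ds$metadata$river_km,
                    method = "spearman")), 0.5)
  expect_gte(sp$global_test$p_value, 1 / 200)
  # spatially shuffled genotypes: no significant global structure (this seed)
  set.seed(3)
  perm <- sample(nrow(ibd_g$codes))
  gs <- ibd_g[perm, ]
  rownames(gs$codes) <- rownames(ibd_g$codes)
  sp0 <- spca(gs, proj$coords, n_perm = 199, seed = 4)
  expect_gt(sp0$global_test$p_value, 0.05)
  # all samples at one point: degenerate connection network
  same <- matrix(0, 6, 2)
  expect_error(spca(ibd_g[1:6, ], same), "degenerate")
})

test_that("MEM forward selection finds broad-scale river structure, and nothing in noise", {
  mem <- mem_forward_selection(ibd_g, ibd_d, n_perm = 199, seed = 5)
  expect_gt(mem$r2adj, 0)
  # a broad-scale eigenvector (first quarter of the basis) is selected
  idx <- as.integer(gsub("PCNM", "", mem$selected))
  expect_lte(min(idx), ceiling(ncol(mem$mem) / 4))
  set.seed(6)
  perm <- sample(nrow(ibd_g$codes))
  gs <- ibd_g[perm, ]
  rownames(gs$codes) <- rownames(ibd_g$codes)
  mem0 <- mem_forward_selection(gs, ibd_d, n_perm = 199, seed = 7)
  expect_lt(mem0$r2adj, 0.02)
})

test_that("the Mantel correlogram agrees with vegan and sizes the neighbourhood", {
  gd <- shared_allele_distance(ibd_g)
  cg <- mantel_correlogram(gd, ibd_d, 20, 380, 20, n_perm = 499, seed = 8)
  expect_equal(nrow(cg$classes), 19L)
  ref <- vegan::mantel.correlog(as.dist(gd), as.dist(ibd_d),
                                break.pts = seq(0, 380, 20), nperm = 0)
  n_ref <- sum(!is.na(ref$mantel.res[, 3]))
  expect_equal(cg$classes$mantel_r[seq_len(n_ref)],
               unname(ref$mantel.res[seq_len(n_ref), 3]), tolerance = 1e-10)
  expect_true(all(abs(cg$classes$mantel_r) <= 1, na.rm = TRUE))
  expect_true(all(cg$classes$p_value >= 1 / 500, na.rm = TRUE))
  expect_false(is.na(cg$neighbourhood_size_km))
  # the default 10-300 km grid gives exactly 30 classes
  cg30 <- mantel_correlogram(gd, ibd_d, 10, 300, 10, n_perm = 19, seed = 9)
  expect_equal(nrow(cg30$classes), 30L)
})

test_that("shuffled coordinates yield no initial significant run", {
  gd <- shared_allele_distance(ibd_g)
  set.seed(11)
  perm <- sample(nrow(ibd_d))
  d0 <- ibd_d[perm, perm]
  cg <- mantel_correlogram(gd, d0, 20, 380, 20, n_perm = 199, seed = 12)
  expect_true(is.na(cg$neighbourhood_size_km))
})

test_that("neighbourhood diversity at infinite radius equals global diversity exactly", {
  sub <- ibd_g[1:40, 1:60]
  d <- ibd_d[1:40, 1:40]
  nb <- neighborhood_diversity(sub, d, radius_km = max(d) + 1, min_n = 20)
  hh <- ho_hs_fis(sub)
  expect_true(all(nb$computed))
  expect_equal(nb$Ho, rep(unname(hh$means["Ho"]), 40))
  expect_equal(nb$He, rep(unname(hh$means["Hs"]), 40))
  expect_equal(nb$Fis, rep(unname(hh$means["Fis"]), 40))
})

test_that("isolated samples are reported as not computed, with rarefied Ar in bounds", {
  # 25 clustered samples plus one far-away individual (a Lake-Ontario-like case)
  g <- ibd_g[1:26, 1:60]
  d <- matrix(0, 26, 26)
  d[1:25, 1:25] <- ibd_d[1:25, 1:25]
  d[26, 1:25] <- d[1:25, 26] <- 1000
  nb <- neighborhood_diversity(g, d, radius_km = 220, min_n = 20)
  expect_false(nb$computed[26])
  expect_match(nb$reason[26], "insufficient")
  expect_true(all(nb$Ar[nb$computed] >= 1 & nb$Ar[nb$computed] <= 2))
  # a fixed locus rarefies to exactly one allele
  fixed <- gm(cbind(rep(0L, 30), c(rep(0L, 15), rep(1L, 15))))
  ar <- allelic_richness(fixed, 20)
  expect_equal(ar[1], 1)
  expect_gt(ar[2], 1)
})

test_that("decay regressions keep real directional interactions and recover slopes", {
  md <- data.frame(sample_id = sprintf("s%03d", 1:120),
                   dist_origin_km = rep(seq(0, 590, length.out = 60), 2),
                   direction = rep(c("north", "south"), each = 60))
  # noiseless constructed response: -0.007 per 100 km everywhere
  y0 <- 0.5 - 0.007 * md$dist_origin_km / 100
  fit0 <- decay_regression(y0 + rnorm(120, sd = 1e-6), md)
  expect_equal(unname(fit0$slopes_per_100km[1]), -0.007, tolerance = 1e-3)
  # opposite slopes north/south at 2 x residual SD: interaction retained
  set.seed(90)
  hits <- 0
  for (i in 1:20) {
    slope <- 0.02 * (md$direction == "north") - 0.02 * (md$direction == "south")
    y <- 0.4 + slope * md$dist_origin_km / 100 + rnorm(120, sd = 0.02)
    fit <- decay_regression(y, md)
    hits <- hits + ("dist:direction" %in% fit$terms)
  }
  expect_gte(hits, 18)
  # single direction level: direction terms dropped with a warning
  md1 <- md[md$direction == "north", ]
  expect_warning(f1 <- decay_regression(y0[md$direction == "north"] +
                                          rnorm(60, sd = 0.001), md1),
                 "single direction")
  expect_equal(f1$terms, "dist")
})

test_that("pure-noise metrics collapse to an intercept-only model (fixed seed)", {
  set.seed(91)
  md <- data.frame(sample_id = sprintf("s%03d", 1:100),
                   dist_origin_km = runif(100, 0, 500),
                   direction = sample(c("north", "south"), 100, replace = TRUE))
  fit <- decay_regression(rnorm(100), md)
  expect_length(fit$terms, 0)
})
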