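#' Load or build a pairwise distance matrix
#'
#' Reads a square along-river distance matrix (TSV with a \code{sample_id}
#' column naming rows) or, when only lon/lat coordinates are supplied, falls
#' back to great-circle (haversine) distances with a warning — along-river
#' distance is the intended metric and straight-line distance understates it.
#'
#' @param path TSV file with a square matrix (first column sample_id)
#' @param metadata data.frame with sample_id and, for the fallback, lon/lat
#' @param ids sample ids the matrix must cover (defaults to metadata ids)
#' @param tol asymmetry tolerance
#' @return square symmetric matrix (km) keyed by sample id
#' @export
load_distances <- function(path = NULL, metadata = NULL, ids = NULL,
                           tol = 1e-6) {
  if (is.null(ids) && !is.null(metadata)) ids <- metadata$sample_id
  if (!is.null(path)) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    rn <- tab[[1]]
    d <- as.matrix(tab[, -1, drop = FALSE])
    rownames(d) <- rn
    storage.mode(d) <- "double"
  } else if (!is.null(metadata) && all(c("lon", "lat") %in% names(metadata))) {
    warning("no distance matrix supplied; using haversine distances ",
            "(along-river distance is the intended metric)")
    d <- haversine_matrix(metadata$lon, metadata$lat)
    dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  } else stop("supply a distance matrix path or metadata with lon/lat")
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, rownames(d))
    if (length(missing_ids))
      stop("distance matrix lacks ids: ", paste(missing_ids, collapse = ", "))
    d <- d[ids, ids]
  }
  if (max(abs(d - t(d))) > tol) stop("distance matrix is asymmetric beyond tolerance")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (any(d < 0)) stop("distances must be non-negative")
  d
}

haversine_matrix <- function(lon, lat, r_km = 6371) {
  to_rad <- pi / 180
  lon <- lon * to_rad; lat <- lat * to_rad
  n <- length(lon)
  dlat <- outer(lat, lat, `-`); dlon <- outer(lon, lon, `-`)
  a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  2 * r_km * asin(pmin(sqrt(a), 1))
}

#' Project a distance matrix to Cartesian coordinates by nMDS
#'
#' Nonmetric multidimensional scaling with seeded random restarts; the lowest
#' stress configuration is kept.
#'
#' @param d square distance matrix
#' @param dims embedding dimension
#' @param n_restarts random restarts
#' @param seed integer seed
#' @return list(coords, stress)
#' @export
nmds_project <- function(d, dims = 2, n_restarts = 10, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("nMDS needs >= 3 samples")
  if (dims >= n) stop("dims must be smaller than the number of samples")
  if (!is.null(seed)) set.seed(seed)
  dd <- as.dist(d)
  best <- NULL
  init <- cmdscale(dd, k = dims)
  for (i in seq_len(n_restarts)) {
    start <- if (i == 1) init else init + matrix(rnorm(n * dims, sd = sd(init)),
                                                 n, dims)
    fit <- vegan::monoMDS(dd, y = start, k = dims)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rownames(coords) <- rownames(d)
  list(coords = coords, stress = best$stress)
}

# smallest distance threshold that connects all samples; edges are pairs with
# d <= threshold
min_connecting_threshold <- function(d) {
  vals <- sort(unique(d[upper.tri(d)]))
  vals <- vals[vals > 0]
  if (!length(vals)) stop("degenerate graph: all pairwise distances are zero")
  lo <- 1L; hi <- length(vals)
  connected_at <- function(thr) {
    adj <- d <= thr & upper.tri(d)
    gr <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
    igraph::components(gr)$no == 1
  }
  if (!connected_at(vals[hi])) stop("graph cannot be connected")
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (connected_at(vals[mid])) hi <- mid else lo <- mid + 1L
  }
  vals[lo]
}

#' Spatial principal component analysis of genotypes
#'
#' Eigenanalysis of the product of the centred allele-frequency matrix with a
#' row-normalised spatial connection operator (the minimum-distance neighbour
#' graph: every pair closer than the smallest threshold that keeps the graph
#' connected is joined). Positive eigenvalues capture global structure
#' (neighbours alike), negative eigenvalues local structure (neighbours
#' contrasting). Monte Carlo tests permute genotype rows across locations;
#' the global (local) statistic is the largest positive (most negative)
#' eigenvalue.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param coords numeric matrix of Cartesian coordinates (e.g. from
#'   \code{\link{nmds_project}})
#' @param n_perm Monte Carlo permutations
#' @param seed integer seed
#' @return list: eigenvalues, scores (individuals x axes, positive axes
#'   first), n_positive, global_test, local_test (each: statistic, p_value),
#'   threshold_km
#' @export
spca <- function(g, coords, n_perm = 999, seed = NULL) {
  stopifnot(is_geno_matrix(g))
  coords <- as.matrix(coords)
  n <- nrow(g$codes)
  if (nrow(coords) != n) stop("coords must align with individuals")
  if (n < 4) stop("sPCA needs >= 4 individuals")
  if (!is.null(seed)) set.seed(seed)
  dmat <- as.matrix(dist(coords))
  thr <- min_connecting_threshold(dmat)
  W <- (dmat <= thr) & (dmat > 0 | upper.tri(dmat) | lower.tri(dmat))
  diag(W) <- FALSE
  W <- W * 1
  rs <- rowSums(W)
  if (any(rs == 0)) stop("degenerate graph: isolated node(s)")
  L <- W / rs
  M <- (L + t(L)) / 2
  x <- g$codes / 2
  x[is.na(x)] <- NA
  mu <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2, mu)
  xc[is.na(xc)] <- 0
  sv <- svd(xc)
  r <- sum(sv$d > 1e-9)
  U <- sv$u[, seq_len(r), drop = FALSE]
  S <- sv$d[seq_len(r)]
  core <- function(Uo) {
    B <- crossprod(Uo * 1, M %*% Uo)
    B <- (B + t(B)) / 2
    eigen((S * t(S * t(B))) / n, symmetric = TRUE)
  }
  ei <- core(U)
  scores <- U %*% (S * ei$vectors)   # = Xc V a
  rownames(scores) <- rownames(g$codes)
  obs_global <- max(ei$values)
  obs_local <- min(ei$values)
  perm_stats <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    e <- core(U[p, , drop = FALSE])
    c(max(e$values), min(e$values))
  }, numeric(2))
  p_global <- (1 + sum(perm_stats[1, ] >= obs_global)) / (n_perm + 1)
  p_local <- (1 + sum(perm_stats[2, ] <= obs_local)) / (n_perm + 1)
  list(eigenvalues = ei$values, scores = scores,
       n_positive = sum(ei$values > 0),
       global_test = list(statistic = obs_global, p_value = p_global,
                          n_permutations = n_perm),
       local_test = list(statistic = obs_local, p_value = p_local,
                         n_permutations = n_perm),
       threshold_km = thr)
}

#' Pairwise genetic distance: one minus proportion of shared alleles
#'
#' For diploid biallelic codes a, b the per-locus shared-allele proportion is
#' 1 - |a - b| / 2; the distance averages |a - b| / 2 over loci non-missing in
#' both individuals.
#'
#' @param g a \code{\link{geno_matrix}}
#' @return square symmetric matrix in [0, 1]
#' @export
shared_allele_distance <- function(g) {
  stopifnot(is_geno_matrix(g))
  x <- g$codes
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0L
  storage.mode(x0) <- "double"
  obs_n <- matrix(as.double(obs), nrow(obs))
  # |a-b| over codes {0,1,2}: (a-b)^2 equals |a-b| except when |a-b| = 2,
  # where it overshoots by 2; so sum|a-b| = sum(a-b)^2 - 2 * #{|a-b| = 2}
  sq <- tcrossprod(x0 * x0, obs_n)
  sumsq <- sq + t(sq) - 2 * tcrossprod(x0)
  a0 <- (obs & x0 == 0) * 1
  a2 <- (obs & x0 == 2) * 1
  n2 <- tcrossprod(a0, a2)
  n2 <- n2 + t(n2)
  shared <- tcrossprod(obs_n)
  d <- (sumsq - 2 * n2) / (2 * pmax(shared, 1))
  d[shared == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(rownames(g$codes), rownames(g$codes))
  d
}

#' Moran-eigenvector-map analysis with forward selection
#'
#' Builds a Moran eigenvector basis from the truncated pairwise distance
#' matrix (principal coordinates of neighbour matrices), takes the principal
#' coordinates of the shared-allele genetic distance as the multivariate
#' response, and forward-selects eigenvectors by permutation tests with an
#' adjusted-R-squared stopping rule (double-stopping forward selection on an
#' RDA). An empty selection with R2adj = 0 is a valid no-structure outcome.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param d square distance matrix aligned with individuals
#' @param n_perm permutations per selection step
#' @param seed integer seed
#' @return list: selected (names), r2adj, full_r2adj, mem (basis matrix),
#'   model (the final rda fit or NULL)
#' @export
mem_forward_selection <- function(g, d, n_perm = 999, seed = NULL) {
  stopifnot(is_geno_matrix(g))
  d <- as.matrix(d)
  n <- nrow(g$codes)
  if (n < 10) stop("MEM analysis needs >= 10 samples")
  if (!is.null(seed)) set.seed(seed)
  mem <- vegan::pcnm(as.dist(d))
  mems <- as.data.frame(mem$vectors)
  gd <- shared_allele_distance(g)
  pco <- cmdscale(as.dist(gd), k = min(n - 1, 20), eig = TRUE)
  keep_axes <- which(pco$eig[seq_len(ncol(pco$points))] > 1e-9)
  Y <- pco$points[, keep_axes, drop = FALSE]
  rda <- vegan::rda  # local binding so ordiR2step can re-evaluate the call
  full <- rda(Y ~ ., data = mems)
  full_r2 <- max(0, vegan::RsquareAdj(full)$adj.r.squared)
  m0 <- rda(Y ~ 1, data = mems)
  sel <- tryCatch(
    vegan::ordiR2step(m0, scope = stats::formula(full), data = mems,
                      permutations = n_perm, R2scope = TRUE, trace = FALSE,
                      direction = "forward"),
    error = function(e) m0)
  terms_sel <- attr(stats::terms(sel), "term.labels")
  r2 <- if (length(terms_sel)) max(0, vegan::RsquareAdj(sel)$adj.r.squared) else 0
  list(selected = terms_sel, r2adj = r2, full_r2adj = full_r2,
       mem = mem$vectors, model = if (length(terms_sel)) sel else NULL)
}

#' Mantel correlogram with genetic neighbourhood sizing
#'
#' For each distance class (lower, upper], computes the Mantel correlation
#' between the pairwise genetic distance and class membership (sign flipped so
#' that positive values mean individuals within the class are genetically more
#' alike than average), with permutation p-values (individuals permuted) and
#' progressive Holm correction across classes. The genetic neighbourhood size
#' is the upper bound of the last class in the initial unbroken run of
#' significant positive correlations; the first class at which the correlation
#' stops being significant is also reported (the two readings coincide when
#' significance is an unbroken prefix).
#'
#' @param gdist square genetic distance matrix (e.g.
#'   \code{\link{shared_allele_distance}})
#' @param d square geographic distance matrix, km
#' @param class_start,class_end,class_step class grid (upper bounds
#'   \code{seq(class_start, class_end, class_step)})
#' @param n_perm permutations
#' @param seed integer seed
#' @param alpha significance level for the neighbourhood rule
#' @return list: classes (data.frame: class_upper_km, mantel_r, p_value,
#'   p_holm, n_pairs, significant), neighbourhood_size_km (NA when no
#'   significant initial run), first_nonsignificant_km
#' @export
mantel_correlogram <- function(gdist, d, class_start = 10, class_end = 300,
                               class_step = 10, n_perm = 999, seed = NULL,
                               alpha = 0.05) {
  gdist <- as.matrix(gdist); d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(all(dim(gdist) == dim(d)))
  if (!is.null(seed)) set.seed(seed)
  uppers <- seq(class_start, class_end, class_step)
  ut <- upper.tri(d)
  gv <- gdist[ut]
  dv <- d[ut]
  ind <- vapply(uppers, function(u) {
    lo <- u - class_step
    if (u == uppers[1]) (dv <= u) * 1 else (dv > lo & dv <= u) * 1
  }, numeric(length(dv)))  # first class closed at zero (same-site pairs)
  n_pairs <- colSums(ind)
  evaluated <- n_pairs > 0
  r_obs <- rep(NA_real_, length(uppers))
  suppressWarnings(
    r_obs[evaluated] <- -cor(gv, ind[, evaluated, drop = FALSE])[1, ])
  perm_g <- matrix(0, length(gv), n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    perm_g[, b] <- gdist[p, p][ut]
  }
  suppressWarnings(rp <- -cor(perm_g, ind[, evaluated, drop = FALSE]))
  p_raw <- rep(NA_real_, length(uppers))
  p_raw[evaluated] <- vapply(seq_len(sum(evaluated)), function(j) {
    (1 + sum(rp[, j] >= r_obs[evaluated][j])) / (n_perm + 1)
  }, 0)
  # progressive Holm: the k-th evaluated class corrected within the first k
  p_holm <- rep(NA_real_, length(uppers))
  ev_idx <- which(evaluated)
  for (k in seq_along(ev_idx))
    p_holm[ev_idx[k]] <- p.adjust(p_raw[ev_idx[seq_len(k)]], "holm")[k]
  signif_pos <- !is.na(p_holm) & p_holm <= alpha & r_obs > 0
  run <- 0L
  for (i in seq_along(uppers)) {
    if (!evaluated[i]) next   # empty class: skipped by the rule
    if (signif_pos[i]) run <- i else break
  }
  nbhd <- if (run > 0) uppers[run] else NA_real_
  first_ns <- if (run < length(uppers)) uppers[run + 1] else NA_real_
  list(classes = data.frame(class_upper_km = uppers, mantel_r = r_obs,
                            p_value = p_raw, p_holm = p_holm,
                            n_pairs = n_pairs, significant = signif_pos),
       neighbourhood_size_km = nbhd, first_nonsignificant_km = first_ns)
}

#' Genetic-neighbourhood diversity per individual
#'
#' For each focal individual, the neighbourhood is every individual within
#' \code{radius_km} (inclusive) along the supplied distances. Neighbourhoods
#' reaching \code{min_n} members get observed heterozygosity, unbiased gene
#' diversity (He), Fis, and allelic richness rarefied to 2 x (the smallest
#' qualifying neighbourhood size) gene copies; smaller neighbourhoods are
#' reported as not computed with the reason.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param d square distance matrix aligned with individuals
#' @param radius_km neighbourhood radius (the distance-class reading of the
#'   correlogram size; halve it for a diameter reading)
#' @param min_n minimum neighbourhood size
#' @return data.frame: sample_id, n_members, computed, reason, Ho, He, Fis, Ar
#' @export
neighborhood_diversity <- function(g, d, radius_km = 220, min_n = 20) {
  stopifnot(is_geno_matrix(g), radius_km > 0)
  d <- as.matrix(d)
  n <- nrow(g$codes)
  members <- lapply(seq_len(n), function(i) which(d[i, ] <= radius_km))
  sizes <- lengths(members)
  qualifying <- sizes >= min_n
  rare_n <- if (any(qualifying)) 2L * min(sizes[qualifying]) else NA_integer_
  out <- data.frame(sample_id = rownames(g$codes), n_members = sizes,
                    computed = qualifying,
                    reason = ifelse(qualifying, "", "insufficient n"),
                    Ho = NA_real_, He = NA_real_, Fis = NA_real_,
                    Ar = NA_real_, stringsAsFactors = FALSE)
  for (i in which(qualifying)) {
    sub <- g[members[[i]], ]
    hh <- ho_hs_fis(sub)
    out$Ho[i] <- hh$means["Ho"]
    out$He[i] <- hh$means["Hs"]
    out$Fis[i] <- hh$means["Fis"]
    out$Ar[i] <- mean(allelic_richness(sub, rare_n))
  }
  attr(out, "rarefaction_gene_copies") <- rare_n
  out
}

#' Rarefied allelic richness per locus
#'
#' Expected number of distinct alleles in a random draw of \code{gene_copies}
#' gene copies: Ar = sum over alleles of 1 - C(2n - n_a, g) / C(2n, g). For
#' biallelic loci Ar lies in [1, 2] and equals 1 at fixed loci.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param gene_copies rarefaction depth in gene copies
#' @return numeric vector per locus
#' @export
allelic_richness <- function(g, gene_copies) {
  stopifnot(is_geno_matrix(g))
  n2 <- 2 * colSums(!is.na(g$codes))
  alt <- colSums(g$codes, na.rm = TRUE)
  ref <- n2 - alt
  gc <- pmin(gene_copies, n2)
  miss_prob <- function(n_a) {
    # P(allele absent from a draw of gc copies) = C(n2 - n_a, gc) / C(n2, gc)
    ok <- n2 - n_a >= gc
    p <- numeric(length(n_a))
    p[ok] <- exp(lchoose(n2[ok] - n_a[ok], gc[ok]) - lchoose(n2[ok], gc[ok]))
    p
  }
  (1 - miss_prob(ref)) + (1 - miss_prob(alt))
}

#' Distance-decay regression with directional interaction
#'
#' Ordinary least squares of a diversity metric on distance from the
#' introduction point, direction (north/south of it), and their interaction,
#' followed by backward elimination with likelihood-ratio tests at
#' \code{alpha}, starting from the interaction. Slopes are reported per
#' 100 km. An optional leverage rule excludes points whose distance exceeds
#' 4 x the mean distance (off by default; applied exclusions are logged in
#' the result).
#'
#' @param metric numeric response per individual
#' @param metadata data.frame with dist_origin_km and direction
#' @param alpha LRT significance level for keeping a term
#' @param exclude_outliers apply the 4 x mean-distance leverage rule
#' @return list: model (final lm), terms (kept), trace (data.frame of LRT
#'   steps), adj_r2, slopes_per_100km (named, by direction when the
#'   interaction is kept), excluded (character vector)
#' @export
decay_regression <- function(metric, metadata, alpha = 0.05,
                             exclude_outliers = FALSE) {
  stopifnot(nrow(metadata) == length(metric))
  dat <- data.frame(y = metric,
                    dist = metadata$dist_origin_km / 100,
                    direction = as.character(metadata$direction),
                    stringsAsFactors = FALSE)
  dat <- dat[stats::complete.cases(dat), ]
  excluded <- character()
  if (exclude_outliers) {
    cut <- 4 * mean(dat$dist)
    drop <- dat$dist > cut
    excluded <- metadata$sample_id[stats::complete.cases(
      data.frame(metric, metadata$dist_origin_km, metadata$direction))][drop]
    dat <- dat[!drop, ]
  }
  if (nrow(dat) < 10) stop("need >= 10 complete observations")
  one_dir <- length(unique(dat$direction)) < 2
  if (one_dir) {
    warning("single direction level: direction terms dropped")
    dat$direction <- NULL
    terms_now <- "dist"
    fit <- lm(y ~ dist, data = dat)
    trace <- data.frame()
  } else {
    dat$direction <- factor(dat$direction)
    fit <- lm(y ~ dist * direction, data = dat)
    trace <- data.frame()
    drop_term <- function(fit, term) {
      red <- stats::update(fit, stats::as.formula(paste(". ~ . -", term)))
      lr <- lmtest::lrtest(red, fit)
      list(red = red, chisq = lr$Chisq[2], df = lr$Df[2], p = lr$`Pr(>Chisq)`[2])
    }
    st <- drop_term(fit, "dist:direction")
    trace <- rbind(trace, data.frame(term = "dist:direction", chisq = st$chisq,
                                     df = st$df, p = st$p,
                                     kept = st$p < alpha))
    if (st$p >= alpha) {
      fit <- st$red
      for (term in c("direction", "dist")) {
        st <- drop_term(fit, term)
        trace <- rbind(trace, data.frame(term = term, chisq = st$chisq,
                                         df = st$df, p = st$p,
                                         kept = st$p < alpha))
        if (st$p >= alpha) fit <- st$red
      }
    }
  }
  kept <- attr(stats::terms(fit), "term.labels")
  cf <- coef(fit)
  slopes <- c()
  if ("dist:direction" %in% kept || any(grepl("dist:direction", names(cf)))) {
    lev <- levels(dat$direction)
    s1 <- cf[["dist"]]
    s2 <- s1 + cf[[grep("^dist:direction", names(cf), value = TRUE)[1]]]
    slopes <- setNames(c(s1, s2), paste0("slope_per_100km_", lev))
  } else if ("dist" %in% kept) {
    slopes <- c(slope_per_100km = unname(cf[["dist"]]))
  }
  list(model = fit, terms = kept, trace = trace,
       adj_r2 = summary(fit)$adj.r.squared,
       slopes_per_100km = slopes, excluded = excluded)
}
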