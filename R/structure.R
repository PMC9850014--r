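#' PCA of a genotype matrix
#'
#' Genotypes are centred per locus; missing values are mean-imputed for the
#' decomposition only (never written back). Deterministic up to axis sign.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param n_components axes to keep (default all)
#' @return list: scores (individuals x components), eigenvalues,
#'   prop_variance
#' @export
geno_pca <- function(g, n_components = NULL) {
  stopifnot(is_geno_matrix(g))
  if (nrow(g$codes) < 2) stop("PCA needs >= 2 individuals")
  x <- g$codes
  all_missing <- colMeans(is.na(x)) == 1
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing locus(i) removed before PCA")
    x <- x[, !all_missing, drop = FALSE]
  }
  mu <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2, mu)
  xc[is.na(xc)] <- 0
  pr <- prcomp(xc, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  k <- if (is.null(n_components)) sum(ev > 1e-12) else min(n_components, length(ev))
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       eigenvalues = ev[seq_len(k)],
       prop_variance = ev[seq_len(k)] / sum(ev),
       center = mu, rotation = pr$rotation[, seq_len(k), drop = FALSE])
}

#' K-means scan with BIC model selection
#'
#' K-means (multiple seeded restarts) on the retained principal components for
#' K = 1..k_max, scored by BIC = n log(WSS/n) + K log(n). Two selection rules
#' are reported: "min" (smallest BIC) and "diffNgroup" (the smallest K whose
#' BIC decrease to K+1 falls below one third of the maximal successive
#' decrease; i.e. the K after which the curve flattens sharply).
#'
#' @param scores numeric matrix of PC scores (individuals x components)
#' @param k_max largest K scanned
#' @param n_starts random restarts per K
#' @param seed integer seed
#' @return list: bic (numeric by K), assignments (list by K), best_k_min,
#'   best_k_diffNgroup
#' @export
kmeans_bic_scan <- function(scores, k_max = 10, n_starts = 10, seed = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max < 2) stop("k_max must be >= 2")
  if (n < k_max) {
    warning("fewer individuals than k_max; scan truncated at n")
    k_max <- n
  }
  if (!is.null(seed)) set.seed(seed)
  bic <- numeric(k_max)
  assignments <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k == 1) {
      wss <- sum(scale(scores, scale = FALSE)^2)
      assignments[[k]] <- rep(1L, n)
    } else {
      km <- kmeans(scores, centers = k, nstart = n_starts, iter.max = 100)
      wss <- km$tot.withinss
      assignments[[k]] <- km$cluster
    }
    bic[k] <- n * log(wss / n) + k * log(n)
  }
  drops <- -diff(bic)               # decrease from K to K+1
  best_min <- which.min(bic)
  if (all(drops <= 0)) {
    best_diff <- 1L
  } else {
    flat <- which(drops < max(drops) / 3)
    best_diff <- if (length(flat)) flat[1] else k_max
  }
  list(bic = bic, assignments = assignments,
       best_k_min = best_min, best_k_diffNgroup = best_diff)
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on retained PCs. With \code{n_pcs = "cv"} the
#' number of PCs is chosen by repeated stratified 90/10 cross-validation,
#' taking the candidate with the lowest mean squared assignment error
#' (1 - assignment success, squared as a proportion).
#'
#' @param scores PC score matrix
#' @param groups group labels (>= 2 groups of >= 3 members)
#' @param n_pcs integer number of PCs, or "cv"
#' @param n_rep cross-validation repetitions per candidate
#' @param candidates candidate PC counts for cross-validation
#' @param seed integer seed
#' @return list: lda fit, n_pcs, posterior (individuals x groups),
#'   assigned, cv (data.frame of candidate vs mean squared error, when run)
#' @export
dapc <- function(scores, groups, n_pcs = "cv", n_rep = 30,
                 candidates = NULL, seed = NULL) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("DAPC needs >= 2 groups")
  if (min(table(groups)) < 3) stop("every group needs >= 3 members")
  if (!is.null(seed)) set.seed(seed)
  max_pc <- min(ncol(scores), nrow(scores) - nlevels(groups) - 1)
  cv_tab <- NULL
  if (identical(n_pcs, "cv")) {
    if (is.null(candidates))
      candidates <- unique(pmax(1, round(seq(1, max_pc, length.out = min(8, max_pc)))))
    err <- vapply(candidates, function(k) {
      e <- replicate(n_rep, {
        test <- unlist(lapply(levels(groups), function(gl) {
          i <- which(groups == gl)
          sample(i, max(1, round(0.1 * length(i))))
        }))
        train <- setdiff(seq_len(nrow(scores)), test)
        fit <- suppressWarnings(MASS::lda(scores[train, seq_len(k), drop = FALSE],
                                          grouping = groups[train]))
        pred <- predict(fit, scores[test, seq_len(k), drop = FALSE])$class
        mean(pred != groups[test])
      })
      mean(e^2)
    }, 0)
    cv_tab <- data.frame(n_pcs = candidates, mse = err)
    n_pcs <- candidates[which.min(err)]
  }
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  n_pcs <- min(n_pcs, ncol(scores))
  fit <- suppressWarnings(
    MASS::lda(scores[, seq_len(n_pcs), drop = FALSE], grouping = groups))
  pr <- predict(fit, scores[, seq_len(n_pcs), drop = FALSE])
  list(lda = fit, n_pcs = n_pcs, posterior = pr$posterior,
       assigned = pr$class, scores = pr$x, cv = cv_tab)
}

#' Association between de novo clusters and sampling locations
#'
#' Contingency chi-squared test (simulated p-value) between cluster
#' assignments and a location factor.
#'
#' @param clusters,locations aligned factors
#' @param n_sim Monte Carlo replicates for the p-value
#' @param seed integer seed
#' @return htest object
#' @export
cluster_location_association <- function(clusters, locations, n_sim = 2000,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  suppressWarnings(chisq.test(table(clusters, locations),
                              simulate.p.value = TRUE, B = n_sim))
}
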