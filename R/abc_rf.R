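#' Default competing invasion-history scenarios
#'
#' Eight single-population scenarios in two groups: group 1 (ids 1-4) without
#' and group 2 (ids 5-8) with a founding bottleneck of size Nbottleneck
#' starting td generations ago. Within each group the four variants are the
#' 2x2 combinations of whether the population size changes at ta (to
#' Ncontemporary) and whether it changes at tc (recovery/establishment at
#' Nestablishment). Scenario 5 is a bottleneck with establishment-size
#' recovery at tc and no later change (no subsequent recovery of the
#' contemporary size). Each scenario is a rule mapping a prior draw to a
#' \code{\link{demography}}; users can supply their own list of rules with the
#' same structure wherever a \code{scenarios} argument is accepted.
#'
#' @return named list of scenario specs: id, group, description,
#'   build (function(draw) -> demography)
#' @export
default_scenarios <- function() {
  sc <- function(id, group, description, build)
    list(id = id, group = group, description = description, build = build)
  list(
    s1 = sc(1L, 1L, "changes at ta and tc, no bottleneck", function(d)
      demography(c(0, d$ta, d$tc),
                 c(d$Ncontemporary, d$Nestablishment, d$Nancestral), "s1")),
    s2 = sc(2L, 1L, "change at ta only, no bottleneck", function(d)
      demography(c(0, d$ta), c(d$Ncontemporary, d$Nancestral), "s2")),
    s3 = sc(3L, 1L, "change at tc only, no bottleneck", function(d)
      demography(c(0, d$tc), c(d$Ncontemporary, d$Nancestral), "s3")),
    s4 = sc(4L, 1L, "constant size, no bottleneck", function(d)
      demography(0, d$Nancestral, "s4")),
    s5 = sc(5L, 2L, "bottleneck at td, establishment at tc persisting", function(d)
      demography(c(0, d$tc, d$td),
                 c(d$Nestablishment, d$Nbottleneck, d$Nancestral), "s5")),
    s6 = sc(6L, 2L, "bottleneck at td, establishment at tc, change at ta", function(d)
      demography(c(0, d$ta, d$tc, d$td),
                 c(d$Ncontemporary, d$Nestablishment, d$Nbottleneck,
                   d$Nancestral), "s6")),
    s7 = sc(7L, 2L, "bottleneck at td persisting to ta, change at ta", function(d)
      demography(c(0, d$ta, d$td),
                 c(d$Ncontemporary, d$Nbottleneck, d$Nancestral), "s7")),
    s8 = sc(8L, 2L, "bottleneck at td, still bottlenecked", function(d)
      demography(c(0, d$td), c(d$Nbottleneck, d$Nancestral), "s8"))
  )
}

#' Default prior bounds for the invasion-history parameters
#'
#' Uniform bounds (inclusive): population sizes Nancestral, Nestablishment,
#' Ncontemporary in [2, 10000], Nbottleneck in [2, 100]; times (generations
#' backwards) t0 in [0, 5] (contemporary sampling), ta in [2, 15], tb in
#' [2, 15] (historical sampling), tc in [2, 50], td in [1, 100], with the
#' ordering constraint t0 < ta < tb < tc < td enforced by rejection.
#'
#' @return named list of c(lower, upper) integer bounds
#' @export
default_priors <- function() {
  list(Nancestral = c(2L, 10000L), Nestablishment = c(2L, 10000L),
       Ncontemporary = c(2L, 10000L), Nbottleneck = c(2L, 100L),
       t0 = c(0L, 5L), ta = c(2L, 15L), tb = c(2L, 15L),
       tc = c(2L, 50L), td = c(1L, 100L))
}

#' Draw one parameter vector from the priors
#'
#' Independent integer-uniform draws per parameter, rejection-resampled until
#' t0 < ta < tb < tc < td holds.
#'
#' @param priors prior bounds as from \code{\link{default_priors}}
#' @param seed optional integer seed
#' @param max_tries rejection cap
#' @return named list of integer parameter values
#' @export
draw_prior <- function(priors = default_priors(), seed = NULL,
                       max_tries = 100000L) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    d <- lapply(priors, function(b) sample(b[1]:b[2], 1L))
    if (d$t0 < d$ta && d$ta < d$tb && d$tb < d$tc && d$tc < d$td)
      return(d)
  }
  stop("prior rejection sampling failed to satisfy the time ordering")
}

# vectorized two-or-more-population Weir-Cockerham theta (point estimate only)
wc_theta_point <- function(codes, pops) {
  lev <- sort(unique(pops))
  r <- length(lev)
  obs <- !is.na(codes)
  ni <- vapply(lev, function(k) colSums(obs[pops == k, , drop = FALSE]), numeric(ncol(codes)))
  pi <- vapply(lev, function(k) {
    m <- codes[pops == k, , drop = FALSE]
    colSums(m, na.rm = TRUE) / (2 * pmax(colSums(!is.na(m)), 1))
  }, numeric(ncol(codes)))
  hi <- vapply(lev, function(k) {
    m <- codes[pops == k, , drop = FALSE]
    colSums(m == 1L, na.rm = TRUE) / pmax(colSums(!is.na(m)), 1)
  }, numeric(ncol(codes)))
  ok <- rowSums(ni >= 1) == r & rowSums(ni) >= 2
  ni <- ni[ok, , drop = FALSE]; pi <- pi[ok, , drop = FALSE]; hi <- hi[ok, , drop = FALSE]
  nbar <- rowMeans(ni)
  nsum <- rowSums(ni)
  nc <- (nsum - rowSums(ni^2) / nsum) / (r - 1)
  pbar <- rowSums(ni * pi) / nsum
  s2 <- rowSums(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / nsum
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  keep <- is.finite(a) & is.finite(b)
  sum(a[keep]) / sum(a[keep] + b[keep] + cc[keep])
}

#' Summary-statistic vector for ABC
#'
#' A fixed-order vector spanning the moments classically used for SNP data:
#' for each era group and for the pooled sample, the proportion of loci
#' monomorphic in that group, mean and variance of MAF, mean and variance of
#' per-locus Ho and Hs, and mean Fis; between eras, Weir-Cockerham Fst, Nei's
#' standard genetic distance, and the mean absolute allele-frequency
#' difference; plus the pooled MAF-spectrum deciles (10\%..90\%).
#'
#' @param dataset a \code{sim_dataset}, or a list with \code{genotypes}
#'   (\code{geno_matrix}) and \code{metadata} carrying an \code{era} column
#'   with exactly two levels
#' @return named numeric vector (constant length and order)
#' @export
summarize_dataset <- function(dataset) {
  g <- dataset$genotypes
  era <- dataset$metadata$era
  lev <- sort(unique(era))
  if (length(lev) != 2) stop("summaries require exactly two era groups")
  per_group <- function(codes, tag) {
    n <- colSums(!is.na(codes))
    p <- colSums(codes, na.rm = TRUE) / (2 * pmax(n, 1))
    maf <- pmin(p, 1 - p)
    ho <- colSums(codes == 1L, na.rm = TRUE) / pmax(n, 1)
    ok <- n >= 2
    hs <- ifelse(ok, n / pmax(n - 1, 1) *
                   (1 - p^2 - (1 - p)^2 - ho / (2 * pmax(n, 1))), NA)
    fis <- ifelse(!is.na(hs) & hs > 0, 1 - ho / hs, NA)
    v <- c(mean(maf == 0), mean(maf), var(maf), mean(ho), var(ho),
           mean(hs, na.rm = TRUE), var(hs, na.rm = TRUE),
           mean(fis, na.rm = TRUE))
    v[!is.finite(v)] <- 0
    names(v) <- paste0(tag, "_", c("prop_mono", "maf_mean", "maf_var",
                                   "ho_mean", "ho_var", "hs_mean", "hs_var",
                                   "fis_mean"))
    v
  }
  codes <- g$codes
  s <- c(per_group(codes[era == lev[1], , drop = FALSE], "g1"),
         per_group(codes[era == lev[2], , drop = FALSE], "g2"),
         per_group(codes, "pooled"))
  p1 <- colMeans(codes[era == lev[1], , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(codes[era == lev[2], , drop = FALSE], na.rm = TRUE) / 2
  p1[!is.finite(p1)] <- 0; p2[!is.finite(p2)] <- 0
  jx <- mean(p1^2 + (1 - p1)^2)
  jy <- mean(p2^2 + (1 - p2)^2)
  jxy <- mean(p1 * p2 + (1 - p1) * (1 - p2))
  neiD <- -log(jxy / sqrt(jx * jy))
  theta <- wc_theta_point(codes, era)
  if (!is.finite(theta)) theta <- 0
  pool_p <- colMeans(codes, na.rm = TRUE) / 2
  dec <- quantile(pmin(pool_p, 1 - pool_p), probs = seq(0.1, 0.9, 0.1),
                  na.rm = TRUE, names = FALSE)
  out <- c(s, between_fst = theta, between_neiD = neiD,
           between_abs_dp = mean(abs(p1 - p2)),
           setNames(dec, paste0("maf_decile_", 1:9)))
  out[!is.finite(out)] <- 0
  out
}

#' Build an ABC reference table
#'
#' For each scenario, draws \code{n_per_scenario} parameter vectors from the
#' priors, simulates a serial-sampling SNP dataset matching the observed
#' design (n historical + n contemporary diploids, n loci), and records the
#' summary vector.
#'
#' @param scenarios list of scenario specs (\code{\link{default_scenarios}})
#' @param n_per_scenario simulated datasets per scenario
#' @param n_contemporary,n_historical diploids sampled at t0 / tb
#' @param n_loci SNP loci per dataset
#' @param priors prior bounds
#' @param seed integer seed (the whole table is reproducible from it)
#' @return list of class \code{abc_reference}: \code{summaries} (matrix),
#'   \code{scenario} (integer vector), \code{group} (integer vector),
#'   \code{params} (data.frame of drawn parameters), \code{design} metadata
#' @export
build_reference_table <- function(scenarios = default_scenarios(),
                                  n_per_scenario = 500,
                                  n_contemporary = 195, n_historical = 8,
                                  n_loci = 300, priors = default_priors(),
                                  seed = NULL) {
  stopifnot(n_per_scenario >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(scenarios) * n_per_scenario)
  scen_id <- integer(length(rows))
  grp <- integer(length(rows))
  params <- vector("list", length(rows))
  k <- 0L
  for (sc in scenarios) {
    for (i in seq_len(n_per_scenario)) {
      k <- k + 1L
      repeat {
        d <- draw_prior(priors)
        ds <- try(simulate_scenario_dataset(sc, d, n_contemporary,
                                            n_historical, n_loci),
                  silent = TRUE)
        if (!inherits(ds, "try-error")) break
      }
      rows[[k]] <- summarize_dataset(ds)
      scen_id[k] <- sc$id
      grp[k] <- sc$group
      params[[k]] <- unlist(d)
    }
  }
  structure(list(summaries = do.call(rbind, rows), scenario = scen_id,
                 group = grp,
                 params = as.data.frame(do.call(rbind, params)),
                 design = list(n_contemporary = n_contemporary,
                               n_historical = n_historical, n_loci = n_loci,
                               n_per_scenario = n_per_scenario,
                               priors = priors, seed = seed)),
            class = "abc_reference")
}

#' Simulate one dataset under a scenario and a parameter draw
#'
#' @param scenario a scenario spec (see \code{\link{default_scenarios}})
#' @param draw named parameter list as from \code{\link{draw_prior}}
#' @param n_contemporary,n_historical diploids sampled at t0 / tb
#' @param n_loci SNP loci
#' @return a \code{sim_dataset}; \code{true_params$draw} holds the draw
#' @export
simulate_scenario_dataset <- function(scenario, draw, n_contemporary = 195,
                                      n_historical = 8, n_loci = 300) {
  demog <- scenario$build(draw)
  scheme <- sampling_scheme(time = c(draw$t0, draw$tb),
                            n_diploids = c(n_contemporary, n_historical),
                            era = c("contemporary", "historical"))
  ds <- simulate_snp_dataset(demog, scheme, n_loci)
  ds$true_params$draw <- draw
  ds$true_params$scenario_id <- scenario$id
  ds$true_params$group <- scenario$group
  ds
}

#' Random-forest scenario choice
#'
#' Trains a classification forest on the reference summaries (targets: group
#' membership or scenario id), reports per-class tree votes at the observed
#' summary, the out-of-bag misclassification rate (the prior error rate), and
#' a posterior probability for the selected class estimated by a second
#' regression forest trained on out-of-bag classification success and
#' evaluated at the observed summary. A linear-discriminant projection of the
#' reference rows plus the observed point is returned for overlap inspection.
#'
#' @param ref an \code{abc_reference}
#' @param observed_summary named numeric vector from
#'   \code{\link{summarize_dataset}}
#' @param level "group" or "scenario"
#' @param n_trees trees in each forest
#' @param seed integer seed
#' @return list: votes (named integer), selected, posterior_probability,
#'   prior_error_rate, lda_projection (data.frame), forest
#' @export
scenario_choice <- function(ref, observed_summary, level = c("group", "scenario"),
                            n_trees = 1000, seed = NULL) {
  level <- match.arg(level)
  y <- factor(if (level == "group") ref$group else ref$scenario)
  if (nlevels(y) < 2) stop("reference table contains a single class")
  if (length(observed_summary) != ncol(ref$summaries))
    stop("observed summary length does not match the reference table")
  dat <- as.data.frame(ref$summaries)
  dat$.class <- y
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  rf <- ranger::ranger(dependent.variable.name = ".class", data = dat,
                       num.trees = n_trees, seed = seed, num.threads = 1,
                       keep.inbag = FALSE)
  obs <- as.data.frame(rbind(observed_summary))
  colnames(obs) <- colnames(ref$summaries)
  pred_all <- predict(rf, data = obs, predict.all = TRUE, num.threads = 1)
  votes_idx <- as.vector(pred_all$predictions)
  votes <- table(factor(levels(y)[votes_idx], levels = levels(y)))
  selected <- names(which.max(votes))
  oob_ok <- as.numeric(rf$predictions == y)
  dat2 <- as.data.frame(ref$summaries)
  dat2$.ok <- oob_ok
  rf2 <- ranger::ranger(dependent.variable.name = ".ok", data = dat2,
                        num.trees = n_trees, seed = seed + 1L, num.threads = 1)
  post <- predict(rf2, data = obs, num.threads = 1)$predictions
  proj <- tryCatch({
    keep <- apply(ref$summaries, 2, function(v) var(v) > 1e-12)
    ld <- suppressWarnings(
      MASS::lda(ref$summaries[, keep, drop = FALSE], grouping = y))
    sc_ref <- predict(ld, ref$summaries[, keep, drop = FALSE])$x
    sc_obs <- predict(ld, rbind(observed_summary[keep]))$x
    data.frame(rbind(sc_ref, sc_obs),
               class = c(as.character(y), "observed"),
               row.names = NULL)
  }, error = function(e) NULL)
  list(votes = votes, selected = selected,
       posterior_probability = min(max(post, 0), 1),
       prior_error_rate = rf$prediction.error,
       lda_projection = proj, level = level, forest = rf)
}

#' Quantile-regression-forest parameter estimation
#'
#' On the reference rows of a single scenario, fits one quantile regression
#' forest per parameter and reports the median and [0.025, 0.975] quantiles at
#' the observed summary, plus the normalized mean absolute error
#' NMAE = mean(|OOB prediction - true| / true) over the training rows.
#'
#' @param ref an \code{abc_reference} restricted (or restrictable via
#'   \code{scenario_id}) to one scenario, with >= 500 rows
#' @param observed_summary named numeric vector, or a matrix with one summary
#'   per row (each forest is trained once and evaluated at every row; the
#'   result then carries one estimate row per observed summary per parameter,
#'   with an \code{obs} index column)
#' @param params parameter names to estimate (columns of \code{ref$params})
#' @param scenario_id optional scenario to subset the table to
#' @param n_trees trees per forest
#' @param seed integer seed
#' @return data.frame: parameter, median, q025, q975, nmae
#' @export
estimate_parameters <- function(ref, observed_summary,
                                params = c("Nancestral", "Nbottleneck", "td"),
                                scenario_id = NULL, n_trees = 1000,
                                seed = NULL) {
  rows <- if (is.null(scenario_id)) seq_along(ref$scenario) else
    which(ref$scenario == scenario_id)
  if (length(rows) < 500)
    stop("need >= 500 reference rows for parameter estimation")
  miss <- setdiff(params, colnames(ref$params))
  if (length(miss)) stop("parameter(s) absent from draws: ",
                         paste(miss, collapse = ", "))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  x <- as.data.frame(ref$summaries[rows, , drop = FALSE])
  obs <- if (is.matrix(observed_summary)) as.data.frame(observed_summary) else
    as.data.frame(rbind(observed_summary))
  colnames(obs) <- colnames(x)
  out <- lapply(seq_along(params), function(i) {
    pname <- params[i]
    dat <- x
    dat$.y <- ref$params[[pname]][rows]
    if (var(dat$.y) < 1e-12) {
      v <- dat$.y[1]
      return(data.frame(parameter = pname, obs = seq_len(nrow(obs)),
                        median = v, q025 = v, q975 = v, nmae = 0))
    }
    rf <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                         num.trees = n_trees, quantreg = TRUE,
                         seed = seed + i, num.threads = 1)
    q <- predict(rf, data = obs, type = "quantiles",
                 quantiles = c(0.025, 0.5, 0.975), num.threads = 1)$predictions
    nmae <- mean(abs(rf$predictions - dat$.y) / dat$.y)
    data.frame(parameter = pname, obs = seq_len(nrow(obs)),
               median = q[, 2], q025 = q[, 1], q975 = q[, 3], nmae = nmae)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
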