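#' Iterative, alternating missingness filter
#'
#' Alternately drops loci then individuals whose missingness exceeds the
#' current cut-off, tightening the cut-off along \code{step_schedule} and
#' finishing when the final locus and individual thresholds hold
#' simultaneously. This mirrors the common practice of starting with lenient
#' cut-offs so that a few terrible samples do not drag down otherwise good
#' loci (and vice versa). The result is idempotent at the final thresholds.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param locus_threshold final maximum missing fraction per locus
#' @param individual_threshold final maximum missing fraction per individual
#' @param step_schedule decreasing thresholds applied alternately
#'   (locus pass then individual pass at each step)
#' @return filtered \code{geno_matrix}; attribute \code{filter_log} is a
#'   data.frame recording every removal with its reason
#' @export
iterative_missingness_filter <- function(g, locus_threshold = 0.30,
                                         individual_threshold = 0.30,
                                         step_schedule = c(0.9, 0.7, 0.5, 0.3)) {
  stopifnot(is_geno_matrix(g))
  thr <- c(locus_threshold, individual_threshold)
  if (any(thr <= 0) || any(thr > 1)) stop("thresholds must be in (0, 1]")
  log <- data.frame(item = character(), type = character(),
                    value = numeric(), threshold = numeric(),
                    stringsAsFactors = FALSE)
  steps <- sort(unique(c(step_schedule, locus_threshold, individual_threshold)),
                decreasing = TRUE)
  drop_pass <- function(g, cut_l, cut_i) {
    ml <- geno_missing_by_locus(g)
    bad_l <- which(ml > cut_l)
    if (length(bad_l)) {
      log <<- rbind(log, data.frame(item = colnames(g$codes)[bad_l],
                                    type = "locus", value = ml[bad_l],
                                    threshold = cut_l))
      g <- g[, -bad_l]
    }
    mi <- geno_missing_by_ind(g)
    bad_i <- which(mi > cut_i)
    if (length(bad_i)) {
      log <<- rbind(log, data.frame(item = rownames(g$codes)[bad_i],
                                    type = "individual", value = mi[bad_i],
                                    threshold = cut_i))
      g <- g[-bad_i, ]
    }
    g
  }
  for (s in steps)
    g <- drop_pass(g, max(s, locus_threshold), max(s, individual_threshold))
  repeat {
    before <- dim(g)
    g <- drop_pass(g, locus_threshold, individual_threshold)
    if (all(dim(g) == before)) break
  }
  if (nrow(g$codes) == 0) stop("missingness filter removed all individuals")
  attr(g, "filter_log") <- log
  g
}

#' Minor-allele-count filter
#'
#' Removes loci whose minor allele count over non-missing genotypes is below
#' \code{min_mac}; monomorphic loci are always removed.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param min_mac minimum minor allele count to retain a locus (>= 1)
#' @return filtered \code{geno_matrix} with a \code{filter_log} attribute
#' @export
mac_filter <- function(g, min_mac = 2L) {
  stopifnot(is_geno_matrix(g), min_mac >= 1)
  mac <- geno_mac(g)
  drop <- which(mac < min_mac)
  out <- if (length(drop)) g[, -drop] else g
  attr(out, "filter_log") <- data.frame(
    item = colnames(g$codes)[drop], type = rep("locus", length(drop)),
    value = mac[drop], threshold = rep(min_mac, length(drop)),
    stringsAsFactors = FALSE)
  out
}

#' HDplot locus diagnostics
#'
#' Per-locus heterozygote proportion H and read-ratio deviation D for paralog
#' detection in RAD data. H is the heterozygous fraction among non-missing
#' genotypes. D = (A - B) / sqrt(A + B), where A and B are total reference and
#' alternate read counts summed over heterozygous individuals at the locus: the
#' z-score of the observed allele balance against binomial(0.5) expectation.
#' Duplicated loci collapsed into one show inflated H and/or |D|.
#'
#' @param g a \code{\link{geno_matrix}} carrying read depths
#' @return data.frame with snp_id, locus_tag, position, H, D, n_het, maf,
#'   missing_fraction
#' @export
hdplot <- function(g) {
  stopifnot(is_geno_matrix(g))
  if (is.null(g$ref_depth) || is.null(g$alt_depth))
    stop("HDplot requires per-genotype read depths (ref_depth/alt_depth)")
  het <- !is.na(g$codes) & g$codes == 1L
  A <- colSums(g$ref_depth * het, na.rm = TRUE)
  B <- colSums(g$alt_depth * het, na.rm = TRUE)
  D <- ifelse(A + B > 0, (A - B) / sqrt(A + B), 0)
  data.frame(snp_id = colnames(g$codes), locus_tag = g$locus_tag,
             position = g$position,
             H = colMeans(het & !is.na(g$codes)) /
               pmax(colMeans(!is.na(g$codes)), .Machine$double.eps),
             D = D, n_het = colSums(het),
             maf = geno_maf(g),
             missing_fraction = geno_missing_by_locus(g),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter loci by HDplot thresholds
#'
#' Removes loci with H > \code{h_max} or |D| > \code{d_max}.
#'
#' @inheritParams hdplot
#' @param h_max maximum heterozygote proportion
#' @param d_max maximum |read-ratio deviation|
#' @return filtered \code{geno_matrix} with a \code{filter_log} attribute
#' @export
filter_hdplot <- function(g, h_max = 0.55, d_max = 7) {
  qc <- hdplot(g)
  drop <- which(qc$H > h_max | abs(qc$D) > d_max)
  out <- if (length(drop)) g[, -drop] else g
  attr(out, "filter_log") <- data.frame(
    item = qc$snp_id[drop], type = rep("locus", length(drop)),
    value = pmax(qc$H[drop] / h_max, abs(qc$D[drop]) / d_max),
    threshold = rep(NA_real_, length(drop)),
    reason = ifelse(qc$H[drop] > h_max, "H", "D"),
    stringsAsFactors = FALSE)
  out
}

#' Keep one SNP per locus: the highest-MAF site
#'
#' Within each locus tag, retains the SNP with the highest minor allele
#' frequency; ties are broken by the lowest site position.
#'
#' @param g a \code{\link{geno_matrix}}
#' @return filtered \code{geno_matrix}
#' @export
select_one_snp_per_locus <- function(g) {
  stopifnot(is_geno_matrix(g))
  maf <- geno_maf(g)
  ord <- order(g$locus_tag, -maf, g$position)
  keep_first <- ord[!duplicated(g$locus_tag[ord])]
  g[, sort(keep_first)]
}

#' Method-of-moments pairwise relatedness
#'
#' Genome-wide allele-sharing relatedness for each pair of individuals:
#' r_ij = sum_l (x_il - 2p_l)(x_jl - 2p_l) / sum_l 2 p_l (1 - p_l), with x the
#' alternate-allele count and p the pooled sample frequency (a VanRaden-style
#' kinship scaled to relatedness). Expectation ~0.5 for parent-offspring, ~0
#' for unrelated pairs. Values are clipped to [-1, 1]. Loci missing in either
#' member of a pair are excluded from that pair only.
#'
#' @param g a \code{\link{geno_matrix}} with >= 2 individuals
#' @return symmetric matrix of r with NA diagonal
#' @export
pairwise_relatedness <- function(g) {
  stopifnot(is_geno_matrix(g))
  if (nrow(g$codes) < 2) stop("need at least two individuals")
  if (ncol(g$codes) == 0) stop("locus set is empty")
  p <- geno_allele_freq(g)
  usable <- p > 0 & p < 1 & !is.na(p)
  if (!any(usable)) stop("no polymorphic loci for relatedness")
  x <- g$codes[, usable, drop = FALSE]
  p <- p[usable]
  centred <- sweep(x, 2, 2 * p)
  w <- 2 * p * (1 - p)
  obs <- !is.na(centred)
  centred[!obs] <- 0
  num <- tcrossprod(centred)
  den <- tcrossprod(obs * rep(sqrt(w), each = nrow(obs)))  # sum w over shared loci
  # den above multiplies sqrt(w) twice per shared locus -> w per shared locus
  r <- num / den
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- NA
  dimnames(r) <- list(rownames(g$codes), rownames(g$codes))
  r
}

#' Apply the full locus/individual filtering cascade
#'
#' Runs, in order: iterative missingness filter, minor-allele-count filter,
#' HDplot paralog filter (when depths are present), and one-SNP-per-locus
#' selection. Returns the filtered matrix with a combined provenance log.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param locus_missing,individual_missing final missingness cut-offs
#' @param min_mac minimum minor allele count
#' @param h_max,d_max HDplot thresholds
#' @param hdplot_filter apply the HDplot step (requires depths)
#' @return filtered \code{geno_matrix}; attribute \code{cascade_log} lists the
#'   surviving dimensions after each stage
#' @export
filter_cascade <- function(g, locus_missing = 0.30, individual_missing = 0.30,
                           min_mac = 2L, h_max = 0.55, d_max = 7,
                           hdplot_filter = !is.null(g$ref_depth)) {
  stages <- list()
  g <- iterative_missingness_filter(g, locus_missing, individual_missing)
  stages$missingness <- dim(g)
  g <- mac_filter(g, min_mac)
  stages$mac <- dim(g)
  if (hdplot_filter) {
    g <- filter_hdplot(g, h_max, d_max)
    stages$hdplot <- dim(g)
  }
  g <- select_one_snp_per_locus(g)
  stages$one_snp_per_locus <- dim(g)
  attr(g, "cascade_log") <- stages
  g
}
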