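#' Simulate one locus genealogy under a serial-sampling coalescent
#'
#' Runs the n-coalescent with piecewise-constant diploid size N(t): among k
#' active lineages the coalescence rate is k(k-1)/(4N(t)). Each sampled diploid
#' contributes two lineages; lineages sampled at time t enter the process at t.
#'
#' @param demog a \code{\link{demography}}
#' @param scheme a \code{\link{sampling_scheme}}
#' @param seed optional integer seed
#' @return A \code{genealogy}: list with \code{n_tips}, \code{node_time}
#'   (generations backwards; tips first, then internal nodes in coalescence
#'   order), \code{left}/\code{right}/\code{parent} (1-based child/parent
#'   pointers, \code{NA} where absent), and \code{tip_era}.
#' @export
simulate_locus_genealogy <- function(demog, scheme, seed = NULL) {
  stopifnot(inherits(demog, "demography"), inherits(scheme, "sampling_scheme"))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_genealogy(demog$start, demog$N, scheme$time, 2L * scheme$n_diploids)
  idx <- function(v) ifelse(v < 0L, NA_integer_, v + 1L)
  structure(list(
    n_tips = res$n_tips,
    node_time = res$node_time,
    left = idx(res$left), right = idx(res$right), parent = idx(res$parent),
    tip_era = rep(scheme$era, 2L * scheme$n_diploids)
  ), class = "genealogy")
}

#' Time to the most recent common ancestor of a genealogy
#' @param g a \code{genealogy}
#' @export
tmrca <- function(g) max(g$node_time)

#' Total branch length of a genealogy, in generations
#' @param g a \code{genealogy}
#' @export
total_branch_length <- function(g) {
  has_parent <- !is.na(g$parent)
  sum(g$node_time[g$parent[has_parent]] - g$node_time[which(has_parent)])
}

#' Simulate a dataset of unlinked single-mutation SNPs
#'
#' One genealogy per locus; a single mutation is placed on a branch chosen with
#' probability proportional to branch length (fixed-S ascertainment, S = 1), so
#' every locus is polymorphic in the pooled haploid sample. Loci monomorphic
#' after mutation placement (a numerical impossibility for a proper branch, but
#' guarded) are redrawn up to \code{retry_cap} times.
#'
#' @inheritParams simulate_locus_genealogy
#' @param n_loci number of SNP loci (>= 0)
#' @param retry_cap redraw attempts per locus before an ascertainment error
#' @param label optional label stored with the dataset
#' @return A \code{sim_dataset}: list with \code{genotypes} (a
#'   \code{\link{geno_matrix}}), \code{metadata} (sample_id, era, time_gen,
#'   river_km, direction), and \code{true_params}.
#' @export
simulate_snp_dataset <- function(demog, scheme, n_loci, seed = NULL,
                                 retry_cap = 100L, label = "") {
  stopifnot(inherits(demog, "demography"), inherits(scheme, "sampling_scheme"))
  if (n_loci < 0) stop("n_loci must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_ind <- sum(scheme$n_diploids)
  era <- rep(scheme$era, scheme$n_diploids)
  tgen <- rep(scheme$time, scheme$n_diploids)
  ids <- sprintf("%s_%03d", era, stats::ave(seq_len(n_ind), era, FUN = seq_along))
  if (n_loci == 0) {
    codes <- matrix(integer(0), nrow = n_ind, ncol = 0,
                    dimnames = list(ids, NULL))
    geno <- geno_matrix(codes)
  } else {
    codes <- cpp_sim_snps(demog$start, demog$N, scheme$time, scheme$n_diploids,
                          as.integer(n_loci), as.integer(retry_cap))
    rownames(codes) <- ids
    colnames(codes) <- sprintf("L%05d:1", seq_len(n_loci))
    geno <- geno_matrix(codes, locus_tag = sprintf("L%05d", seq_len(n_loci)),
                        position = rep(1L, n_loci))
  }
  metadata <- data.frame(sample_id = ids, era = era, time_gen = tgen,
                         river_km = 0, direction = NA_character_,
                         stringsAsFactors = FALSE)
  structure(list(genotypes = geno, metadata = metadata,
                 true_params = list(demography = demog, scheme = scheme),
                 label = label),
            class = "sim_dataset")
}

#' @exportS3Method base::print
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset%s: %d individuals x %d SNPs; eras: %s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$genotypes$codes), ncol(x$genotypes$codes),
              paste(names(table(x$metadata$era)), table(x$metadata$era),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Simulate a river population under a linear stepping-stone model
#'
#' Forward-time diploid Wright-Fisher simulation of demes on a line, founded
#' from a common pool (per-locus founder frequencies uniform on
#' \code{init_freq_range}), with symmetric nearest-neighbour migration.
#' Produces isolation by distance when \code{migration_rate} is small. Loci
#' monomorphic in the pooled final sample are dropped (SNP ascertainment), so
#' the returned dataset can carry fewer than \code{n_loci} SNPs.
#'
#' @param n_demes number of demes on the line (>= 1)
#' @param deme_size diploids per deme
#' @param migration_rate per-parent probability of originating from an adjacent
#'   deme, in [0, 0.5]
#' @param generations forward generations simulated
#' @param n_loci unlinked biallelic loci simulated
#' @param samples_per_deme diploids sampled per deme (<= deme_size)
#' @param deme_spacing_km distance between adjacent demes, km
#' @param origin_deme deme treated as the introduction point for the
#'   direction flag (default: middle deme)
#' @param init_freq_range range of founder allele frequencies
#' @param seed optional integer seed
#' @return A \code{sim_dataset}; metadata carries \code{river_km} (coordinate
#'   along the river), \code{dist_origin_km} and \code{direction}
#'   ("north" downstream of the origin, "south" upstream).
#' @export
simulate_river_population <- function(n_demes, deme_size, migration_rate,
                                      generations, n_loci, samples_per_deme,
                                      deme_spacing_km = 10,
                                      origin_deme = ceiling(n_demes / 2),
                                      init_freq_range = c(0.05, 0.95),
                                      seed = NULL) {
  if (migration_rate < 0 || migration_rate > 0.5)
    stop("migration_rate must be in [0, 0.5]")
  stopifnot(n_demes >= 1, deme_size >= 1, generations >= 1, n_loci >= 1,
            samples_per_deme >= 1, samples_per_deme <= deme_size,
            deme_spacing_km > 0)
  if (!is.null(seed)) set.seed(seed)
  init_freq <- runif(n_loci, init_freq_range[1], init_freq_range[2])
  full <- cpp_stepping_stone(as.integer(n_demes), as.integer(deme_size),
                             migration_rate, as.integer(generations),
                             as.integer(n_loci), init_freq)
  keep_ind <- as.vector(outer(seq_len(samples_per_deme),
                              (seq_len(n_demes) - 1L) * deme_size, `+`))
  codes <- full[keep_ind, , drop = FALSE]
  poly <- apply(codes, 2, function(x) length(unique(x)) > 1 || any(x == 1))
  codes <- codes[, poly, drop = FALSE]
  deme <- rep(seq_len(n_demes), each = samples_per_deme)
  ids <- sprintf("d%02d_i%02d", deme, rep(seq_len(samples_per_deme), n_demes))
  rownames(codes) <- ids
  colnames(codes) <- sprintf("L%05d:1", seq_len(ncol(codes)))
  geno <- geno_matrix(codes, locus_tag = sprintf("L%05d", seq_len(ncol(codes))))
  coord <- (deme - 1) * deme_spacing_km
  origin_coord <- (origin_deme - 1) * deme_spacing_km
  metadata <- data.frame(
    sample_id = ids, era = "contemporary", time_gen = 0,
    deme = deme, river_km = coord,
    dist_origin_km = abs(coord - origin_coord),
    direction = ifelse(coord >= origin_coord, "north", "south"),
    stringsAsFactors = FALSE)
  structure(list(genotypes = geno, metadata = metadata,
                 true_params = list(n_demes = n_demes, deme_size = deme_size,
                                    migration_rate = migration_rate,
                                    generations = generations,
                                    deme_spacing_km = deme_spacing_km),
                 label = "stepping_stone"),
            class = "sim_dataset")
}

#' Pairwise along-river distance matrix from a dataset's metadata
#' @param dataset a \code{sim_dataset}
#' @return square symmetric matrix keyed by sample id, km
#' @export
river_distances <- function(dataset) {
  km <- dataset$metadata$river_km
  d <- abs(outer(km, km, `-`))
  dimnames(d) <- list(dataset$metadata$sample_id, dataset$metadata$sample_id)
  d
}

#' Synthesize per-genotype read depths for a dataset
#'
#' Total depth per non-missing genotype is negative binomial around
#' \code{depth_mean}; heterozygote reads split binomially with allele balance
#' 0.5 for true SNPs. A fraction of loci can be converted into a synthetic
#' "paralog" class emulating two collapsed duplicated copies: individuals
#' appear heterozygous with probability \code{paralog_het_rate} (inflating H)
#' and their reads split at \code{paralog_balance} instead of 0.5 (inflating
#' |D|), giving the HDplot screen a separable signal on both axes.
#'
#' @param dataset a \code{sim_dataset}
#' @param depth_mean mean total read depth per genotype
#' @param nb_size negative-binomial size (dispersion) parameter
#' @param paralog_fraction fraction of loci assigned to the paralog class
#' @param paralog_balance heterozygote reference-read proportion for paralogs
#' @param paralog_het_rate probability an individual is called heterozygous at
#'   a paralog locus (divergent duplicated copies mimic heterozygotes)
#' @param seed optional integer seed
#' @return the dataset with \code{ref_depth}/\code{alt_depth} filled in and a
#'   logical attribute \code{paralog} on the genotype object marking the class
#' @export
add_read_depths <- function(dataset, depth_mean = 100, nb_size = 20,
                            paralog_fraction = 0, paralog_balance = 0.65,
                            paralog_het_rate = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- dataset$genotypes
  codes <- g$codes
  n <- length(codes)
  total <- matrix(rnbinom(n, mu = depth_mean, size = nb_size), nrow = nrow(codes))
  total[total == 0L] <- 1L
  total[is.na(codes)] <- 0L
  n_par <- round(paralog_fraction * ncol(codes))
  is_paralog <- rep(FALSE, ncol(codes))
  if (n_par > 0) is_paralog[sample.int(ncol(codes), n_par)] <- TRUE
  for (j in which(is_paralog)) {
    ok <- !is.na(codes[, j])
    make_het <- ok & runif(nrow(codes)) < paralog_het_rate
    codes[make_het, j] <- 1L
  }
  balance <- matrix(rep(ifelse(is_paralog, paralog_balance, 0.5),
                        each = nrow(codes)), nrow = nrow(codes))
  ref <- matrix(0L, nrow(codes), ncol(codes))
  het <- !is.na(codes) & codes == 1L
  ref[het] <- rbinom(sum(het), total[het], balance[het])
  homr <- !is.na(codes) & codes == 0L
  ref[homr] <- total[homr]
  alt <- total - ref
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  dimnames(ref) <- dimnames(alt) <- dimnames(codes)
  g$codes <- codes
  g$ref_depth <- ref
  g$alt_depth <- alt
  attr(g, "paralog") <- is_paralog
  dataset$genotypes <- g
  dataset
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Writes \code{genotypes.vcf} (GT and, when depths are present, AD fields),
#' \code{metadata.tsv}, and \code{distances.tsv} (pairwise along-river
#' distances). Round-trips losslessly through \code{\link{read_vcf}}.
#'
#' @param dataset a \code{sim_dataset}
#' @param directory output directory (created if needed)
#' @return named character vector of the files written (invisibly)
#' @export
write_fixture <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(directory, "genotypes.vcf"),
             metadata = file.path(directory, "metadata.tsv"),
             distances = file.path(directory, "distances.tsv"))
  write_vcf(dataset$genotypes, paths["vcf"])
  write.table(dataset$metadata, paths["metadata"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  d <- river_distances(dataset)
  write.table(data.frame(sample_id = rownames(d), d, check.names = FALSE),
              paths["distances"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
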