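# shared fixture builders: everything generated in code at test time

# geno_matrix from a plain matrix given as individuals x loci
gm <- function(codes, ...) {
  geno_matrix(as.matrix(codes), ...)
}

# Hardy-Weinberg genotypes at given allele frequencies, no missing data
hwe_genotypes <- function(n_ind, freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- vapply(freqs, function(p) rbinom(n_ind, 2, p), numeric(n_ind))
  gm(codes)
}

# time to coalescence of two tips of a genealogy (walk to the MRCA)
pair_coal_time <- function(g, i, j) {
  anc <- function(v) {
    path <- v
    while (!is.na(g$parent[v])) { v <- g$parent[v]; path <- c(path, v) }
    path
  }
  common <- intersect(anc(i), anc(j))
  min(g$node_time[common])
}

# small two-era dataset wrapper for summarize_dataset
era_dataset <- function(g, era) {
  list(genotypes = g,
       metadata = data.frame(sample_id = rownames(g$codes), era = era,
                             stringsAsFactors = FALSE))
}
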