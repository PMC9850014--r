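#' Genotype matrix container
#'
#' A light container for diploid biallelic SNP genotypes: an individuals x loci
#' integer matrix of alternate-allele counts (0, 1, 2; \code{NA} = missing),
#' optional per-genotype read depths (needed for HDplot), and locus identity.
#' Several SNPs may share a locus tag (RAD locus); \code{position} orders SNPs
#' within a tag.
#'
#' @param codes integer matrix, individuals in rows, SNPs in columns; values in
#'   \{0, 1, 2, NA\}. Row names are sample ids, column names SNP ids.
#' @param ref_depth,alt_depth optional integer matrices of per-genotype
#'   reference/alternate read counts, same shape as \code{codes}.
#' @param locus_tag character vector, one tag per SNP column; defaults to one
#'   tag per SNP (all loci unlinked).
#' @param position integer vector of within-locus site positions; defaults to 1.
#' @return An object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(codes, ref_depth = NULL, alt_depth = NULL,
                        locus_tag = NULL, position = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("ind_%03d", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("snp_%05d", seq_len(ncol(codes)))
  if (is.null(locus_tag)) locus_tag <- colnames(codes)
  if (is.null(position)) position <- rep(1L, ncol(codes))
  bad <- codes[!is.na(codes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  for (d in list(ref_depth, alt_depth))
    if (!is.null(d) && !all(dim(d) == dim(codes)))
      stop("depth matrices must match the genotype matrix shape")
  if (length(locus_tag) != ncol(codes) || length(position) != ncol(codes))
    stop("locus_tag and position must have one entry per SNP column")
  structure(list(codes = codes, ref_depth = ref_depth, alt_depth = alt_depth,
                 locus_tag = as.character(locus_tag),
                 position = as.integer(position)),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%d locus tags)%s\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$locus_tag)),
              if (is.null(x$ref_depth)) "" else ", with read depths"))
  invisible(x)
}

#' @rdname geno_matrix
#' @param x object to test / subset
#' @export
is_geno_matrix <- function(x) inherits(x, "geno_matrix")

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param x a \code{geno_matrix}
#' @param i,j individual / SNP index (any standard matrix index)
#' @param ... unused
#' @param drop ignored; the result is always a \code{geno_matrix}
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$codes))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  jj <- setNames(seq_len(ncol(x$codes)), colnames(x$codes))[j]
  geno_matrix(x$codes[i, j, drop = FALSE], sub(x$ref_depth), sub(x$alt_depth),
              x$locus_tag[jj], x$position[jj])
}

# --- internal per-locus helpers (non-missing genotypes only) ---

geno_allele_freq <- function(g) {
  # alternate-allele frequency per SNP
  colMeans(g$codes, na.rm = TRUE) / 2
}

geno_maf <- function(g) {
  p <- geno_allele_freq(g)
  pmin(p, 1 - p)
}

geno_mac <- function(g) {
  # minor allele count over non-missing genotypes
  alt <- colSums(g$codes, na.rm = TRUE)
  n2 <- 2L * colSums(!is.na(g$codes))
  pmin(alt, n2 - alt)
}

geno_missing_by_locus <- function(g) colMeans(is.na(g$codes))
geno_missing_by_ind <- function(g) rowMeans(is.na(g$codes))
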