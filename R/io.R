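#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCFv4.2 with one record per SNP: CHROM = locus tag,
#' POS = within-locus position, GT (unphased) and, when depths are present,
#' AD (ref,alt) per genotype.
#'
#' @param g a \code{\link{geno_matrix}}
#' @param path output file
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=invadepop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$codes)), collapse = "\t")), con)
  if (ncol(g$codes) == 0) return(invisible(path))
  gt_map <- c("0/0", "0/1", "1/1")
  has_ad <- !is.null(g$ref_depth)
  lines <- vapply(seq_len(ncol(g$codes)), function(j) {
    x <- g$codes[, j]
    gt <- ifelse(is.na(x), "./.", gt_map[x + 1L])
    if (has_ad) {
      ad <- paste(g$ref_depth[, j], g$alt_depth[, j], sep = ",")
      ad[is.na(x)] <- ".,."
      gt <- paste(gt, ad, sep = ":")
    }
    paste(c(g$locus_tag[j], g$position[j], colnames(g$codes)[j], "A", "T",
            ".", "PASS", ".", if (has_ad) "GT:AD" else "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT into alternate-allele counts \{0, 1, 2, NA\} and AD (when present)
#' into reference/alternate depth matrices. Multi-allelic records are excluded
#' with a warning giving their count. The CHROM field is used as the locus tag
#' and POS as the within-locus site position, matching RAD-style loci where
#' several SNPs share a tag.
#'
#' @param path VCF file (plain text or gzipped)
#' @return a \code{\link{geno_matrix}}
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    ids <- colnames(v@gt)[-1]
    return(geno_matrix(matrix(integer(0), nrow = length(ids), ncol = 0,
                              dimnames = list(ids, NULL))))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) excluded")
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  alleles <- gsub("[|]", "/", gt)
  code[alleles %in% c("0/0")] <- 0L
  code[alleles %in% c("0/1", "1/0")] <- 1L
  code[alleles %in% c("1/1")] <- 2L
  codes <- t(code)
  snp_id <- fix[keep, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[no_id]
  colnames(codes) <- snp_id
  ref_depth <- alt_depth <- NULL
  fmt <- v@gt[keep, 1]
  if (all(grepl("AD", fmt))) {
    ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
    split_ad <- function(i) {
      parts <- strsplit(ad[, i], ",", fixed = TRUE)
      cbind(suppressWarnings(as.integer(vapply(parts, `[`, "", 1))),
            suppressWarnings(as.integer(vapply(parts, `[`, "", 2))))
    }
    ref_depth <- matrix(NA_integer_, nrow(codes), ncol(codes), dimnames = dimnames(codes))
    alt_depth <- ref_depth
    for (i in seq_len(ncol(ad))) {
      s <- split_ad(i)
      ref_depth[i, ] <- s[, 1]
      alt_depth[i, ] <- s[, 2]
    }
  }
  geno_matrix(codes, ref_depth = ref_depth, alt_depth = alt_depth,
              locus_tag = unname(fix[keep, "CHROM"]),
              position = as.integer(fix[keep, "POS"]))
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns including \code{sample_id} and \code{era};
#' optional columns \code{year}, \code{river_km}, \code{dist_origin_km},
#' \code{direction}, \code{lon}, \code{lat}.
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "era") %in% names(md)))
    stop("metadata must contain sample_id and era columns")
  md
}
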