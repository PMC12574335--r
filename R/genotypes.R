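#' Construct a genotype matrix container
#'
#' Bundles a biallelic dosage matrix (accessions in rows, markers in columns,
#' values 0/1/2 counting alternate alleles, `NA` for missing) with marker map
#' information and optional per-accession group labels.
#'
#' @param dosage Numeric matrix, accessions x markers, entries in
#'   \{0, 1, 2, NA\}. Row names are accession ids, column names marker ids
#'   (generated when absent).
#' @param chrom Character or integer vector of chromosome labels, one per
#'   marker.
#' @param pos Integer vector of 1-based physical positions (bp), strictly
#'   increasing within each chromosome.
#' @param ref,alt Optional allele vectors (single characters); defaults are
#'   "A"/"T".
#' @param groups Optional per-accession labels (crop type or population).
#' @param depth,gq Optional accession x marker matrices of read depth and
#'   genotype quality, used by [filter_markers()] when the corresponding
#'   rules are enabled.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL,
                            groups = NULL, depth = NULL, gq = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (length(chrom) != m || length(pos) != m)
    stop_param("chrom/pos must have one entry per marker")
  if (any(!is.na(dosage) & !(dosage %in% 0:2)))
    stop_param("dosage entries must be 0, 1, 2 or NA")
  pos <- as.integer(pos)
  chrom <- as.character(chrom)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop_param("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("acc%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0(chrom, "_", pos)
  structure(list(
    dosage = dosage,
    chrom = chrom,
    pos = pos,
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("T", m),
    groups = groups,
    depth = depth,
    gq = gq
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "accessions x", ncol(x$dosage),
      "markers on", length(unique(x$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by markers and/or accessions
#'
#' @param genotypes A [genotype_matrix()].
#' @param markers Marker ids, indices or a logical vector.
#' @param accessions Accession ids, indices or a logical vector.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(genotypes, markers = NULL, accessions = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  mi <- if (is.null(markers)) seq_len(ncol(genotypes$dosage)) else {
    if (is.character(markers)) match(markers, colnames(genotypes$dosage)) else which(rep(TRUE, ncol(genotypes$dosage)))[markers]
  }
  ai <- if (is.null(accessions)) seq_len(nrow(genotypes$dosage)) else {
    if (is.character(accessions)) match(accessions, rownames(genotypes$dosage)) else which(rep(TRUE, nrow(genotypes$dosage)))[accessions]
  }
  if (anyNA(mi) || anyNA(ai)) stop_param("unknown marker or accession in subset")
  genotype_matrix(
    genotypes$dosage[ai, mi, drop = FALSE],
    chrom = genotypes$chrom[mi], pos = genotypes$pos[mi],
    ref = genotypes$ref[mi], alt = genotypes$alt[mi],
    groups = if (!is.null(genotypes$groups)) genotypes$groups[ai],
    depth = if (!is.null(genotypes$depth)) genotypes$depth[ai, mi, drop = FALSE],
    gq = if (!is.null(genotypes$gq)) genotypes$gq[ai, mi, drop = FALSE]
  )
}

#' Mean-impute missing dosages per marker
#'
#' @param genotypes A [genotype_matrix()] or plain dosage matrix.
#' @return A numeric dosage matrix without missing values.
#' @export
impute_dosage <- function(genotypes) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else as.matrix(genotypes)
  if (!anyNA(g)) return(g)
  cm <- colMeans(g, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(g), arr.ind = TRUE)
  g[idx] <- cm[idx[, 2]]
  g
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits a sites-by-samples VCF with only the GT field, unphased diploid
#' genotypes, 1-based positions. Missing dosages become `./.`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$dosage
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=rootqg",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(g)), function(j) {
    calls <- gt_code[as.character(g[, j])]
    calls[is.na(calls)] <- "./."
    paste(c(genotypes$chrom[j], genotypes$pos[j], colnames(g)[j],
            genotypes$ref[j], genotypes$alt[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a VCF file into a genotype matrix
#'
#' Parses GT (and DP/GQ when present) from a VCF via \pkg{vcfR}, keeping
#' biallelic SNP records, and codes dosage as the count of alternate alleles.
#'
#' @param path VCF file path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biall <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos[gt %in% c("0/0")] <- 0
  dos[gt %in% c("0/1", "1/0")] <- 1
  dos[gt %in% c("1/1")] <- 2
  dos <- dos[biall, , drop = FALSE]
  dp <- gq <- NULL
  fmt <- v@gt[1, "FORMAT"]
  if (grepl("DP", fmt)) {
    dp <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[biall, , drop = FALSE])
  }
  if (grepl("GQ", fmt)) {
    gq <- t(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)[biall, , drop = FALSE])
  }
  genotype_matrix(
    t(dos),
    chrom = fix[biall, "CHROM"],
    pos = as.integer(fix[biall, "POS"]),
    ref = fix[biall, "REF"], alt = fix[biall, "ALT"],
    depth = dp, gq = gq
  )
}
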