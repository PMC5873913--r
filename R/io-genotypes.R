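#' Genotype matrix container
#'
#' Additive genotype codes (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing) for individuals x markers, plus
#' per-marker metadata (`marker_id, chrom, pos, alleles, gene_context`).
#' `gene_context` is one of exon / intron / downstream / upstream /
#' intergenic and drives neutral-marker selection.
#'
#' @param geno integer matrix, rows = individuals (rownames = ids),
#'   columns = markers (colnames = marker ids); entries in \{0,1,2,NA\}.
#' @param markers data.frame of marker metadata; row order must match
#'   `colnames(geno)`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, markers = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    dg_stop("geno", "geno must have individual rownames and marker colnames")
  if (anyDuplicated(colnames(geno)))
    dg_stop("geno", "duplicate marker id")
  bad <- !(geno %in% c(0, 1, 2, NA))
  if (any(bad)) dg_stop("geno", "genotype codes must be 0/1/2/NA")
  storage.mode(geno) <- "integer"
  if (is.null(markers)) {
    markers <- data.frame(marker_id = colnames(geno), chrom = NA_character_,
                          pos = NA_integer_, alleles = NA_character_,
                          gene_context = NA_character_)
  }
  if (!identical(as.character(markers$marker_id), colnames(geno)))
    dg_stop("geno", "marker metadata does not match genotype columns")
  rownames(markers) <- NULL
  structure(list(geno = geno, markers = markers), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix %d individuals x %d markers>\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# subset helper keeping metadata aligned
subset_genotypes <- function(g, individuals = NULL, markers = NULL) {
  keep_i <- if (is.null(individuals)) rownames(g$geno) else individuals
  keep_m <- if (is.null(markers)) colnames(g$geno) else markers
  genotype_matrix(g$geno[keep_i, keep_m, drop = FALSE],
                  g$markers[match(keep_m, g$markers$marker_id), , drop = FALSE])
}

.gt_code <- function(gt) {
  # "0/1", "1|0", "./." -> additive code; phasing ignored
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1")] <- 2L
  out
}

#' Read biallelic SNP genotypes
#'
#' VCF input is parsed with `VariantAnnotation::readVcf`; GT fields are
#' recoded additively (0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA;
#' phasing ignored). Multiallelic records are skipped with a warning and
#' counted. CSV input is an individuals x markers numeric matrix (first
#' column = individual id) with an optional sidecar marker metadata CSV
#' (`marker_id,chrom,pos,alleles,gene_context`).
#'
#' @param path genotype file path.
#' @param format `"vcf"` or `"csv"`.
#' @param metadata_path marker metadata CSV (csv format only; optional).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "csv"),
                           metadata_path = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    vcf <- VariantAnnotation::readVcf(path)
    alt <- VariantAnnotation::alt(vcf)
    n_alt <- S4Vectors::elementNROWS(alt)
    multi <- n_alt > 1L
    if (any(multi)) {
      dg_warn("vcf", sum(multi), " multiallelic record(s) skipped")
      vcf <- vcf[!multi, ]
    }
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) dg_stop("vcf", "VCF has no GT field")
    codes <- apply(gt, 2, .gt_code)
    if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(gt),
                                             dimnames = dimnames(gt))
    geno <- t(codes)  # individuals x markers
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt1 <- vapply(as.list(VariantAnnotation::alt(vcf)),
                   function(a) as.character(a)[1], character(1))
    info <- VariantAnnotation::info(vcf)
    ctx <- if (!is.null(info$GCTX)) as.character(info$GCTX) else NA_character_
    markers <- data.frame(marker_id = rownames(gt),
                          chrom = as.character(GenomeInfoDb::seqnames(rr)),
                          pos = BiocGenerics::start(rr),
                          alleles = paste0(ref, "/", alt1),
                          gene_context = ctx)
    colnames(geno) <- markers$marker_id
    if (anyDuplicated(colnames(geno))) dg_stop("vcf", "duplicate marker id")
    return(genotype_matrix(geno, markers))
  }
  d <- data.table::fread(path, na.strings = c("", "NA"), data.table = FALSE)
  ids <- as.character(d[[1]])
  geno <- as.matrix(d[, -1, drop = FALSE])
  rownames(geno) <- ids
  markers <- NULL
  if (!is.null(metadata_path)) {
    markers <- data.table::fread(metadata_path, na.strings = c("", "NA"),
                                 data.table = FALSE)
    markers <- markers[match(colnames(geno), markers$marker_id), , drop = FALSE]
  }
  genotype_matrix(geno, markers)
}

#' Write genotypes as minimal VCF 4.2 text
#'
#' Each marker becomes one biallelic record; additive codes map back to GT
#' (`0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`, `NA -> ./.`). The `gene_context`
#' annotation is carried in the INFO field as `GCTX=`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=GCTX,Number=1,Type=String,Description=\"Gene context of the SNP\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  ids <- rownames(g$geno)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  m <- g$markers
  al <- strsplit(ifelse(is.na(m$alleles), "A/G", m$alleles), "/")
  for (j in seq_len(ncol(g$geno))) {
    codes <- g$geno[, j]
    gt <- ifelse(is.na(codes), "./.", gt_map[as.character(codes)])
    info <- if (is.na(m$gene_context[[j]])) "." else
      paste0("GCTX=", m$gene_context[[j]])
    chrom <- if (is.na(m$chrom[[j]])) "1" else m$chrom[[j]]
    pos <- if (is.na(m$pos[[j]])) j else m$pos[[j]]
    writeLines(paste(c(chrom, pos, m$marker_id[[j]], al[[j]][1], al[[j]][2],
                       ".", "PASS", info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotypes and marker metadata as CSV
#'
#' @param g a `genotype_matrix`.
#' @param path genotype CSV path (first column `individual_id`).
#' @param metadata_path marker metadata CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(g, path, metadata_path) {
  d <- data.frame(individual_id = rownames(g$geno), g$geno,
                  check.names = FALSE)
  data.table::fwrite(d, path, na = "NA")
  data.table::fwrite(g$markers, metadata_path, na = "NA")
  invisible(path)
}

#' Read / write an admixture (Q) matrix CSV
#'
#' Header `individual_id,Q1..QK`; rows must sum to 1 within 1e-9 and entries
#' lie in [0, 1].
#'
#' @param path CSV path.
#' @return numeric matrix with individual rownames and K columns.
#' @export
read_q_matrix <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  q <- as.matrix(d[, -1, drop = FALSE])
  rownames(q) <- as.character(d[[1]])
  if (any(q < -1e-12 | q > 1 + 1e-12))
    dg_stop("qmatrix", "admixture proportions must be in [0, 1]")
  if (any(abs(rowSums(q) - 1) > 1e-9))
    dg_stop("qmatrix", "Q rows must sum to 1 within 1e-9")
  q
}

#' @rdname read_q_matrix
#' @param q numeric Q matrix with rownames.
#' @export
write_q_matrix <- function(q, path) {
  d <- data.frame(individual_id = rownames(q), q)
  names(d)[-1] <- paste0("Q", seq_len(ncol(q)))
  data.table::fwrite(d, path)
  invisible(path)
}

#' Read / write a square kinship matrix CSV (id header)
#'
#' @param path CSV path; first column and header carry individual ids.
#' @return symmetric numeric matrix.
#' @export
read_kinship_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  k <- as.matrix(d[, -1, drop = FALSE])
  rownames(k) <- as.character(d[[1]])
  if (!identical(rownames(k), colnames(k)))
    dg_stop("kinship", "kinship row/column ids differ")
  k
}

#' @rdname read_kinship_csv
#' @param k square matrix with dimnames.
#' @export
write_kinship_csv <- function(k, path) {
  d <- data.frame(individual_id = rownames(k), k, check.names = FALSE)
  data.table::fwrite(d, path)
  invisible(path)
}

#' Read / write a trait table CSV
#'
#' First column `individual_id`; remaining columns are named traits, missing
#' allowed.
#'
#' @param path CSV path.
#' @return data.frame with rownames = individual ids.
#' @export
read_trait_table <- function(path) {
  d <- data.table::fread(path, na.strings = c("", "NA"), data.table = FALSE)
  if (anyDuplicated(names(d))) dg_stop("traits", "duplicate trait column name")
  rownames(d) <- as.character(d[[1]])
  d[[1]] <- NULL
  d
}

#' @rdname read_trait_table
#' @param traits data.frame of traits with individual rownames.
#' @export
write_trait_table <- function(traits, path) {
  d <- data.frame(individual_id = rownames(traits), traits,
                  check.names = FALSE)
  data.table::fwrite(d, path, na = "NA")
  invisible(path)
}
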