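# Readers and writers for the package's plain-text interchange formats.
# Coordinates are 1-based inclusive throughout (VCF convention).

#' Write a recoded genotype matrix as TSV
#'
#' Rows are segregants, columns marker ids, values -1/1/NA. The per-segregant
#' cross labels go to a sample-sheet sidecar (<path>.samples.tsv).
#'
#' @param G a \code{geno_matrix}.
#' @param path output TSV path.
#' @export
write_genotypes_tsv <- function(G, path) {
  df <- data.frame(segregant = rownames(G$values), G$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- data.frame(segregant = rownames(G$values),
                   cross = as.character(G$cross))
  utils::write.table(ss, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recoded genotype TSV written by \code{write_genotypes_tsv}
#'
#' @param path TSV path; the sample sheet <path>.samples.tsv supplies cross
#'   labels (or pass \code{cross}).
#' @param markers optional marker data frame to attach.
#' @param cross optional cross labels overriding the sidecar.
#' @return a \code{geno_matrix}.
#' @export
read_genotypes_tsv <- function(path, markers = NULL, cross = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df[[1]]
  if (is.null(cross)) {
    ss_path <- paste0(path, ".samples.tsv")
    if (!file.exists(ss_path))
      stop("sample sheet not found: ", ss_path)
    ss <- utils::read.table(ss_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cross <- ss$cross[match(rownames(V), ss$segregant)]
  }
  structure(list(values = V, cross = as.factor(cross), markers = markers,
                 ref_hap = NULL, design = NULL),
            class = "geno_matrix")
}

#' Write the marker map as TSV
#' @param markers marker data frame.
#' @param path output path.
#' @export
write_marker_map <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a marker map TSV
#' @param path input path.
#' @return marker data frame.
#' @export
read_marker_map <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write phenotypes in long format (segregant, cross, replicate, value)
#' @param pheno long data frame (e.g. \code{sim_pheno$pheno}).
#' @param path output path.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype TSV
#' @param path input path.
#' @return data frame with segregant, cross, replicate, value.
#' @export
read_phenotypes_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write the simulation ground truth as JSON
#' @param truth a \code{sim_truth}.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(qtl = truth$qtl, epistasis = truth$epistasis,
                            seed = truth$seed,
                            coupling_tau = truth$coupling_tau,
                            sign_bias_recent = truth$sign_bias_recent),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write genotypes as a haploid VCF
#'
#' One sample per segregant, GT 0 for the reference-parent allele (-1 in the
#' recoded matrix), 1 otherwise, '.' where the marker does not segregate in
#' the segregant's cross.
#'
#' @param G a \code{geno_matrix} with a marker map.
#' @param path output .vcf path (uncompressed).
#' @export
write_genotypes_vcf <- function(G, path) {
  mk <- G$markers
  if (is.null(mk)) stop("marker map required to write VCF")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rrqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G$values)), collapse = "\t"),
             con)
  gt <- t(G$values)  # markers x segregants
  gt_chr <- matrix(".", nrow(gt), ncol(gt))
  gt_chr[gt == -1] <- "0"
  gt_chr[gt == 1] <- "1"
  lines <- paste(paste0("chr", mk$chrom), mk$pos_bp, mk$id,
                 mk$ref_allele, mk$alt_allele, ".", "PASS", ".", "GT",
                 apply(gt_chr, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from VCF or TSV
#'
#' VCF input must contain haploid biallelic records; a multiallelic record
#' raises an error naming its position. Cross labels come from a sample
#' sheet (TSV: segregant, cross).
#'
#' @param path input file.
#' @param format "vcf" or "tsv".
#' @param sample_sheet path to the sample sheet (TSV), or NULL for the TSV
#'   sidecar convention.
#' @param markers optional marker data frame to attach.
#' @return a \code{geno_matrix}.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           sample_sheet = NULL, markers = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    cross <- NULL
    if (!is.null(sample_sheet)) {
      ss <- utils::read.table(sample_sheet, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      cross <- ss$cross
    }
    return(read_genotypes_tsv(path, markers = markers, cross = cross))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multiallelic record at position ",
         vcfR::getPOS(v)[which(multi)[1]])
  gt <- vcfR::extract.gt(v)
  if (any(grepl("[/|]", gt), na.rm = TRUE))
    stop("diploid genotype record found; haploid GT required")
  V <- t(ifelse(gt == "0", -1, ifelse(gt == "1", 1, NA_real_)))
  colnames(V) <- vcfR::getID(v)
  cross <- rep("X01", nrow(V))
  if (!is.null(sample_sheet)) {
    ss <- utils::read.table(sample_sheet, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cross <- ss$cross[match(rownames(V), ss$segregant)]
  }
  structure(list(values = V, cross = as.factor(cross), markers = markers,
                 ref_hap = NULL, design = NULL),
            class = "geno_matrix")
}

#' Save a kinship matrix as TSV with segregant ids
#' @param K kinship matrix.
#' @param path output path.
#' @export
write_kinship_tsv <- function(K, path) {
  df <- data.frame(id = rownames(K) %||% seq_len(nrow(K)), unclass(K),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
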