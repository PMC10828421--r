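#' Read genotypes from VCF or dosage TSV
#'
#' VCF v4.2 input is parsed with \pkg{vcfR}; dosage is the ALT-allele count
#' from `GT` (or the `DS` field when `GT` is absent), `./.` becomes missing.
#' Only biallelic diploid records are supported. The dosage TSV format has
#' one row per variant with columns `variant_id`, `chrom`, `pos`, `ref`,
#' `alt` followed by one numeric column per sample; [write_dosage_tsv()]
#' round-trips it losslessly.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @param multiallelic `"error"` or `"skip"` for VCF records with more than
#'   one ALT allele.
#' @return a [geno_matrix()] with QC statistics populated.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                           multiallelic = c("error", "skip")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path, multiallelic) else read_dosage_tsv(path)
}

read_genotypes_vcf <- function(path, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "error") {
      abort(sprintf("multiallelic record at line for %s:%s; use multiallelic = 'skip'",
                    fix$CHROM[which(multi)[1]], fix$POS[which(multi)[1]]))
    }
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  has_gt <- any(grepl("GT", vcf@gt[, "FORMAT"]))
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- gt_to_dosage(gt)
  } else {
    ds <- vcfR::extract.gt(vcf, element = "DS")
    if (all(is.na(ds))) abort("VCF has neither GT nor DS fields")
    dos <- apply(ds, 2, as.numeric)
    rownames(dos) <- rownames(ds)
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble::tibble(
    variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  d <- t(dos)
  colnames(d) <- variants$variant_id
  geno_matrix(d, variants)
}

gt_to_dosage <- function(gt) {
  parse_one <- function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_real_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (length(alleles) != 2L) {
      abort(sprintf("non-diploid genotype '%s' (ploidy != 2)", x))
    }
    if (any(alleles == ".")) return(NA_real_)
    sum(as.numeric(alleles) > 0)
  }
  out <- vapply(gt, parse_one, numeric(1))
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(tab))) {
    abort(sprintf("malformed dosage TSV header: expected columns %s",
                  paste(meta_cols, collapse = ", ")))
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  d <- t(as.matrix(tab[sample_cols]))
  colnames(d) <- tab$variant_id
  geno_matrix(d, tab[meta_cols])
}

#' Write genotypes as a dosage TSV
#' @param g a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  tab <- dplyr::bind_cols(
    g$variants[c("variant_id", "chrom", "pos", "ref", "alt")],
    tibble::as_tibble(t(g$dosage))
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Write hard-called genotypes as VCF v4.2
#'
#' Dosages must be in \{0, 1, 2\} or missing; fractional dosages cannot be
#' represented as GT calls.
#'
#' @param g a [geno_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  d <- g$dosage
  if (!all(d[!is.na(d)] %in% c(0, 1, 2))) {
    abort("write_vcf requires hard-called dosages in {0, 1, 2}")
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  ), con)
  v <- g$variants
  for (j in seq_len(ncol(d))) {
    calls <- ifelse(is.na(d[, j]), "./.", gt_code[as.character(d[, j])])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a MetaPhlAn-style relative abundance TSV
#'
#' First column is the clade label (pipe-separated `k__|p__|...|s__` lineage),
#' remaining columns are samples. Values in percent are auto-detected from
#' the column sums and converted to fractions.
#'
#' @param path file path.
#' @return an [abund_table()] (samples in rows).
#' @export
read_abundance <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  clade <- tab[[1]]
  vals <- as.matrix(tab[-1])
  if (max(colSums(vals), na.rm = TRUE) > 1.5) vals <- vals / 100
  features <- tibble::tibble(
    feature_id = make.unique(sub(".*\\|", "", clade)),
    clade_name = clade
  )
  a <- t(vals)
  colnames(a) <- features$feature_id
  abund_table(a, features)
}

#' Write an abundance table in MetaPhlAn style
#' @param a an [abund_table()].
#' @param path output path.
#' @param percent write values in percent (default `TRUE`, the MetaPhlAn
#'   convention).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(a, path, percent = TRUE) {
  vals <- t(a$values)
  if (percent) vals <- vals * 100
  tab <- dplyr::bind_cols(
    tibble::tibble(clade_name = a$features$clade_name %||% a$features$feature_id),
    tibble::as_tibble(vals)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a covariate or trait TSV
#'
#' Tab-separated, header row, `sample_id` first column, numeric columns after.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_sample_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "sample_id") {
    abort("first column of a sample table must be `sample_id`")
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab
}
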