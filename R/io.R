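#' Write a genotype matrix as a TSV dosage table
#'
#' Variants in rows: the metadata columns (`variant_id`, `chrom`, `pos`,
#' `ref`, `alt`, plus any extra variant columns) followed by one dosage
#' column per sample. Stratum labels are stored in a `#stratum:` header
#' comment so the table round-trips.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output file.
#' @export
write_dosage_tsv <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#stratum:\t",
                    paste(geno$samples$stratum, collapse = "\t")), con)
  tab <- cbind(geno$variants, as.data.frame(t(geno$dosages)))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV dosage table written by [write_dosage_tsv()]
#'
#' @param path Input file.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  first <- readLines(path, n = 1)
  strata <- NULL
  if (startsWith(first, "#stratum:"))
    strata <- strsplit(first, "\t")[[1]][-1]
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_cols <- which(names(tab) %in% c("variant_id", "chrom", "pos", "ref",
                                       "alt", "block", "freq_EA", "freq_AA"))
  variants <- tab[, meta_cols, drop = FALSE]
  variants$chrom <- as.character(variants$chrom)
  dos <- t(as.matrix(tab[, -meta_cols, drop = FALSE]))
  ids <- rownames(dos)
  if (is.null(strata)) strata <- rep("EA", nrow(dos))
  genotype_matrix(dos, variants,
                  data.frame(sample_id = ids, stratum = strata,
                             stringsAsFactors = FALSE))
}

#' Write a genotype matrix as a minimal VCF with a DS FORMAT field
#'
#' @param geno A [genotype_matrix()].
#' @param path Output `.vcf` file (uncompressed).
#' @export
write_vcf_dosage <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$samples$sample_id),
                     collapse = "\t")), con)
  v <- geno$variants
  body <- vapply(seq_len(nrow(v)), function(i) {
    ds <- geno$dosages[, i]
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "DS",
            ifelse(is.na(ds), ".", formatC(ds, format = "g"))),
          collapse = "\t")
  }, "")
  writeLines(body, con)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Uses `vcfR` when available; falls back to a reader for the plain
#' single-field VCFs written by [write_vcf_dosage()].
#'
#' @param path `.vcf` file.
#' @param strata Optional stratum labels per sample (defaults to "EA").
#' @return A [genotype_matrix()].
#' @export
read_vcf_dosage <- function(path, strata = NULL) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                           pos = as.integer(fix$POS), ref = fix$REF,
                           alt = fix$ALT, stringsAsFactors = FALSE)
    dos <- t(ds)
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    cols <- strsplit(hdr, "\t")[[1]]
    ids <- cols[-(1:9)]
    body <- strsplit(lines[!startsWith(lines, "#")], "\t")
    variants <- data.frame(
      variant_id = vapply(body, `[`, "", 3),
      chrom = vapply(body, `[`, "", 1),
      pos = as.integer(vapply(body, `[`, "", 2)),
      ref = vapply(body, `[`, "", 4), alt = vapply(body, `[`, "", 5),
      stringsAsFactors = FALSE)
    dos <- matrix(unlist(lapply(body, function(x)
      suppressWarnings(as.numeric(x[-(1:9)])))),
      nrow = length(ids))  # samples x variants, column per variant
    rownames(dos) <- ids
  }
  if (is.null(strata)) strata <- rep("EA", nrow(dos))
  genotype_matrix(dos, variants,
                  data.frame(sample_id = rownames(dos) %||% colnames(dos) %||%
                               paste0("S", seq_len(nrow(dos))),
                             stratum = strata, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read external summary statistics with a column mapping
#'
#' @param path TSV file.
#' @param mapping Named list mapping canonical names (`variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `p`, `n`) to the file's column names; unmapped canonical names are
#'   assumed to match literally.
#' @return Summary-statistics `data.frame` in canonical column order.
#' @export
read_sumstats_tsv <- function(path, mapping = list()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  canon <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "p", "n")
  out <- list()
  for (nm in canon) {
    src <- mapping[[nm]] %||% nm
    if (!src %in% names(tab))
      stop("summary-statistics file lacks column '", src, "' for ", nm)
    out[[nm]] <- tab[[src]]
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$chrom <- as.character(out$chrom)
  if ("stratum" %in% names(tab)) out$stratum <- tab$stratum
  out
}

#' Write summary statistics as TSV
#'
#' @param stats Summary-statistics `data.frame`.
#' @param path Output file.
#' @export
write_sumstats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
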