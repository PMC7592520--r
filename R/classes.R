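#' Genotype dosage matrix with variant and sample metadata
#'
#' The central genotype container: an `n_samples x n_variants` matrix of
#' imputed dosages in `[0, 2]` (expected alternate-allele counts), together
#' with a variant table (chromosome, 1-based position, REF/ALT alleles,
#' per-stratum generating frequencies when known) and a sample table
#' (ancestry stratum labels).
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#'   Row names are sample ids, column names variant ids. `NA` marks a
#'   missing dosage.
#' @param variants `data.frame` with at least `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`; one row per column of `dosages`, in the same order.
#' @param samples `data.frame` with at least `sample_id` and `stratum`; one
#'   row per row of `dosages`, in the same order.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  stopifnot(is.numeric(dosages) || ncol(dosages) == 0L)
  if (nrow(variants) != ncol(dosages))
    stop("variants table must have one row per dosage column")
  if (nrow(samples) != nrow(dosages))
    stop("samples table must have one row per dosage row")
  need_v <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need_v, names(variants))
  if (length(miss)) stop("variants table missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "stratum") %in% names(samples)))
    stop("samples table needs sample_id and stratum columns")
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  colnames(dosages) <- variants$variant_id
  rownames(dosages) <- samples$sample_id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 samples  = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  tab <- table(x$samples$stratum)
  cat("strata:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param geno A [genotype_matrix()].
#' @param samples,variants Logical, integer or character index into the
#'   sample / variant axis; `NULL` keeps everything.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(geno, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(geno$dosages)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(geno$dosages)) else variants
  if (is.character(si)) si <- match(si, geno$samples$sample_id)
  if (is.character(vi)) vi <- match(vi, geno$variants$variant_id)
  genotype_matrix(geno$dosages[si, vi, drop = FALSE],
                  geno$variants[vi, , drop = FALSE],
                  geno$samples[si, , drop = FALSE])
}

#' Observed alternate-allele frequencies
#'
#' @param geno A [genotype_matrix()].
#' @return Named numeric vector, mean dosage / 2 per variant (missing
#'   dosages excluded).
#' @export
allele_freqs <- function(geno) {
  colMeans(geno$dosages, na.rm = TRUE) / 2
}

#' Population specification for the synthetic genotype generator
#'
#' Describes a two-stratum population as a set of linkage blocks. Variants
#' within a block share a latent exchangeable Gaussian factor, so their
#' pairwise genotype correlation is tunable; variants in different blocks
#' are independent. Per-variant base frequencies are drawn uniformly from
#' `allele_freq_range` and then perturbed per stratum by a Balding-Nichols
#' draw governed by `fst_divergence`.
#'
#' @param n_blocks Number of independent linkage blocks.
#' @param block_size Variants per block.
#' @param allele_freq_range Length-2 numeric strictly inside (0, 1): range
#'   of ancestral allele frequencies.
#' @param within_block_r2 Target mean pairwise genotype r-squared within a
#'   block, in `[0, 1)`.
#' @param fst_divergence Balding-Nichols F parameter (>= 0) controlling
#'   allele-frequency divergence between the two strata; 0 means shared
#'   frequencies.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_blocks = 20L, block_size = 10L,
                            allele_freq_range = c(0.05, 0.5),
                            within_block_r2 = 0.4,
                            fst_divergence = 0.1) {
  n_blocks <- as.integer(n_blocks); block_size <- as.integer(block_size)
  if (block_size <= 0L || n_blocks <= 0L)
    stop("n_blocks and block_size must be positive")
  if (length(allele_freq_range) != 2L ||
      allele_freq_range[1] <= 0 || allele_freq_range[2] >= 1 ||
      allele_freq_range[1] > allele_freq_range[2])
    stop("allele_freq_range must be an ordered interval strictly inside (0, 1)")
  if (within_block_r2 < 0 || within_block_r2 >= 1)
    stop("within_block_r2 must lie in [0, 1)")
  if (fst_divergence < 0) stop("fst_divergence must be >= 0")
  structure(list(n_blocks = n_blocks, block_size = block_size,
                 n_variants = n_blocks * block_size,
                 allele_freq_range = as.numeric(allele_freq_range),
                 within_block_r2 = within_block_r2,
                 fst_divergence = fst_divergence),
            class = "population_spec")
}

#' Trait architecture specification
#'
#' @param name Trait label (column name in the cohort table).
#' @param kind `"quantitative"` or `"binary"`.
#' @param n_causal Number of causal variants.
#' @param h2 Narrow-sense heritability on the trait / liability scale,
#'   in `[0, 1]`.
#' @param prevalence Population prevalence in (0, 1); required for binary
#'   traits, ignored otherwise.
#' @param covariate_effects Named numeric vector of linear covariate effects
#'   (names are cohort-table columns), applied on the standardized trait /
#'   liability scale.
#' @param ancestry_effect_corr Correlation of causal effect sizes between
#'   the two strata, in `[-1, 1]`; 1 means identical effects.
#'
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name, kind = c("quantitative", "binary"),
                       n_causal = 20L, h2 = 0.3, prevalence = NULL,
                       covariate_effects = numeric(0),
                       ancestry_effect_corr = 1) {
  kind <- match.arg(kind)
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (kind == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("binary traits require prevalence in (0, 1)")
  } else prevalence <- NULL
  if (abs(ancestry_effect_corr) > 1)
    stop("ancestry_effect_corr must lie in [-1, 1]")
  structure(list(name = name, kind = kind, n_causal = as.integer(n_causal),
                 h2 = h2, prevalence = prevalence,
                 covariate_effects = covariate_effects,
                 ancestry_effect_corr = ancestry_effect_corr),
            class = "trait_spec")
}

#' Polygenic risk score model
#'
#' A set of (variant, effect allele, weight) triples with the derivation
#' p-value threshold and LD-pruning provenance.
#'
#' @param trait Trait label the score targets.
#' @param source Label of the summary-statistics source.
#' @param threshold P-value inclusion cutoff used at derivation.
#' @param weights `data.frame` with `variant_id`, `effect_allele`, `beta`
#'   and optionally `source_p`, `eaf`.
#' @param pruning List with `r2_cutoff` and `panel` label.
#' @return An object of class `prs_model`.
#' @export
prs_model <- function(trait, source, threshold, weights,
                      pruning = list(r2_cutoff = 0.5, panel = "unspecified")) {
  stopifnot(all(c("variant_id", "effect_allele", "beta") %in% names(weights)))
  structure(list(trait = trait, source = source, threshold = threshold,
                 weights = as.data.frame(weights, stringsAsFactors = FALSE),
                 pruning = pruning, n_variants = nrow(weights)),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model '%s' (source %s): %d variants, p < %g, pruned at r2 %s\n",
              x$trait, x$source, x$n_variants, x$threshold,
              format(x$pruning$r2_cutoff)))
  invisible(x)
}

# internal: derive a reproducible child seed from (seed, tag); kept < 2^31
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 69091 + h * 101 + 1L) %% 2147483629)
}

# internal: run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
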