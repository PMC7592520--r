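#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; invariant under
#' permutation of the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))
  out[ok][o] <- adj
  out
}

#' Cohort-specific variant calls by dual p-thresholds and CI separation
#'
#' A variant is called cohort-specific when (1) its cohort association p is
#' below `p_cohort`, (2) its reference p is at or above `p_reference`, and
#' (3) the two `ci_level` confidence intervals for the effect
#' (`beta +/- z * se`) are disjoint — intervals sharing even an endpoint
#' count as overlapping. Both sources must be allele-harmonized and on a
#' comparable (standardized) effect scale.
#'
#' @param cohort,reference Summary-statistics `data.frame`s with
#'   `variant_id`, `beta`, `se`, `p`.
#' @param p_cohort,p_reference,ci_level Thresholds (defaults 0.01, 0.05,
#'   0.99).
#' @return `data.frame` per cohort variant: the paired stats, the interval
#'   bounds, logical `specific`, and a `reasons` string listing failed
#'   criteria (or `"absent_from_reference"` for uncallable variants).
#' @export
specific_variant_filter <- function(cohort, reference, p_cohort = 0.01,
                                    p_reference = 0.05, ci_level = 0.99) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  j <- match(cohort$variant_id, reference$variant_id)
  out <- data.frame(variant_id = cohort$variant_id,
                    beta_cohort = cohort$beta, se_cohort = cohort$se,
                    p_cohort = cohort$p,
                    beta_ref = reference$beta[j], se_ref = reference$se[j],
                    p_ref = reference$p[j], stringsAsFactors = FALSE)
  out$ci_cohort_lo <- out$beta_cohort - z * out$se_cohort
  out$ci_cohort_hi <- out$beta_cohort + z * out$se_cohort
  out$ci_ref_lo <- out$beta_ref - z * out$se_ref
  out$ci_ref_hi <- out$beta_ref + z * out$se_ref
  reasons <- character(nrow(out))
  callable <- !is.na(j) & !is.na(out$p_ref) & !is.na(out$p_cohort)
  pass_c <- callable & out$p_cohort < p_cohort
  pass_r <- callable & out$p_ref >= p_reference
  disjoint <- callable & (out$ci_cohort_lo > out$ci_ref_hi |
                            out$ci_cohort_hi < out$ci_ref_lo)
  for (i in seq_len(nrow(out))) {
    if (!callable[i]) { reasons[i] <- "absent_from_reference"; next }
    r <- character(0)
    if (!pass_c[i]) r <- c(r, "cohort_p")
    if (!pass_r[i]) r <- c(r, "reference_p")
    if (!disjoint[i]) r <- c(r, "ci_overlap")
    reasons[i] <- if (length(r)) paste(r, collapse = ",") else "specific"
  }
  out$specific <- pass_c & pass_r & disjoint
  out$reasons <- reasons
  out
}

# pairwise dosage r2 between one variant and a set, from a genotype panel
panel_r2 <- function(geno, id1, ids2) {
  j1 <- match(id1, geno$variants$variant_id)
  j2 <- match(ids2, geno$variants$variant_id)
  x <- geno$dosages[, j1]
  suppressWarnings(
    as.numeric(stats::cor(x, geno$dosages[, j2, drop = FALSE],
                          use = "pairwise.complete.obs"))^2)
}

#' Greedy clumping of calls into independent loci
#'
#' Visits variants by ascending cohort p (ties broken by position, then
#' id). A variant joins an existing locus when it lies within
#' `window_kb` of that locus's index variant on the same chromosome and
#' has r-squared > `r2_max` with it; otherwise it founds a new locus with
#' itself as index.
#'
#' @param calls `data.frame` with `variant_id` and `p` (e.g. the specific
#'   calls with their cohort p).
#' @param geno Genotype panel for LD ([genotype_matrix()]) containing the
#'   call variants.
#' @param r2_max LD threshold (default 0.5).
#' @param window_kb Window around the index variant in kb (default 500).
#' @return `data.frame`: `variant_id`, `p`, `locus` (integer),
#'   `is_index`.
#' @export
independent_loci <- function(calls, geno, r2_max = 0.5, window_kb = 500) {
  vi <- match(calls$variant_id, geno$variants$variant_id)
  if (anyNA(vi)) stop("calls contain variants absent from the panel")
  d <- data.frame(variant_id = calls$variant_id, p = calls$p,
                  chrom = geno$variants$chrom[vi],
                  pos = geno$variants$pos[vi], stringsAsFactors = FALSE)
  d <- d[order(d$p, d$pos, d$variant_id), , drop = FALSE]
  idx_id <- character(0); idx_chrom <- character(0); idx_pos <- numeric(0)
  locus <- integer(nrow(d))
  for (i in seq_len(nrow(d))) {
    assigned <- 0L
    near <- which(idx_chrom == d$chrom[i] &
                    abs(idx_pos - d$pos[i]) <= window_kb * 1000)
    for (k in near) {
      if (panel_r2(geno, d$variant_id[i], idx_id[k]) > r2_max) {
        assigned <- k; break
      }
    }
    if (assigned == 0L) {
      idx_id <- c(idx_id, d$variant_id[i])
      idx_chrom <- c(idx_chrom, d$chrom[i])
      idx_pos <- c(idx_pos, d$pos[i])
      assigned <- length(idx_id)
    }
    locus[i] <- assigned
  }
  d$locus <- locus
  d$is_index <- d$variant_id %in% idx_id
  rownames(d) <- NULL
  d
}

#' Fisher over-representation test against gene-set libraries
#'
#' One-sided (enrichment) Fisher exact test per gene set on the 2x2 table
#' of hit/non-hit by in-set/out-of-set within the supplied universe, with
#' Benjamini-Hochberg adjustment across sets. Depletion is not flagged.
#'
#' @param hit_genes Character vector, a subset of `universe`.
#' @param library Named list of gene sets (as from [read_gmt()]).
#' @param universe Character vector of all testable genes.
#' @return `data.frame` sorted by adjusted p: `set`, `n_hit_in`,
#'   `n_hit_out`, `n_miss_in`, `n_miss_out`, `odds_ratio`, `p`,
#'   `fdr_adjusted_p`.
#' @export
gene_set_enrichment <- function(hit_genes, library, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(hit_genes %in% universe))
    stop("hit_genes must be a subset of the universe")
  hit_genes <- unique(hit_genes)
  universe <- unique(universe)
  rows <- lapply(names(library), function(nm) {
    set <- intersect(library[[nm]], universe)
    a <- length(intersect(hit_genes, set))
    b <- length(hit_genes) - a
    cc <- length(set) - a
    d <- length(universe) - a - b - cc
    p <- if (!length(set)) 1 else
      stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                         alternative = "greater")$p.value
    or <- if (b * cc == 0) {
      if (a * d == 0) 0 else Inf
    } else (a * d) / (b * cc)
    data.frame(set = nm, n_hit_in = a, n_hit_out = b, n_miss_in = cc,
               n_miss_out = d, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_adjusted_p <- bh_fdr(out$p)
  out <- out[order(out$fdr_adjusted_p, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set library
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' eSNP enrichment among cohort-specific variants
#'
#' Per experimental condition: (1) drop variants strongly associated in
#' the reference GWAS (`p < exclude_ref_p`), (2) LD-prune the remainder at
#' r-squared > `prune_r2` (priority by ascending cohort p), (3) compare
#' the eSNP proportion among the surviving cohort-specific variants to the
#' remaining non-specific variants with a 1-df chi-squared test without
#' continuity correction (falling back to Fisher's exact test, flagged,
#' when a table cell is empty). Benjamini-Hochberg adjustment is applied
#' across conditions.
#'
#' @param calls Output of [specific_variant_filter()].
#' @param all_stats Cohort summary statistics for all tested variants
#'   (supplies cohort p for the pruning priority and the test universe).
#' @param esnp_table Long `data.frame` (`variant_id`, `condition`, `esnp`).
#' @param reference Reference summary statistics (`variant_id`, `p`).
#' @param geno Genotype panel for LD pruning.
#' @param exclude_ref_p Reference-GWAS exclusion threshold (default 1e-6).
#' @param prune_r2 Pruning threshold, removal at r-squared strictly above
#'   it (default 0.2).
#' @return `data.frame` per condition: 2x2 counts (`n_spec_esnp`,
#'   `n_spec_other`, `n_rest_esnp`, `n_rest_other`), `odds_ratio`,
#'   `statistic`, `p`, `fdr_adjusted_p`, `method`.
#' @export
eqtl_enrichment <- function(calls, all_stats, esnp_table, reference, geno,
                            exclude_ref_p = 1e-6, prune_r2 = 0.2) {
  refp <- reference$p[match(all_stats$variant_id, reference$variant_id)]
  pool <- all_stats[is.na(refp) | refp >= exclude_ref_p, , drop = FALSE]
  pruned <- ld_prune(pool[, c("variant_id", "p")], geno,
                     r2_cutoff = prune_r2, strict = TRUE)
  spec_ids <- intersect(calls$variant_id[calls$specific], pruned)
  rest_ids <- setdiff(pruned, spec_ids)
  conds <- unique(esnp_table$condition)
  rows <- lapply(conds, function(cond) {
    et <- esnp_table[esnp_table$condition == cond, , drop = FALSE]
    es <- stats::setNames(et$esnp, et$variant_id)
    a <- sum(es[spec_ids], na.rm = TRUE)
    b <- length(spec_ids) - a
    cc <- sum(es[rest_ids], na.rm = TRUE)
    d <- length(rest_ids) - cc
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (any(tab == 0)) {
      ft <- stats::fisher.test(tab)
      stat <- NA_real_; p <- ft$p.value; method <- "fisher_exact"
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- as.numeric(ct$statistic); p <- ct$p.value; method <- "chisq"
    }
    or <- if (b * cc == 0) NA_real_ else (a * d) / (b * cc)
    data.frame(condition = cond, n_spec_esnp = a, n_spec_other = b,
               n_rest_esnp = cc, n_rest_other = d, odds_ratio = or,
               statistic = stat, p = p, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_adjusted_p <- bh_fdr(out$p)
  out
}
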