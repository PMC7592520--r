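# Hand-built genotype fixtures for unit tests.

# genotype_matrix from a plain dosage matrix (samples x variants)
make_geno <- function(dos, strata = NULL, chrom = NULL, pos = NULL,
                      ref = NULL, alt = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  genotype_matrix(
    dos,
    data.frame(variant_id = sprintf("v%03d", seq_len(m)),
               chrom = chrom %||% rep("1", m),
               pos = pos %||% (seq_len(m) * 1000L),
               ref = ref %||% rep("A", m),
               alt = alt %||% rep("G", m),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               stratum = strata %||% rep("EA", n),
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent binomial genotypes at given allele frequencies
random_geno <- function(n, freqs, seed, strata = NULL) {
  set.seed(seed)
  dos <- sapply(freqs, function(f) stats::rbinom(n, 2, f))
  make_geno(matrix(dos, nrow = n), strata = strata)
}

# brute-force exact HWE p: enumerate all heterozygote counts directly from
# the conditional multinomial probabilities (independent of the package's
# log-space implementation)
hwe_brute <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  prob <- sapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    (factorial(n) / (factorial(hom_r) * factorial(hom_c) * factorial(h))) *
      2^h / (factorial(2 * n) / (factorial(n_rare) * factorial(2 * n - n_rare)))
  })
  obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}
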