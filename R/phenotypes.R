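#' Friedewald estimate of LDL cholesterol
#'
#' `LDL = TC - HDL - TG/5` (all mg/dL). The relation is unreliable at high
#' triglycerides, so `NA` is returned when TG exceeds 400 mg/dL, the
#' standard validity bound.
#'
#' @param tc,hdl,tg Total cholesterol, HDL and triglycerides in mg/dL;
#'   vectors are recycled to a common length.
#' @return Numeric vector of LDL estimates (`NA` where TG > 400 or any
#'   input is missing).
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc < 0, na.rm = TRUE) || any(hdl < 0, na.rm = TRUE) ||
      any(tg < 0, na.rm = TRUE))
    stop("lipid concentrations must be non-negative")
  out <- tc - hdl - tg / 5
  out[!is.na(tg) & tg > 400] <- NA_real_
  out
}

#' Per-sample mean lipid values over repeated draws
#'
#' Averages all available draws per sample. On each draw the LDL used is
#' the directly measured value when present, otherwise the Friedewald
#' estimate; draws where neither resolves contribute nothing to the LDL
#' mean.
#'
#' @param records Lipid panel `data.frame` with `sample_id`,
#'   `total_cholesterol`, `hdl`, `triglycerides` and optionally
#'   `ldl_direct`.
#' @return `data.frame` with one row per sample: `sample_id`, `hdl`, `ldl`,
#'   `tg`, `n_draws`. Samples with zero records simply do not appear.
#' @export
mean_lipids <- function(records) {
  stopifnot(all(c("sample_id", "total_cholesterol", "hdl", "triglycerides")
                %in% names(records)))
  ld <- if ("ldl_direct" %in% names(records)) records$ldl_direct else
    rep(NA_real_, nrow(records))
  fw <- friedewald_ldl(records$total_cholesterol, records$hdl,
                       records$triglycerides)
  ldl <- ifelse(is.na(ld), fw, ld)
  agg <- function(v) tapply(v, records$sample_id, function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  ids <- sort(unique(records$sample_id))
  data.frame(sample_id = ids,
             hdl = as.numeric(agg(records$hdl)[ids]),
             ldl = as.numeric(agg(ldl)[ids]),
             tg = as.numeric(agg(records$triglycerides)[ids]),
             n_draws = as.integer(table(records$sample_id)[ids]),
             stringsAsFactors = FALSE)
}

#' Exclude samples on lipid-lowering therapy at baseline
#'
#' Baseline is the earliest medication record date per sample; samples with
#' a `lipid_lowering` class record on that date are dropped from lipid
#' analyses (they are not dropped from disease analyses — apply this filter
#' to the lipid cohort only).
#'
#' @param cohort `data.frame` with `sample_id`.
#' @param meds Medication `data.frame` with `sample_id`, `class`, `date`.
#' @return `cohort` without the excluded samples; excluded ids in attribute
#'   `"excluded"`.
#' @export
statin_exclusion <- function(cohort, meds) {
  if (nrow(meds) == 0) {
    attr(cohort, "excluded") <- character(0)
    return(cohort)
  }
  first_date <- tapply(meds$date, meds$sample_id, min)
  base <- meds[meds$date == first_date[as.character(meds$sample_id)], , drop = FALSE]
  flagged <- unique(base$sample_id[base$class == "lipid_lowering"])
  keep <- !(cohort$sample_id %in% flagged)
  if (!any(keep))
    warning("all samples excluded by lipid-lowering medication at baseline")
  out <- cohort[keep, , drop = FALSE]
  attr(out, "excluded") <- intersect(cohort$sample_id, flagged)
  out
}

#' Adjudicate type 2 diabetes status from clinical records
#'
#' A sample is adjudicated T2D-positive if any of: (1) HbA1c >= 6.5 at any
#' draw; (2) any diabetes-specific medication (e.g. insulin); (3) a
#' diabetes-related medication (e.g. a biguanide) together with a diabetes
#' diagnosis flag. Absent sources count as negative evidence.
#'
#' @param sample_ids Character vector of samples to adjudicate.
#' @param labs `data.frame` (`sample_id`, `hba1c`) or `NULL`.
#' @param meds `data.frame` (`sample_id`, `class`) or `NULL`; classes
#'   `diabetes_specific` and `diabetes_related` are recognized.
#' @param diagnoses `data.frame` (`sample_id`, `diabetes_dx` logical) or
#'   `NULL`.
#' @return Named logical vector over `sample_ids`.
#' @export
t2d_adjudicate <- function(sample_ids, labs = NULL, meds = NULL,
                           diagnoses = NULL) {
  if (is.null(labs) && is.null(meds) && is.null(diagnoses))
    stop("at least one data source is required")
  pos_a1c <- pos_spec <- pos_rel <- dx <- character(0)
  if (!is.null(labs))
    pos_a1c <- unique(labs$sample_id[!is.na(labs$hba1c) & labs$hba1c >= 6.5])
  if (!is.null(meds)) {
    pos_spec <- unique(meds$sample_id[meds$class == "diabetes_specific"])
    pos_rel <- unique(meds$sample_id[meds$class == "diabetes_related"])
  }
  if (!is.null(diagnoses))
    dx <- unique(diagnoses$sample_id[as.logical(diagnoses$diabetes_dx)])
  res <- sample_ids %in% pos_a1c | sample_ids %in% pos_spec |
    (sample_ids %in% pos_rel & sample_ids %in% dx)
  stats::setNames(res, sample_ids)
}

#' Body mass index
#'
#' @param height_m Height in meters (> 0).
#' @param weight_kg Weight in kilograms.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(height_m, weight_kg) {
  if (any(height_m <= 0, na.rm = TRUE)) stop("height must be positive")
  weight_kg / height_m^2
}

#' Welch's unequal-variance t-test from summary statistics
#'
#' Two-sided test from group sizes, means and SDs with the
#' Welch-Satterthwaite degrees of freedom, as used to compare baseline
#' continuous variables between cohort strata. Agrees exactly with
#' `t.test(..., var.equal = FALSE)` run on the underlying data.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries; `n >= 2`, `sd > 0`.
#' @return List of class `baseline_stat`: `statistic` (t), `df`, `p_value`,
#'   group summaries, `test = "welch_t"`.
#' @export
welch_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  tt <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  structure(list(statistic = tt, df = df,
                 p_value = 2 * stats::pt(-abs(tt), df),
                 n = c(n1, n2), mean = c(mean1, mean2), sd = c(sd1, sd2),
                 test = "welch_t"),
            class = "baseline_stat")
}

#' @export
print.baseline_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %.1f, p = %.4g\n",
              x$test, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Baseline characteristics table by ancestry stratum
#'
#' Per-stratum counts and percentages (one decimal, percent of stratum n)
#' for categorical variables, means and SDs with Welch t-tests between
#' strata for continuous variables, and chi-squared tests for categorical
#' variables.
#'
#' @param cohort `data.frame` with `stratum` plus the requested variables.
#' @param continuous,categorical Character vectors of column names.
#' @return `data.frame` with one row per (variable, level): `variable`,
#'   `level`, per-stratum `n`/`mean`/`sd` or `count`/`pct`, `test`,
#'   `statistic`, `p_value`.
#' @export
baseline_table <- function(cohort, continuous = character(0),
                           categorical = character(0)) {
  if (!"stratum" %in% names(cohort)) stop("cohort needs a stratum column")
  strata <- sort(unique(cohort$stratum))
  empty <- vapply(strata, function(s) sum(cohort$stratum == s) == 0, TRUE)
  if (any(empty)) {
    warning("omitting empty strata: ", paste(strata[empty], collapse = ", "))
    strata <- strata[!empty]
  }
  rows <- list()
  for (v in continuous) {
    x <- split(cohort[[v]], factor(cohort$stratum, strata))
    ms <- vapply(x, function(z) mean(z, na.rm = TRUE), 0)
    ss <- vapply(x, function(z) stats::sd(z, na.rm = TRUE), 0)
    ns <- vapply(x, function(z) sum(!is.na(z)), 0L)
    st <- if (length(strata) == 2 && all(ns >= 2) && all(ss > 0))
      welch_t_from_summary(ns[1], ms[1], ss[1], ns[2], ms[2], ss[2])
    else list(statistic = NA_real_, p_value = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = NA_character_,
      stratum = strata, n = ns, mean = ms, sd = ss,
      count = NA_integer_, pct = NA_real_,
      test = "welch_t", statistic = st$statistic, p_value = st$p_value,
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    f <- factor(cohort[[v]])
    tab <- table(f, factor(cohort$stratum, strata))
    cs <- colSums(tab)
    chi <- if (all(dim(tab) >= 2) && all(cs > 0))
      suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    else list(statistic = NA_real_, p.value = NA_real_)
    for (lev in rownames(tab)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lev, stratum = strata,
        n = as.integer(cs), mean = NA_real_, sd = NA_real_,
        count = as.integer(tab[lev, ]),
        pct = round(100 * as.integer(tab[lev, ]) / as.integer(cs), 1),
        test = "chisq", statistic = as.numeric(chi$statistic),
        p_value = chi$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
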