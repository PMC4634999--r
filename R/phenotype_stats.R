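## Cohort tabulations and genotype-phenotype statistics: organ-system
## involvement, major-feature totals, summary fractions, group medians,
## chi-square and Mann-Whitney comparisons across mutation-status groups.

ORGAN_COLUMNS <- c("skin", "brain", "heart", "kidney_lung")

#' Number of organ systems involved per subject
#'
#' Counts organ systems (skin, CNS, heart, kidney/lung — the latter two
#' merged as one system, reflecting the shared pathogenesis of renal
#' angiomyolipoma and LAM) with at least one major feature.
#'
#' @param subjects Subject data.frame with the four organ columns.
#' @return Integer vector in 0..4.
#' @export
organ_systems_involved <- function(subjects) {
  as.integer(rowSums(subjects[, ORGAN_COLUMNS, drop = FALSE] > 0))
}

#' Total major diagnostic features per subject
#'
#' @param subjects Subject data.frame with the four organ columns.
#' @return Integer vector of per-subject sums.
#' @export
major_feature_total <- function(subjects) {
  as.integer(rowSums(subjects[, ORGAN_COLUMNS, drop = FALSE]))
}

#' Summarize a cohort
#'
#' Tabulates mutation-identification and mosaicism fractions, gene and
#' splice-mutation counts, and allele-fraction bins.  Skin-biopsy-only
#' detections (mutation identified but AF absent in blood/saliva) are
#' counted as mosaic and inside the AF < 5% bin; the AF < 1% bin counts
#' numeric AFs only, with skin-only cases reported separately.
#'
#' @param subjects Subject data.frame (see [load_table1_fixture()]).
#' @return A `cohort_summary` list of counts and fractions.
#' @export
summarize_cohort <- function(subjects) {
  n <- nrow(subjects)
  identified <- subjects$gene != "none"
  mosaic <- subjects$status == "mosaic"
  het <- subjects$status == "heterozygous"
  skin_only <- identified & is.na(subjects$af)
  n_id <- sum(identified)
  structure(list(
    n_subjects = n,
    n_with_mutation = n_id,
    frac_identified = if (n > 0) n_id / n else NA_real_,
    n_heterozygous = sum(het),
    n_mosaic = sum(mosaic),
    frac_mosaic_of_identified = if (n_id > 0) sum(mosaic) / n_id else NA_real_,
    n_splice = sum(identified & subjects$mutation_type == "splice"),
    frac_splice_of_identified =
      if (n_id > 0) sum(identified & subjects$mutation_type == "splice") / n_id
      else NA_real_,
    n_tsc1 = sum(subjects$gene == "TSC1"),
    n_tsc2 = sum(subjects$gene == "TSC2"),
    n_af_below_5pct = sum(identified &
                            (skin_only | (!is.na(subjects$af) &
                                            subjects$af < 0.05))),
    n_af_below_1pct = sum(identified & !is.na(subjects$af) &
                            subjects$af < 0.01),
    n_skin_only = sum(skin_only)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subjects\n", x$n_subjects))
  cat(sprintf("  mutation identified: %d (%.0f%%)\n", x$n_with_mutation,
              100 * x$frac_identified))
  cat(sprintf("  mosaic: %d of %d identified (%.0f%%)\n", x$n_mosaic,
              x$n_with_mutation, 100 * x$frac_mosaic_of_identified))
  cat(sprintf("  splice: %d (%.0f%%); TSC1/TSC2: %d/%d\n", x$n_splice,
              100 * x$frac_splice_of_identified, x$n_tsc1, x$n_tsc2))
  cat(sprintf("  AF<5%%: %d (of which skin-only: %d); numeric AF<1%%: %d\n",
              x$n_af_below_5pct, x$n_skin_only, x$n_af_below_1pct))
  invisible(x)
}

#' Group medians of a per-subject quantity
#'
#' Standard median (mean of the central pair for even group sizes).
#'
#' @param subjects Subject data.frame.
#' @param value_fun Function mapping the data.frame to a numeric vector
#'   (default [major_feature_total()]).
#' @param by Grouping column name (default `"status"`).
#' @return Named numeric vector of per-group medians.
#' @export
group_medians <- function(subjects, value_fun = major_feature_total,
                          by = "status") {
  vals <- value_fun(subjects)
  vapply(split(vals, subjects[[by]]), stats::median, numeric(1L))
}

#' Organ-system involvement by mutation status
#'
#' Contingency table of the number of organ systems involved (rows) against
#' mutation status (columns), the comparison behind the severity-by-status
#' analysis.
#'
#' @param subjects Subject data.frame.
#' @return A contingency table.
#' @export
organ_status_table <- function(subjects) {
  n_org <- organ_systems_involved(subjects)
  table(organ_systems = n_org,
        status = factor(subjects$status,
                        levels = c("heterozygous", "mosaic",
                                   "persistent_NMI")))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic with p from the upper chi-square tail on
#' `(r-1)(c-1)` degrees of freedom; no continuity correction by default
#' (Yates correction available for 2x2 tables).
#'
#' @param tab Matrix or table of observed counts.
#' @param yates Apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `dof`, `p`.
#' @export
chi_square_test <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined: zero marginal total", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  if (any(res$expected <= 0)) {
    stop("chi-square test undefined: zero expected count", call. = FALSE)
  }
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p = res$p.value)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U from rank sums with midrank ties; exact enumeration p-value for small
#' untied samples (n_a * n_b <= 400), otherwise the two-sided normal
#' approximation with tie correction.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  use_exact <- length(group_a) * length(group_b) <= 400 &&
    !any(duplicated(c(group_a, group_b)))
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Run the genotype-phenotype comparisons across status groups
#'
#' The organ-involvement chi-square plus pairwise Mann-Whitney tests on
#' major-feature totals and on age.
#'
#' @param subjects Subject data.frame.
#' @return List: `organ_chisq`, `medians`, and pairwise tests
#'   `features_het_vs_nmi`, `features_mosaic_vs_nmi`, `age_het_vs_nmi`,
#'   `age_mosaic_vs_nmi`.
#' @export
phenotype_comparisons <- function(subjects) {
  feats <- major_feature_total(subjects)
  age <- subjects$age_years
  grp <- function(s) subjects$status == s
  list(
    organ_chisq = chi_square_test(organ_status_table(subjects)),
    medians = group_medians(subjects),
    features_het_vs_nmi = mann_whitney(feats[grp("heterozygous")],
                                       feats[grp("persistent_NMI")]),
    features_mosaic_vs_nmi = mann_whitney(feats[grp("mosaic")],
                                          feats[grp("persistent_NMI")]),
    age_het_vs_nmi = mann_whitney(age[grp("heterozygous") & !is.na(age)],
                                  age[grp("persistent_NMI") & !is.na(age)]),
    age_mosaic_vs_nmi = mann_whitney(age[grp("mosaic") & !is.na(age)],
                                     age[grp("persistent_NMI") & !is.na(age)])
  )
}
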