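#' Five-number group summary
#'
#' Median, 25th/75th percentile (linear-interpolation quantiles, the type-7
#' convention) and range of a score vector, the summary format used for all
#' group descriptions.
#'
#' @param scores numeric vector, `n >= 1`, no missing values.
#' @param group label stored in the output.
#' @return one-row data.frame: `group`, `n`, `median`, `q25`, `q75`, `min`,
#'   `max`.
#' @export
#' @examples
#' summarize_group(c(1, 2, 3, 4, 5))
summarize_group <- function(scores, group = NA_character_) {
  if (!is.numeric(scores) || length(scores) < 1L || anyNA(scores))
    abort_invalid_input("scores must be a non-empty numeric vector without NA")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(group = group, n = length(scores), median = q[2],
             q25 = q[1], q75 = q[3], min = min(scores), max = max(scores))
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. For combined `n <= 20`
#' without ties the exact permutation distribution is used; otherwise the
#' tie-corrected normal approximation with continuity correction. The method
#' actually taken is declared in the result.
#'
#' @param group_a,group_b numeric score vectors, each `n >= 1`.
#' @return list with `U` (number of (a, b) pairs with a > b, ties counting
#'   half), `p` (two-sided), `method` (`"exact"` or `"normal_approximation"`),
#'   `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12)) # U = 0, exact p = 0.1
mann_whitney_u <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (!is.numeric(g) || length(g) < 1L || anyNA(g))
      abort_invalid_input("both groups must be non-empty numeric vectors without NA")
  }
  n_a <- length(group_a); n_b <- length(group_b)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !has_ties && (n_a + n_b) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  # all ranks tied: tie-corrected variance is 0, no evidence of a difference
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p = min(p, 1),
       method = if (exact) "exact" else "normal_approximation",
       n_a = n_a, n_b = n_b)
}

#' Evaluate a Ricotem+ screening cut-off against laboratory ground truth
#'
#' Flags every patient classified `high` by [classify_responder()] at the
#' given Ricotem+ cut-off, then counts how many flagged patients have
#' laboratory-confirmed VWD. The proportion of flagged patients with VWD is
#' reported as `flagged_positive_proportion` — this is the quantity quoted as
#' "specificity" in the assay's original description, arithmetically a
#' positive-predictive proportion; the conventional specificity
#' (non-VWD patients not flagged / all non-VWD) is reported alongside, as is
#' sensitivity (flagged VWD / all VWD).
#'
#' @param records data.frame with columns `ricotem_minus`, `ricotem_plus`,
#'   `phenotype` (and optionally `patient_id`).
#' @param cutoff_pct Ricotem+ cut-off in percent.
#' @param include_possible count `possible_vwd` as VWD?
#' @param minus_cutoff_pct Ricotem- cut-off for the normal-responder gate.
#' @return one-row data.frame: `cutoff_pct`, `n`, `n_flagged`,
#'   `n_flagged_with_vwd`, `flagged_positive_proportion`, `sensitivity`,
#'   `specificity`. Proportions are `NA` when their denominator is 0.
#' @export
evaluate_cutoff <- function(records, cutoff_pct, include_possible = FALSE,
                            minus_cutoff_pct = 25) {
  need <- c("ricotem_minus", "ricotem_plus", "phenotype")
  miss <- setdiff(need, names(records))
  if (length(miss))
    abort_schema(paste("records missing columns:",
                       paste(miss, collapse = ", ")))
  bad <- is.na(records$ricotem_minus) | is.na(records$ricotem_plus)
  if (any(bad)) {
    ids <- if ("patient_id" %in% names(records))
      records$patient_id[bad] else which(bad)
    abort_missing_data(paste("missing Ricotem scores for:",
                             paste(ids, collapse = ", ")))
  }
  cfg <- cutoff_config(ricotem_minus_cutoff_pct = minus_cutoff_pct,
                       ricotem_plus_cutoff_pct = cutoff_pct)
  flagged <- classify_responder(records$ricotem_minus, records$ricotem_plus,
                                cfg = cfg) == "high"
  vwd <- has_vwd(records$phenotype, include_possible = include_possible)
  n_flagged <- sum(flagged)
  n_fv <- sum(flagged & vwd)
  prop <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(cutoff_pct = cutoff_pct,
             n = nrow(records),
             n_flagged = n_flagged,
             n_flagged_with_vwd = n_fv,
             flagged_positive_proportion = prop(n_fv, n_flagged),
             sensitivity = prop(n_fv, sum(vwd)),
             specificity = prop(sum(!flagged & !vwd), sum(!vwd)))
}

#' Which patients does a Ricotem+ cut-off flag?
#'
#' Helper exposing the flagged set itself (for subset / monotonicity checks
#' and plots).
#'
#' @inheritParams evaluate_cutoff
#' @return logical vector, one element per record.
#' @export
flagged_at_cutoff <- function(records, cutoff_pct, minus_cutoff_pct = 25) {
  cfg <- cutoff_config(ricotem_minus_cutoff_pct = minus_cutoff_pct,
                       ricotem_plus_cutoff_pct = cutoff_pct)
  classify_responder(records$ricotem_minus, records$ricotem_plus,
                     cfg = cfg) == "high"
}
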