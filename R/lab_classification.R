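#' Laboratory VWD phenotypes
#'
#' Ordered from least to most severe: `no_vwd`, `possible_vwd`,
#' `mild_type1`, `type1`, `type2`, `type3`.
#'
#' @format character vector of the six levels.
#' @export
vwd_phenotype_levels <- c("no_vwd", "possible_vwd", "mild_type1",
                          "type1", "type2", "type3")

#' Classify the laboratory VWD phenotype
#'
#' Applies the conventional-laboratory phenotyping rules to the three VWF
#' measures (antigen VWF:Ag, ristocetin cofactor VWF:RCo, collagen binding
#' VWF:CB, each as percent of normal), the bleeding history and the multimer
#' gel-electrophoresis flag. A 50% threshold on the VWF measures rules VWD
#' out. Rules are evaluated severity-first:
#'
#' 1. `type3` if VWF:Ag < 3% (virtual absence of VWF);
#' 2. `type2` if the multimer pattern is abnormal (qualitative defect —
#'    supplied as a flag, the gel itself is out of scope);
#' 3. `type1` if any VWF measure < 30%, or if there is a bleeding history and
#'    any measure < 50%;
#' 4. `mild_type1` if all three measures lie in \[30, 50);
#' 5. `possible_vwd` if one or two measures are < 50% with the rest normal;
#' 6. `no_vwd` if all three are >= 50%.
#'
#' An unknown multimer result (`NA`) never assigns `type2`. Low factor VIII
#' with normal VWF (mild hemophilia pattern) is *not* called VWD here; see
#' [flag_low_fviii()].
#'
#' @param vwf_ag_pct,vwf_rco_pct,vwf_cb_pct VWF antigen, ristocetin-cofactor
#'   and collagen-binding activity, percent of normal, `>= 0`.
#' @param bleeding_history logical.
#' @param multimer_abnormal logical or `NA` (unknown).
#' @return factor with levels [vwd_phenotype_levels]. Vectorized.
#' @export
#' @examples
#' classify_vwd(2, 1, 1, TRUE, TRUE)            # type3 (antigen wins)
#' classify_vwd(80, 75, 90, FALSE, FALSE)       # no_vwd
#' classify_vwd(40, 45, 48, FALSE, FALSE)       # mild_type1
#' classify_vwd(60, 45, 70, FALSE, FALSE)       # possible_vwd
classify_vwd <- function(vwf_ag_pct, vwf_rco_pct, vwf_cb_pct,
                         bleeding_history = FALSE, multimer_abnormal = FALSE) {
  for (nm in c("vwf_ag_pct", "vwf_rco_pct", "vwf_cb_pct")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v))
      abort_missing_data(sprintf("%s must be numeric and non-missing", nm))
    if (any(v < 0))
      abort_invalid_input(sprintf("%s must be >= 0", nm))
  }
  n <- max(length(vwf_ag_pct), length(vwf_rco_pct), length(vwf_cb_pct))
  ag <- rep_len(vwf_ag_pct, n); rco <- rep_len(vwf_rco_pct, n)
  cb <- rep_len(vwf_cb_pct, n)
  bleed <- rep_len(as.logical(bleeding_history), n)
  multi <- rep_len(as.logical(multimer_abnormal), n)
  if (anyNA(bleed)) abort_missing_data("bleeding_history must be TRUE/FALSE")

  low30 <- ag < 30 | rco < 30 | cb < 30
  low50 <- ag < 50 | rco < 50 | cb < 50
  n_low50 <- (ag < 50) + (rco < 50) + (cb < 50)
  all_30_50 <- ag >= 30 & ag < 50 & rco >= 30 & rco < 50 & cb >= 30 & cb < 50

  out <- rep("no_vwd", n)
  out[n_low50 %in% c(1L, 2L)] <- "possible_vwd"
  out[all_30_50] <- "mild_type1"
  out[low30 | (bleed & low50)] <- "type1"
  out[!is.na(multi) & multi] <- "type2"
  out[ag < 3] <- "type3"
  factor(out, levels = vwd_phenotype_levels)
}

#' Does a phenotype count as VWD?
#'
#' @param phenotype factor/character of [vwd_phenotype_levels].
#' @param include_possible should `possible_vwd` count as VWD?
#' @return logical vector.
#' @export
has_vwd <- function(phenotype, include_possible = FALSE) {
  phenotype <- as.character(phenotype)
  bad <- setdiff(unique(phenotype), vwd_phenotype_levels)
  if (length(bad))
    abort_invalid_input(paste("unknown phenotype:", paste(bad, collapse = ", ")))
  phenotype %in% c("mild_type1", "type1", "type2", "type3") |
    (include_possible & phenotype == "possible_vwd")
}

#' Advisory flag for a mild-hemophilia laboratory pattern
#'
#' Low factor VIII with the VWF measures normal suggests hemophilia rather
#' than VWD; the screening does not claim VWD for such panels but surfaces an
#' advisory flag.
#'
#' @param fviii_pct factor VIII activity, percent of normal.
#' @param threshold_pct flag below this (default 50).
#' @return logical vector.
#' @export
flag_low_fviii <- function(fviii_pct, threshold_pct = 50) {
  if (!is.numeric(fviii_pct)) abort_invalid_input("fviii_pct must be numeric")
  !is.na(fviii_pct) & fviii_pct < threshold_pct
}
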