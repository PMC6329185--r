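#' Ricotem- score
#'
#' Ratio of the AUC after ristocetin preincubation to the plain Extem AUC, in
#' percent: `auc_rico / auc_extem * 100`. Ristocetin agglutinates platelets in
#' proportion to functional VWF, so low values mean strong platelet depletion
#' (functional VWF present) and values near 100% mean ristocetin had no
#' effect — the hallmark of missing or dysfunctional VWF.
#'
#' @param auc_rico AUC of the ristocetin-preincubated Extem assay, `>= 0`.
#' @param auc_extem AUC of the plain Extem assay, `> 0`.
#' @return percent, `>= 0`. Vectorized.
#' @export
#' @examples
#' ricotem_minus(250, 1000) # 25
ricotem_minus <- function(auc_rico, auc_extem) {
  check_aucs(auc_extem = auc_extem, auc_rico = auc_rico)
  auc_rico / auc_extem * 100
}

#' Ricotem+ score
#'
#' Signed difference of the two ristocetin AUCs (without and with prior VWF
#' concentrate), normalized to the Extem AUC, in percent:
#' `(auc_rico - auc_rico_haemate) / auc_extem * 100`.
#'
#' When the supplemented VWF restores ristocetin-induced platelet
#' agglutination, the supplemented clot is weaker and the score is large —
#' flagging VWF deficiency amenable to substitution. Equal AUCs give exactly
#' 0; the score is not clamped and may be negative (a supplemented clot
#' slightly stronger than the unsupplemented one, as in healthy subjects).
#'
#' @inheritParams ricotem_minus
#' @param auc_rico_haemate AUC of the assay with VWF concentrate added before
#'   ristocetin, `>= 0`.
#' @return signed percent. Vectorized.
#' @export
#' @examples
#' ricotem_plus(759, 62, 1000)  # 69.7: strong concentrate effect
#' ricotem_plus(55, 140, 1000)  # -8.5: none
ricotem_plus <- function(auc_rico, auc_rico_haemate, auc_extem) {
  check_aucs(auc_extem = auc_extem, auc_rico = auc_rico,
             auc_rico_haemate = auc_rico_haemate)
  (auc_rico - auc_rico_haemate) / auc_extem * 100
}

check_aucs <- function(auc_extem, auc_rico = NULL, auc_rico_haemate = NULL) {
  if (!is.numeric(auc_extem) || anyNA(auc_extem) || any(auc_extem <= 0))
    abort_invalid_input("auc_extem must be numeric and > 0")
  if (!is.null(auc_rico) &&
      (!is.numeric(auc_rico) || anyNA(auc_rico) || any(auc_rico < 0)))
    abort_invalid_input("auc_rico must be numeric and >= 0")
  if (!is.null(auc_rico_haemate) &&
      (!is.numeric(auc_rico_haemate) ||
       any(auc_rico_haemate < 0, na.rm = TRUE)))
    abort_invalid_input("auc_rico_haemate must be numeric and >= 0")
  invisible(TRUE)
}

#' Responder-classification cut-offs
#'
#' The screening uses two cut-offs: `ricotem_minus_cutoff_pct` separates
#' normal responders (strong ristocetin effect, score at or below the
#' cut-off, default 25) from suspected VWD; `ricotem_plus_cutoff_pct`
#' separates high responders (clear concentrate effect, score at or above the
#' cut-off, default 50; 35 is the documented lower alternative) from low
#' responders.
#'
#' @param ricotem_minus_cutoff_pct percent in (0, 100), default 25.
#' @param ricotem_plus_cutoff_pct percent in (0, 100), default 50.
#' @return a `cutoff_config` list.
#' @export
cutoff_config <- function(ricotem_minus_cutoff_pct = 25,
                          ricotem_plus_cutoff_pct = 50) {
  for (v in c(ricotem_minus_cutoff_pct, ricotem_plus_cutoff_pct)) {
    if (!is_scalar_number(v) || v <= 0 || v >= 100)
      abort_invalid_parameter("cut-offs must lie strictly between 0 and 100")
  }
  structure(list(ricotem_minus_cutoff_pct = ricotem_minus_cutoff_pct,
                 ricotem_plus_cutoff_pct = ricotem_plus_cutoff_pct),
            class = "cutoff_config")
}

#' Assemble a per-patient Ricotem panel
#'
#' Derives both scores from the three assay AUCs. `auc_rico_haemate` may be
#' `NA` (channel not run), in which case `ricotem_plus` is `NA`.
#'
#' @inheritParams ricotem_plus
#' @param patient_id optional identifier column.
#' @return data.frame with the three AUCs and derived `ricotem_minus`,
#'   `ricotem_plus`.
#' @export
ricotem_panel <- function(auc_extem, auc_rico, auc_rico_haemate = NA_real_,
                          patient_id = NULL) {
  check_aucs(auc_extem, auc_rico, auc_rico_haemate)
  n <- length(auc_extem)
  if (length(auc_rico) != n ||
      length(rep_len(auc_rico_haemate, n)) != n)
    abort_invalid_input("AUC vectors must have equal length")
  auc_rico_haemate <- rep_len(auc_rico_haemate, n)
  plus <- ifelse(is.na(auc_rico_haemate), NA_real_,
                 (auc_rico - auc_rico_haemate) / auc_extem * 100)
  out <- data.frame(auc_extem = auc_extem, auc_rico = auc_rico,
                    auc_rico_haemate = auc_rico_haemate,
                    ricotem_minus = auc_rico / auc_extem * 100,
                    ricotem_plus = plus)
  if (!is.null(patient_id)) out <- cbind(patient_id = patient_id, out)
  out
}

#' Classify responder group from the Ricotem scores
#'
#' Stepwise grouping: a patient whose Ricotem- score is at or below the first
#' cut-off responded normally to ristocetin (functional VWF present) and is
#' `normal`; otherwise the concentrate response decides — Ricotem+ at or
#' above the second cut-off is `high` (clear VWF-substitution effect), else
#' `low`. Ricotem+ is only required when Ricotem- exceeds the first cut-off,
#' mirroring the stepwise bench procedure. Negative Ricotem+ values classify
#' as `low`.
#'
#' @param ricotem_minus percent, from [ricotem_minus()].
#' @param ricotem_plus percent or `NA`; required only when `ricotem_minus`
#'   exceeds the first cut-off.
#' @param cfg a [cutoff_config()].
#' @param patient_id optional identifiers used in error messages.
#' @return factor with levels `normal`, `low`, `high`. Vectorized.
#' @export
#' @examples
#' classify_responder(5.5, -8.5)           # normal
#' classify_responder(75.9, 69.7)          # high
#' classify_responder(40, 10)              # low
classify_responder <- function(ricotem_minus, ricotem_plus = NA_real_,
                               cfg = cutoff_config(), patient_id = NULL) {
  if (!inherits(cfg, "cutoff_config")) abort_invalid_parameter("cfg must be a cutoff_config")
  if (!is.numeric(ricotem_minus) || anyNA(ricotem_minus))
    abort_invalid_input("ricotem_minus must be numeric and non-missing")
  n <- length(ricotem_minus)
  ricotem_plus <- rep_len(ricotem_plus, n)
  needs_plus <- ricotem_minus > cfg$ricotem_minus_cutoff_pct
  if (any(needs_plus & is.na(ricotem_plus))) {
    who <- which(needs_plus & is.na(ricotem_plus))
    ids <- if (is.null(patient_id)) paste0("#", who) else patient_id[who]
    abort_missing_data(paste0(
      "ricotem_plus required (ricotem_minus above cut-off) but missing for: ",
      paste(ids, collapse = ", ")))
  }
  out <- rep("normal", n)
  out[needs_plus] <- ifelse(
    ricotem_plus[needs_plus] >= cfg$ricotem_plus_cutoff_pct, "high", "low")
  factor(out, levels = c("normal", "low", "high"))
}
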