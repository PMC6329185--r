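#' A microvascular-bleeding case for decision support
#'
#' Bundles the inputs of the advisory algorithm: whether bleeding is
#' clinically relevant, the standard ROTEM findings (may be absent), the
#' Ricotem+ score if the panel was run, and whether the preceding
#' standard-algorithm steps are exhausted.
#'
#' @param clinically_relevant_bleeding logical, required.
#' @param extem_ct_s,fibtem_mcf_mm,extem_mcf_mm standard ROTEM findings or
#'   `NA`.
#' @param ricotem_plus_pct Ricotem+ in percent, or `NA` if the panel was not
#'   run.
#' @param prior_steps_exhausted logical.
#' @return a `bleeding_case` list.
#' @export
bleeding_case <- function(clinically_relevant_bleeding,
                          extem_ct_s = NA_real_, fibtem_mcf_mm = NA_real_,
                          extem_mcf_mm = NA_real_,
                          ricotem_plus_pct = NA_real_,
                          prior_steps_exhausted = FALSE) {
  if (!is.logical(clinically_relevant_bleeding) ||
      length(clinically_relevant_bleeding) != 1L ||
      is.na(clinically_relevant_bleeding))
    abort_invalid_input("clinically_relevant_bleeding must be TRUE or FALSE")
  for (v in list(extem_ct_s, fibtem_mcf_mm, extem_mcf_mm)) {
    if (!is.na(v) && (!is.numeric(v) || v < 0))
      abort_invalid_input("ROTEM findings must be >= 0 when present")
  }
  structure(list(clinically_relevant_bleeding = clinically_relevant_bleeding,
                 extem_ct_s = extem_ct_s, fibtem_mcf_mm = fibtem_mcf_mm,
                 extem_mcf_mm = extem_mcf_mm,
                 ricotem_plus_pct = ricotem_plus_pct,
                 prior_steps_exhausted = isTRUE(prior_steps_exhausted)),
            class = "bleeding_case")
}

#' Load a base-algorithm rule table
#'
#' The established bleeding-management algorithm the Ricotem+ path extends is
#' represented as a user-editable rule table, one row per threshold rule:
#' `rule_id`, `parameter` (a `bleeding_case` ROTEM field), `op`
#' (`lt|le|gt|ge`), `threshold`, `action`, `rationale`. The packaged default
#' (`system.file("extdata", "base_rules.yaml", package = "ricotem")`)
#' contains no numeric clinical thresholds — the base algorithm is
#' institution-specific and must be configured, not invented; rules fire only
#' when their parameter is present.
#'
#' @param path YAML file; default the packaged (empty) table.
#' @return data.frame of rules (possibly zero rows).
#' @export
read_rule_table <- function(path = system.file("extdata", "base_rules.yaml",
                                               package = "ricotem")) {
  y <- yaml::read_yaml(path)
  rules <- y$rules
  if (is.null(rules) || length(rules) == 0L)
    return(data.frame(rule_id = character(), parameter = character(),
                      op = character(), threshold = numeric(),
                      action = character(), rationale = character()))
  need <- c("rule_id", "parameter", "op", "threshold", "action", "rationale")
  out <- do.call(rbind, lapply(rules, function(r) {
    miss <- setdiff(need, names(r))
    if (length(miss))
      abort_schema(paste("rule missing fields:", paste(miss, collapse = ", ")))
    as.data.frame(r[need])
  }))
  if (!all(out$op %in% c("lt", "le", "gt", "ge")))
    abort_schema("rule op must be one of lt, le, gt, ge")
  out
}

rule_fires <- function(value, op, threshold) {
  if (is.na(value)) return(FALSE)
  switch(op, lt = value < threshold, le = value <= threshold,
         gt = value > threshold, ge = value >= threshold)
}

ricotem_disclaimer <- paste(
  "Research software - advisory output only, not a clinical directive.",
  "Desmopressin (DDAVP) can be harmful in VWD Type 2B; subtype before use.")

#' Advisory recommendation for a bleeding case
#'
#' Pure function of the case, the cut-off configuration and the rule table.
#' Without clinically relevant bleeding the recommendation is empty. With
#' bleeding, the configured base-algorithm rules are applied first
#' (pass-through: each fired rule appends its action), then the Ricotem+
#' extension path: a Ricotem+ score at or above the cut-off appends
#' `consider-VWF-concentrate`; a score below it adds no VWF action; an absent
#' score with the prior steps exhausted appends the advisory
#' `perform-ricotem-panel`. Every appended action is justified in the rule
#' trace, so a recommendation is reproducible from its trace.
#'
#' @param case a [bleeding_case()].
#' @param cfg a [cutoff_config()]; only the Ricotem+ cut-off is used.
#' @param rules base-algorithm rule table from [read_rule_table()].
#' @return list with `actions` (character, ordered), `rule_trace`
#'   (data.frame: `rule_id`, `action`, `rationale`), `disclaimer`.
#' @export
#' @examples
#' recommend(bleeding_case(TRUE, ricotem_plus_pct = 69.7))$actions
recommend <- function(case, cfg = cutoff_config(), rules = read_rule_table()) {
  if (!inherits(case, "bleeding_case"))
    abort_invalid_input("case must be a bleeding_case")
  if (!inherits(cfg, "cutoff_config"))
    abort_invalid_parameter("cfg must be a cutoff_config")
  trace <- data.frame(rule_id = character(), action = character(),
                      rationale = character())
  if (!case$clinically_relevant_bleeding)
    return(list(actions = character(), rule_trace = trace,
                disclaimer = ricotem_disclaimer))

  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (rule_fires(case[[r$parameter]], r$op, r$threshold)) {
      trace <- rbind(trace, data.frame(rule_id = r$rule_id,
                                       action = r$action,
                                       rationale = r$rationale))
    }
  }
  cut <- cfg$ricotem_plus_cutoff_pct
  rp <- case$ricotem_plus_pct
  if (!is.na(rp)) {
    if (rp >= cut) {
      trace <- rbind(trace, data.frame(
        rule_id = "ricotem_plus_path",
        action = "consider-VWF-concentrate",
        rationale = sprintf(
          "Ricotem+ %.1f%% >= cut-off %.1f%%: clot strength restored by exogenous VWF; VWF substitution likely beneficial",
          rp, cut)))
    }
  } else if (case$prior_steps_exhausted) {
    trace <- rbind(trace, data.frame(
      rule_id = "ricotem_panel_advisory",
      action = "perform-ricotem-panel",
      rationale = "standard steps exhausted and no Ricotem+ result: run the ristocetin / ristocetin+VWF panel"))
  }
  list(actions = trace$action, rule_trace = trace,
       disclaimer = ricotem_disclaimer)
}
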