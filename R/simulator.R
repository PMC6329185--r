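#' Ground-truth parameters for one simulated subject
#'
#' The clot-amplitude model is an exponential approach to a plateau:
#' `A(t) = M_eff * (1 - exp(-(t - lag)/tau))` for `t >= lag`, else 0, with
#' optional multiplicative noise. The plateau `M_eff` depends on the assay
#' condition (see [simulate_trace()]): a fraction `fibrinogen_fraction` of
#' total clot strength is platelet-independent (fibrin only), and ristocetin
#' removes the platelet-dependent remainder in proportion to the agglutinated
#' platelet fraction `g(V) = V / (V + K)`, a saturating function of
#' functional VWF activity `V` with half-saturation `K`.
#'
#' @param vwf_activity_pct functional VWF activity, percent of normal
#'   (ground truth; in cohort simulation set from the drawn VWF:RCo).
#' @param fibrinogen_fraction fraction of total clot strength that is
#'   fibrinogen-dependent, in (0, 1); default 0.20.
#' @param mcf_total_mm total (Extem) clot-strength plateau, mm; default 60.
#' @param lag_s clot-initiation lag (CT ground truth), seconds; default 120.
#' @param tau_s exponential time constant, seconds; default 300.
#' @param haemate_increment_pct VWF activity added by the concentrate dose
#'   (0.8 IU into 0.4 mL is about 200 IU/dL); default 200.
#' @param haemate_procoagulant_mm small additive firmness from the
#'   concentrate itself, mm; default 2.
#' @param agglutination_k_pct half-saturation VWF activity `K` for the
#'   ristocetin response; default 30.
#' @param noise_cv coefficient of variation of multiplicative amplitude
#'   noise; default 0.05, 0 disables noise.
#' @return a `phenotype_params` list.
#' @export
phenotype_params <- function(vwf_activity_pct,
                             fibrinogen_fraction = 0.20,
                             mcf_total_mm = 60,
                             lag_s = 120,
                             tau_s = 300,
                             haemate_increment_pct = 200,
                             haemate_procoagulant_mm = 2,
                             agglutination_k_pct = 30,
                             noise_cv = 0.05) {
  p <- list(vwf_activity_pct = vwf_activity_pct,
            fibrinogen_fraction = fibrinogen_fraction,
            mcf_total_mm = mcf_total_mm, lag_s = lag_s, tau_s = tau_s,
            haemate_increment_pct = haemate_increment_pct,
            haemate_procoagulant_mm = haemate_procoagulant_mm,
            agglutination_k_pct = agglutination_k_pct, noise_cv = noise_cv)
  for (nm in names(p)) {
    if (!is_scalar_number(p[[nm]]))
      abort_invalid_parameter(sprintf("%s must be a single finite number", nm))
  }
  if (p$fibrinogen_fraction <= 0 || p$fibrinogen_fraction >= 1)
    abort_invalid_parameter("fibrinogen_fraction must lie in (0, 1)")
  if (p$vwf_activity_pct < 0 || p$noise_cv < 0 ||
      p$haemate_procoagulant_mm < 0 || p$haemate_increment_pct < 0)
    abort_invalid_parameter("activities, increments and noise_cv must be >= 0")
  if (p$mcf_total_mm <= 0 || p$lag_s <= 0 || p$tau_s <= 0 ||
      p$agglutination_k_pct <= 0)
    abort_invalid_parameter("mcf_total_mm, lag_s, tau_s, agglutination_k_pct must be > 0")
  structure(p, class = "phenotype_params")
}

# agglutinated platelet fraction under ristocetin at VWF activity v (percent)
agglutinated_fraction <- function(v, k) v / (v + k)

# condition-specific plateau (mm) and additive term of the amplitude model
condition_plateau <- function(params, condition) {
  phi <- params$fibrinogen_fraction
  m <- params$mcf_total_mm
  k <- params$agglutination_k_pct
  v <- params$vwf_activity_pct
  switch(condition,
    extem = list(m_eff = m, add = 0),
    fibtem = list(m_eff = phi * m, add = 0),
    rico = list(
      m_eff = m * (phi + (1 - phi) * (1 - agglutinated_fraction(v, k))),
      add = 0),
    rico_haemate = list(
      m_eff = m * (phi + (1 - phi) *
                     (1 - agglutinated_fraction(v + params$haemate_increment_pct, k))),
      add = params$haemate_procoagulant_mm),
    abort_invalid_parameter(sprintf("unknown condition '%s'", condition)))
}

#' Simulate a clot-amplitude trace for one assay condition
#'
#' Generates a [rotem_trace] from the mechanistic model in
#' [phenotype_params()]. The plateau by condition:
#'
#' * `extem` — full clot strength `mcf_total_mm`;
#' * `fibtem` — the fibrinogen-only fraction (platelets inhibited);
#' * `rico` — fibrinogen part plus the platelet part that survives
#'   ristocetin agglutination, `m * [phi + (1 - phi) * (1 - g(V))]`;
#' * `rico_haemate` — as `rico` with `V` raised by the concentrate increment,
#'   plus a small additive procoagulant term.
#'
#' Noise is multiplicative log-normal per sample, normalized to mean 1 with
#' coefficient of variation `noise_cv`; `noise_cv = 0` returns the closed
#' form exactly. Given `seed` the trace is fully reproducible.
#'
#' @param params a [phenotype_params()].
#' @param condition one of `"extem"`, `"rico"`, `"rico_haemate"`, `"fibtem"`.
#' @param duration_min trace length in minutes, `>= 30` so AUC30 is
#'   computable; default 35.
#' @param dt_s sampling interval in seconds; default 1.
#' @param seed integer RNG seed; ignored when `noise_cv = 0`.
#' @return a [rotem_trace] with `channel = condition`.
#' @export
#' @examples
#' p <- phenotype_params(vwf_activity_pct = 100, noise_cv = 0)
#' tr <- simulate_trace(p, "extem")
#' extract_mcf(tr)
simulate_trace <- function(params, condition = c("extem", "rico",
                                                 "rico_haemate", "fibtem"),
                           duration_min = 35, dt_s = 1, seed = 1L) {
  if (!inherits(params, "phenotype_params"))
    abort_invalid_parameter("params must be a phenotype_params object")
  condition <- match.arg(condition)
  if (!is_scalar_number(dt_s) || dt_s <= 0)
    abort_invalid_parameter("dt_s must be > 0")
  if (!is_scalar_number(duration_min) || duration_min < 30)
    abort_invalid_parameter("duration_min must be >= 30 (AUC30 needs a 30-min span)")

  times <- seq(0, duration_min * 60, by = dt_s)
  cp <- condition_plateau(params, condition)
  amp <- ifelse(times >= params$lag_s,
                cp$m_eff * (1 - exp(-(times - params$lag_s) / params$tau_s)) +
                  cp$add,
                0)
  if (params$noise_cv > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    sdlog <- sqrt(log(1 + params$noise_cv^2))
    eps <- exp(stats::rnorm(length(times), mean = -sdlog^2 / 2, sd = sdlog))
    amp <- amp * eps
  }
  rotem_trace(times, amp, channel = condition)
}

# per-class uniform ranges for the laboratory draws; chosen so classify_vwd
# recovers the generating class by construction.
class_lab_ranges <- list(
  control = list(vwf = c(60, 150), fviii = c(60, 150), aptt = c(25, 36),
                 bleeding = FALSE, multimer = FALSE),
  type1 = list(vwf = c(5, 29.5), fviii = c(30, 70), aptt = c(30, 45),
               bleeding = NA, multimer = FALSE),
  mild_type1 = list(vwf = c(30, 49.5), fviii = c(40, 90), aptt = c(28, 40),
                    bleeding = FALSE, multimer = FALSE),
  type2a = list(vwf = c(10, 40), fviii = c(30, 80), aptt = c(28, 42),
                bleeding = NA, multimer = TRUE),
  type3 = list(vwf = c(0, 2.5), fviii = c(2, 20), aptt = c(45, 70),
               bleeding = TRUE, multimer = TRUE),
  possible = list(vwf = c(55, 120), fviii = c(60, 120), aptt = c(25, 38),
                  bleeding = FALSE, multimer = FALSE),
  hemophilia_mild = list(vwf = c(60, 140), fviii = c(5, 40), aptt = c(40, 60),
                         bleeding = TRUE, multimer = FALSE))

#' Phenotype classes recognized by the cohort simulator
#' @export
simulated_classes <- names(class_lab_ranges)

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Simulate one patient: laboratory panel, assay traces and ground truth
#'
#' Draws a class-consistent laboratory panel (uniform within documented
#' ranges chosen so that [classify_vwd()] recovers the generating class),
#' sets the simulator's VWF activity from the drawn VWF:RCo, and simulates
#' the `extem`, `rico` and `rico_haemate` traces. For `type2a` the antigen is
#' drawn normal-to-mildly-low while activity measures are low, the classic
#' discordant qualitative-defect pattern; `possible` draws exactly one
#' mildly low measure; `hemophilia_mild` draws normal VWF with low factor
#' VIII.
#'
#' @param phenotype_class one of [simulated_classes].
#' @param seed integer seed; labs and traces derive from it.
#' @param noise_cv trace noise, passed to [phenotype_params()].
#' @param patient_id identifier stored in the record.
#' @return list with `patient_id`, `class`, `lab` (one-row data.frame),
#'   `params`, `traces` (named list of three [rotem_trace]s), `panel`
#'   (one-row data.frame from [ricotem_panel()]).
#' @export
simulate_patient <- function(phenotype_class, seed = 1L, noise_cv = 0.05,
                             patient_id = paste0("P", seed)) {
  if (!phenotype_class %in% simulated_classes)
    abort_invalid_parameter(sprintf(
      "unknown phenotype class '%s' (known: %s)", phenotype_class,
      paste(simulated_classes, collapse = ", ")))
  r <- class_lab_ranges[[phenotype_class]]
  set.seed(as.integer(seed %% .Machine$integer.max))

  ag <- runif1(r$vwf); rco <- runif1(r$vwf); cb <- runif1(r$vwf)
  if (phenotype_class == "type2a") {
    ag <- stats::runif(1, 40, 90)        # antigen preserved, activity lost
  } else if (phenotype_class == "possible") {
    low <- sample(3, 1)
    val <- stats::runif(1, 35, 49.5)     # one mildly low measure, >= 30
    if (low == 1) ag <- val else if (low == 2) rco <- val else cb <- val
  }
  bleeding <- if (is.na(r$bleeding)) stats::runif(1) < 0.3 else r$bleeding
  lab <- data.frame(
    patient_id = patient_id,
    sex = sample(c("f", "m"), 1),
    age_y = round(stats::runif(1, 0.5, 62), 1),
    abo = sample(c("A", "B", "O", "AB"), 1),
    pt_pct = round(stats::runif(1, 80, 120), 0),
    aptt_s = round(runif1(r$aptt), 1),
    fibrinogen_gL = round(stats::runif(1, 1.8, 4.0), 2),
    platelets_per_nL = round(stats::runif(1, 150, 400), 0),
    fviii_pct = round(runif1(r$fviii), 1),
    vwf_ag_pct = round(ag, 1),
    vwf_rco_pct = round(rco, 1),
    vwf_cb_pct = round(cb, 1),
    bleeding_history = bleeding,
    multimer_abnormal = r$multimer)

  params <- phenotype_params(vwf_activity_pct = lab$vwf_rco_pct,
                             noise_cv = noise_cv)
  trace_seeds <- seed + 1:3
  traces <- list(
    extem = simulate_trace(params, "extem", seed = trace_seeds[1]),
    rico = simulate_trace(params, "rico", seed = trace_seeds[2]),
    rico_haemate = simulate_trace(params, "rico_haemate", seed = trace_seeds[3]))
  aucs <- vapply(traces, auc30, numeric(1))
  panel <- ricotem_panel(auc_extem = aucs[["extem"]],
                         auc_rico = aucs[["rico"]],
                         auc_rico_haemate = aucs[["rico_haemate"]],
                         patient_id = patient_id)
  list(patient_id = patient_id, class = phenotype_class, lab = lab,
       params = params, traces = traces, panel = panel)
}

#' Cohort composition for the simulator
#'
#' Defaults mirror the study cohort: 27 subjects — 7 controls, 9 Type 1,
#' 6 Type 2A, 2 Type 3, 2 possible VWD and 1 mild hemophilia.
#'
#' @param controls,type1,mild_type1,type2a,type3,possible,hemophilia_mild
#'   per-class counts, `>= 0`, total `>= 1`.
#' @param seed integer master seed; all randomness in [simulate_cohort()]
#'   derives from it.
#' @param noise_cv trace noise level.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(controls = 7, type1 = 9, mild_type1 = 0, type2a = 6,
                        type3 = 2, possible = 2, hemophilia_mild = 1,
                        seed = 42L, noise_cv = 0.05) {
  counts <- c(control = controls, type1 = type1, mild_type1 = mild_type1,
              type2a = type2a, type3 = type3, possible = possible,
              hemophilia_mild = hemophilia_mild)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_invalid_parameter("class counts must be non-negative integers")
  if (sum(counts) < 1) abort_invalid_parameter("cohort must have >= 1 subject")
  structure(list(counts = counts, seed = as.integer(seed),
                 noise_cv = noise_cv), class = "cohort_spec")
}

#' Simulate a full cohort
#'
#' Simulates every patient of a [cohort_spec()] (per-patient seeds are the
#' master seed plus a fixed offset times the patient index, so runs are
#' reproducible and patients independent), assembles the Table-1-style cohort
#' table with laboratory values, assay AUCs, Ricotem scores, the laboratory
#' phenotype assigned by [classify_vwd()] and the responder group, and
#' optionally writes the cohort CSV plus one multi-channel trace CSV per
#' patient.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory; created if needed.
#' @param cfg [cutoff_config()] used for responder grouping.
#' @return list with `cohort` (data.frame, one row per patient), `patients`
#'   (list of [simulate_patient()] records), `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL,
                            cfg = cutoff_config()) {
  if (!inherits(spec, "cohort_spec"))
    abort_invalid_parameter("spec must be a cohort_spec")
  classes <- rep(names(spec$counts), times = spec$counts)
  n <- length(classes)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    patients[[i]] <- simulate_patient(
      classes[i], seed = spec$seed + 7919L * i, noise_cv = spec$noise_cv,
      patient_id = sprintf("P%02d", i))
  }
  labs <- do.call(rbind, lapply(patients, `[[`, "lab"))
  panels <- do.call(rbind, lapply(patients, `[[`, "panel"))
  phenotype <- classify_vwd(labs$vwf_ag_pct, labs$vwf_rco_pct,
                            labs$vwf_cb_pct, labs$bleeding_history,
                            labs$multimer_abnormal)
  responder <- classify_responder(panels$ricotem_minus, panels$ricotem_plus,
                                  cfg = cfg, patient_id = labs$patient_id)
  cohort <- cbind(labs,
                  true_class = classes,
                  panels[, setdiff(names(panels), "patient_id")],
                  phenotype = phenotype,
                  low_fviii_flag = flag_low_fviii(labs$fviii_pct),
                  responder = responder)
  rownames(cohort) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(dir, "cohort.csv"))
    for (p in patients) {
      write_trace_csv(p$traces,
                      file.path(dir, sprintf("traces_%s.csv", p$patient_id)))
    }
  }
  list(cohort = cohort, patients = patients, spec = spec)
}
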