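noise_free <- function(v, ...) phenotype_params(v, noise_cv = 0, ...)

test_that("model limits: no VWF means no ristocetin effect, saturation leaves fibrin only", {
  p0 <- noise_free(0)
  expect_equal(simulate_trace(p0, "rico")$amplitudes,
               simulate_trace(p0, "extem")$amplitudes)
  pinf <- noise_free(1e12)
  expect_equal(extract_mcf(simulate_trace(pinf, "rico")),
               0.20 * 60 * (1 - exp(-(2100 - 120) / 300)), tolerance = 1e-6)
  # fibtem is the fibrinogen-only fraction regardless of VWF
  expect_equal(extract_mcf(simulate_trace(noise_free(100), "fibtem")),
               extract_mcf(simulate_trace(p0, "fibtem")))
})

test_that("noisy healthy trace recovers the configured plateau within noise", {
  p <- phenotype_params(100)  # defaults, noise_cv 0.05
  mcf <- extract_mcf(simulate_trace(p, "extem", seed = 7))
  expect_gt(mcf, 55)
  expect_lt(mcf, 75)  # max over ~2000 multiplicative-noise samples
})

test_that("noise-free extractors recover the closed-form CT, MCF and AUC to < 1%", {
  for (v in c(5, 30, 100)) {
    p <- noise_free(v)
    for (cond in c("extem", "rico", "rico_haemate", "fibtem")) {
      tr <- simulate_trace(p, cond)
      want_ct <- closed_crossing(p, cond, 2)
      want_mcf <- closed_amplitude(p, cond, 2100)
      want_auc <- 100 * closed_amplitude(p, cond, 1800)
      expect_equal(extract_ct(tr), want_ct, tolerance = 0.01)
      expect_equal(extract_mcf(tr), want_mcf, tolerance = 0.01)
      expect_equal(auc30(tr), want_auc, tolerance = 0.01)
    }
  }
  # severe deficiency: the post-ristocetin clot is barely affected and still
  # crosses 20 mm, so its CFT is present
  expect_false(is.na(extract_cft(simulate_trace(noise_free(1), "rico"))))
})

test_that("traces are deterministic given a seed and validate parameters", {
  p <- phenotype_params(50)
  t1 <- simulate_trace(p, "rico", seed = 9)
  t2 <- simulate_trace(p, "rico", seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_trace(p, "rico", seed = 10)))
  expect_error(simulate_trace(p, "rico", duration_min = 25),
               class = "ricotem_invalid_parameter")
  expect_error(simulate_trace(p, "rico", dt_s = 0),
               class = "ricotem_invalid_parameter")
  expect_error(phenotype_params(100, fibrinogen_fraction = 1.2),
               class = "ricotem_invalid_parameter")
})

test_that("noise-free Ricotem+ decreases with endogenous VWF activity", {
  rplus <- vapply(seq(0, 200, 10), function(v) {
    p <- noise_free(v)
    aucs <- vapply(c("extem", "rico", "rico_haemate"),
                   function(cc) auc30(simulate_trace(p, cc)), numeric(1))
    ricotem_plus(aucs[["rico"]], aucs[["rico_haemate"]], aucs[["extem"]])
  }, numeric(1))
  expect_true(all(diff(rplus) < 0))
  # and matches the closed-form value at every grid point
  closed <- vapply(seq(0, 200, 10),
                   function(v) closed_ricotem_plus(noise_free(v)), numeric(1))
  expect_equal(rplus, closed, tolerance = 1e-9)
})

test_that("simulated patients are recovered by the laboratory classifier", {
  expected <- c(control = "no_vwd", type1 = "type1", mild_type1 = "mild_type1",
                type2a = "type2", type3 = "type3", possible = "possible_vwd",
                hemophilia_mild = "no_vwd")
  for (cls in simulated_classes) {
    for (seed in c(1, 77, 991)) {
      rec <- simulate_patient(cls, seed = seed)
      got <- classify_vwd(rec$lab$vwf_ag_pct, rec$lab$vwf_rco_pct,
                          rec$lab$vwf_cb_pct, rec$lab$bleeding_history,
                          rec$lab$multimer_abnormal)
      expect_identical(as.character(got), unname(expected[cls]))
    }
  }
  # mild type 1 draws keep all three measures inside [30, 50)
  vws <- t(vapply(1:100, function(s) {
    lab <- simulate_patient("mild_type1", seed = s)$lab
    c(lab$vwf_ag_pct, lab$vwf_rco_pct, lab$vwf_cb_pct)
  }, numeric(3)))
  expect_true(all(vws >= 30 & vws < 50))
  expect_error(simulate_patient("type5"), class = "ricotem_invalid_parameter")
})

test_that("cohort simulation is reproducible and matches its composition", {
  spec <- cohort_spec(seed = 5)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co$cohort), 27)
  expect_equal(as.vector(table(co$cohort$true_class)[c("control", "type1",
                                                       "type2a", "type3")]),
               c(7L, 9L, 6L, 2L))
  expect_identical(co$cohort, simulate_cohort(cohort_spec(seed = 5))$cohort)
  expect_false(identical(co$cohort$auc_extem,
                         simulate_cohort(cohort_spec(seed = 6))$cohort$auc_extem))
  one <- simulate_cohort(cohort_spec(1, 0, 0, 0, 0, 0, 0, seed = 2))
  expect_equal(nrow(one$cohort), 1)
  expect_identical(as.character(one$cohort$phenotype), "no_vwd")
  expect_error(cohort_spec(controls = -1), class = "ricotem_invalid_parameter")
})

test_that("written cohorts are byte-identical across runs with one seed", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  spec <- cohort_spec(2, 1, 0, 1, 1, 0, 0, seed = 13)
  simulate_cohort(spec, dir = d1)
  simulate_cohort(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
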