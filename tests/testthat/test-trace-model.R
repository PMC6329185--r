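test_that("trace construction validates its inputs", {
  expect_error(rotem_trace(1, 1), class = "ricotem_invalid_input")
  expect_error(rotem_trace(c(0, 1), c(0, -1)), class = "ricotem_invalid_input")
  expect_error(rotem_trace(c(0, 2, 1), c(0, 1, 2)), class = "ricotem_invalid_input")
  expect_error(rotem_trace(c(0, 1, 1), c(0, 1, 2)), class = "ricotem_invalid_input")
  # identical duplicate rows are collapsed, not rejected
  tr <- rotem_trace(c(0, 1, 1, 2), c(0, 3, 3, 5))
  expect_equal(tr$times, c(0, 1, 2))
})

test_that("clotting time is the interpolated first threshold crossing", {
  flat <- rotem_trace(c(0, 600), c(0, 0))
  expect_true(is.na(extract_ct(flat)))
  ramp <- rotem_trace(c(0, 100), c(0, 4))
  expect_equal(extract_ct(ramp), 50)
  # already above threshold at the first sample
  high <- rotem_trace(c(10, 100), c(5, 8))
  expect_equal(extract_ct(high), 10)
  expect_error(extract_ct(ramp, threshold_mm = -1),
               class = "ricotem_invalid_parameter")
})

test_that("clot formation time spans the 2 to 20 mm rise", {
  weak <- rotem_trace(c(0, 100, 200), c(0, 5, 10))
  expect_true(is.na(extract_cft(weak)))
  ramp <- rotem_trace(c(0, 400), c(0, 40))
  expect_equal(extract_cft(ramp), 180)  # crossings at 20 s and 200 s
  expect_error(extract_cft(ramp, low_mm = 20, high_mm = 2),
               class = "ricotem_invalid_parameter")
})

test_that("maximum clot firmness is the amplitude maximum", {
  expect_equal(extract_mcf(rotem_trace(c(0, 1800), c(0, 0))), 0)
  expect_equal(extract_mcf(rotem_trace(0:3 * 100, c(0, 12, 55, 54))), 55)
})

test_that("velocity curve is the per-minute difference quotient at midpoints", {
  const <- rotem_trace(c(0, 60, 120), c(7, 7, 7))
  expect_equal(velocity_curve(const)$velocity_mm_min, c(0, 0))
  ramp <- rotem_trace(seq(0, 600, 60), seq(0, 60, 6))  # 6 mm/min
  vc <- velocity_curve(ramp)
  expect_equal(vc$velocity_mm_min, rep(6, 10))
  expect_equal(vc$time_s, seq(30, 570, 60))
  # exponential approach: velocities match the analytic derivative
  tt <- seq(0, 2100, 5)
  amp <- 60 * (1 - exp(-tt / 300))
  vc <- velocity_curve(rotem_trace(tt, amp))
  analytic <- 60 / 300 * exp(-vc$time_s / 300) * 60
  expect_equal(vc$velocity_mm_min, analytic, tolerance = 1e-4)
  # duplicate timestamps smuggled past the constructor are caught
  broken <- structure(list(channel = "extem", times = c(0, 1, 1, 2),
                           amplitudes = c(0, 1, 2, 3)),
                      class = "rotem_trace")
  expect_error(velocity_curve(broken), class = "ricotem_invalid_input")
})

test_that("auc30 integrates the velocity curve to 30 minutes", {
  flat <- rotem_trace(c(0, 1800), c(0, 0))
  expect_equal(auc30(flat), 0)
  # reaching exactly 10 mm at 30 min from 0, scale 100 -> 1000
  tr <- rotem_trace(c(0, 900, 1800, 2100), c(0, 5, 10, 11))
  expect_equal(auc30(tr), 1000)
  short <- rotem_trace(c(0, 1500), c(0, 20))
  expect_error(auc30(short), class = "ricotem_insufficient_span")
})

test_that("auc30 obeys the fundamental-theorem identity and is refinement-invariant", {
  set.seed(11)
  for (i in 1:25) {
    tr <- random_monotone_trace(n = 30, tmax = 2400)
    if (max(tr$times) < 1800) next
    ident <- 100 * approx(tr$times, tr$amplitudes, xout = 1800)$y
    expect_equal(auc30(tr), ident, tolerance = 1e-9)
    # insert collinear midpoints: the integral must not move
    mids <- head(tr$times, -1) + diff(tr$times) / 2
    amps_mid <- approx(tr$times, tr$amplitudes, xout = mids)$y
    refined <- rotem_trace(sort(c(tr$times, mids)),
                           c(rbind(head(tr$amplitudes, -1), amps_mid),
                             tail(tr$amplitudes, 1)))
    expect_equal(auc30(refined), auc30(tr), tolerance = 1e-9)
  }
})

test_that("threshold extractors agree with a brute-force scan on random traces", {
  set.seed(7)
  for (i in 1:200) {
    tr <- random_monotone_trace()
    for (thr in c(2, 20, runif(1, 0.5, max(tr$amplitudes) + 1))) {
      got <- extract_ct(tr, threshold_mm = thr)
      want <- oracle_first_crossing(tr$times, tr$amplitudes, thr)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 0.02)
    }
    expect_gte(extract_mcf(tr), max(tr$amplitudes))
    ct <- extract_ct(tr)
    cft <- extract_cft(tr)
    if (!is.na(ct) && !is.na(cft)) expect_lte(ct, ct + cft)
  }
})

test_that("clot_parameters bundles the four extractors", {
  tt <- seq(0, 2100, 1)
  amp <- ifelse(tt >= 120, 60 * (1 - exp(-(tt - 120) / 300)), 0)
  cp <- clot_parameters(rotem_trace(tt, amp, channel = "extem"))
  expect_equal(cp$mcf_mm, max(amp))
  expect_equal(cp$auc30, 100 * amp[tt == 1800])
  expect_false(is.na(cp$ct_s))
  # short trace: AUC is NA, the rest still extract
  cp2 <- clot_parameters(rotem_trace(c(0, 600), c(0, 30)))
  expect_true(is.na(cp2$auc30))
  expect_equal(cp2$mcf_mm, 30)
})
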