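test_that("Ricotem- is the ristocetin/Extem AUC ratio in percent", {
  expect_identical(ricotem_minus(1234.5, 1234.5), 100)
  expect_identical(ricotem_minus(0, 800), 0)
  # the healthy worked example: a 94.5% AUC reduction is a score of 5.5%
  expect_equal(ricotem_minus(55, 1000), 5.5)
  expect_error(ricotem_minus(10, 0), class = "ricotem_invalid_input")
  expect_error(ricotem_minus(-1, 10), class = "ricotem_invalid_input")
})

test_that("Ricotem+ is the signed normalized AUC difference", {
  expect_identical(ricotem_plus(640, 640, 900), 0)
  # severe-deficiency worked example: 75.9% and 6.2% of the Extem AUC
  expect_equal(ricotem_plus(759, 62, 1000), 69.7)
  # healthy worked example: 5.5% rising to 14.0% gives a negative score
  expect_equal(ricotem_plus(55, 140, 1000), -8.5)
  expect_error(ricotem_plus(10, 10, -5), class = "ricotem_invalid_input")
})

test_that("scores are invariant to the device scale factor", {
  set.seed(3)
  for (i in 1:50) {
    ex <- runif(1, 100, 5000); ri <- runif(1, 0, ex); rh <- runif(1, 0, ex)
    ccc <- runif(1, 1e-3, 1e3)
    expect_equal(ricotem_minus(ri, ex), ricotem_minus(ccc * ri, ccc * ex))
    expect_equal(ricotem_plus(ri, rh, ex),
                 ricotem_plus(ccc * ri, ccc * rh, ccc * ex))
    expect_identical(
      classify_responder(ricotem_minus(ri, ex), ricotem_plus(ri, rh, ex)),
      classify_responder(ricotem_minus(ccc * ri, ccc * ex),
                         ricotem_plus(ccc * ri, ccc * rh, ccc * ex)))
    # Ricotem+ can never exceed Ricotem-, with equality only at AUC_rh = 0
    expect_lte(ricotem_plus(ri, rh, ex), ricotem_minus(ri, ex))
    expect_equal(ricotem_plus(ri, 0, ex), ricotem_minus(ri, ex))
  }
})

test_that("responder classification follows the stepwise cut-offs", {
  expect_identical(as.character(classify_responder(5.5)), "normal")
  expect_identical(as.character(classify_responder(75.9, 69.7)), "high")
  expect_identical(as.character(classify_responder(40, 10)), "low")
  # boundary conventions: ties at 25 stay normal; ties at 50 are high
  expect_identical(as.character(classify_responder(25, NA)), "normal")
  expect_identical(as.character(classify_responder(25.01, 50)), "high")
  expect_identical(as.character(classify_responder(25.01, 49.999)), "low")
  # negative Ricotem+ is a valid low-effect result
  expect_identical(as.character(classify_responder(30, -8.5)), "low")
})

test_that("a missing Ricotem+ is only an error when the score is needed", {
  expect_identical(as.character(classify_responder(10, NA)), "normal")
  err <- expect_error(
    classify_responder(c(10, 60), c(NA, NA), patient_id = c("A", "B")),
    class = "ricotem_missing_data")
  expect_match(conditionMessage(err), "B")
  expect_no_match(conditionMessage(err), "A")
})

test_that("classification is monotone in Ricotem+", {
  set.seed(4)
  lv <- function(x) as.integer(factor(x, levels = c("normal", "low", "high")))
  for (i in 1:100) {
    minus <- runif(1, 26, 100)
    p1 <- runif(1, -20, 100); p2 <- p1 + runif(1, 0, 50)
    expect_lte(lv(classify_responder(minus, p1)),
               lv(classify_responder(minus, p2)))
  }
})

test_that("ricotem_panel derives both scores and tolerates a missing channel", {
  pan <- ricotem_panel(auc_extem = c(1000, 2000), auc_rico = c(55, 1518),
                       auc_rico_haemate = c(140, NA),
                       patient_id = c("H", "T"))
  expect_equal(pan$ricotem_minus, c(5.5, 75.9))
  expect_equal(pan$ricotem_plus[1], -8.5)
  expect_true(is.na(pan$ricotem_plus[2]))
})

test_that("cut-off configuration is validated", {
  expect_error(cutoff_config(ricotem_minus_cutoff_pct = 0),
               class = "ricotem_invalid_parameter")
  expect_error(cutoff_config(ricotem_plus_cutoff_pct = 100),
               class = "ricotem_invalid_parameter")
  cfg <- cutoff_config(25, 35)
  expect_identical(as.character(classify_responder(60, 40, cfg)), "high")
})
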