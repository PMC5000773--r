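test_that("quench correction rescales counts by the counting efficiency", {
  expect_equal(quenchCorrect(31, 0.31), 100)
  expect_identical(quenchCorrect(57, 1), 57)
  expect_error(quenchCorrect(57, 0), "efficiency")
  expect_error(quenchCorrect(-1, 0.31), "non-negative")
})

test_that("mass balance and transfer percentage reproduce the worked arithmetic", {
  expect_equal(massBalance(4.6, 0.7), 3.9)
  expect_identical(massBalance(2.5, 0), 2.5)
  expect_identical(massBalance(1.0, 1.0), 0)
  expect_error(massBalance(1, 2), "uptake >= transferred")

  expect_equal(percentTransferred(4.6, 0.7), 100 * 0.7 / 4.6)
  expect_equal(round(percentTransferred(4.6, 0.7)), 15)
  expect_equal(percentTransferred(3, 3), 100)
  expect_identical(percentTransferred(3, 0), 0)
  expect_error(percentTransferred(0, 0), "positive")
})

test_that("recovery fraction behaves as a percentage of the retained tracer", {
  expect_equal(round(recoveryFraction(1.0, 1.2, 3.9)), 56)
  expect_identical(recoveryFraction(0, 0, 3.9), 0)
  expect_equal(recoveryFraction(2, 1.9, 3.9), 100)
  expect_warning(recoveryFraction(3, 2, 3.9), "exceeds")
  expect_error(recoveryFraction(1, 1, 0), "positive")
})

test_that("tissue concentration converts tracer content to the trophoblast water space", {
  expect_equal(tissueConcentration(1.03, 42, 0.15, 1), 1.03 / 6.3e-3)
  expect_equal(round(tissueConcentration(1.03, 42, 0.15, 1)), 163)
  # trophoblast volume of exactly 1 l returns the amount itself
  expect_equal(tissueConcentration(5, 1000, 1, 1), 5)
  expect_equal(tissueConcentration(1, 42, 0.075, 1),
               2 * tissueConcentration(1, 42, 0.15, 1))
  expect_error(tissueConcentration(1, 42, 1.5), "at most 1")
  expect_error(tissueConcentration(0, 42, 0.15), "positive")
})

test_that("basal-membrane gradient is the tissue-to-fetal concentration ratio", {
  expect_equal(bmGradient(163, 1), 163)
  expect_equal(bmGradient(163, 0.3), 163 / 0.3)
  expect_identical(bmGradient(5, 5), 1)
  expect_error(bmGradient(163, 0), "positive")
})

test_that("tracer accounts are internally consistent", {
  set.seed(33)
  for (i in 1:20) {
    uptake <- runif(1, 1, 10)
    transferred <- runif(1, 0, uptake)
    retained <- uptake - transferred
    free <- runif(1, 0, retained)
    protein <- runif(1, 0, retained - free)
    acc <- tracerAccount(uptake, transferred, free, protein)
    expect_equal(acc$retained + acc$transferred, acc$uptake)
    expect_equal(acc$percentTransferred,
                 100 * acc$transferred / acc$uptake)
    expect_gte(acc$recovery, 0)
    expect_lte(acc$recovery, 100 * (1 + 1e-12))
    expect_equal(acc$totalRecovered, free + protein)
  }
})

test_that("the accounting chain recovers ~100% of a conservative simulation", {
  traj <- simulatePerfusion()  # full protocol including the wash
  acc <- accountFromTrajectory(traj)
  expect_equal(acc$recovery, 100, tolerance = 1e-5)
  expect_equal(acc$retained, acc$uptake - acc$transferred)
  # protein ends up holding most of the retained tracer in the full model
  expect_gt(acc$protein / acc$retained, 0.5)
})
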