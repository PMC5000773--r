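test_that("fit targets validate feasibility", {
  expect_error(fitTargets(1e-11, 2e-11), "infeasible")
  expect_error(fitTargets(c(1, 2) * 1e-11, 1e-12), "same length")
  expect_error(fitTargets(-1e-11, 0), "positive")
  tg <- fitTargets(2e-11, 3e-12)
  expect_s3_class(tg, "fitTargets")
})

test_that("fitRates recovers generating parameters from noiseless targets", {
  truth <- transporterParams()
  g <- predictGrid(truth)
  fit <- fitRates(fitTargets(g$uptake, g$transfer, g$F_m, g$F_f))
  expect_lt(abs(fit$V_ex_mvm / truth$V_ex_mvm - 1), 0.05)
  expect_lt(abs(fit$V_fa_bm / truth$V_fa_bm - 1), 0.05)
  expect_lt(abs(fit$k_metab / truth$k_metab - 1), 0.05)
  expect_equal(fit$V_ex_bm, fit$V_fa_bm)  # shared BM Vmax constraint
  # and the fitted model reproduces the targets
  gf <- predictGrid(fit)
  expect_lt(max(abs(gf$uptake / g$uptake - 1)), 0.01)
  expect_lt(max(abs(gf$transfer / g$transfer - 1)), 0.01)
})

test_that("metabolised fraction matches the uptake/transfer split of the targets", {
  # transfer/uptake = 0.15 at steady state implies ~85% metabolised
  ss <- steadyState()
  fl <- attr(ss, "fluxes")
  expect_equal(fl[["metabolism"]] / fl[["uptake"]],
               1 - fl[["transfer"]] / fl[["uptake"]], tolerance = 1e-9)
})

test_that("fitRates without metabolism handles uptake == transfer targets", {
  truth <- transporterParams(k_metab = 0)
  variant <- modelVariant("transport")
  g <- predictGrid(truth, variant = variant)
  fit <- fitRates(fitTargets(g$uptake, g$transfer),
                  free = c("V_ex_mvm", "V_bm"), params = truth,
                  variant = variant)
  expect_lt(abs(fit$V_ex_mvm / truth$V_ex_mvm - 1), 0.05)
  expect_lt(abs(fit$V_fa_bm / truth$V_fa_bm - 1), 0.05)
  expect_error(fitRates(fitTargets(g$uptake, g$transfer),
                        free = "k_metab", variant = variant),
               "without metabolism")
  expect_error(fitRates(fitTargets(g$uptake, g$transfer), free = "K_ex"),
               "subset")
})

test_that("fitVdif round-trips, is linear at small permeability, and rejects unattainable targets", {
  vd0 <- 1.5e-3
  g <- predictGrid(transporterParams(V_dif = vd0),
                   variant = modelVariant("diffusion"))
  vd <- fitVdif(mean(g$uptake))
  expect_lt(abs(vd / vd0 - 1), 0.01)
  expect_identical(fitVdif(0), 0)
  # far below the fetal flows the permeability-uptake map is linear
  v1 <- fitVdif(2e-13)
  v2 <- fitVdif(4e-13)
  expect_lt(abs(v2 / (2 * v1) - 1), 0.05)
  # pure diffusion saturates at the flow-limited ceiling
  expect_error(fitVdif(2.2e-11), "ceiling")
})

test_that("sensitivity at factor 1 returns unit ratios and respects baseline symmetry", {
  sa <- sensitivityAnalysis(factor = 1, protocol = shortProtocol(),
                            parameters = c("V_ex_mvm", "k_metab"),
                            steadyOffsets = c(5, 8))
  expect_true(all(abs(sa$uptake_ratio - 1) < 1e-9))
  expect_true(all(abs(sa$transfer_ratio - 1) < 1e-9))
})

test_that("uptake is insensitive to the basal-membrane exchanger in tracer mode", {
  sa <- sensitivityAnalysis(parameters = "V_ex_bm",
                            protocol = shortProtocol(),
                            steadyOffsets = c(5, 8))
  v <- sa[sa$parameter == "V_ex_bm", ]
  expect_true(all(abs(v$uptake_ratio - 1) < 0.01))
})

test_that("uptake depends on the K/Vmax ratio in the trace-linear regime", {
  g0 <- predictGrid(protocol = shortProtocol(), steadyOffsets = c(5, 8))
  p <- transporterParams(V_ex_mvm = 3 * 1.977e-06, K_ex = 3 * 200e-6)
  g1 <- predictGrid(p, protocol = shortProtocol(), steadyOffsets = c(5, 8))
  expect_equal(g1$uptake, g0$uptake, tolerance = 1e-3)
})

test_that("model-vs-data regression returns the OLS coefficient of determination", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(suppressWarnings(as.numeric(regressModelVsData(x, x))), 1)
  # zero covariance with the predictor
  y <- c(1, -1, 0, 1, -1)
  x0 <- c(1, 1, 0, -1, -1)
  expect_equal(as.numeric(regressModelVsData(x0, y)), 0)
  expect_error(regressModelVsData(1:2, 1:2), "length")
})

test_that("transport truth is preferred over the diffusion prediction", {
  set.seed(11)
  gT <- predictGrid()
  gD <- predictGrid(variant = modelVariant("diffusion"))
  obs <- gT$uptake * exp(rnorm(9, sd = 0.05))
  r2T <- regressModelVsData(gT$uptake, obs)
  r2D <- regressModelVsData(gD$uptake, obs)
  expect_gt(r2T, r2D)
})

test_that("flow ANOVA detects a maternal effect and controls the null", {
  set.seed(21)
  # pure maternal-flow effect with small noise
  ds <- manualDataset(function(Fm, Ff) Fm, sd = 5e-4)
  au <- flowAnova(ds, "uptake")
  expect_lt(au$p.value[au$effect == "maternal_flow"], 0.05)
  expect_gt(au$p.value[au$effect == "fetal_flow"], 0.05)

  # pure noise: type-I control at the nominal level across seeds
  set.seed(22)
  hits <- replicate(40, {
    d <- manualDataset(function(Fm, Ff) 0 * Fm, sd = 1)
    a <- flowAnova(d, "uptake")
    any(a$p.value < 0.05)
  })
  # three tests per dataset at alpha 0.05: expect ~14% families with a hit
  expect_lt(mean(hits), 0.45)

  # constant response: nothing to detect
  dc <- manualDataset(function(Fm, Ff) 1 + 0 * Fm, sd = 0)
  ac <- flowAnova(dc, "uptake")
  expect_false(any(ac$p.value < 0.05, na.rm = TRUE))

  expect_error(flowAnova(manualDataset(function(Fm, Ff) Fm, nPlacentas = 1)),
               "2 placentas")
})
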