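test_that("datasets are reproducible under a fixed seed", {
  d1 <- generatePerfusionDataset(nPlacentas = 2, noiseCv = 0.1, seed = 5,
                                 protocol = shortProtocol())
  d2 <- generatePerfusionDataset(nPlacentas = 2, noiseCv = 0.1, seed = 5,
                                 protocol = shortProtocol())
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$placentas, d2$placentas)
  d3 <- generatePerfusionDataset(nPlacentas = 2, noiseCv = 0.1, seed = 6,
                                 protocol = shortProtocol())
  expect_false(identical(d1$samples$uptake, d3$samples$uptake))
})

test_that("a noiseless single placenta at reference weight reproduces the simulator", {
  ds <- generatePerfusionDataset(nPlacentas = 1, noiseCv = 0, weightSd = 0,
                                 seed = 1, protocol = shortProtocol())
  expect_warning(sm <- datasetSummary(ds, steadyOffsets = c(5, 8)),
                 "single placenta")
  traj <- simulatePerfusion(shortProtocol())
  expect_equal(ds$samples$A_maternal_venous, traj$samples$A_maternal_venous)
  expect_equal(ds$samples$uptake, traj$samples$uptake)
  expect_true(attr(sm, "seUndefined"))
  expect_true(all(is.na(sm$uptake_se)))
})

test_that("generator validates noise and weight settings", {
  expect_error(generatePerfusionDataset(noiseCv = -0.1), "noiseCv")
  expect_error(generatePerfusionDataset(weightMean = 5, weightMin = 10),
               "weight")
  expect_error(generatePerfusionDataset(nPlacentas = 0), "nPlacentas")
})

test_that("summary is invariant to placenta order and reflects weight variability", {
  ds <- generatePerfusionDataset(nPlacentas = 3, noiseCv = 0, seed = 9,
                                 protocol = shortProtocol())
  sm <- datasetSummary(ds, steadyOffsets = c(5, 8))
  perm <- ds
  ord <- order(-perm$samples$placenta, perm$samples$time)
  perm$samples <- perm$samples[ord, ]
  smPerm <- datasetSummary(perm, steadyOffsets = c(5, 8))
  expect_equal(sm, smPerm, ignore_attr = TRUE)
  # noiseless, but cotyledon weights differ: SE comes from weight variability
  expect_true(all(sm$uptake_se > 0))
  expect_equal(sm$n, rep(3, nrow(sm)))
})

test_that("noisy placenta means stay within sampling error of the noiseless value", {
  noiseless <- generatePerfusionDataset(nPlacentas = 1, noiseCv = 0,
                                        weightSd = 0, seed = 1,
                                        protocol = shortProtocol())
  sm0 <- suppressWarnings(datasetSummary(noiseless, steadyOffsets = c(5, 8)))
  ds <- generatePerfusionDataset(nPlacentas = 5, noiseCv = 0.1, weightSd = 0,
                                 seed = 17, protocol = shortProtocol())
  sm <- datasetSummary(ds, steadyOffsets = c(5, 8))
  expect_true(all(abs(sm$uptake - sm0$uptake) <= 3 * sm$uptake_se))
})

test_that("the generating truth is recorded in the dataset", {
  ds <- generatePerfusionDataset(nPlacentas = 1, noiseCv = 0.2, seed = 3,
                                 protocol = shortProtocol())
  expect_identical(ds$truth$seed, 3)
  expect_identical(ds$truth$noiseCv, 0.2)
  expect_s3_class(ds$truth$params, "transporterParams")
})
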