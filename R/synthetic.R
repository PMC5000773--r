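#' Generate a synthetic perfusion dataset with known ground truth
#'
#' Emulates the output structure of the dual perfusion experiment: for
#' each placenta a cotyledon weight is drawn (normal, truncated above a
#' minimum), the full flow protocol is simulated with the geometry and the
#' mass-dependent rate constants scaled to that weight (transporter
#' density per gram held constant), venous concentrations are sampled at
#' the protocol sampling times, and multiplicative lognormal measurement
#' noise with a given coefficient of variation is applied to the sampled
#' concentrations.  Uptake and transfer are derived from the noisy
#' samples exactly as in the experiment.
#'
#' The noise is mean-unbiased lognormal (scintillation-counting error
#' scales with the signal).  With `noiseCv = 0` and a single placenta at
#' the reference weight the samples equal the simulator output.
#'
#' @param params Generating [transporterParams()] (defined at the
#'   reference cotyledon mass).
#' @param variant A [modelVariant()] object.
#' @param nPlacentas Number of placentas (default 5).
#' @param noiseCv Coefficient of variation of the measurement noise
#'   (default 0.1).
#' @param weightMean,weightSd Cotyledon weight distribution in grams
#'   (defaults 42.0 and 9.7), truncated below at `weightMin`.
#' @param weightMin Lower truncation bound for weights, g.
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @param protocol A [flowProtocol()] object.
#' @param inflow A [perfusateInflow()] object.
#' @param referenceGeometry Geometry at which `params` are defined; per-g
#'   densities are taken from it.
#' @param pools A [substratePools()] object.
#' @param ... Passed to [simulatePerfusion()].
#' @return An object of class `"perfusionDataset"`: a list with `samples`
#'   (long data frame: placenta, nominal flows, sampling time, sampled
#'   concentrations, derived uptake and transfer), `placentas` (weights)
#'   and `truth` (generating parameters, variant, noise and seed).
#' @export
#' @examples
#' ds <- generatePerfusionDataset(nPlacentas = 2, noiseCv = 0.05, seed = 1,
#'                                protocol = flowProtocol(washDuration = 0))
generatePerfusionDataset <- function(params = transporterParams(),
                                     variant = modelVariant(),
                                     nPlacentas = 5,
                                     noiseCv = 0.1,
                                     weightMean = 42.0,
                                     weightSd = 9.7,
                                     weightMin = 10,
                                     seed = 1,
                                     protocol = flowProtocol(),
                                     inflow = perfusateInflow(),
                                     referenceGeometry = compartmentGeometry(),
                                     pools = substratePools(),
                                     ...) {
  if (!is.finite(noiseCv) || noiseCv < 0)
    stop("noiseCv must be non-negative")
  if (!is.finite(weightMean) || weightMean <= weightMin || weightSd < 0)
    stop("weight distribution must have positive spread above weightMin")
  if (nPlacentas < 1) stop("nPlacentas must be at least 1")

  set.seed(seed)
  drawWeight <- function() {
    repeat {
      w <- stats::rnorm(1, weightMean, weightSd)
      if (w > weightMin) return(w)
    }
  }
  weights <- if (weightSd == 0) rep(weightMean, nPlacentas) else
    vapply(seq_len(nPlacentas), function(i) drawWeight(), numeric(1))
  sigma <- sqrt(log(1 + noiseCv^2))

  refMass <- referenceGeometry$cotyledonMass
  allSamples <- vector("list", nPlacentas)
  for (i in seq_len(nPlacentas)) {
    scale <- weights[i] / refMass
    gi <- compartmentGeometry(
      cotyledonMass = weights[i],
      density = referenceGeometry$density,
      fractionM = referenceGeometry$v_m / referenceGeometry$cotyledonVolume,
      fractionS = referenceGeometry$v_s / referenceGeometry$cotyledonVolume,
      fractionF = referenceGeometry$v_f / referenceGeometry$cotyledonVolume,
      trophoblastFraction = referenceGeometry$trophoblastFraction)
    pi <- params
    for (nm in c("V_ex_mvm", "V_ex_bm", "V_fa_bm", "k_metab", "V_dif"))
      pi[[nm]] <- pi[[nm]] * scale
    traj <- simulatePerfusion(protocol, pi, pools, gi, variant, inflow, ...)
    smp <- traj$samples
    nS <- nrow(smp)
    noise <- function() if (noiseCv == 0) rep(1, nS) else
      stats::rlnorm(nS, meanlog = -sigma^2 / 2, sdlog = sigma)
    smp$A_maternal_venous <- smp$A_maternal_venous * noise()
    smp$A_fetal_venous <- smp$A_fetal_venous * noise()
    smp$C_fetal_venous <- smp$C_fetal_venous * noise()
    smp$uptake <- (smp$A_arterial - smp$A_maternal_venous) * smp$F_m
    smp$transfer <- smp$A_fetal_venous * smp$F_f
    smp$creatinine_transfer <- smp$C_fetal_venous * smp$F_f
    smp$placenta <- i
    smp$F_m_nominal <- smp$F_m
    smp$F_f_nominal <- smp$F_f
    allSamples[[i]] <- smp
  }
  samples <- do.call(rbind, allSamples)
  rownames(samples) <- NULL
  structure(
    list(samples = samples,
         placentas = data.frame(placenta = seq_len(nPlacentas),
                                weight = weights),
         truth = list(params = params, variant = variant, noiseCv = noiseCv,
                      weightMean = weightMean, weightSd = weightSd,
                      seed = seed),
         protocol = protocol, inflow = inflow),
    class = "perfusionDataset"
  )
}

#' @export
print.perfusionDataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic perfusion dataset: %d placentas (weights %.1f +/- %.1f g), %d samples\n",
    nrow(x$placentas), mean(x$placentas$weight),
    stats::sd(x$placentas$weight), nrow(x$samples)))
  cat(sprintf("  truth: variant '%s', noise CV %.2g, seed %d\n",
              x$truth$variant$name, x$truth$noiseCv, x$truth$seed))
  invisible(x)
}

#' Per-condition summary of a perfusion dataset
#'
#' Means and standard errors of uptake and transfer for each of the flow
#' conditions, computed from the quasi-steady samples (15 and 18 min by
#' default) averaged within placenta first, then across placentas — the
#' layout of the experimental summary figures.  With a single placenta
#' the standard errors are `NA` and flagged.
#'
#' @param dataset A [generatePerfusionDataset()] object.
#' @param steadyOffsets Sampling offsets (min) treated as quasi-steady.
#' @return A data frame with one row per flow condition: `F_m`, `F_f`,
#'   `uptake`, `uptake_se`, `transfer`, `transfer_se`, `n`; attribute
#'   `seUndefined` is `TRUE` when n = 1.
#' @export
datasetSummary <- function(dataset, steadyOffsets = c(15, 18)) {
  smp <- dataset$samples
  smp <- smp[!smp$is_baseline & smp$offset %in% steadyOffsets, ]
  if (nrow(smp) == 0) stop("no quasi-steady samples in dataset")
  per <- stats::aggregate(
    smp[, c("uptake", "transfer")],
    by = list(placenta = smp$placenta, segment = smp$segment,
              F_m = smp$F_m_nominal, F_f = smp$F_f_nominal),
    FUN = mean)
  n <- length(unique(per$placenta))
  se <- function(v) if (n < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(per, per$segment), function(d) {
    data.frame(segment = d$segment[1], F_m = d$F_m[1], F_f = d$F_f[1],
               uptake = mean(d$uptake), uptake_se = se(d$uptake),
               transfer = mean(d$transfer), transfer_se = se(d$transfer),
               n = nrow(d))
  }))
  out <- out[order(out$segment), ]
  rownames(out) <- NULL
  if (n < 2)
    warning("single placenta: standard errors are undefined")
  structure(out, seUndefined = n < 2)
}
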