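#' Calibration targets for the transport model
#'
#' Targets are steady-state uptake and transfer values, either as scalar
#' means over all flow conditions (as used when matching a reported
#' experimental average) or as per-condition vectors in protocol order
#' (as produced by [datasetSummary()], which makes all three free
#' parameters identifiable through the transient rise of transfer over
#' the protocol).
#'
#' @param uptake Target uptake, mol/min (scalar or one value per
#'   experimental sub-block).
#' @param transfer Target transfer, mol/min (same length as `uptake`).
#' @param F_m,F_f Optional flow annotations for vector targets, l/min.
#' @return An object of class `"fitTargets"`.
#' @export
fitTargets <- function(uptake, transfer, F_m = NULL, F_f = NULL) {
  if (length(uptake) != length(transfer))
    stop("uptake and transfer targets must have the same length")
  if (any(!is.finite(uptake)) || any(!is.finite(transfer)))
    stop("targets must be finite")
  if (any(uptake <= 0) || any(transfer < 0))
    stop("uptake targets must be positive and transfer targets non-negative")
  if (mean(transfer) > mean(uptake))
    stop("infeasible targets: mean transfer exceeds mean uptake ",
         "(tracer cannot appear from nothing)")
  structure(list(uptake = uptake, transfer = transfer, F_m = F_m, F_f = F_f),
            class = "fitTargets")
}

.applyFree <- function(params, free, theta) {
  for (i in seq_along(free)) {
    v <- exp(theta[i])
    if (free[i] == "V_bm") {
      params$V_ex_bm <- v
      params$V_fa_bm <- v
    } else {
      params[[free[i]]] <- v
    }
  }
  params
}

#' Fit maximal transport rates and the metabolic constant
#'
#' Deterministic least-squares calibration of the transport model against
#' uptake/transfer targets.  Free parameters are any subset of
#' `V_ex_mvm` (microvillous exchanger maximal rate), `V_bm` (the shared
#' basal-membrane maximal rate) and `k_metab`.  The objective is the sum
#' of squared relative errors between the model's [predictGrid()] values
#' (per-condition, or their mean for scalar targets) and the targets,
#' minimised on log-parameters by Levenberg-Marquardt from a fixed
#' multi-start grid, so the result is reproducible.
#'
#' @param targets A [fitTargets()] object.
#' @param free Character vector of free parameter names, a subset of
#'   `c("V_ex_mvm", "V_bm", "k_metab")`.
#' @param params Starting/fixed parameter set; fixed parameters are taken
#'   from here unchanged.
#' @inheritParams predictGrid
#' @return A [transporterParams()] object with fitted values; attributes
#'   `fit` (the best `nls.lm` object) and `relResidual` (the final
#'   root-mean-square relative residual).
#' @export
fitRates <- function(targets,
                     free = c("V_ex_mvm", "V_bm", "k_metab"),
                     params = transporterParams(),
                     geometry = compartmentGeometry(),
                     variant = modelVariant("transport+metabolism"),
                     mode = c("tracer", "physiological"),
                     protocol = flowProtocol(),
                     inflow = perfusateInflow(),
                     ...) {
  stopifnot(inherits(targets, "fitTargets"))
  mode <- match.arg(mode)
  allowed <- c("V_ex_mvm", "V_bm", "k_metab")
  if (length(free) == 0 || !all(free %in% allowed))
    stop("free must be a non-empty subset of ",
         paste(allowed, collapse = ", "))
  if ("k_metab" %in% free && !variant$metabolism)
    stop("cannot fit k_metab in a variant without metabolism")
  scalar <- length(targets$uptake) == 1
  pools <- substratePools(mode)

  resFun <- function(theta) {
    p <- .applyFree(params, free, theta)
    g <- predictGrid(p, geometry, variant, pools = pools,
                     protocol = protocol, inflow = inflow, ...)
    if (!scalar && nrow(g) != length(targets$uptake))
      stop("vector targets must have one value per experimental sub-block (",
           nrow(g), " in this protocol)")
    mu <- if (scalar) mean(g$uptake) else g$uptake
    mt <- if (scalar) mean(g$transfer) else g$transfer
    c((mu - targets$uptake) / mean(targets$uptake),
      (mt - targets$transfer) / max(mean(targets$transfer),
                                    1e-6 * mean(targets$uptake)))
  }

  # heuristic centre: invert the flow-extraction relation for the MVM rate,
  # split the BM rate and metabolic constant assuming an intracellular
  # tracer concentration scale of ~160 nmol/l, then multi-start along the
  # (V_bm, k_metab) ridge that scalar targets leave unresolved
  U <- mean(targets$uptake)
  Tr <- mean(targets$transfer)
  Fbar <- 14e-3
  Ain <- inflow$tracer_m
  R_s <- sum(pools$s)
  denom_ms <- params$K_ex * (sum(pools$m) + R_s + Ain) / 2 +
    (sum(pools$m) + Ain) * R_s
  cEff <- Fbar * U / max(Fbar * Ain - U, 0.05 * Fbar * Ain)
  h <- c(V_ex_mvm = max(cEff * denom_ms / R_s, 1e-9),
         V_bm = max(Tr, 1e-3 * U) * (params$K_fa + pools$s["fa"]) / 1.6e-7,
         k_metab = max(U - Tr, 1e-3 * U) / 1.6e-7)
  names(h) <- c("V_ex_mvm", "V_bm", "k_metab")

  ridge <- if (any(c("V_bm", "k_metab") %in% free)) c(0.2, 1, 5) else 1
  best <- NULL
  for (lam in ridge) {
    start <- log(sapply(free, function(nm)
      h[[nm]] * if (nm %in% c("V_bm", "k_metab")) lam else 1))
    fit <- minpack.lm::nls.lm(
      par = start, fn = resFun,
      lower = start - log(1e4), upper = start + log(1e4),
      control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-12,
                                           ftol = 1e-14))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (best$info == 0 || best$info == 9)
    stop(sprintf("fitRates did not converge; best residual %.3g",
                 sqrt(best$deviance / length(best$fvec))))
  out <- .applyFree(params, free, best$par)
  out$sharedBmVmax <- "V_bm" %in% free || params$sharedBmVmax
  attr(out, "fit") <- best
  attr(out, "relResidual") <- sqrt(best$deviance / length(best$fvec))
  out
}

#' Fit the effective diffusive permeability
#'
#' Calibrates `V_dif` so that the diffusion-only model variant reproduces
#' a target mean steady-state uptake over the flow protocol.  The mean
#' uptake is monotone in `V_dif`, so the fit is a bracketed root solve on
#' the log scale.
#'
#' @param targetUptake Target mean uptake, mol/min (>= 0; 0 returns 0).
#' @inheritParams predictGrid
#' @param tol Relative tolerance on the matched uptake.
#' @return The fitted `V_dif` in l/min.
#' @export
fitVdif <- function(targetUptake,
                    params = transporterParams(),
                    geometry = compartmentGeometry(),
                    protocol = flowProtocol(),
                    inflow = perfusateInflow(),
                    tol = 1e-4, ...) {
  if (!is.finite(targetUptake) || targetUptake < 0)
    stop("targetUptake must be non-negative")
  if (targetUptake == 0) return(0)
  variant <- modelVariant("diffusion")
  meanUptake <- function(logV) {
    p <- params
    p$V_dif <- exp(logV)
    mean(predictGrid(p, geometry, variant, protocol = protocol,
                     inflow = inflow, ...)$uptake)
  }
  lo <- log(1e-8); hi <- log(10)
  # diffusive uptake equals transfer and saturates at the flow-limited
  # ceiling ~ F_m F_f / (F_m + F_f) * A_in as V_dif grows
  uHi <- meanUptake(hi)
  if (targetUptake >= uHi)
    stop("targetUptake cannot be matched by the diffusion variant: ",
         sprintf("flow-limited ceiling is %.3g mol/min", uHi))
  r <- stats::uniroot(function(lv) meanUptake(lv) - targetUptake,
                      lower = lo, upper = hi, tol = 1e-3)
  # polish on the achieved-uptake scale
  r <- stats::uniroot(function(lv) meanUptake(lv) - targetUptake,
                      lower = r$root - 0.5, upper = r$root + 0.5,
                      tol = tol * abs(r$root) + 1e-8)
  exp(r$root)
}

#' Five-fold parameter sensitivity analysis
#'
#' Re-runs the protocol simulation with each kinetic parameter increased
#' and decreased by a given factor (default 5) and reports mean uptake and
#' transfer as ratios to the baseline prediction.  Basal-membrane maximal
#' rates are varied individually even when the baseline constrains them to
#' a shared value.
#'
#' @inheritParams predictGrid
#' @param factor Fold-change applied up and down (default 5).
#' @param parameters Parameters to vary.
#' @return A data frame of class `"sensitivityResult"` with columns
#'   `parameter`, `factor`, `uptake_ratio`, `transfer_ratio`, including a
#'   baseline row at factor 1 with both ratios exactly 1.
#' @export
sensitivityAnalysis <- function(params = transporterParams(),
                                variant = modelVariant("transport+metabolism"),
                                mode = c("tracer", "physiological"),
                                factor = 5,
                                geometry = compartmentGeometry(),
                                protocol = flowProtocol(),
                                inflow = perfusateInflow(),
                                parameters = c("V_ex_mvm", "K_ex", "V_ex_bm",
                                               "V_fa_bm", "K_fa", "k_metab"),
                                ...) {
  mode <- match.arg(mode)
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  pools <- substratePools(mode)
  base <- predictGrid(params, geometry, variant, pools = pools,
                      protocol = protocol, inflow = inflow, ...)
  u0 <- mean(base$uptake)
  t0 <- mean(base$transfer)
  params$sharedBmVmax <- FALSE
  rows <- list(data.frame(parameter = "baseline", factor = 1,
                          uptake_ratio = 1, transfer_ratio = 1))
  for (pm in parameters) {
    for (f in unique(c(factor, 1 / factor))) {
      p <- params
      p[[pm]] <- p[[pm]] * f
      g <- predictGrid(p, geometry, variant, pools = pools,
                       protocol = protocol, inflow = inflow, ...)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = pm, factor = f,
        uptake_ratio = mean(g$uptake) / u0,
        transfer_ratio = mean(g$transfer) / t0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivityResult", "data.frame")
  out
}

#' Coefficient of determination between model and data
#'
#' Ordinary least-squares regression of observed values on model
#' predictions, as used to compare the flow-design grid of predicted
#' uptake or transfer with experimental means.
#'
#' @param predicted,observed Numeric vectors of equal length (>= 3).
#' @return The R-squared of the regression (in \[0, 1\] for a fit with
#'   intercept), with the `lm` fit attached as attribute `"fit"`.
#' @export
regressModelVsData <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3)
    stop("predicted and observed must have equal length >= 3")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("inputs must be finite")
  fit <- stats::lm(observed ~ predicted)
  r2 <- summary(fit)$r.squared
  structure(r2, fit = fit)
}

#' Two-way ANOVA of uptake or transfer on the flow design
#'
#' Fixed-effects two-way analysis of variance with maternal and fetal flow
#' as discrete factors, applied to placenta-level condition means (the
#' quasi-steady samples averaged within each placenta and flow condition).
#' Repeated measurements within a placenta are averaged, not modelled.
#'
#' @param dataset A [generatePerfusionDataset()] object (or any list with
#'   a compatible `samples` data frame).
#' @param response `"uptake"` or `"transfer"`.
#' @param steadyOffsets Sampling offsets (min) averaged per condition.
#' @return A data frame with one row per effect (`maternal_flow`,
#'   `fetal_flow`, `interaction`): degrees of freedom, F statistic and
#'   p-value.  The `aov` fit is attached as attribute `"fit"`.
#' @export
flowAnova <- function(dataset, response = c("uptake", "transfer"),
                      steadyOffsets = c(15, 18)) {
  response <- match.arg(response)
  smp <- dataset$samples
  smp <- smp[!smp$is_baseline & smp$offset %in% steadyOffsets, ]
  if (length(unique(smp$placenta)) < 2)
    stop("flowAnova requires at least 2 placentas")
  agg <- stats::aggregate(smp[[response]],
                          by = list(placenta = smp$placenta,
                                    F_m = smp$F_m_nominal,
                                    F_f = smp$F_f_nominal),
                          FUN = mean)
  names(agg)[4] <- "y"
  if (length(unique(agg$F_m)) < 2 || length(unique(agg$F_f)) < 2)
    stop("flowAnova requires at least two levels of each flow factor")
  agg$F_m <- factor(agg$F_m)
  agg$F_f <- factor(agg$F_f)
  fit <- stats::aov(y ~ F_m * F_f, data = agg)
  tab <- summary(fit)[[1]]
  out <- data.frame(
    effect = c("maternal_flow", "fetal_flow", "interaction"),
    df = tab[1:3, "Df"],
    statistic = tab[1:3, "F value"],
    p.value = tab[1:3, "Pr(>F)"]
  )
  rownames(out) <- NULL
  structure(out, fit = fit)
}
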