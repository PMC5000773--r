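#' Simulate the perfusion protocol
#'
#' Integrates the three-compartment model over a stepwise flow protocol,
#' restarting the stiff solver at every flow change so that the state is
#' continuous across events while fluxes jump.  The trajectory carries the
#' compartment concentrations, the cumulative protein-incorporated amount
#' and the cumulative circuit inflows/outflows needed for tracer
#' mass-balance accounting, plus the venous samples drawn at the protocol
#' sampling times (venous concentration equals compartment concentration
#' under the well-mixed assumption).
#'
#' During wash segments all inflow concentrations are zero.
#'
#' @param protocol A [flowProtocol()] object.
#' @param params A [transporterParams()] object.
#' @param pools A [substratePools()] object.
#' @param geometry A [compartmentGeometry()] object.
#' @param variant A [modelVariant()] object.
#' @param inflow A [perfusateInflow()] object.
#' @param init Optional named initial state (`A_m`, `A_s`, `A_f`, `C_m`,
#'   `C_f` in mol/l, `P` in mol); defaults to all zero.
#' @param rtol,atol Solver relative/absolute tolerances (defaults 1e-8 and
#'   1e-15, matched to tracer concentration scales).
#' @param outputDt Output grid spacing, min.
#' @return An object of class `"perfusionTrajectory"`: a list with
#'   elements `time` (data frame of the full state over time), `samples`
#'   (venous samples with derived uptake and transfer), `cumulative`
#'   (tracer amounts in mol), `massBalanceError` (relative conservation
#'   residual; `NA` when the intracellular clamp breaks conservation) and
#'   the simulation inputs.
#' @export
#' @examples
#' traj <- simulatePerfusion(flowProtocol(baselineDuration = 10,
#'                                        washDuration = 0))
simulatePerfusion <- function(protocol = flowProtocol(),
                              params = transporterParams(),
                              pools = substratePools(),
                              geometry = compartmentGeometry(),
                              variant = modelVariant(),
                              inflow = perfusateInflow(),
                              init = NULL,
                              rtol = 1e-8, atol = 1e-15,
                              outputDt = 0.5) {
  stopifnot(inherits(protocol, "flowProtocol"))
  y <- stats::setNames(numeric(10), .stateNames)
  if (!is.null(init)) {
    known <- intersect(names(init), .stateNames)
    if (length(known) == 0)
      stop("init must use the state names ",
           paste(.stateNames[1:6], collapse = ", "))
    y[known] <- init[known]
    if (any(y[1:5] < 0)) stop("initial concentrations must be non-negative")
  }
  offsets <- attr(protocol, "sampleOffsets")
  washInflow <- perfusateInflow(0, 0, 0, 0)

  rows <- vector("list", nrow(protocol))
  samples <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    seg <- protocol[i, ]
    segInflow <- if (seg$tracer_on) inflow else washInflow
    p <- .rhsPars(params, pools, geometry, variant, seg$F_m, seg$F_f,
                  segInflow)
    sOff <- offsets[offsets <= seg$duration]
    times <- sort(unique(c(seq(0, seg$duration, by = outputDt),
                           seg$duration, sOff)))
    sol <- deSolve::lsoda(y = unname(y), times = times, func = .rhsCore,
                          parms = p, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failed in segment %d (t = %.1f..%.1f min)",
                   seg$segment, seg$t_start, seg$t_end))
    mat <- as.matrix(sol)
    concs <- mat[, 2:6, drop = FALSE]
    if (any(concs < -1e3 * atol)) {
      warning(sprintf(
        "segment %d: negative concentration excursion projected to zero",
        seg$segment))
    }
    mat[, 2:6] <- pmax(concs, 0)
    y <- stats::setNames(mat[nrow(mat), -1], .stateNames)

    df <- as.data.frame(mat)
    names(df) <- c("time", .stateNames)
    df$time <- df$time + seg$t_start
    df$segment <- seg$segment
    df$F_m <- seg$F_m
    df$F_f <- seg$F_f
    rows[[i]] <- if (i > 1) df[-1, ] else df

    if (length(sOff) && !seg$is_wash) {
      idx <- match(sOff, times)
      samples[[i]] <- data.frame(
        segment = seg$segment, F_m = seg$F_m, F_f = seg$F_f,
        is_baseline = seg$is_baseline, offset = sOff,
        time = seg$t_start + sOff,
        A_arterial = segInflow$tracer_m,
        A_maternal_venous = mat[idx, 2],
        A_fetal_venous = mat[idx, 4],
        C_maternal_venous = mat[idx, 5],
        C_fetal_venous = mat[idx, 6]
      )
    }
  }
  time <- do.call(rbind, rows)
  rownames(time) <- NULL
  samples <- do.call(rbind, samples)
  if (!is.null(samples)) {
    samples$uptake <- (samples$A_arterial - samples$A_maternal_venous) *
      samples$F_m
    samples$transfer <- samples$A_fetal_venous * samples$F_f
    samples$creatinine_transfer <- samples$C_fetal_venous * samples$F_f
    rownames(samples) <- NULL
  }

  cumulative <- list(
    inflow_m = unname(y["in_m"]), outflow_m = unname(y["out_m"]),
    inflow_f = unname(y["in_f"]), outflow_f = unname(y["out_f"]),
    metabolized = unname(y["P"]),
    uptake = unname(y["in_m"] - y["out_m"]),
    transfer = unname(y["out_f"] - y["in_f"])
  )
  retainedEnd <- geometry$v_m * y["A_m"] + geometry$v_s * y["A_s"] +
    geometry$v_f * y["A_f"] + y["P"]
  netIn <- (y["in_m"] - y["out_m"]) + (y["in_f"] - y["out_f"])
  mbe <- if (variant$clampIntracellular) NA_real_ else {
    denom <- max(unname(y["in_m"] + y["in_f"]), .Machine$double.xmin)
    unname(abs(retainedEnd - netIn)) / denom
  }

  structure(
    list(time = time, samples = samples, cumulative = cumulative,
         massBalanceError = mbe, finalState = y, protocol = protocol,
         params = params, pools = pools, geometry = geometry,
         variant = variant, inflow = inflow),
    class = "perfusionTrajectory"
  )
}

#' @export
print.perfusionTrajectory <- function(x, ...) {
  cat(sprintf(
    "Perfusion trajectory: %.0f min, variant '%s', %d samples\n",
    max(x$time$time), x$variant$name,
    if (is.null(x$samples)) 0L else nrow(x$samples)))
  cat(sprintf(
    "  cumulative uptake %.4g mol, transfer %.4g mol, metabolised %.4g mol\n",
    x$cumulative$uptake, x$cumulative$transfer, x$cumulative$metabolized))
  if (!is.na(x$massBalanceError))
    cat(sprintf("  mass-balance residual %.2g (relative)\n",
                x$massBalanceError))
  invisible(x)
}

#' Steady state at constant flows
#'
#' Finds the concentrations at which every time derivative vanishes for
#' fixed maternal and fetal flows, by integrating towards equilibrium and
#' polishing with damped Newton iterations on a finite-difference
#' Jacobian.  The returned state satisfies a flux balance: maternal uptake
#' equals fetal transfer plus metabolism.
#'
#' @inheritParams simulatePerfusion
#' @param F_m,F_f Constant flows, l/min (> 0).
#' @param init Optional initial concentrations (used as the fixed `A_s`
#'   when the intracellular clamp is active).
#' @param settleTime Integration horizon used to approach the steady state
#'   before polishing, min.
#' @return Named concentration vector (`A_m`, `A_s`, `A_f`, `C_m`, `C_f`,
#'   mol/l) with attributes `residual` (max |v_i dA_i/dt| relative to the
#'   dominant flux) and `fluxes` (steady uptake, transfer and metabolism,
#'   mol/min).
#' @export
steadyState <- function(params = transporterParams(),
                        pools = substratePools(),
                        geometry = compartmentGeometry(),
                        variant = modelVariant(),
                        F_m = 14e-3, F_f = 6e-3,
                        inflow = perfusateInflow(),
                        init = NULL, settleTime = 5000) {
  if (F_m <= 0 || F_f <= 0) stop("steadyState requires positive flows")
  p <- .rhsPars(params, pools, geometry, variant, F_m, F_f, inflow)
  y0 <- numeric(10)
  if (!is.null(init)) {
    known <- intersect(names(init), .stateNames[1:5])
    y0[match(known, .stateNames)] <- init[known]
  }

  fluxScale <- max(F_m * p$Ain_m, F_f * p$Ain_f,
                   F_m * p$Cin_m, F_f * p$Cin_f)
  concDeriv <- function(x) {
    y <- y0
    y[1:5] <- x
    .rhsCore(0, y, p)[[1]][1:5]
  }
  residual <- function(x) {
    d <- concDeriv(x)
    max(abs(d * c(p$v_m, p$v_s, p$v_f, p$v_m, p$v_f)))
  }

  if (fluxScale == 0) {
    # no input anywhere: the zero state is the steady state
    x <- if (variant$clampIntracellular) c(0, y0[2], 0, 0, 0) else numeric(5)
    return(structure(stats::setNames(x, .stateNames[1:5]),
                     residual = 0,
                     fluxes = c(uptake = 0, transfer = 0, metabolism = 0)))
  }

  sol <- deSolve::lsoda(y = y0, times = c(0, settleTime), func = .rhsCore,
                        parms = p, rtol = 1e-10, atol = 1e-18)
  x <- pmax(as.numeric(sol[nrow(sol), 2:6]), 0)
  free <- if (variant$clampIntracellular) c(1, 3, 4, 5) else 1:5

  tol <- 1e-12 * fluxScale
  for (iter in seq_len(50)) {
    if (residual(x) < tol) break
    f0 <- concDeriv(x)[free]
    J <- matrix(0, length(free), length(free))
    for (j in seq_along(free)) {
      h <- max(abs(x[free[j]]), fluxScale * 1e-3) * 1e-7
      xh <- x
      xh[free[j]] <- xh[free[j]] + h
      J[, j] <- (concDeriv(xh)[free] - f0) / h
    }
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- x
      xn[free] <- pmax(x[free] + lambda * step, 0)
      if (residual(xn) < residual(x) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  res <- residual(x)
  if (res >= tol)
    stop(sprintf("steadyState did not converge: residual %.3g (tol %.3g)",
                 res, tol))

  uptake <- F_m * (p$Ain_m - x[1])
  transfer <- F_f * x[3] - F_f * p$Ain_f
  metab <- if (p$metabolism) p$k_metab * x[2] else 0
  structure(stats::setNames(x, .stateNames[1:5]), residual = res,
            fluxes = c(uptake = uptake, transfer = transfer,
                       metabolism = metab))
}

#' Placental uptake from arteriovenous difference
#'
#' Uptake (mol/min) is the maternal arterial minus maternal venous
#' concentration times the maternal flow rate.  A negative value (net
#' release into the maternal circuit) is returned with a warning.
#'
#' @param C_ma Maternal arterial concentration, mol/l.
#' @param C_mv Maternal venous concentration, mol/l.
#' @param F_m Maternal flow, l/min (> 0).
#' @return Uptake, mol/min.
#' @export
computeUptake <- function(C_ma, C_mv, F_m) {
  if (any(F_m <= 0)) stop("computeUptake requires F_m > 0")
  u <- (C_ma - C_mv) * F_m
  if (any(u < 0)) warning("negative uptake: net release into the maternal circuit")
  u
}

#' Placental transfer from fetal venous appearance
#'
#' Transfer (mol/min) is the fetal venous concentration times the fetal
#' flow rate.
#'
#' @param C_fv Fetal venous concentration, mol/l.
#' @param F_f Fetal flow, l/min (> 0).
#' @return Transfer, mol/min (non-negative for non-negative concentration).
#' @export
computeTransfer <- function(C_fv, F_f) {
  if (any(F_f <= 0)) stop("computeTransfer requires F_f > 0")
  C_fv * F_f
}

#' Predicted uptake and transfer over the 3 x 3 flow design
#'
#' Runs the full protocol simulation and summarises each experimental
#' sub-block by its quasi-steady venous samples: uptake and transfer at
#' the 15- and 18-min sampling times, their mean (the primary summary),
#' and the time-average over the whole sub-block.
#'
#' In `"physiological"` mode the maternal generic amino acid pools are set
#' to physiological arterial levels (615 and 915 umol/l), which saturates
#' the microvillous exchanger so that delivery is no longer rate-limiting;
#' the tracer inflow itself is unchanged.
#'
#' @inheritParams simulatePerfusion
#' @param mode `"tracer"` or `"physiological"`; ignored when `pools` is
#'   supplied explicitly.
#' @param steadyOffsets Sampling offsets (min) treated as quasi-steady.
#' @return A data frame with one row per experimental sub-block: flows,
#'   sampled uptake/transfer at each steady offset, their means (`uptake`,
#'   `transfer`), block time-averages and the creatinine transfer.
#' @export
predictGrid <- function(params = transporterParams(),
                        geometry = compartmentGeometry(),
                        variant = modelVariant(),
                        mode = c("tracer", "physiological"),
                        pools = NULL,
                        protocol = flowProtocol(),
                        inflow = perfusateInflow(),
                        steadyOffsets = c(15, 18),
                        ...) {
  mode <- match.arg(mode)
  if (is.null(pools)) pools <- substratePools(mode)
  traj <- simulatePerfusion(protocol, params, pools, geometry, variant,
                            inflow, ...)
  smp <- traj$samples[!traj$samples$is_baseline &
                        traj$samples$offset %in% steadyOffsets, ]
  if (is.null(smp) || nrow(smp) == 0)
    stop("protocol has no experimental segments sampled at the steady offsets")
  segs <- unique(smp$segment)
  out <- do.call(rbind, lapply(segs, function(sg) {
    s <- smp[smp$segment == sg, ]
    tt <- traj$time[traj$time$segment == sg, ]
    d <- data.frame(segment = sg, F_m = s$F_m[1], F_f = s$F_f[1])
    for (k in seq_along(steadyOffsets)) {
      d[[paste0("uptake_", steadyOffsets[k])]] <- s$uptake[k]
      d[[paste0("transfer_", steadyOffsets[k])]] <- s$transfer[k]
    }
    d$uptake <- mean(s$uptake)
    d$transfer <- mean(s$transfer)
    d$uptake_block_mean <- mean((s$A_arterial[1] - tt$A_m) * s$F_m[1])
    d$transfer_block_mean <- mean(tt$A_f * s$F_f[1])
    d$creatinine_transfer <- mean(s$creatinine_transfer)
    d
  }))
  rownames(out) <- NULL
  attr(out, "trajectory") <- traj
  out
}
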