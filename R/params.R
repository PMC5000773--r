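#' Transporter, metabolic and diffusive parameters
#'
#' Bundles every kinetic constant of the placental transfer model in an
#' internally consistent unit system (mol, litres, minutes).  Maximal
#' transport rates (`V_*`, mol/min) and clearance constants (`k_metab`,
#' `V_dif`, l/min) refer to one perfused cotyledon; dissociation constants
#' (`K_*`, mol/l) are membrane properties and do not scale with tissue mass.
#'
#' The default maximal rates and the metabolic constant are calibrated so
#' that the default protocol simulation (see [flowProtocol()]) reproduces
#' the reference perfusion observables: cumulative tracer uptake of
#' 4.6 nmol per cotyledon over the 210-min tracer infusion, cumulative
#' transfer of 0.7 nmol, and an end-of-experiment free tissue tracer
#' concentration of ~163 nmol/l.  `V_dif` is calibrated so the
#' diffusion-only model variant matches the same cumulative uptake.
#'
#' @param V_ex_mvm Maximal exchange rate at the microvillous (maternal-facing)
#'   membrane, mol/min.
#' @param V_ex_bm Maximal exchange rate at the basal (fetal-facing) membrane,
#'   mol/min.
#' @param V_fa_bm Maximal facilitated-transport rate at the basal membrane,
#'   mol/min.
#' @param K_ex Dissociation constant of the exchanger, mol/l (default
#'   200 umol/l).
#' @param K_fa Dissociation constant of the facilitated transporter, mol/l
#'   (default 1,000 umol/l).
#' @param k_metab First-order metabolic clearance constant, l/min; converts
#'   free intracellular tracer into the protein-incorporated pool.
#' @param V_dif Effective paracellular diffusive permeability, l/min.
#' @param sharedBmVmax Logical; when `TRUE` (default) the basal-membrane
#'   exchanger and facilitated transporter are constrained to the same
#'   maximal rate and `V_ex_bm` must equal `V_fa_bm`.
#'
#' @return An object of class `"transporterParams"` (a named list).
#' @seealso [compartmentGeometry()], [substratePools()], [modelVariant()]
#' @export
#' @examples
#' p <- transporterParams()
#' p$K_ex  # 2e-04 mol/l
transporterParams <- function(V_ex_mvm = 1.977e-06,
                              V_ex_bm = 1.593e-07,
                              V_fa_bm = 1.593e-07,
                              K_ex = 200e-6,
                              K_fa = 1000e-6,
                              k_metab = 1.184e-04,
                              V_dif = 1.847e-03,
                              sharedBmVmax = TRUE) {
  vals <- c(V_ex_mvm = V_ex_mvm, V_ex_bm = V_ex_bm, V_fa_bm = V_fa_bm,
            K_ex = K_ex, K_fa = K_fa, k_metab = k_metab, V_dif = V_dif)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all transporter parameters must be finite and non-negative")
  }
  if (isTRUE(sharedBmVmax) && !isTRUE(all.equal(V_ex_bm, V_fa_bm))) {
    stop("sharedBmVmax = TRUE requires V_ex_bm == V_fa_bm")
  }
  structure(
    list(V_ex_mvm = V_ex_mvm, V_ex_bm = V_ex_bm, V_fa_bm = V_fa_bm,
         K_ex = K_ex, K_fa = K_fa, k_metab = k_metab, V_dif = V_dif,
         sharedBmVmax = isTRUE(sharedBmVmax)),
    class = "transporterParams"
  )
}

#' @export
print.transporterParams <- function(x, ...) {
  cat("Transporter parameters (mol, l, min):\n")
  cat(sprintf("  V_ex_mvm: %.4g mol/min   V_ex_bm: %.4g   V_fa_bm: %.4g%s\n",
              x$V_ex_mvm, x$V_ex_bm, x$V_fa_bm,
              if (x$sharedBmVmax) " (shared BM Vmax)" else ""))
  cat(sprintf("  K_ex: %.4g mol/l   K_fa: %.4g mol/l\n", x$K_ex, x$K_fa))
  cat(sprintf("  k_metab: %.4g l/min   V_dif: %.4g l/min\n",
              x$k_metab, x$V_dif))
  invisible(x)
}

#' Compartment volumes of the perfused cotyledon
#'
#' The model represents the cotyledon as three well-mixed volumes: the
#' maternal intervillous space (`m`), the syncytiotrophoblast (`s`) and the
#' fetal capillaries (`f`).  Volumes are derived from the cotyledon wet
#' weight under a 1 ml/g density assumption and fixed volume fractions.
#' The syncytiotrophoblast fraction defaults to 0.15, the value also used
#' to convert free tissue tracer content into a tissue concentration.
#'
#' @param cotyledonMass Cotyledon wet weight in grams (default 42, the mean
#'   of the reference perfusion series).
#' @param density Tissue density in ml per gram (default 1).
#' @param fractionM,fractionS,fractionF Volume fractions of the intervillous
#'   space, syncytiotrophoblast and fetal capillaries (defaults 0.25, 0.15,
#'   0.05; must sum to at most 1).
#' @param trophoblastFraction Fraction of placental volume occupied by
#'   trophoblast, used for tissue-concentration estimates (default 0.15).
#'
#' @return An object of class `"compartmentGeometry"` with volumes `v_m`,
#'   `v_s`, `v_f` in litres.
#' @export
#' @examples
#' g <- compartmentGeometry()
#' g$v_s  # 0.0063 l
compartmentGeometry <- function(cotyledonMass = 42,
                                density = 1,
                                fractionM = 0.25,
                                fractionS = 0.15,
                                fractionF = 0.05,
                                trophoblastFraction = 0.15) {
  if (!is.finite(cotyledonMass) || cotyledonMass <= 0)
    stop("cotyledonMass must be positive")
  if (!is.finite(density) || density <= 0)
    stop("density must be positive")
  fr <- c(fractionM, fractionS, fractionF)
  if (any(!is.finite(fr)) || any(fr <= 0))
    stop("volume fractions must be positive")
  if (sum(fr) > 1 + 1e-12)
    stop("volume fractions must not exceed the cotyledon volume (sum <= 1)")
  if (!is.finite(trophoblastFraction) ||
      trophoblastFraction <= 0 || trophoblastFraction > 1)
    stop("trophoblastFraction must be in (0, 1]")
  vol <- cotyledonMass * density / 1000  # litres
  structure(
    list(v_m = vol * fractionM, v_s = vol * fractionS, v_f = vol * fractionF,
         cotyledonMass = cotyledonMass, density = density,
         cotyledonVolume = vol, trophoblastFraction = trophoblastFraction),
    class = "compartmentGeometry"
  )
}

#' @export
print.compartmentGeometry <- function(x, ...) {
  cat(sprintf("Cotyledon %.3g g (%.3g ml/g): v_m %.4g l, v_s %.4g l, v_f %.4g l\n",
              x$cotyledonMass, x$density, x$v_m, x$v_s, x$v_f))
  invisible(x)
}

#' Generic amino acid substrate pools
#'
#' Two generic amino acids represent the endogenous substrate pools that
#' drive carrier fluxes: `fa` groups substrates of both the facilitated
#' transporters and the exchangers (the pool that includes phenylalanine),
#' `ex` groups substrates of the exchangers only.  Pools are boundary
#' conditions: they are held constant in every compartment throughout a
#' simulation, and only tracer, creatinine and the protein pool are
#' dynamic.
#'
#' Syncytiotrophoblast pools default to the literature sums 3,132 umol/l
#' (`fa`) and 4,491 umol/l (`ex`).  In `"tracer"` mode the maternal and
#' fetal perfusates carry no transporter substrates besides the tracer, so
#' those pools are zero.  In `"physiological"` mode the maternal pools are
#' set to 615 umol/l (`fa`) and 915 umol/l (`ex`), emulating physiological
#' maternal arterial amino acid levels.
#'
#' @param mode `"tracer"` (default) or `"physiological"`.
#' @param m,s,f Optional length-2 named numeric overrides
#'   `c(fa = ..., ex = ...)` in mol/l for the maternal, syncytiotrophoblast
#'   and fetal compartments.
#'
#' @return An object of class `"substratePools"`.
#' @export
#' @examples
#' substratePools("physiological")$m
substratePools <- function(mode = c("tracer", "physiological"),
                           m = NULL, s = NULL, f = NULL) {
  mode <- match.arg(mode)
  pools <- list(
    m = if (mode == "tracer") c(fa = 0, ex = 0) else c(fa = 615e-6, ex = 915e-6),
    s = c(fa = 3132e-6, ex = 4491e-6),
    f = c(fa = 0, ex = 0)
  )
  override <- list(m = m, s = s, f = f)
  for (cp in names(override)) {
    ov <- override[[cp]]
    if (!is.null(ov)) {
      if (length(ov) != 2 || !all(c("fa", "ex") %in% names(ov)))
        stop("pool overrides must be named numeric vectors c(fa = , ex = )")
      pools[[cp]] <- c(fa = unname(ov["fa"]), ex = unname(ov["ex"]))
    }
  }
  allv <- unlist(pools)
  if (any(!is.finite(allv)) || any(allv < 0))
    stop("substrate pool concentrations must be finite and non-negative")
  structure(c(pools, list(mode = mode)), class = "substratePools")
}

#' @export
print.substratePools <- function(x, ...) {
  cat(sprintf("Substrate pools (%s mode), mol/l:\n", x$mode))
  for (cp in c("m", "s", "f"))
    cat(sprintf("  %s: fa %.4g, ex %.4g\n", cp, x[[cp]]["fa"], x[[cp]]["ex"]))
  invisible(x)
}

#' Model variant flags
#'
#' Selects which transfer mechanisms act on the tracer.  The named variants
#' mirror the simulation scenarios of the perfusion study: `"diffusion"`
#' (paracellular diffusion only), `"transport"` (carrier-mediated transport
#' without intracellular metabolism) and `"transport+metabolism"` (the full
#' model).  Creatinine, the paracellular diffusion marker, always moves by
#' flow and diffusion regardless of the tracer flags.
#'
#' `clampIntracellular` holds the syncytiotrophoblast tracer concentration
#' fixed at its current value (d[A]s/dt = 0), the scenario in which
#' transfer no longer drifts with accumulating intracellular tracer.
#'
#' @param variant One of `"transport+metabolism"`, `"transport"`,
#'   `"diffusion"`, or `"custom"` (in which case the flags are taken from
#'   the remaining arguments).
#' @param transport,diffusion,metabolism Logical mechanism flags, used when
#'   `variant = "custom"`.
#' @param clampIntracellular Logical; clamp the syncytiotrophoblast tracer
#'   concentration.
#'
#' @return An object of class `"modelVariant"`.
#' @export
#' @examples
#' modelVariant("diffusion")
modelVariant <- function(variant = c("transport+metabolism", "transport",
                                     "diffusion", "custom"),
                         transport = TRUE, diffusion = FALSE,
                         metabolism = TRUE, clampIntracellular = FALSE) {
  variant <- match.arg(variant)
  flags <- switch(variant,
    "transport+metabolism" = list(transport = TRUE, diffusion = FALSE,
                                  metabolism = TRUE),
    "transport" = list(transport = TRUE, diffusion = FALSE,
                       metabolism = FALSE),
    "diffusion" = list(transport = FALSE, diffusion = TRUE,
                       metabolism = FALSE),
    "custom" = list(transport = isTRUE(transport),
                    diffusion = isTRUE(diffusion),
                    metabolism = isTRUE(metabolism))
  )
  if (!flags$transport && !flags$diffusion)
    stop("at least one transfer mechanism (transport or diffusion) must be enabled")
  structure(
    c(list(name = variant), flags,
      list(clampIntracellular = isTRUE(clampIntracellular))),
    class = "modelVariant"
  )
}

#' @export
print.modelVariant <- function(x, ...) {
  on <- c(transport = x$transport, diffusion = x$diffusion,
          metabolism = x$metabolism)
  cat(sprintf("Model variant '%s': %s%s\n", x$name,
              paste(names(on)[on], collapse = " + "),
              if (x$clampIntracellular) " (intracellular tracer clamped)" else ""))
  invisible(x)
}

#' Perfusate inflow concentrations
#'
#' Inlet concentrations of the dynamic species for the maternal and fetal
#' circuits.  The reference experiment infuses 2.7 nmol/l tracer
#' phenylalanine and 1.8 mmol/l creatinine into the maternal circuit only.
#'
#' @param tracer_m,tracer_f Tracer phenylalanine inflow, mol/l.
#' @param creatinine_m,creatinine_f Creatinine inflow, mol/l.
#' @return An object of class `"perfusateInflow"`.
#' @export
perfusateInflow <- function(tracer_m = 2.7e-9, tracer_f = 0,
                            creatinine_m = 1.8e-3, creatinine_f = 0) {
  v <- c(tracer_m = tracer_m, tracer_f = tracer_f,
         creatinine_m = creatinine_m, creatinine_f = creatinine_f)
  if (any(!is.finite(v)) || any(v < 0))
    stop("inflow concentrations must be finite and non-negative")
  structure(as.list(v), class = "perfusateInflow")
}
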