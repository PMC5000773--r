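#' Quench correction of scintillation counts
#'
#' Scales raw counts by the counting efficiency measured from spiked
#' standards (31% in the protein pellet of the reference experiments;
#' no quenching in the supernatant).
#'
#' @param counts Raw counts (non-negative).
#' @param efficiency Counting efficiency as a fraction in (0, 1].
#' @return Corrected counts, `counts / efficiency`.
#' @export
#' @examples
#' quenchCorrect(31, 0.31)  # 100
quenchCorrect <- function(counts, efficiency) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(!is.finite(efficiency)) || any(efficiency <= 0) ||
      any(efficiency > 1))
    stop("efficiency must be in (0, 1]")
  counts / efficiency
}

#' Tracer retained in the cotyledon
#'
#' Mass balance of the perfusion experiment: whatever was taken up from
#' the maternal circuit and not transferred to the fetal circuit remains
#' in the tissue.
#'
#' @param uptake Total uptake per cotyledon, nmol.
#' @param transferred Amount transferred to the fetal circuit, nmol.
#' @return Retained amount, nmol.
#' @export
#' @examples
#' massBalance(4.6, 0.7)  # 3.9
massBalance <- function(uptake, transferred) {
  if (any(!is.finite(c(uptake, transferred))))
    stop("inputs must be finite")
  if (any(transferred < 0) || any(uptake < transferred))
    stop("require uptake >= transferred >= 0")
  uptake - transferred
}

#' Percentage of uptake transferred to the fetal circuit
#'
#' @param uptake Total uptake, nmol (> 0).
#' @param transferred Transferred amount, nmol.
#' @return Percentage `100 * transferred / uptake` (full precision; round
#'   to the nearest integer for the conventional reported figure).
#' @export
#' @examples
#' percentTransferred(4.6, 0.7)  # 15.2...
percentTransferred <- function(uptake, transferred) {
  if (any(!is.finite(c(uptake, transferred))))
    stop("inputs must be finite")
  if (any(uptake <= 0)) stop("uptake must be positive")
  if (any(transferred < 0)) stop("transferred must be non-negative")
  100 * transferred / uptake
}

#' Recovery of retained tracer in the tissue fractions
#'
#' Fraction of the retained tracer recovered as free tracer plus
#' protein-incorporated tracer after homogenisation and protein
#' precipitation.
#'
#' @param free Free tissue tracer, nmol.
#' @param protein Protein-incorporated tracer, nmol.
#' @param retained Retained tracer from [massBalance()], nmol (> 0).
#' @return Recovery percentage `100 * (free + protein) / retained`; values
#'   above 100 are returned with a warning.
#' @export
#' @examples
#' recoveryFraction(1.0, 1.2, 3.9)  # 56.4...
recoveryFraction <- function(free, protein, retained) {
  if (any(!is.finite(c(free, protein, retained))))
    stop("inputs must be finite")
  if (any(c(free, protein) < 0)) stop("amounts must be non-negative")
  if (any(retained <= 0)) stop("retained must be positive")
  r <- 100 * (free + protein) / retained
  if (any(r > 100 * (1 + 1e-9)))
    warning("recovery exceeds 100% of the retained tracer")
  r
}

#' Free-tracer concentration in the trophoblast
#'
#' Converts the free tracer content of a cotyledon into a concentration in
#' the trophoblast water space, assuming a tissue density (default 1 ml/g)
#' and that the trophoblast occupies a fixed fraction of placental volume
#' (default 15%).
#'
#' @param free Free tissue tracer, nmol.
#' @param wetWeight Cotyledon wet weight, g.
#' @param trophoblastFraction Trophoblast volume fraction in (0, 1].
#' @param density Tissue density, ml per g.
#' @return Concentration in nmol/l.
#' @export
#' @examples
#' tissueConcentration(1.03, 42, 0.15, 1)  # ~163 nmol/l
tissueConcentration <- function(free, wetWeight, trophoblastFraction = 0.15,
                                density = 1) {
  v <- c(free, wetWeight, trophoblastFraction, density)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all inputs must be positive")
  if (any(trophoblastFraction > 1))
    stop("trophoblastFraction must be at most 1")
  volume_l <- wetWeight * density * trophoblastFraction / 1000
  free / volume_l
}

#' Tracer gradient across the basal membrane
#'
#' Ratio of the trophoblast free-tracer concentration to the fetal vein
#' concentration, the concentration gradient available to drive
#' basal-membrane efflux.
#'
#' @param tissueConc Trophoblast tracer concentration, nmol/l.
#' @param fetalVeinConc Fetal vein tracer concentration, nmol/l (> 0).
#' @return Dimensionless concentration ratio.
#' @export
#' @examples
#' bmGradient(163, 1)    # 163
#' bmGradient(163, 0.3)  # ~543
bmGradient <- function(tissueConc, fetalVeinConc) {
  if (any(!is.finite(c(tissueConc, fetalVeinConc))))
    stop("inputs must be finite")
  if (any(fetalVeinConc <= 0)) stop("fetalVeinConc must be positive")
  tissueConc / fetalVeinConc
}

#' Full tracer account for a perfused cotyledon
#'
#' Combines the experimental arithmetic into one report: retained tracer
#' from mass balance, percentage transferred, recovery of the retained
#' tracer in the measured tissue fractions, trophoblast free-tracer
#' concentration, and (optionally) the basal-membrane gradient.
#'
#' @param uptake Total uptake per cotyledon, nmol.
#' @param transferred Transferred amount, nmol.
#' @param free Free tissue tracer, nmol.
#' @param protein Protein-incorporated tracer, nmol.
#' @param wetWeight Cotyledon wet weight, g.
#' @param trophoblastFraction Trophoblast volume fraction.
#' @param density Tissue density, ml/g.
#' @param fetalVeinConc Optional fetal vein concentration, nmol/l, for the
#'   basal-membrane gradient.
#' @return An object of class `"tracerAccount"`: a list with `retained`,
#'   `percentTransferred`, `recovery` (each with a `rounded` companion),
#'   `tissueConcentration` (nmol/l) and `bmGradient` (or `NA`).
#' @export
#' @examples
#' tracerAccount(4.6, 0.7, free = 1.0, protein = 1.2)
tracerAccount <- function(uptake, transferred, free, protein,
                          wetWeight = 42, trophoblastFraction = 0.15,
                          density = 1, fetalVeinConc = NULL) {
  retained <- massBalance(uptake, transferred)
  pct <- percentTransferred(uptake, transferred)
  rec <- recoveryFraction(free, protein, retained)
  conc <- tissueConcentration(free, wetWeight, trophoblastFraction, density)
  grad <- if (is.null(fetalVeinConc)) NA_real_ else
    bmGradient(conc, fetalVeinConc)
  structure(
    list(uptake = uptake, transferred = transferred, free = free,
         protein = protein, retained = retained,
         percentTransferred = pct, percentTransferredRounded = round(pct),
         totalRecovered = free + protein,
         recovery = rec, recoveryRounded = round(rec),
         tissueConcentration = conc, bmGradient = grad),
    class = "tracerAccount"
  )
}

#' @export
print.tracerAccount <- function(x, ...) {
  cat("Tracer account (nmol per cotyledon):\n")
  cat(sprintf("  uptake %.3g, transferred %.3g (%d%%), retained %.3g\n",
              x$uptake, x$transferred, x$percentTransferredRounded,
              x$retained))
  cat(sprintf("  recovered %.3g free + %.3g protein = %.3g (%d%% of retained)\n",
              x$free, x$protein, x$totalRecovered, x$recoveryRounded))
  cat(sprintf("  trophoblast free tracer %.0f nmol/l\n",
              x$tissueConcentration))
  if (!is.na(x$bmGradient))
    cat(sprintf("  basal-membrane gradient %.0f-fold\n", x$bmGradient))
  invisible(x)
}

#' Tracer account computed from a simulated trajectory
#'
#' Applies the experimental accounting chain to a model trajectory:
#' cumulative maternal extraction as uptake, cumulative fetal outflow as
#' transfer, the protein pool as protein-incorporated tracer, and the
#' tracer remaining free in the three compartments as free tissue tracer.
#' Because the simulator conserves tracer, the recovery is ~100% — the
#' benchmark against which incomplete experimental recovery is judged.
#'
#' @param trajectory A [simulatePerfusion()] result.
#' @return A `"tracerAccount"` (amounts in nmol).
#' @export
accountFromTrajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "perfusionTrajectory"))
  g <- trajectory$geometry
  y <- trajectory$finalState
  toN <- 1e9  # mol -> nmol
  freeAmount <- (g$v_m * y[["A_m"]] + g$v_s * y[["A_s"]] +
                   g$v_f * y[["A_f"]]) * toN
  tracerAccount(
    uptake = trajectory$cumulative$uptake * toN,
    transferred = trajectory$cumulative$transfer * toN,
    free = freeAmount,
    protein = y[["P"]] * toN,
    wetWeight = g$cotyledonMass,
    trophoblastFraction = g$trophoblastFraction,
    density = g$density
  )
}
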