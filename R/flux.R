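#' Carrier-mediated exchanger (antiporter) net flux
#'
#' Net flux of substrate A from compartment I to compartment II through a
#' symmetric carrier that exchanges A against the other substrates of the
#' same carrier.  The flux is trans-stimulated: movement of A out of a
#' compartment requires counter-substrate on the opposite face.
#'
#' \deqn{J = V_{ex} \frac{A_I R_{II} - A_{II} R_I}
#'   {K_{ex} (Tot_I + Tot_{II})/2 + Tot_I\, Tot_{II}}}
#'
#' `Tot` is the total concentration of all carrier substrates in a
#' compartment (including A itself); `R` is the same sum excluding A.
#' The law is antisymmetric under swapping the compartments and vanishes at
#' exchange equilibrium (`A_I R_II == A_II R_I`).  When both `Tot` are zero
#' and `K_ex` is zero there is no substrate anywhere and the flux is
#' defined as zero.
#'
#' @param A_I,A_II Substrate A concentration in compartments I and II, mol/l.
#' @param R_I,R_II Summed carrier substrates excluding A, mol/l.
#' @param Tot_I,Tot_II Summed carrier substrates including A, mol/l.
#' @param V_ex Maximal exchange rate, mol/min.
#' @param K_ex Carrier dissociation constant, mol/l.
#' @return Net flux I -> II in mol/min.
#' @export
#' @examples
#' exchangerFlux(1, 0, 0, 1, 1, 1, V_ex = 1, K_ex = 0)  # 1
exchangerFlux <- function(A_I, A_II, R_I, R_II, Tot_I, Tot_II, V_ex, K_ex) {
  args <- c(A_I, A_II, R_I, R_II, Tot_I, Tot_II, V_ex, K_ex)
  if (any(!is.finite(args)))
    stop("exchangerFlux: all inputs must be finite")
  if (any(args < 0))
    stop("exchangerFlux: concentrations, V_ex and K_ex must be non-negative")
  denom <- K_ex * (Tot_I + Tot_II) / 2 + Tot_I * Tot_II
  num <- A_I * R_II - A_II * R_I
  ifelse(denom == 0, 0, V_ex * num / denom)
}

#' Facilitated transporter (uniporter) net flux
#'
#' Net flux of substrate A from compartment I to II through a saturable
#' carrier moving A down its gradient, with competition from the total
#' carrier substrate load on each face:
#' \deqn{J = V_{fa}\left(\frac{A_I}{K_{fa} + Tot_I} -
#'   \frac{A_{II}}{K_{fa} + Tot_{II}}\right)}
#' The flux is antisymmetric and bounded by `V_fa` in magnitude (given
#' `A <= Tot`, which holds by construction since Tot includes A).
#'
#' @param A_I,A_II Substrate A concentration, mol/l.
#' @param Tot_I,Tot_II Total facilitated-carrier substrate concentration
#'   (including A), mol/l.
#' @param V_fa Maximal transport rate, mol/min.
#' @param K_fa Carrier dissociation constant, mol/l (> 0).
#' @return Net flux I -> II in mol/min.
#' @export
#' @examples
#' facilitatedFlux(1, 0, 1, 0, V_fa = 1, K_fa = 1)  # 0.5
facilitatedFlux <- function(A_I, A_II, Tot_I, Tot_II, V_fa, K_fa) {
  args <- c(A_I, A_II, Tot_I, Tot_II, V_fa, K_fa)
  if (any(!is.finite(args)))
    stop("facilitatedFlux: all inputs must be finite")
  if (any(args < 0))
    stop("facilitatedFlux: inputs must be non-negative")
  if (any(K_fa <= 0))
    stop("facilitatedFlux: K_fa must be positive")
  V_fa * (A_I / (K_fa + Tot_I) - A_II / (K_fa + Tot_II))
}

#' Perfusate flow flux
#'
#' Net molecular flux into a well-mixed compartment perfused at flow `F`
#' with inlet concentration `A_in`; the venous outflow leaves at the
#' compartment concentration: `J = F (A_in - A)`.
#'
#' @param F_flow Flow rate, l/min (non-negative).
#' @param A_in Inlet concentration, mol/l.
#' @param A Compartment concentration, mol/l.
#' @return Net flux into the compartment, mol/min.
#' @export
flowFlux <- function(F_flow, A_in, A) {
  if (any(!is.finite(c(F_flow, A_in, A))))
    stop("flowFlux: all inputs must be finite")
  if (any(F_flow < 0))
    stop("flowFlux: flow must be non-negative")
  F_flow * (A_in - A)
}

#' Metabolic consumption flux
#'
#' First-order metabolic removal of free intracellular tracer,
#' `J = k_metab * A_s`, representing incorporation into protein (release
#' from the protein pool is not modelled).
#'
#' @param A_s Syncytiotrophoblast free tracer concentration, mol/l.
#' @param k_metab Metabolic clearance constant, l/min.
#' @return Consumption rate, mol/min (non-negative).
#' @export
metabolicFlux <- function(A_s, k_metab) {
  if (any(!is.finite(c(A_s, k_metab))))
    stop("metabolicFlux: all inputs must be finite")
  if (any(c(A_s, k_metab) < 0))
    stop("metabolicFlux: inputs must be non-negative")
  k_metab * A_s
}

#' Paracellular diffusion flux
#'
#' Simple diffusion from the maternal intervillous space directly into the
#' fetal capillary, `J = V_dif (A_m - A_f)`.
#'
#' @param A_m,A_f Maternal and fetal concentrations, mol/l.
#' @param V_dif Effective diffusive permeability, l/min.
#' @return Net flux m -> f, mol/min.
#' @export
diffusionFlux <- function(A_m, A_f, V_dif) {
  if (any(!is.finite(c(A_m, A_f, V_dif))))
    stop("diffusionFlux: all inputs must be finite")
  if (any(c(A_m, A_f, V_dif) < 0))
    stop("diffusionFlux: inputs must be non-negative")
  V_dif * (A_m - A_f)
}

# ---- right-hand side ------------------------------------------------------

# State vector layout used throughout the integrator:
#   1 A_m, 2 A_s, 3 A_f   free tracer, mol/l
#   4 C_m, 5 C_f          creatinine, mol/l
#   6 P                   cumulative tracer metabolised, mol
#   7 in_m, 8 out_m       cumulative maternal tracer in/outflow, mol
#   9 in_f, 10 out_f      cumulative fetal tracer in/outflow, mol
.stateNames <- c("A_m", "A_s", "A_f", "C_m", "C_f", "P",
                 "in_m", "out_m", "in_f", "out_f")

# Unchecked core; `p` carries scalars precomputed per protocol segment.
# Negative excursions from the integrator are projected to zero before the
# flux laws are evaluated (nonnegativity projection).
.rhsCore <- function(t, y, p) {
  A_m <- max(y[1], 0); A_s <- max(y[2], 0); A_f <- max(y[3], 0)
  C_m <- max(y[4], 0); C_f <- max(y[5], 0)

  J_ex_mvm <- 0; J_ex_bm <- 0; J_fa_bm <- 0; J_dif <- 0; J_metab <- 0
  if (p$transport) {
    Tot_m <- A_m + p$pool_m_fa + p$pool_m_ex
    Tot_s <- A_s + p$pool_s_fa + p$pool_s_ex
    Tot_f <- A_f + p$pool_f_fa + p$pool_f_ex
    R_m <- p$pool_m_fa + p$pool_m_ex
    R_s <- p$pool_s_fa + p$pool_s_ex
    R_f <- p$pool_f_fa + p$pool_f_ex
    den_ms <- p$K_ex * (Tot_m + Tot_s) / 2 + Tot_m * Tot_s
    den_sf <- p$K_ex * (Tot_s + Tot_f) / 2 + Tot_s * Tot_f
    if (den_ms > 0) J_ex_mvm <- p$V_ex_mvm * (A_m * R_s - A_s * R_m) / den_ms
    if (den_sf > 0) J_ex_bm <- p$V_ex_bm * (A_s * R_f - A_f * R_s) / den_sf
    J_fa_bm <- p$V_fa_bm *
      (A_s / (p$K_fa + A_s + p$pool_s_fa) - A_f / (p$K_fa + A_f + p$pool_f_fa))
  }
  if (p$diffusion) J_dif <- p$V_dif * (A_m - A_f)
  if (p$metabolism) J_metab <- p$k_metab * A_s

  dA_m <- (p$F_m * (p$Ain_m - A_m) - J_ex_mvm - J_dif) / p$v_m
  dA_s <- if (p$clamp) 0 else
    (J_ex_mvm - J_ex_bm - J_fa_bm - J_metab) / p$v_s
  dA_f <- (p$F_f * (p$Ain_f - A_f) + J_ex_bm + J_fa_bm + J_dif) / p$v_f

  # creatinine: flow and paracellular diffusion only
  J_dif_cr <- p$V_dif * (C_m - C_f)
  dC_m <- (p$F_m * (p$Cin_m - C_m) - J_dif_cr) / p$v_m
  dC_f <- (p$F_f * (p$Cin_f - C_f) + J_dif_cr) / p$v_f

  list(c(dA_m, dA_s, dA_f, dC_m, dC_f, J_metab,
         p$F_m * p$Ain_m, p$F_m * A_m, p$F_f * p$Ain_f, p$F_f * A_f))
}

.rhsPars <- function(params, pools, geometry, variant, F_m, F_f, inflow) {
  list(
    transport = variant$transport, diffusion = variant$diffusion,
    metabolism = variant$metabolism, clamp = variant$clampIntracellular,
    V_ex_mvm = params$V_ex_mvm, V_ex_bm = params$V_ex_bm,
    V_fa_bm = params$V_fa_bm, K_ex = params$K_ex, K_fa = params$K_fa,
    k_metab = params$k_metab, V_dif = params$V_dif,
    pool_m_fa = unname(pools$m["fa"]), pool_m_ex = unname(pools$m["ex"]),
    pool_s_fa = unname(pools$s["fa"]), pool_s_ex = unname(pools$s["ex"]),
    pool_f_fa = unname(pools$f["fa"]), pool_f_ex = unname(pools$f["ex"]),
    v_m = geometry$v_m, v_s = geometry$v_s, v_f = geometry$v_f,
    F_m = F_m, F_f = F_f,
    Ain_m = inflow$tracer_m, Ain_f = inflow$tracer_f,
    Cin_m = inflow$creatinine_m, Cin_f = inflow$creatinine_f
  )
}

#' Time derivative of the three-compartment state
#'
#' Evaluates the right-hand side of the compartmental model: tracer in the
#' maternal intervillous space, syncytiotrophoblast and fetal capillary,
#' creatinine in the two perfused compartments, and the cumulative
#' protein-incorporated amount.  Mechanism terms are omitted according to
#' the model variant; with `clampIntracellular` the syncytiotrophoblast
#' derivative is forced to zero.  Internal membrane fluxes cancel pairwise,
#' so total tracer (sum of `v_i * A_i` plus protein) changes only through
#' the two flow terms.
#'
#' @param state Named numeric vector with at least `A_m`, `A_s`, `A_f`,
#'   `C_m`, `C_f` (mol/l); a `P` entry (mol) is accepted and ignored.
#' @param pools A [substratePools()] object.
#' @param params A [transporterParams()] object.
#' @param geometry A [compartmentGeometry()] object.
#' @param F_m,F_f Maternal and fetal flow, l/min.
#' @param inflow A [perfusateInflow()] object.
#' @param variant A [modelVariant()] object.
#' @return Named numeric vector of derivatives: `dA_m`, `dA_s`, `dA_f`
#'   (mol/l/min), `dC_m`, `dC_f` (mol/l/min) and `dP` (mol/min).
#' @export
modelDerivatives <- function(state, pools, params, geometry, F_m, F_f,
                             inflow = perfusateInflow(),
                             variant = modelVariant()) {
  need <- c("A_m", "A_s", "A_f", "C_m", "C_f")
  if (!all(need %in% names(state)))
    stop("state must contain named entries ", paste(need, collapse = ", "))
  if (any(is.na(state[need])) || any(!is.finite(state[need])))
    stop("state contains NaN or non-finite concentrations")
  if (any(F_m < 0) || any(F_f < 0))
    stop("flows must be non-negative")
  p <- .rhsPars(params, pools, geometry, variant, F_m, F_f, inflow)
  y <- c(state[need], 0, 0, 0, 0, 0)
  d <- .rhsCore(0, unname(y), p)[[1]]
  c(dA_m = d[1], dA_s = d[2], dA_f = d[3], dC_m = d[4], dC_f = d[5],
    dP = d[6])
}
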