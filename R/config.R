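#' Write model parameters to a flat text configuration file
#'
#' Serialises a [transporterParams()] object to YAML with flat keys whose
#' names carry explicit unit suffixes (SI-like units: mol, l, min).
#'
#' @param params A [transporterParams()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeParamsConfig <- function(params, path) {
  stopifnot(inherits(params, "transporterParams"))
  cfg <- list(
    v_ex_mvm_mol_per_min = params$V_ex_mvm,
    v_ex_bm_mol_per_min = params$V_ex_bm,
    v_fa_bm_mol_per_min = params$V_fa_bm,
    k_ex_mol_per_l = params$K_ex,
    k_fa_mol_per_l = params$K_fa,
    k_metab_l_per_min = params$k_metab,
    v_dif_l_per_min = params$V_dif,
    shared_bm_vmax = params$sharedBmVmax
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read model parameters from a configuration file
#'
#' Counterpart of [writeParamsConfig()]; unknown keys raise an error
#' naming them, missing keys fall back to the defaults of
#' [transporterParams()].
#'
#' @param path Path to a YAML configuration written by
#'   [writeParamsConfig()].
#' @return A [transporterParams()] object.
#' @export
readParamsConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  keymap <- c(
    v_ex_mvm_mol_per_min = "V_ex_mvm",
    v_ex_bm_mol_per_min = "V_ex_bm",
    v_fa_bm_mol_per_min = "V_fa_bm",
    k_ex_mol_per_l = "K_ex",
    k_fa_mol_per_l = "K_fa",
    k_metab_l_per_min = "k_metab",
    v_dif_l_per_min = "V_dif",
    shared_bm_vmax = "sharedBmVmax"
  )
  bad <- setdiff(names(cfg), names(keymap))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  args <- stats::setNames(cfg, keymap[names(cfg)])
  do.call(transporterParams, args)
}
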