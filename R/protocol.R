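#' Stepwise perfusion flow protocol
#'
#' Builds the piecewise-constant maternal/fetal flow schedule of the dual
#' perfusion experiment.  The default reproduces the reference design: a
#' 30-min baseline at maternal 14 ml/min and fetal 6 ml/min, followed by
#' three 60-min maternal flow blocks (10, 14, 18 ml/min), each subdivided
#' into three 20-min fetal sub-blocks (3, 6, 9 ml/min), giving the complete
#' 3 x 3 flow design, and a final 15-min tracer-free wash.  Venous samples
#' are drawn 5, 10, 15 and 18 min into every segment; the 15- and 18-min
#' samples are treated as the quasi-steady-state measurements.
#'
#' @param maternalFlows Maternal block flows, l/min.
#' @param fetalFlows Fetal sub-block flows, l/min.
#' @param subBlockDuration Duration of each fetal sub-block, min.
#' @param baselineDuration Baseline (equilibration) duration, min; 0 omits
#'   the baseline segment.
#' @param baselineFm,baselineFf Baseline flows, l/min.
#' @param washDuration Tracer-free wash duration, min; 0 omits the wash.
#' @param sampleOffsets Sampling times within each segment, min.
#' @param segments Optional data frame with columns `F_m`, `F_f`,
#'   `duration` (and optionally `tracer_on`) overriding the factorial
#'   design entirely.
#' @return An object of class `"flowProtocol"`: a data frame of segments
#'   with onset/offset times, flows and flags, carrying the sampling
#'   offsets as an attribute.
#' @export
#' @examples
#' p <- flowProtocol()
#' nrow(p)  # 1 baseline + 9 experimental sub-blocks + 1 wash
flowProtocol <- function(maternalFlows = c(10, 14, 18) * 1e-3,
                         fetalFlows = c(3, 6, 9) * 1e-3,
                         subBlockDuration = 20,
                         baselineDuration = 30,
                         baselineFm = 14e-3,
                         baselineFf = 6e-3,
                         washDuration = 15,
                         sampleOffsets = c(5, 10, 15, 18),
                         segments = NULL) {
  if (is.null(segments)) {
    if (length(maternalFlows) < 1 || length(fetalFlows) < 1)
      stop("maternalFlows and fetalFlows must be non-empty")
    flows <- c(maternalFlows, fetalFlows, baselineFm, baselineFf)
    if (any(!is.finite(flows)) || any(flows <= 0))
      stop("flow rates must be positive")
    if (!is.finite(subBlockDuration) || subBlockDuration <= 0)
      stop("subBlockDuration must be positive")
    segs <- list()
    if (baselineDuration > 0) {
      segs[[1]] <- data.frame(F_m = baselineFm, F_f = baselineFf,
                              duration = baselineDuration,
                              is_baseline = TRUE, is_wash = FALSE,
                              tracer_on = TRUE)
    }
    for (Fm in maternalFlows) for (Ff in fetalFlows) {
      segs[[length(segs) + 1]] <- data.frame(
        F_m = Fm, F_f = Ff, duration = subBlockDuration,
        is_baseline = FALSE, is_wash = FALSE, tracer_on = TRUE)
    }
    if (washDuration > 0) {
      segs[[length(segs) + 1]] <- data.frame(
        F_m = baselineFm, F_f = baselineFf, duration = washDuration,
        is_baseline = FALSE, is_wash = TRUE, tracer_on = FALSE)
    }
    out <- do.call(rbind, segs)
  } else {
    if (!is.data.frame(segments) || nrow(segments) == 0)
      stop("segments must be a non-empty data frame")
    need <- c("F_m", "F_f", "duration")
    missing <- setdiff(need, names(segments))
    if (length(missing))
      stop("segments is missing columns: ", paste(missing, collapse = ", "))
    if (any(!is.finite(segments$duration)) || any(segments$duration <= 0))
      stop("segment durations must be positive")
    if (any(segments$F_m < 0) || any(segments$F_f < 0))
      stop("segment flows must be non-negative")
    out <- data.frame(F_m = segments$F_m, F_f = segments$F_f,
                      duration = segments$duration,
                      is_baseline = FALSE, is_wash = FALSE,
                      tracer_on = if ("tracer_on" %in% names(segments))
                        segments$tracer_on else TRUE)
  }
  if (any(!is.finite(sampleOffsets)) || any(sampleOffsets <= 0))
    stop("sampleOffsets must be positive")
  out$segment <- seq_len(nrow(out))
  out$t_start <- cumsum(c(0, out$duration[-nrow(out)]))
  out$t_end <- out$t_start + out$duration
  out <- out[, c("segment", "F_m", "F_f", "duration", "t_start", "t_end",
                 "is_baseline", "is_wash", "tracer_on")]
  structure(out, sampleOffsets = sort(unique(sampleOffsets)),
            class = c("flowProtocol", "data.frame"))
}

#' Build a flow protocol from a configuration list
#'
#' Thin validated wrapper around [flowProtocol()] accepting a plain list
#' (for instance read from a YAML file).  Recognised keys match the
#' arguments of [flowProtocol()]; unknown keys raise an error naming them.
#'
#' @param config A named list of protocol settings; `list()` gives the
#'   default protocol.
#' @return A `"flowProtocol"` object.
#' @export
buildProtocol <- function(config = list()) {
  if (!is.list(config))
    stop("config must be a list")
  allowed <- names(formals(flowProtocol))
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("unknown protocol configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(config$segments) && is.list(config$segments) &&
      !is.data.frame(config$segments)) {
    config$segments <- as.data.frame(config$segments)
  }
  do.call(flowProtocol, config)
}

#' @export
print.flowProtocol <- function(x, ...) {
  nexp <- sum(!x$is_baseline & !x$is_wash)
  cat(sprintf(
    "Flow protocol: %d segments (%s%d experimental%s), total %.0f min\n",
    nrow(x), if (any(x$is_baseline)) "baseline + " else "", nexp,
    if (any(x$is_wash)) " + wash" else "", max(x$t_end)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
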