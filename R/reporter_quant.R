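#' Median fluorescence intensity of a channel
#'
#' Standard median over gated events; even counts return the midpoint
#' of the two central order statistics.
#'
#' @param events Non-empty numeric vector of positive event intensities.
#' @return Positive scalar MFI.
#' @export
median_mfi <- function(events) {
  if (length(events) == 0L) stop("Empty channel: no events to compute MFI")
  stopifnot(all(events > 0))
  stats::median(events)
}

#' NGFR/Thy1.1 reporter ratio for one well
#'
#' The reporter readout is the ratio of the NGFR MFI (miRNA-responsive
#' reporter) to the Thy1.1 MFI (internal transfection control), which
#' cancels well-to-well transfection efficiency. Either channel may be
#' supplied as a precomputed MFI or as raw events (reduced by
#' [median_mfi()]); both modes yield identical ratios.
#'
#' @param ngfr_mfi,thy_mfi Precomputed channel MFIs (scalars), or `NULL`
#'   if events are given.
#' @param ngfr_events,thy_events Raw event vectors, used when the MFI is
#'   `NULL`.
#' @param floor Detection floor for the transfection control; a Thy1.1
#'   MFI at or below it indicates a failed transfection and errors.
#' @return Scalar NGFR/Thy1.1 ratio.
#' @export
reporter_ratio <- function(ngfr_mfi = NULL, thy_mfi = NULL,
                           ngfr_events = NULL, thy_events = NULL,
                           floor = 0) {
  if (is.null(ngfr_mfi)) ngfr_mfi <- median_mfi(ngfr_events)
  if (is.null(thy_mfi)) thy_mfi <- median_mfi(thy_events)
  if (thy_mfi <= floor)
    stop("Thy1.1 MFI at or below detection floor: failed transfection control")
  ngfr_mfi / thy_mfi
}

#' Normalize reporter ratios to the empty-vector condition
#'
#' Per construct, per-well NGFR/Thy1.1 ratios are averaged within the
#' miRNA-expressing and empty-vector groups; the normalized value is
#' their quotient, so the empty-vector condition is exactly 1 and
#' values below 1 indicate repression. A two-tailed two-sample t test
#' (Welch by default) on the per-well ratios accompanies each
#' construct.
#'
#' @param wells Data frame, one row per well: `well_id`, `construct`
#'   (e.g. `wt_utr`, `mut_utr`, `no_utr`), `vector` (`mir_expressing`
#'   or `empty`), `ngfr_mfi`, `thy_mfi`.
#' @param var_equal Passed to [stats::t.test()] (`FALSE` = Welch,
#'   default).
#' @return Data frame, one row per construct x vector group:
#'   `construct`, `vector`, `ratio_mean`, `normalized_value` (empty
#'   group = 1), `replicate_count`, `p_value` (on the mir vs empty
#'   comparison; `NA` for groups with < 2 replicates).
#' @export
normalize_reporter <- function(wells, var_equal = FALSE) {
  stopifnot(all(c("construct", "vector", "ngfr_mfi", "thy_mfi") %in% names(wells)))
  wells$ratio <- wells$ngfr_mfi / wells$thy_mfi
  rows <- list()
  for (con in unique(wells$construct)) {
    w <- wells[wells$construct == con, , drop = FALSE]
    mir <- w$ratio[w$vector == "mir_expressing"]
    emp <- w$ratio[w$vector == "empty"]
    if (length(emp) == 0L)
      stop("Construct ", con, " has no empty-vector wells; cannot normalize")
    if (length(mir) == 0L)
      stop("Construct ", con, " has no miRNA-expressing wells")
    p <- if (length(mir) >= 2L && length(emp) >= 2L)
      tryCatch(stats::t.test(mir, emp, var.equal = var_equal)$p.value,
               error = function(e) NA_real_)  # zero-variance groups
      else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      construct = con, vector = "empty", ratio_mean = mean(emp),
      normalized_value = 1, replicate_count = length(emp), p_value = NA_real_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      construct = con, vector = "mir_expressing", ratio_mean = mean(mir),
      normalized_value = mean(mir) / mean(emp),
      replicate_count = length(mir), p_value = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-dCt method
#'
#' `2^-(Ct_target - Ct_reference)`: one cycle of delta-Ct halves the
#' relative expression. The ddCt variant (additionally referenced to a
#' calibrator sample's dCt) is available but off by default.
#'
#' @param ct_target Ct of the target assay (cycles).
#' @param ct_reference Ct of the endogenous control (e.g. U6,
#'   miR-191-5p or beta-actin), same sample.
#' @param calibrator_dct Optional calibrator delta-Ct; when given, the
#'   2^-ddCt value relative to the calibrator is returned instead.
#' @return Positive relative-expression value(s); vectorized.
#' @export
relative_expression <- function(ct_target, ct_reference, calibrator_dct = NULL) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  dct <- ct_target - ct_reference
  if (!is.null(calibrator_dct)) dct <- dct - calibrator_dct
  2^(-dct)
}
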