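#' Assign dye-dilution events to division generations
#'
#' A covalent proliferation dye halves per division, so generation g has
#' theoretical fluorescence center `gen0_center / 2^g`. Each event is
#' assigned to the nearest center in log-fluorescence among generations
#' 0..`max_generations`; events dimmer than
#' `gen0_center / 2^(max_generations + 0.5)` are below the resolution
#' floor and are discarded (the discarded count is reported).
#'
#' @param fluorescence Positive numeric vector, one value per live
#'   gated event.
#' @param gen0_center Fluorescence center of the undivided peak,
#'   calibrated from an undivided reference well (see
#'   [calibrate_gen0()]).
#' @param max_generations Highest resolvable generation (default 8).
#' @param well_id Identifier carried into the result.
#' @return List of class `"generation_table"`: `well_id`, `counts`
#'   (events per generation 0..G), `precursors` (`counts / 2^g`),
#'   `discarded` (events below the floor).
#' @export
assign_generations <- function(fluorescence, gen0_center,
                               max_generations = 8L, well_id = NA_character_) {
  if (length(gen0_center) != 1L || is.na(gen0_center) || gen0_center <= 0)
    stop("gen0_center must be a single positive number (calibration error)")
  if (length(fluorescence) == 0L) stop("Empty event list for well ", well_id)
  stopifnot(all(fluorescence > 0), max_generations >= 1L)
  # generations measured in halvings from the undivided center
  gexact <- log2(gen0_center / fluorescence)
  below <- gexact > max_generations + 0.5
  g <- pmin(pmax(round(gexact[!below]), 0L), max_generations)
  counts <- tabulate(g + 1L, nbins = max_generations + 1L)
  structure(list(
    well_id = well_id,
    counts = counts,
    precursors = counts / 2^(0:max_generations),
    discarded = sum(below)
  ), class = "generation_table")
}

#' Calibrate the undivided-peak center from an undivided reference well
#'
#' The modal 1%-trimmed log-fluorescence of a known-undivided well
#' (e.g. a time-0 aliquot of the labeled Teffs): the top and bottom 1%
#' of events are trimmed, and the mode of the log10 density is
#' back-transformed. Calibrating from a well that has already divided
#' places the center on a later generation and shifts every assignment,
#' so only undivided events should be supplied.
#'
#' @param fluorescence Positive numeric vector of reference-well events.
#' @return Positive scalar, the generation-0 center.
#' @export
calibrate_gen0 <- function(fluorescence) {
  stopifnot(length(fluorescence) > 1L, all(fluorescence > 0))
  lf <- log10(fluorescence)
  q <- stats::quantile(lf, c(0.01, 0.99), names = FALSE)
  lf <- lf[lf >= q[1L] & lf <= q[2L]]
  dens <- stats::density(lf)
  10^dens$x[which.max(dens$y)]
}

#' Precursor-cohort statistics for one well
#'
#' Back-calculates founding precursors from per-generation counts:
#' generation g holds `n_g` events descending from `n_g / 2^g`
#' precursors. `percent_divided` is the percentage of precursors that
#' divided at least once -- the quantity entering the suppression
#' statistic -- and is unbiased by clonal expansion.
#'
#' @param table A `generation_table` from [assign_generations()], or a
#'   plain vector of per-generation counts (generation 0 first).
#' @return List: `total_precursors`, `percent_divided`.
#' @export
precursor_stats <- function(table) {
  counts <- if (inherits(table, "generation_table")) table$counts else table
  stopifnot(all(counts >= 0))
  prec <- counts / 2^(seq_along(counts) - 1L)
  total <- sum(prec)
  if (total == 0) stop("No precursors in well (total_precursors = 0); statistic undefined")
  list(total_precursors = total,
       percent_divided = 100 * sum(prec[-1L]) / total)
}

#' Percentage suppression of proliferation
#'
#' `S = 100 - (c/d x 100)`, where `c` is the percentage of proliferating
#' precursors in the presence of Tregs and `d` the percentage in their
#' absence. Negative values (enhanced proliferation) are reported
#' as-is, never clipped.
#'
#' @param c Percent proliferating precursors with Tregs (0--100).
#' @param d Percent proliferating precursors without Tregs (> 0).
#' @return Percentage suppression (scalar, can be negative).
#' @export
suppression_score <- function(c, d) {
  if (any(d <= 0)) stop("Reference well has no proliferation (d = 0); S undefined")
  stopifnot(all(c >= 0), all(c <= 100))
  100 - (c / d * 100)
}

#' Suppression curve across Teff:Treg titrations
#'
#' Computes percent-divided per well, then the suppression statistic per
#' coculture replicate against its matched Teff-alone reference (matched
#' by replicate id when available, otherwise the mean reference), and
#' averages replicates within each ratio. Results are ordered by
#' increasing Teff:Treg ratio.
#'
#' @param events Data frame of events: `well_id`, `fluorescence`.
#' @param wells Well metadata: `well_id`, `condition` (`teff_alone`,
#'   `coculture`, or `undivided` for a time-0 calibration aliquot),
#'   `ratio` (numeric Teff:Treg, `NA` unless `coculture`), `replicate`.
#' @param gen0_center Undivided-peak center. If `NULL`, calibrated via
#'   [calibrate_gen0()] from the pooled `undivided` wells when present,
#'   otherwise from the `teff_alone` wells (only valid if those are
#'   read before substantial division).
#' @param max_generations Passed to [assign_generations()].
#' @return Data frame, one row per ratio: `ratio`, `c`, `d`, `S`,
#'   `n_replicates`.
#' @export
suppression_curve <- function(events, wells, gen0_center = NULL,
                              max_generations = 8L) {
  stopifnot(all(c("well_id", "fluorescence") %in% names(events)),
            all(c("well_id", "condition") %in% names(wells)))
  ref_wells <- wells[wells$condition == "teff_alone", , drop = FALSE]
  if (nrow(ref_wells) == 0L)
    stop("No teff_alone reference well in metadata (configuration error)")
  if (is.null(gen0_center)) {
    und <- wells$well_id[wells$condition == "undivided"]
    cal_wells <- if (length(und) > 0L) und else ref_wells$well_id
    gen0_center <- calibrate_gen0(
      events$fluorescence[events$well_id %in% cal_wells])
  }
  wells <- wells[wells$condition != "undivided", , drop = FALSE]
  pd <- vapply(wells$well_id, function(w) {
    f <- events$fluorescence[events$well_id == w]
    precursor_stats(assign_generations(f, gen0_center, max_generations,
                                       well_id = w))$percent_divided
  }, numeric(1L))
  names(pd) <- wells$well_id

  has_rep <- "replicate" %in% names(wells)
  d_mean <- mean(pd[ref_wells$well_id])
  cc <- wells[wells$condition == "coculture", , drop = FALSE]
  if (nrow(cc) == 0L) stop("No coculture wells in metadata")
  ratios <- sort(unique(cc$ratio))
  rows <- lapply(ratios, function(r) {
    ww <- cc[cc$ratio == r, , drop = FALSE]
    s_rep <- vapply(seq_len(nrow(ww)), function(i) {
      d_i <- d_mean
      if (has_rep) {
        match_ref <- ref_wells$well_id[ref_wells$replicate == ww$replicate[i]]
        if (length(match_ref) == 1L) d_i <- pd[[match_ref]]
      }
      suppression_score(pd[[ww$well_id[i]]], d_i)
    }, numeric(1L))
    data.frame(ratio = r, c = mean(pd[ww$well_id]), d = d_mean,
               S = mean(s_rep), n_replicates = nrow(ww))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
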