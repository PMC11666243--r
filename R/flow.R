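#' Spike-in double normalization of a staining phenotype
#'
#' Each sample is harvested together with untreated spike-in cells that
#' share the staining bath, so dividing the treated population's median
#' intensity by the spike-in's removes staining-batch variation; dividing
#' again by the same ratio in the negative-control sample expresses the
#' phenotype relative to control:
#' `(sample_treated / sample_spikein) / (control_treated / control_spikein)`.
#'
#' @param sample_treated,sample_spikein Median intensities of the treated
#'   and spike-in populations in the sample of interest.
#' @param control_treated,control_spikein The same two medians in the
#'   negative-control sample (e.g. non-targeting sgRNA).
#' @return Unitless relative staining intensity.
#' @examples
#' proteostat_normalize(2000, 1000, 1000, 1000)  # 2.0
#' @export
proteostat_normalize <- function(sample_treated, sample_spikein,
                                 control_treated, control_spikein) {
  vals <- c(sample_treated, sample_spikein, control_treated,
            control_spikein)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all four medians must be positive and finite")
  }
  (sample_treated / sample_spikein) / (control_treated / control_spikein)
}

#' Median population intensities from an event table
#'
#' Convenience summary for [proteostat_normalize()]: the per-population
#' median of one channel in an event-level table.
#'
#' @param events data.frame with a `population` column and channel
#'   columns (see [simulate_flow_events()]).
#' @param channel Channel column name.
#' @return Named numeric vector of medians, one per population.
#' @export
population_medians <- function(events, channel) {
  if (!channel %in% names(events)) stop("no channel column '", channel, "'")
  vapply(split(events[[channel]], events$population),
         stats::median, numeric(1))
}

#' Background-subtracted ratiometric pH-reporter ratio
#'
#' The lysosomal pH reporter carries a pH-sensitive sfGFP and a
#' pH-insensitive mCherry. Median background fluorescence measured in
#' cognate non-reporter controls is subtracted channel-wise, and the
#' adjusted sfGFP / mCherry ratio is reported; higher ratios indicate a
#' less acidic lysosome.
#'
#' @param sfgfp_median,mcherry_median Median reporter intensities.
#' @param bg_sfgfp,bg_mcherry Median non-reporter background per channel
#'   (default 0).
#' @return Unitless ratio `(sfgfp - bg_sfgfp) / (mcherry - bg_mcherry)`.
#' @examples
#' phlare_ratio(1000, 600, 200, 100)  # 800/500 = 1.6
#' @export
phlare_ratio <- function(sfgfp_median, mcherry_median,
                         bg_sfgfp = 0, bg_mcherry = 0) {
  if (bg_sfgfp >= sfgfp_median || bg_mcherry >= mcherry_median) {
    stop("background exceeds signal; ratio undefined (no clamping)")
  }
  (sfgfp_median - bg_sfgfp) / (mcherry_median - bg_mcherry)
}

#' Galectin-3 puncta score for lysosomal membrane permeabilization
#'
#' Each imaging field's puncta count is normalized by the number of
#' average-cell-equivalents it contains
#' (`puncta / (total_cell_area / mean_cell_area)`), correcting for cell
#' density. Fields are averaged within each time point, and the maximal
#' per-time mean over the time course is the sample's LMP score.
#'
#' @param fields data.frame with columns `time_h`, `puncta`,
#'   `total_area`, `mean_cell_area` (one row per field).
#' @return List with `per_time` (data.frame `time_h`, `score`) and `max`
#'   (the reported time-course maximum).
#' @examples
#' gal3_puncta_score(data.frame(time_h = 0, puncta = 30,
#'                              total_area = 6000, mean_cell_area = 200))
#' @export
gal3_puncta_score <- function(fields) {
  req <- c("time_h", "puncta", "total_area", "mean_cell_area")
  miss <- setdiff(req, names(fields))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(fields$total_area <= 0) || any(fields$mean_cell_area <= 0)) {
    stop("areas must be positive")
  }
  if (any(fields$puncta < 0)) stop("puncta counts must be non-negative")
  per_field <- fields$puncta / (fields$total_area / fields$mean_cell_area)
  score <- vapply(split(per_field, fields$time_h), mean, numeric(1))
  per_time <- data.frame(time_h = as.numeric(names(score)),
                         score = unname(score))
  per_time <- per_time[order(per_time$time_h), , drop = FALSE]
  rownames(per_time) <- NULL
  list(per_time = per_time, max = max(per_time$score))
}
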