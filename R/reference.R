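# Published behavioural summary statistics, shipped as a read-only fixture,
# and standardized comparison of model metrics against them.

#' Published behavioural summary statistics
#'
#' Returns the behavioural reference table packaged with crawlwave: pooled
#' summary statistics of segmental-boundary contractions in freely
#' crawling first-instar larvae. At 25 degrees C (35 forward waves in 12
#' animals): normalized contraction duration 0.415 +/- 0.076,
#' intersegmental phase lag 0.087 +/- 0.050, wave duration 1.39 +/- 0.25 s,
#' duty cycle 0.83 +/- 0.22. The 34 degrees C conditions (15 forward and
#' 14 backward waves in 10 animals) were reported as similar to the
#' forward waves at 25 degrees C without printed pooled values, so those
#' rows carry the wave/animal counts with `NA` means. The fixture is
#' version-pinned: any edit fails a checksum test.
#'
#' @return A tibble with columns `quantity`, `condition`, `mean`, `sd`,
#'   `n_waves`, `n_animals`.
#' @examples
#' behavioral_summaries()
#' @export
behavioral_summaries <- function() {
  path <- system.file("extdata", "behavioral_summaries.csv",
                      package = "crawlwave", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "numeric",
                                    "numeric", "integer", "integer")))
}

#' Compare model metrics to a behavioural reference
#'
#' Standardizes the deviation of a model summary value from a behavioural
#' reference: `(model mean - reference mean) / reference sd`, plus a flag
#' for whether the model value lies within one SD of the reference.
#'
#' @param metrics A \code{cpg_wave_metrics} object, or a single numeric
#'   model value.
#' @param reference A one-row subset of [behavioral_summaries()] (or any
#'   data frame with `quantity`, `mean`, `sd`).
#' @return A one-row tibble with `quantity`, `model_value`,
#'   `reference_mean`, `reference_sd`, `deviation`, `within_1sd`.
#' @export
compare_to_reference <- function(metrics, reference) {
  stopifnot(is.data.frame(reference), nrow(reference) == 1)
  q <- reference$quantity
  value <-
    if (is.numeric(metrics)) {
      stopifnot(length(metrics) == 1)
      metrics
    } else if (inherits(metrics, "cpg_wave_metrics")) {
      switch(q,
             normalized_contraction_duration =
               mean(metrics$durations$normalized_duration),
             intersegmental_phase_lag = mean(metrics$lags$lag),
             wave_duration_s = metrics$wave_duration,
             abort(sprintf("cannot extract quantity '%s' from wave metrics",
                           q)))
    } else abort("`metrics` must be numeric or a cpg_wave_metrics object")
  dev <- (value - reference$mean) / reference$sd
  tibble(quantity = q, model_value = value,
         reference_mean = reference$mean, reference_sd = reference$sd,
         deviation = dev, within_1sd = abs(dev) <= 1 + 1e-12)
}
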