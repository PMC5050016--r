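# Plain-text on-disk formats: CSV tables with JSON sidecars for metadata.

#' Write / read a gamma-wave table
#'
#' CSV with columns `generator,side,site,start_s,scale_s,amp_uV,dur_s`.
#'
#' @param waves a [gamma_waves()] table.
#' @param path file path.
#' @return `read_waves_csv` returns a [gamma_waves()] table.
#' @export
write_waves_csv <- function(waves, path) {
  df <- data.frame(generator = waves$generator, side = waves$side,
                   site = waves$site, start_s = waves$start,
                   scale_s = waves$scale, amp_uV = waves$amp,
                   dur_s = waves$duration)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waves_csv
#' @export
read_waves_csv <- function(path) {
  df <- utils::read.csv(path)
  gamma_waves(start = df$start_s, scale = df$scale_s, amp = df$amp_uV,
              duration = df$dur_s, side = df$side, site = df$site,
              generator = df$generator)
}

#' Write / read spike trains
#'
#' CSV with columns `unit_id,class,time_s`.
#'
#' @param spikes data.frame `(unit_id, class, time_s)`.
#' @param path file path.
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(spikes[, c("unit_id", "class", "time_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) utils::read.csv(path)

#' Write a wave pairing to CSV + JSON summary
#'
#' The pairs table goes to `<path>`; the lag summary (JSON) to
#' `<path>.json` when `summary = TRUE`.
#'
#' @param pairing a [pair_waves()] result.
#' @param path CSV path.
#' @param summary also write the [lag_statistics()] JSON sidecar.
#' @param alpha CI level for the sidecar.
#' @export
write_pairs_csv <- function(pairing, path, summary = TRUE, alpha = 0.01) {
  utils::write.csv(pairing$pairs, path, row.names = FALSE)
  if (summary && nrow(pairing$pairs) >= 2) {
    s <- lag_statistics(pairing, alpha)
    jsonlite::write_json(
      list(mean_lag_ms = s$mean_lag, ci_low = unname(s$ci[1]),
           ci_high = unname(s$ci[2]), n_pairs = s$n_pairs,
           unilateral_pct = as.list(s$unilateral_pct)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read a multichannel recording as text
#'
#' Voltages as a samples x channels CSV (numeric, uV) plus a JSON sidecar
#' (`<path>.json`) carrying the rate, channel metadata and masks.
#'
#' @param rec an [lfp_recording()].
#' @param path CSV path.
#' @export
write_recording <- function(rec, path) {
  utils::write.csv(t(rec$voltages), path, row.names = FALSE)
  meta <- list(rate_hz = rec$rate,
               channel_meta = rec$channel_meta,
               epoch_masks = rec$epoch_masks)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  v <- t(as.matrix(utils::read.csv(path)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  masks <- meta$epoch_masks
  if (!is.null(masks)) masks <- matrix(unlist(masks), ncol = 2)
  cm <- meta$channel_meta
  if (!is.null(cm)) cm <- as.data.frame(cm)
  rownames(v) <- NULL
  lfp_recording(v, rate = meta$rate_hz, channel_meta = cm,
                epoch_masks = masks)
}

#' Write / read a generator decomposition as text
#'
#' Mixing matrix, activations and variance shares as CSVs under a common
#' stem (`<stem>_mixing.csv`, `<stem>_activations.csv`), with a JSON
#' sidecar for shares, labels and rate.
#'
#' @param dec a `generator_decomposition`.
#' @param stem path stem.
#' @export
write_decomposition <- function(dec, stem) {
  utils::write.csv(dec$mixing, paste0(stem, "_mixing.csv"),
                   row.names = FALSE)
  utils::write.csv(t(dec$activations), paste0(stem, "_activations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(variance_share = dec$variance_share,
                            labels = dec$labels, rate_hz = dec$rate),
                       paste0(stem, ".json"), digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(
    mixing = as.matrix(utils::read.csv(paste0(stem, "_mixing.csv"))),
    activations = t(as.matrix(utils::read.csv(
      paste0(stem, "_activations.csv")))),
    variance_share = meta$variance_share,
    labels = as.character(meta$labels), rate = meta$rate_hz,
    channel_meta = NULL, epoch_masks = NULL),
    class = "generator_decomposition")
}

#' Read a synthetic-generator configuration from YAML
#'
#' The YAML file holds scalar fields of [synth_config()] (e.g.
#' `epoch_length: 60`); unknown fields are rejected by the constructor.
#' Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return a validated [synth_config()].
#' @export
read_synth_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(synth_config, yaml::read_yaml(path))
}
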