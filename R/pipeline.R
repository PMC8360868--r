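# Orchestration: from a raw recording to one 12-feature row, and from a
# manifest of recordings to a cohort table.

#' Names of the twelve maturational EEG features
#' @export
feature_names <- function() {
  c("rel_delta", "rel_theta", "rel_alpha", "rel_beta", "sef75", "sef90",
    "sat_pct_total", "sat_pct_5min_mean", "ibi_median_s",
    "complexity_index", "slope_small", "mse_max")
}

# Per-epoch, per-channel feature vector (means over defined segments).
extract_epoch_channel <- function(rec, epoch, channel, config) {
  out <- setNames(rep(NA_real_, 12), feature_names())
  nseg <- c(spectral = 0L, mse = 0L)

  segs <- segmentize(epoch, "spectral_25s", config)
  sp <- lapply(seq_len(nrow(segs)), function(i) {
    x <- slice_samples(rec, segs$start_s[i], segs$end_s[i], channel)
    tryCatch(spectral_features(x, rec$fs_hz, config),
             error = function(e) NULL)
  })
  sp <- sp[!vapply(sp, is.null, TRUE)]
  if (length(sp) > 0) {
    out[1:6] <- colMeans(do.call(rbind, sp))
    nseg["spectral"] <- length(sp)
  }

  segs <- segmentize(epoch, "mse_100s", config)
  cx <- lapply(seq_len(nrow(segs)), function(i) {
    x <- slice_samples(rec, segs$start_s[i], segs$end_s[i], channel)
    f <- complexity_features(mse_curve(x, config), config)
    if (anyNA(f)) NULL else f
  })
  cx <- cx[!vapply(cx, is.null, TRUE)]
  if (length(cx) > 0) {
    out[c("complexity_index", "slope_small", "mse_max")] <-
      colMeans(do.call(rbind, cx))
    nseg["mse"] <- length(cx)
  }

  x <- slice_samples(rec, epoch$start_s, epoch$end_s, channel)
  ann <- detect_sats(x, rec$fs_hz, config)
  cf <- continuity_features(ann, config)
  out["sat_pct_total"] <- cf$sat_pct_total
  out["sat_pct_5min_mean"] <- cf$sat_pct_5min_mean
  out["ibi_median_s"] <- cf$ibi_median_s

  list(features = out, nseg = nseg)
}

#' Aggregate per-epoch, per-channel features into one value per feature
#'
#' The grand-averaging order of the pipeline: mean over the selected
#' epochs within each channel (a long first recording contributes up to
#' three 1-h epochs), then mean over the channels.  Undefined entries are
#' excluded from each mean, never imputed as zeros.
#'
#' @param tab data.frame with columns `epoch`, `channel` and one column
#'   per feature.
#' @return named numeric vector, one value per feature (NA when a feature
#'   is undefined everywhere).
#' @export
aggregate_features <- function(tab) {
  fcols <- setdiff(names(tab), c("epoch", "channel"))
  per_channel <- lapply(split(tab, tab$channel), function(d)
    colMeans(d[, fcols, drop = FALSE], na.rm = TRUE))
  out <- colMeans(do.call(rbind, per_channel), na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Extract the twelve maturational features of one recording
#'
#' Runs the full chain: band-pass/notch filtering, epoch cutting with the
#' programmatic quality flag, clean-epoch selection (up to three for a
#' multi-day recording, one otherwise), per-segment feature extraction,
#' then aggregation: mean over segments within each epoch, mean over the
#' selected epochs, and finally mean over the two channels.  Features are
#' averaged as features (not signals), so channel order is irrelevant.
#'
#' @param rec an [eeg_recording()] (raw; filtering is applied here).
#' @param config configuration list.
#' @return one-row data.frame: metadata, the 12 features,
#'   `n_seg_spectral`/`n_seg_mse` counts, and `missing_reason` (empty when
#'   all features are defined).
#' @export
extract_recording_features <- function(rec, config = neomat_config()) {
  filtered <- bandpass_notch(rec, config)
  epochs <- cut_epochs(filtered, config = config)
  sel <- select_clean_epochs(epochs)
  meta <- data.frame(subject_id = rec$subject_id,
                     recording_id = rec$recording_id,
                     pma_weeks = rec$pma_weeks, ga_weeks = rec$ga_weeks,
                     morphine = rec$morphine,
                     epoch_index = rec$epoch_index)
  empty <- setNames(as.list(rep(NA_real_, 12)), feature_names())
  if (nrow(sel) == 0) {
    return(cbind(meta, as.data.frame(empty), n_seg_spectral = 0L,
                 n_seg_mse = 0L, missing_reason = "no_clean_epoch"))
  }
  rows <- list()
  nseg <- c(spectral = 0L, mse = 0L)
  for (ch in filtered$channels) {
    for (i in seq_len(nrow(sel))) {
      res <- extract_epoch_channel(filtered, sel[i, ], ch, config)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(epoch = i, channel = ch),
              as.data.frame(as.list(res$features)))
      nseg <- nseg + res$nseg
    }
  }
  feats <- aggregate_features(do.call(rbind, rows))
  reason <- if (anyNA(feats))
    paste0("undefined:", paste(names(feats)[is.na(feats)], collapse = ","))
  else ""
  cbind(meta, as.data.frame(as.list(feats)),
        n_seg_spectral = nseg[["spectral"]], n_seg_mse = nseg[["mse"]],
        missing_reason = reason)
}

#' Extract features for every recording in a manifest
#'
#' @param manifest data.frame (or path to a CSV) with columns
#'   `subject_id`, `ga_weeks`, `morphine`, `recording_id`, `pma_weeks`,
#'   `path` (EDF or CSV waveform file) and optionally `epoch_index`.
#' @param config configuration list.
#' @return cohort table: one row per readable recording.  Unreadable
#'   recordings are skipped with a warning naming the file.
#' @export
run_extract <- function(manifest, config = neomat_config()) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    md <- manifest[i, ]
    tryCatch({
      rec <- suppressWarnings(read_eeg(md$path, md))
      extract_recording_features(rec, config)
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", md$path, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
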