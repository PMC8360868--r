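#' Default analysis configuration
#'
#' Returns the nested list of tunable parameters used throughout the
#' pipeline.  Any subset can be overridden by passing a list with the same
#' structure; unspecified entries keep their defaults.
#'
#' The defaults encode the analysis conventions of the pipeline:
#' 2--40 Hz zero-phase FIR band-pass with a 50 Hz notch, 1-h epochs,
#' Welch spectra on 25-s segments (4-s Hann sub-windows, 50% overlap,
#' 2--30 Hz reference band), NLEO burst detection with the published
#' detector constants (1.5-s smoothing, 1.5 uV^2 threshold, 1-s minimum
#' event, 0.5-s merge gap), and multiscale entropy on 100-s segments with
#' m = 2, r = 0.2 x SD, scales 1..20.
#'
#' @param override optional list of overrides, e.g.
#'   `list(sat = list(threshold = 2))`.
#' @return nested configuration list.
#' @export
neomat_config <- function(override = NULL) {
  cfg <- list(
    io = list(fs_hz = 256, epoch_len_s = 3600),
    qc = list(flat_fraction_max = 0.20, flat_run_min_s = 1,
              clip_rail_uv = 3276.7),
    filter = list(hp_hz = 2, lp_hz = 40, transition_hz = 1,
                  notch_hz = 50, notch_q = 30),
    spectral = list(window_s = 25, welch_sub_s = 4, welch_overlap = 0.5,
                    band_edges = c(2, 4, 8, 12, 30), ref_band = c(2, 30)),
    sat = list(smooth_s = 1.5, threshold = 1.5, min_sat_s = 1,
               min_gap_s = 0.5, min_ibi_s = 1, window_5min_s = 300),
    complexity = list(segment_s = 100, m = 2, r_factor = 0.2,
                      scales_max = 20, small_scale_range = c(1, 5))
  )
  modifyList(cfg, override %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom utils modifyList
NULL
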