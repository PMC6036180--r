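#' Default EEG frequency bands
#'
#' Delta 0.5-4, theta 4-7, alpha 7-13, beta 13-30 Hz, plus the whole range
#' W = 0.5-30 Hz. Per-band features are computed over the four classical
#' bands; W serves as the whole-range filter and as the denominator of
#' relative spectral power. Band membership on a frequency grid is taken as
#' the half-open interval `[lo, hi)`, so the four bands partition W exactly.
#'
#' @return data frame with columns `name`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "whole"),
             lo = c(0.5, 4, 7, 13, 0.5),
             hi = c(4, 7, 13, 30, 30))
}

band_mask <- function(freqs, lo, hi) freqs >= lo & freqs < hi

#' Feature-extraction configuration
#'
#' @param bands band table as from [default_bands()]; must contain a row
#'   named `whole` plus at least one feature band.
#' @param hemi_pairs homologous left/right channel pairs for the
#'   connectivity features ([default_hemi_pairs()] by default). Pairs whose
#'   channels are absent from a recording are dropped at extraction time.
#' @param reeg_win,reeg_overlap window length (s) and fractional overlap of
#'   the range-EEG peak-to-peak windows.
#' @param psd_win,psd_overlap Welch window length (s) and overlap.
#' @param sef_quantile spectral edge frequency quantile (0.95: the
#'   frequency below which 95% of in-band power lies).
#' @param higuchi_kmax maximum scale k of the Higuchi fractal dimension.
#' @param max_lag maximum envelope cross-correlation lag in seconds.
#' @param filter_order effective order of the zero-phase band filter.
#' @return a `feature_config` list.
#' @export
feature_config <- function(bands = default_bands(),
                           hemi_pairs = default_hemi_pairs(),
                           reeg_win = 2, reeg_overlap = 0.5,
                           psd_win = 2, psd_overlap = 0.5,
                           sef_quantile = 0.95,
                           higuchi_kmax = 6,
                           max_lag = 0.2,
                           filter_order = 4) {
  stop_if(!"whole" %in% bands$name, "bands must include a 'whole' row")
  stop_if(any(bands$lo >= bands$hi), "each band needs lo < hi")
  structure(list(bands = bands, hemi_pairs = hemi_pairs,
                 reeg_win = reeg_win, reeg_overlap = reeg_overlap,
                 psd_win = psd_win, psd_overlap = psd_overlap,
                 sef_quantile = sef_quantile, higuchi_kmax = higuchi_kmax,
                 max_lag = max_lag, filter_order = filter_order),
            class = "feature_config")
}

feature_bands <- function(cfg) cfg$bands[cfg$bands$name != "whole", , drop = FALSE]
whole_band <- function(cfg) cfg$bands[cfg$bands$name == "whole", , drop = FALSE]
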