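#' Canonical EEG frequency bands
#'
#' The four bands used throughout the package: theta (4-7 Hz),
#' alpha (8-13 Hz), beta (14-29 Hz) and gamma (30-47 Hz).
#'
#' @param bands Optional named list overriding the defaults. Each element
#'   must be a numeric vector `c(low_hz, high_hz)` with `low < high`.
#' @return Named list of two-element numeric vectors (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(theta = c(4, 7), alpha = c(8, 13),
                  beta = c(14, 29), gamma = c(30, 47))
  }
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("bands must be a named list")
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.numeric(b) || length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("band '", nm, "' must be c(low_hz, high_hz) with low < high")
  }
  bands
}

#' Default 32-channel 10-20 montage
#'
#' Electrode labels of the 32-channel wireless montage used by the package
#' defaults (10-20 placement; T3/T4/T5/T6 are the older labels for the
#' temporal row, with T5/T6 equivalent to the modern P7/P8).
#'
#' @return Character vector of 32 channel names.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8",
    "FC1", "FC2", "FC5", "FC6",
    "Cz", "C3", "C4",
    "CP1", "CP2", "CP5", "CP6",
    "T3", "T4", "T5", "T6",
    "Pz", "P3", "P4",
    "PO3", "PO4",
    "Oz", "O1", "O2",
    "A1", "A2")
}
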