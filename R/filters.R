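# Filter design and zero-phase application.
#
# Designs come from the `signal` package (Butterworth) except the powerline
# notch, for which `signal` offers no IIR designer: the standard RBJ biquad
# notch is computed in closed form. The per-sample recursion runs in
# compiled code (iir_filter_mat) so whole channel blocks filter at once.

design_butter <- function(fs, edges, type, order = 4L) {
  w <- edges / (fs / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("filter edge(s) ", paste(edges, collapse = "-"),
         " Hz invalid for fs = ", fs, " Hz")
  bt <- signal::butter(order, w, type = type)
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

# RBJ biquad notch at f0 Hz with quality factor Q.
design_notch <- function(fs, f0 = 50, Q = 30) {
  if (f0 >= fs / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filtering of a samples x channels matrix: forward-backward
# application with odd (reflected) edge padding to suppress end transients.
filtfilt_mat <- function(filt, x) {
  x <- as.matrix(x)
  nz <- max(length(filt$b), length(filt$a)) - 1L
  pad <- min(nrow(x) - 1L, 10L * nz)
  filtfilt_mat_cpp(filt$b, filt$a, x, pad)
}

# Power gain |H(f)|^2 of a filter at frequencies f (Hz), for calibration.
filter_power_gain <- function(filt, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w)
  H <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b /
    (outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a)
  Mod(drop(H))^2
}
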