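# Orthogonal Daubechies order-5 (10-tap) filter bank. Standard published
# coefficients; dec_hi is the conjugate-quadrature mirror of dec_lo.
DB5_DEC_LO <- c(0.0033357252854737712, -0.012580751999081999,
                -0.006241490212798274, 0.07757149384004572,
                -0.032244869584638375, -0.24229488706638203,
                0.13842814590132074, 0.7243085284377729,
                0.6038292697971896, 0.16010239797419293)
DB5_DEC_HI <- c(-0.16010239797419293, 0.6038292697971896,
                -0.7243085284377729, 0.13842814590132074,
                0.24229488706638203, -0.032244869584638375,
                -0.07757149384004572, -0.006241490212798274,
                0.012580751999081999, 0.0033357252854737712)

sym_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n)
  c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
}

#' Stationary (undecimated) Daubechies-5 wavelet decomposition
#'
#' A-trous analysis: at each level the filters are upsampled by inserting
#' zeros, so every detail band and the final approximation keep the length
#' of the input signal. Boundaries are handled by symmetric extension
#' before a circular transform (the extension is cropped again on
#' reconstruction).
#'
#' @param x numeric signal.
#' @param levels number of decomposition levels (default 3).
#' @param boundary `"symmetric"` (default) or `"circular"`.
#' @return An object of class `swt_decomp`: list with `approx` and
#'   `details` (a length-`levels` list of coefficient bands, level 1 the
#'   finest), plus bookkeeping for [iswt_db5()].
#' @export
swt_db5 <- function(x, levels = 3, boundary = c("symmetric", "circular")) {
  boundary <- match.arg(boundary)
  if (anyNA(x)) stop("signal contains NA")
  n <- length(x)
  if (n < length(DB5_DEC_LO)) stop("signal shorter than the filter support")
  pad <- if (boundary == "symmetric") 2L^levels * length(DB5_DEC_LO) else 0L
  xp <- if (pad > 0L) sym_pad(x, pad) else x
  pad <- (length(xp) - n) %/% 2L
  res <- swt_analysis_cpp(xp, DB5_DEC_LO, DB5_DEC_HI, levels)
  details <- lapply(seq_len(levels), function(l) res$details[, l])
  structure(list(approx = res$approx, details = details, n = n, pad = pad,
                 levels = levels, variant = "stationary"),
            class = "swt_decomp")
}

#' Inverse stationary Daubechies-5 transform
#' @param decomp an `swt_decomp` from [swt_db5()].
#' @return The reconstructed signal, cropped to the original length.
#' @export
iswt_db5 <- function(decomp) {
  stopifnot(inherits(decomp, "swt_decomp"))
  det <- do.call(cbind, decomp$details)
  y <- swt_synthesis_cpp(decomp$approx, det, DB5_DEC_LO, DB5_DEC_HI)
  y[(decomp$pad + 1L):(decomp$pad + decomp$n)]
}

#' Decimated (periodized) Daubechies-5 wavelet decomposition
#'
#' Classical pyramid transform in which band `l` has roughly `1/2^l` of the
#' input samples. Kept for comparison with the stationary variant; the
#' signal is symmetrically extended to a multiple of `2^levels` and cropped
#' after reconstruction.
#'
#' @inheritParams swt_db5
#' @return An object of class `dwt_decomp` (same shape as [swt_db5()]'s
#'   result, but bands shrink by 2 per level).
#' @export
dwt_db5 <- function(x, levels = 3) {
  if (anyNA(x)) stop("signal contains NA")
  n <- length(x)
  block <- 2L^levels
  if (n < length(DB5_DEC_LO)) stop("signal shorter than the filter support")
  total <- ceiling(n / block) * block
  extra <- total - n
  lpad <- extra %/% 2L
  xp <- if (extra > 0L)
    c(rev(x[seq_len(lpad)]), x, rev(x[(n - (extra - lpad) + 1L):n]))
  else x
  if (extra > 0L && lpad == 0L) xp <- c(x, rev(x[(n - extra + 1L):n]))
  a <- xp
  details <- vector("list", levels)
  nf <- length(DB5_DEC_LO)
  for (l in seq_len(levels)) {
    nn <- length(a)
    m <- nn %/% 2L
    idx0 <- 2L * (seq_len(m) - 1L)                       # 0-based
    anew <- numeric(m); d <- numeric(m)
    for (k in seq_len(nf)) {
      xi <- a[((idx0 + (k - 1L)) %% nn) + 1L]
      anew <- anew + DB5_DEC_LO[k] * xi
      d <- d + DB5_DEC_HI[k] * xi
    }
    details[[l]] <- d
    a <- anew
  }
  structure(list(approx = a, details = details, n = n, lpad = lpad,
                 levels = levels, variant = "decimated"),
            class = "dwt_decomp")
}

#' Inverse decimated Daubechies-5 transform
#' @param decomp a `dwt_decomp` from [dwt_db5()].
#' @return The reconstructed signal, cropped to the original length.
#' @export
idwt_db5 <- function(decomp) {
  stopifnot(inherits(decomp, "dwt_decomp"))
  a <- decomp$approx
  nf <- length(DB5_DEC_LO)
  for (l in rev(seq_len(decomp$levels))) {
    d <- decomp$details[[l]]
    m <- length(d)
    nn <- 2L * m
    y <- numeric(nn)
    # x[n] = sum_m a[m] h0[(n - 2m) mod nn] + d[m] h1[(n - 2m) mod nn]
    for (k in seq_len(nf)) {
      pos <- ((2L * (seq_len(m) - 1L) + (k - 1L)) %% nn) + 1L
      contrib <- DB5_DEC_LO[k] * a + DB5_DEC_HI[k] * d
      y[pos] <- y[pos] + contrib
    }
    a <- y
  }
  a[(decomp$lpad + 1L):(decomp$lpad + decomp$n)]
}

#' Continuous-wavelet response with a Ricker kernel
#'
#' Correlates the signal with a Ricker (Mexican-hat) wavelet at one scale,
#' the standard kernel for isolating QRS-like cardiac transients. The
#' response has the same length as the input (edges zero-filled); its local
#' maxima sit at the centres of matching transients.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate in Hz.
#' @param scale_ms kernel scale, interpreted as the full central-lobe width
#'   in milliseconds (default 5).
#' @return Numeric response series, same length as `x`.
#' @export
cwt_ricker <- function(x, sample_rate, scale_ms = 5) {
  if (scale_ms <= 0) stop("scale_ms must be positive")
  if (scale_ms / 1000 >= length(x) / sample_rate)
    stop("scale exceeds the signal duration")
  a_s <- scale_ms / 2000
  half <- max(1L, round(3 * a_s * sample_rate))
  kern <- ricker_wavelet((-half:half) / sample_rate, a_s)
  kern <- kern / sqrt(sum(kern^2))
  y <- stats::filter(x, kern, method = "convolution", sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}
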