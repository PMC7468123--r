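# Least-asymmetric orthonormal scaling filter of length 8 (LA8), the
# conventional default of the WMTSA-style wavelet toolboxes.  Published
# constants; the quadrature-mirror wavelet filter is derived below.
.la8_scaling <- c(-0.07576571478927333, -0.02963552764599851,
                   0.49761866763201545,  0.80373875180591614,
                   0.29785779560527736, -0.09921954357684722,
                  -0.01260396726203783,  0.03222310060404270)

#' MODWT filter pair
#'
#' Returns the scaling (low-pass) and wavelet (high-pass) filters used by the
#' maximal overlap discrete wavelet transform, already rescaled by
#' \eqn{1/\sqrt{2}} as the MODWT requires.
#'
#' @param name Filter name; currently \code{"la8"} (least-asymmetric, length 8)
#'   and \code{"haar"} are provided.
#' @return List with elements \code{g} (scaling) and \code{h} (wavelet).
#' @export
modwt_filters <- function(name = "la8") {
  g <- switch(match.arg(name, c("la8", "haar")),
    la8  = .la8_scaling,
    haar = c(1 / sqrt(2), 1 / sqrt(2))
  )
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1L)  # quadrature mirror
  list(g = g / sqrt(2), h = h / sqrt(2))
}

# Frequency response of a filter whose taps are upsampled by `stride`,
# evaluated on the N-point DFT grid.
.upsampled_response <- function(taps, stride, n) {
  k <- 0:(n - 1L)
  resp <- complex(real = rep(0, n))
  for (l in seq_along(taps)) {
    resp <- resp + taps[l] * exp(-2i * pi * k * ((l - 1L) * stride) / n)
  }
  resp
}

# One MODWT pyramid level by circular convolution in the frequency domain.
# X is a frames x series matrix holding V_{j-1}; returns W_j and V_j.
.modwt_level <- function(X, level, filt) {
  n <- nrow(X)
  stride <- 2L^(level - 1L)
  Xh <- stats::mvfft(X)
  H <- .upsampled_response(filt$h, stride, n)
  G <- .upsampled_response(filt$g, stride, n)
  W <- Re(stats::mvfft(Xh * H, inverse = TRUE)) / n
  V <- Re(stats::mvfft(Xh * G, inverse = TRUE)) / n
  list(W = W, V = V)
}

# Number of boundary-affected coefficients at a given scale: L_j - 1 with
# L_j = (2^j - 1)(L - 1) + 1.
.modwt_boundary_count <- function(scale, filter_length) {
  (2L^scale - 1L) * (filter_length - 1L)
}

#' MODWT wavelet coefficients at one scale
#'
#' Computes the non-decimated (maximal overlap) discrete wavelet transform of
#' one or more series and returns the wavelet (detail) coefficients at the
#' requested scale.  The transform uses periodic (circular) boundary handling;
#' with \code{boundary = "periodic"} all coefficients are retained, with
#' \code{boundary = "discard"} the first \eqn{L_j - 1} boundary-affected
#' coefficients are dropped.
#'
#' @param series Numeric vector, or a matrix with one series per column.
#' @param scale Integer wavelet scale \eqn{j \ge 1}; scale \eqn{j} isolates the
#'   nominal band \eqn{[f_s/2^{j+1}, f_s/2^j]}.
#' @param filter_name Wavelet filter (see \code{\link{modwt_filters}}).
#' @param boundary \code{"periodic"} (retain all coefficients) or
#'   \code{"discard"}.
#' @return Vector or matrix of coefficients, same length as the input (shorter
#'   when \code{boundary = "discard"}).
#' @export
modwt_scale <- function(series, scale = 4L, filter_name = "la8",
                        boundary = c("periodic", "discard")) {
  boundary <- match.arg(boundary)
  filt <- modwt_filters(filter_name)
  vec_in <- is.null(dim(series))
  X <- if (vec_in) matrix(as.numeric(series), ncol = 1L) else as.matrix(series)
  if (anyNA(X)) stop("series contains missing values")
  Lj <- .modwt_boundary_count(scale, length(filt$g) * 2L) + 1L
  if (nrow(X) < Lj) {
    stop(sprintf("series length %d is too short for scale %d (needs >= %d)",
                 nrow(X), scale, Lj))
  }
  V <- X
  W <- NULL
  for (j in seq_len(scale)) {
    lev <- .modwt_level(V, j, filt)
    W <- lev$W
    V <- lev$V
  }
  if (boundary == "discard") {
    nb <- .modwt_boundary_count(scale, length(filt$g) * 2L)
    W <- W[-seq_len(min(nb, nrow(W) - 1L)), , drop = FALSE]
  }
  if (vec_in) drop(W) else W
}

#' Full MODWT decomposition
#'
#' Details at scales \code{1..n_scales} plus the final smooth, mainly used to
#' verify the MODWT energy identity
#' \eqn{\|x\|^2 = \sum_j \|W_j\|^2 + \|V_J\|^2}.
#'
#' @inheritParams modwt_scale
#' @param n_scales Number of detail scales.
#' @return List with \code{details} (list of vectors/matrices) and
#'   \code{smooth}.
#' @export
modwt_decompose <- function(series, n_scales = 4L, filter_name = "la8") {
  filt <- modwt_filters(filter_name)
  vec_in <- is.null(dim(series))
  V <- if (vec_in) matrix(as.numeric(series), ncol = 1L) else as.matrix(series)
  details <- vector("list", n_scales)
  for (j in seq_len(n_scales)) {
    lev <- .modwt_level(V, j, filt)
    details[[j]] <- if (vec_in) drop(lev$W) else lev$W
    V <- lev$V
  }
  list(details = details, smooth = if (vec_in) drop(V) else V)
}

#' Nominal frequency band of MODWT scale 4
#'
#' The nominal passband of MODWT scale \eqn{j} is
#' \eqn{[f_s/2^{j+1}, f_s/2^j]}; for scale 4 this is
#' \eqn{[f_s/32, f_s/16]}.  At a sampling interval of 0.609 s this evaluates
#' to 0.051--0.103 Hz, the conventional "0.05--0.10 Hz" slow fluctuation band.
#'
#' @param sampling_interval Sampling interval in seconds.
#' @return Numeric vector \code{c(low_hz, high_hz)}.
#' @export
scale4_band <- function(sampling_interval) {
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      !is.finite(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be a positive number")
  }
  fs <- 1 / sampling_interval
  c(fs / 32, fs / 16)
}
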