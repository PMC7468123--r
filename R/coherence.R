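#' Welch spectrum estimation settings
#'
#' @param segment_length Samples per Welch segment.
#' @param overlap Fractional overlap between consecutive segments.
#' @param taper Segment taper; \code{"hann"} or \code{"rectangular"}.
#' @param bins Which positive-frequency bins enter the band-averaged
#'   coherence: \code{"band"} restricts to bins inside the nominal wavelet
#'   band of the analysed scale, \code{"all"} averages every positive bin.
#' @return An object of class \code{welch_params}.
#' @export
welch_params <- function(segment_length = 128L, overlap = 0.5,
                         taper = c("hann", "rectangular"),
                         bins = c("band", "all")) {
  taper <- match.arg(taper)
  bins <- match.arg(bins)
  stopifnot(segment_length >= 8, overlap >= 0, overlap < 1)
  structure(list(segment_length = as.integer(segment_length),
                 overlap = overlap, taper = taper, bins = bins),
            class = "welch_params")
}

.taper_window <- function(n, taper) {
  switch(taper,
    hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L))),
    rectangular = rep(1, n)
  )
}

# Segment-start indices and count for a record of length n.
.welch_segments <- function(n, seg, overlap) {
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq.int(1L, n - seg + 1L, by = step)
  if (length(starts) < 1L) stop("segment length exceeds series length")
  starts
}

# Welch segment FFTs for a frames x series matrix.  Returns a K x nf x P
# complex array over positive-frequency bins 1..nf (DC excluded).
.welch_fft <- function(X, params) {
  n <- nrow(X)
  seg <- params$segment_length
  if (seg > n) stop("segment length exceeds series length")
  starts <- .welch_segments(n, seg, params$overlap)
  win <- .taper_window(seg, params$taper)
  nf <- seg %/% 2L
  Z <- array(complex(real = 0), c(length(starts), nf, ncol(X)))
  for (k in seq_along(starts)) {
    piece <- X[starts[k]:(starts[k] + seg - 1L), , drop = FALSE]
    piece <- sweep(piece, 2L, colMeans(piece))
    F <- stats::mvfft(piece * win)
    Z[k, , ] <- F[2L:(nf + 1L), , drop = FALSE]
  }
  Z
}

# Indices of retained frequency bins.
.retained_bins <- function(params, seg, sampling_interval) {
  nf <- seg %/% 2L
  if (params$bins == "all") return(seq_len(nf))
  fs <- 1 / sampling_interval
  freqs <- seq_len(nf) * fs / seg
  band <- scale4_band(sampling_interval)
  keep <- which(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12)
  if (length(keep) == 0L) stop("no Welch frequency bins fall inside the scale-4 band; use a longer segment")
  keep
}

#' Magnitude-squared wavelet coherence of two coefficient series
#'
#' Estimates the magnitude-squared coherence
#' \eqn{|S_{xy}|^2 / (S_{xx} S_{yy})} between two wavelet-coefficient series
#' using Welch's overlapped averaged periodogram, then averages across the
#' retained frequency bins.
#'
#' @param coeff_x,coeff_y Equal-length numeric coefficient series.
#' @param params \code{\link{welch_params}} settings.
#' @param sampling_interval Sampling interval (s); needed to locate the band
#'   bins when \code{params$bins == "band"}.
#' @return Coherence value in \eqn{[0, 1]}.
#' @export
wavelet_coherence <- function(coeff_x, coeff_y, params = welch_params(),
                              sampling_interval = 0.609) {
  if (length(coeff_x) != length(coeff_y)) stop("coefficient series differ in length")
  if (stats::var(coeff_x) <= 0 || stats::var(coeff_y) <= 0) {
    stop("degenerate input: zero-variance coefficient series")
  }
  X <- cbind(coeff_x, coeff_y)
  M <- .coherence_matrix(X, params, sampling_interval)
  M[1, 2]
}

# Band-averaged coherence matrix from a frames x series matrix of wavelet
# coefficients.  One cross-spectral matrix per retained bin, accumulated so
# memory stays O(P^2) regardless of bin count.
.coherence_matrix <- function(X, params, sampling_interval) {
  Z <- .welch_fft(X, params)
  keep <- .retained_bins(params, params$segment_length, sampling_interval)
  P <- dim(Z)[3]
  acc <- matrix(0, P, P)
  for (f in keep) {
    Zf <- Z[, f, , drop = TRUE]
    if (is.null(dim(Zf))) Zf <- matrix(Zf, nrow = dim(Z)[1])
    S <- crossprod(Conj(Zf), Zf)          # P x P cross-spectral matrix
    pw <- Re(diag(S))
    acc <- acc + (Mod(S)^2) / tcrossprod(pw)
  }
  coh <- acc / length(keep)
  coh <- (coh + t(coh)) / 2
  coh[coh > 1] <- 1
  diag(coh) <- 0
  coh
}

#' Connectivity settings for the wavelet-coherence stage
#'
#' @param scale Wavelet scale (the analysis uses 4: the 0.05--0.10 Hz band at
#'   a 0.609 s sampling interval).
#' @param filter_name Wavelet filter.
#' @param boundary Boundary policy passed to \code{\link{modwt_scale}}.
#' @param welch \code{\link{welch_params}} settings.
#' @return An object of class \code{connectivity_config}.
#' @export
connectivity_config <- function(scale = 4L, filter_name = "la8",
                                boundary = "periodic",
                                welch = welch_params()) {
  structure(list(scale = as.integer(scale), filter_name = filter_name,
                 boundary = boundary, welch = welch),
            class = "connectivity_config")
}

#' Wavelet-coherence connectivity matrix of a panel
#'
#' Extracts scale-4 MODWT coefficients from every regional series and computes
#' the magnitude-squared wavelet coherence for all unordered node pairs,
#' giving the symmetric weighted functional connectivity matrix (zero
#' diagonal).
#'
#' @param panel A \code{timeseries_panel} (see \code{\link{as_panel}}).
#' @param config \code{\link{connectivity_config}} settings.
#' @return An object of class \code{connectivity_matrix}: list with
#'   \code{node_ids}, \code{weights} and \code{meta}.
#' @export
build_connectivity_matrix <- function(panel, config = connectivity_config()) {
  panel <- as_panel(panel)
  X <- t(panel$values)                       # frames x nodes
  v <- apply(X, 2L, stats::var)
  if (any(v <= 0)) {
    stop("degenerate input: zero-variance series for node(s) ",
         paste(panel$node_ids[v <= 0], collapse = ", "))
  }
  W <- modwt_scale(X, scale = config$scale, filter_name = config$filter_name,
                   boundary = config$boundary)
  coh <- .coherence_matrix(W, config$welch, panel$sampling_interval)
  dimnames(coh) <- list(panel$node_ids, panel$node_ids)
  structure(list(node_ids = panel$node_ids, weights = coh,
                 meta = list(scale = config$scale,
                             filter = config$filter_name,
                             boundary = config$boundary,
                             welch = unclass(config$welch),
                             band_hz = scale4_band(panel$sampling_interval),
                             sampling_interval = panel$sampling_interval)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d nodes, wavelet scale %d (%s), band %.3f-%.3f Hz\n",
              length(x$node_ids), x$meta$scale, x$meta$filter,
              x$meta$band_hz[1], x$meta$band_hz[2]))
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf("  mean off-diagonal coherence %.3f (range %.3f-%.3f)\n",
              mean(off), min(off), max(off)))
  invisible(x)
}
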