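#' Ramp-filter specification
#'
#' Parameters of the row-wise ramp filtering stage: apodization window,
#' FFT length, and frequency cutoff.
#'
#' @param window apodization applied to the ramp `|f|` response:
#'   `"ramp"` (none), `"shepp-logan"`, `"hamming"` or `"hann"`.
#' @param cutoff frequency cutoff as a fraction of Nyquist, in (0, 1].
#' @param pad_length FFT length after zero-padding, or `NULL` ("auto") for
#'   the next power of two >= twice the detector width.  Must be at least
#'   `2 * det_cols` so the convolution is linear, not circular.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(window = c("ramp", "shepp-logan", "hamming", "hann"),
                        cutoff = 1, pad_length = NULL) {
  window <- match.arg(window)
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0 || cutoff > 1)
    stopf("'cutoff' must be in (0, 1]")
  if (!is.null(pad_length)) pad_length <- check_count(pad_length, "pad_length", min = 2L)
  structure(list(window = window, cutoff = as.numeric(cutoff),
                 pad_length = pad_length), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Filter: %s window, cutoff %g x Nyquist, pad %s\n",
              x$window, x$cutoff,
              if (is.null(x$pad_length)) "auto" else x$pad_length))
  invisible(x)
}

## resolve "auto" padding against a detector width
resolve_pad <- function(spec, det_cols) {
  pad <- spec$pad_length %||% next_pow2(2L * det_cols)
  if (pad < 2L * det_cols)
    stopf("pad_length (%d) must be >= 2 * det_cols (%d) for linear convolution",
          pad, 2L * det_cols)
  pad
}

#' Cosine pre-weight map
#'
#' The FDK per-pixel pre-weight applied to each projection before
#' filtering: `dsd / sqrt(dsd^2 + u^2 + v^2)` at physical detector
#' coordinate (u, v).  Equals 1 on the central ray and decreases with the
#' ray's obliquity.
#'
#' @param geom a [cone_geometry()].
#' @return matrix (`det_rows` x `det_cols`) of weights in (0, 1].
#' @export
cosine_weight_map <- function(geom) {
  uu <- det_u_coords(geom)
  vv <- det_v_coords(geom)
  U2 <- matrix(rep(uu^2, each = geom$det_rows), geom$det_rows, geom$det_cols)
  V2 <- matrix(rep(vv^2, times = geom$det_cols), geom$det_rows, geom$det_cols)
  geom$dsd / sqrt(geom$dsd^2 + U2 + V2)
}

#' Discrete ramp-filter frequency response
#'
#' Samples `H(f) = |f| * window(f)` on the FFT frequency grid of length
#' `pad_length` for detector pixel pitch `det_spacing_u`:
#' `f_k = k / (pad_length * det_spacing_u)` cycles per unit length, with
#' negative frequencies in the upper half in standard FFT order.  The
#' response is zero at DC and beyond `cutoff * Nyquist`.  Units are
#' 1/length, so filtered rows approximate the continuous ramp-filtered
#' projection with no further scaling.
#'
#' @param spec a [filter_spec()] with concrete `pad_length`.
#' @param det_spacing_u detector column pitch.
#' @param det_cols detector width; when given, validates
#'   `pad_length >= 2 * det_cols`.
#' @return numeric vector of length `pad_length`.
#' @export
ramp_kernel <- function(spec, det_spacing_u, det_cols = NULL) {
  pad <- if (!is.null(det_cols)) resolve_pad(spec, det_cols)
         else spec$pad_length %||% stopf("pad_length must be set (or give det_cols)")
  det_spacing_u <- check_positive(det_spacing_u, "det_spacing_u")
  k <- 0:(pad - 1)
  k <- ifelse(k > pad / 2, k - pad, k)
  f <- abs(k) / (pad * det_spacing_u)
  nyq <- 1 / (2 * det_spacing_u)
  fc <- spec$cutoff * nyq
  w <- switch(spec$window,
    ramp = rep(1, pad),
    "shepp-logan" = { x <- pi * f / (2 * fc); ifelse(f == 0, 1, sin(x) / x) },
    hamming = 0.54 + 0.46 * cos(pi * f / fc),
    hann = 0.5 * (1 + cos(pi * f / fc)))
  H <- f * w
  H[f > fc * (1 + 1e-12)] <- 0
  H
}

#' Weight and ramp-filter one projection
#'
#' Stage 1 of FDK for a single view: multiplies the projection by the
#' cosine pre-weight, then filters every detector row independently in the
#' frequency domain (zero-pad to `pad_length`, FFT, multiply by the ramp
#' response, inverse FFT, crop, real part).
#'
#' @param proj matrix (`det_rows` x `det_cols`), one raw projection.
#' @param geom a [cone_geometry()].
#' @param spec a [filter_spec()].
#' @param weighted set `TRUE` if `proj` is already cosine-weighted.
#' @return filtered matrix of the same shape.
#' @export
filter_projection <- function(proj, geom, spec = filter_spec(),
                              weighted = FALSE) {
  if (!identical(dim(proj), c(geom$det_rows, geom$det_cols)))
    stopf("projection dim (%s) does not match geometry (%d x %d)",
          paste(dim(proj), collapse = ", "), geom$det_rows, geom$det_cols)
  pad <- resolve_pad(spec, geom$det_cols)
  H <- ramp_kernel(filter_spec(spec$window, spec$cutoff, pad), geom$det_spacing_u)
  if (!weighted) proj <- proj * cosine_weight_map(geom)
  m <- matrix(0, pad, geom$det_rows)       # rows become columns for mvfft
  m[seq_len(geom$det_cols), ] <- t(proj)
  Fm <- stats::mvfft(m) * H
  q <- Re(stats::mvfft(Fm, inverse = TRUE)) / pad
  t(q[seq_len(geom$det_cols), , drop = FALSE])
}

#' Apply the cosine pre-weight to a whole stack
#'
#' @param stack a raw [projection_stack()].
#' @return a [projection_stack()] with `stage = "weighted"`.
#' @export
weight_stack <- function(stack) {
  check_stage_transition(stack$stage, "weighted")
  w <- cosine_weight_map(stack$geom)
  out <- stack$data * as.vector(w)      # recycles over views
  projection_stack(out, stack$geom, stage = "weighted",
                   precision = stack$precision)
}

#' Weight and filter a whole stack
#'
#' @param stack a [projection_stack()] at stage `"raw"` (cosine weight is
#'   applied first) or `"weighted"`.
#' @param spec a [filter_spec()].
#' @return a [projection_stack()] with `stage = "filtered"`.
#' @export
filter_stack <- function(stack, spec = filter_spec()) {
  check_stage_transition(stack$stage, "filtered")
  out <- array(0, dim = dim(stack$data))
  for (n in seq_len(stack$geom$n_angles))
    out[, , n] <- filter_projection(stack$data[, , n], stack$geom, spec,
                                    weighted = stack$stage == "weighted")
  projection_stack(out, stack$geom, stage = "filtered",
                   precision = stack$precision)
}
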