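#' @useDynLib laminaq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal helpers shared across modules.

#' Otsu threshold of a set of intensity values
#'
#' Thin wrapper around [EBImage::otsu()] operating on a plain numeric vector
#' (e.g. the pixels inside a mask). Values are packed into a 1-row image and
#' thresholded over their own range with 256 grey levels.
#'
#' @param values numeric vector of intensities (finite, length >= 2).
#' @return threshold on the scale of `values`; pixels strictly above it are
#'   "bright".
#' @keywords internal
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || diff(range(values)) == 0)
    stop("cannot threshold: intensities are constant or empty")
  r <- range(values)
  x <- EBImage::Image(matrix((values - r[1]) / (r[2] - r[1]), nrow = 1L))
  thr <- EBImage::otsu(x, range = c(0, 1), levels = 256L)
  r[1] + thr * (r[2] - r[1])
}

# Euclidean distance (in pixels) from every pixel to the nearest TRUE pixel
# of `mask`; 0 on the mask itself.
dist_to <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap(EBImage::Image(1 - mask)))
}

# Morphological closing with a Euclidean disc of `radius` pixels, done with
# two distance transforms (fast and exact for large radii). The mask is
# padded with background first so closing cannot stick to the image border.
close_mask <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  r <- ceiling(radius) + 1L
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L * r, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- mask
  dil <- dist_to(pad) <= radius
  closed <- as.matrix(EBImage::distmap(EBImage::Image(dil))) > radius
  closed[(r + 1L):(r + h), (r + 1L):(r + w)]
}

# Deterministic substream seed below 2^31, derived from a master seed and a
# small index. All randomness in the package flows through this.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483399) + 1L
}

# Jaccard index of two logical masks.
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
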