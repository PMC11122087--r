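#' Parallel-beam acquisition geometry
#'
#' Describes the discrete parallel-beam sampling used to build the system
#' matrix: an `n x n` pixel grid (image vector length `Nx = n^2`) and a set of
#' lines indexed by projection angle and detector bin (`Ny = n_angles *
#' n_detector_bins`).
#'
#' Conventions (fixed for reproducibility): the image is centred at the
#' origin with pixel `(1, 1)` at the lower-left corner; pixel centres sit at
#' half-integer multiples of `pixel_size`; a line at angle `theta` has normal
#' vector `(cos theta, sin theta)` and signed distance `r` from the origin;
#' detector coordinates are centred, `r_k = (k - (n_det + 1)/2) *
#' detector_spacing`. Rays are ordered angle-major: all detector bins of the
#' first angle, then the second, and so on. Image channels are vectorised
#' with the x index fastest (column-major over `(ix, iy)`).
#'
#' @param n_pixels_side Image side length `n` (image is `n x n`), `>= 1`.
#' @param angles Strictly increasing projection angles in radians, all in
#'   `[0, pi)`. Default: `ceiling(pi/2 * n)` equispaced angles.
#' @param n_detector_bins Number of detector elements per angle; must be at
#'   least `n` so the object fits the field of view. Default `ceiling(1.5 n)`.
#' @param pixel_size Pixel edge length in grid units (default 1).
#' @param detector_spacing Detector element spacing (default `pixel_size`).
#' @return An object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_pixels_side,
                        angles = NULL,
                        n_detector_bins = NULL,
                        pixel_size = 1,
                        detector_spacing = pixel_size) {
  n <- as.integer(n_pixels_side)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("n_pixels_side must be a single integer >= 1", call. = FALSE)
  }
  if (is.null(angles)) {
    n_ang <- max(1L, ceiling(pi / 2 * n))
    angles <- seq(0, pi, length.out = n_ang + 1L)[seq_len(n_ang)]
  }
  if (length(angles) == 0L) stop("angles must be non-empty", call. = FALSE)
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles >= pi)) {
    stop("angles must lie in [0, pi)", call. = FALSE)
  }
  if (is.unsorted(angles, strictly = TRUE)) {
    stop("angles must be strictly increasing", call. = FALSE)
  }
  if (is.null(n_detector_bins)) n_detector_bins <- ceiling(1.5 * n)
  n_det <- as.integer(n_detector_bins)
  if (n_det < n) stop("n_detector_bins must be >= n_pixels_side", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive", call. = FALSE)
  }
  if (!is.finite(detector_spacing) || detector_spacing <= 0) {
    stop("detector_spacing must be positive", call. = FALSE)
  }
  structure(
    list(
      n_pixels_side = n,
      pixel_size = pixel_size,
      angles = as.numeric(angles),
      n_detector_bins = n_det,
      detector_spacing = detector_spacing
    ),
    class = "ct_geometry"
  )
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf(
    "<ct_geometry> %d x %d image (pixel %g), %d angles x %d bins = %d rays\n",
    x$n_pixels_side, x$n_pixels_side, x$pixel_size,
    length(x$angles), x$n_detector_bins,
    length(x$angles) * x$n_detector_bins
  ))
  invisible(x)
}

n_image_pixels <- function(geometry) geometry$n_pixels_side^2L

n_rays <- function(geometry) length(geometry$angles) * geometry$n_detector_bins

# Exact pixel/ray intersection lengths for one line (Siddon-style traversal).
# Returns pixel indices (1-based, x fastest) and segment lengths.
ray_trace <- function(n, h, theta, r) {
  half <- n * h / 2
  ct <- cos(theta)
  st <- sin(theta)
  # line: p(t) = r * (ct, st) + t * (-st, ct)
  p0x <- r * ct
  p0y <- r * st
  dx <- -st
  dy <- ct
  eps <- 1e-12
  tmin <- -Inf
  tmax <- Inf
  # slab clipping against the image bounding box
  if (abs(dx) > eps) {
    t1 <- (-half - p0x) / dx
    t2 <- (half - p0x) / dx
    tmin <- max(tmin, min(t1, t2))
    tmax <- min(tmax, max(t1, t2))
  } else if (p0x <= -half || p0x >= half) {
    return(list(idx = integer(0), len = numeric(0)))
  }
  if (abs(dy) > eps) {
    t1 <- (-half - p0y) / dy
    t2 <- (half - p0y) / dy
    tmin <- max(tmin, min(t1, t2))
    tmax <- min(tmax, max(t1, t2))
  } else if (p0y <= -half || p0y >= half) {
    return(list(idx = integer(0), len = numeric(0)))
  }
  if (tmax - tmin <= eps) return(list(idx = integer(0), len = numeric(0)))
  grid <- seq(-half, half, by = h)
  ts <- c(tmin, tmax)
  if (abs(dx) > eps) {
    tx <- (grid - p0x) / dx
    ts <- c(ts, tx[tx > tmin + eps & tx < tmax - eps])
  }
  if (abs(dy) > eps) {
    ty <- (grid - p0y) / dy
    ts <- c(ts, ty[ty > tmin + eps & ty < tmax - eps])
  }
  ts <- sort(ts)
  keep <- c(TRUE, diff(ts) > eps)
  ts <- ts[keep]
  if (length(ts) < 2L) return(list(idx = integer(0), len = numeric(0)))
  len <- diff(ts)
  tm <- (ts[-1L] + ts[-length(ts)]) / 2
  px <- p0x + tm * dx
  py <- p0y + tm * dy
  ix <- pmin(pmax(floor((px + half) / h), 0), n - 1L)
  iy <- pmin(pmax(floor((py + half) / h), 0), n - 1L)
  list(idx = as.integer(iy * n + ix + 1L), len = len)
}

#' Build the discrete Radon transform and its exact adjoint
#'
#' Assembles the system matrix `A` (`Ny x Nx`) with entries equal to the
#' exact intersection length of each ray with each pixel, as an explicit
#' sparse matrix. The adjoint is the exact transpose, so the pair satisfies
#' the matched inner-product identity to machine precision by construction.
#'
#' @param geometry A [ct_geometry()].
#' @return An object of class `ct_projector` with elements `A` (a
#'   `dgCMatrix`), `At` (its transpose, cached), and `geometry`.
#' @export
build_projector <- function(geometry) {
  stopifnot(inherits(geometry, "ct_geometry"))
  n <- geometry$n_pixels_side
  h <- geometry$pixel_size
  n_det <- geometry$n_detector_bins
  rs <- (seq_len(n_det) - (n_det + 1) / 2) * geometry$detector_spacing
  n_ray <- n_rays(geometry)
  ii <- vector("list", n_ray)
  jj <- vector("list", n_ray)
  vv <- vector("list", n_ray)
  row <- 0L
  for (theta in geometry$angles) {
    for (r in rs) {
      row <- row + 1L
      tr <- ray_trace(n, h, theta, r)
      if (length(tr$idx)) {
        ii[[row]] <- rep.int(row, length(tr$idx))
        jj[[row]] <- tr$idx
        vv[[row]] <- tr$len
      }
    }
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(vv),
    dims = c(n_ray, n^2L)
  )
  structure(list(A = A, At = Matrix::t(A), geometry = geometry),
            class = "ct_projector")
}

#' @export
print.ct_projector <- function(x, ...) {
  cat(sprintf(
    "<ct_projector> A: %d x %d sparse (%.2f%% filled)\n",
    nrow(x$A), ncol(x$A), 100 * Matrix::nnzero(x$A) / prod(dim(x$A))
  ))
  invisible(x)
}

#' Apply the Radon transform channel-wise
#'
#' Applies `A` to each material channel of an image, producing the
#' multichannel material sinogram `Z = A X`.
#'
#' @param projector A [build_projector()] result.
#' @param X Image channels: an `Nx x M` matrix (or a vector for `M = 1`).
#' @return `Ny x M` matrix of per-material sinograms.
#' @export
apply_multichannel <- function(projector, X) {
  X <- as_channel_matrix(X, ncol(projector$A), "image")
  as.matrix(projector$A %*% X)
}

#' Apply the exact adjoint channel-wise
#'
#' @param projector A [build_projector()] result.
#' @param Z Sinogram channels: an `Ny x M` matrix (or a vector).
#' @return `Nx x M` matrix (back-projected channels).
#' @export
adjoint_multichannel <- function(projector, Z) {
  Z <- as_channel_matrix(Z, nrow(projector$A), "sinogram")
  as.matrix(projector$At %*% Z)
}

as_channel_matrix <- function(X, n_rows, what) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  if (nrow(X) != n_rows) {
    stop(sprintf(
      "%s has %d rows per channel but the geometry requires %d",
      what, nrow(X), n_rows
    ), call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}
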