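#' Parallel-beam projection geometry
#'
#' @param n_angles Number of projection angles uniformly spaced over 180
#'   degrees (default 128).
#' @param n_radial Number of radial bins (default 128).
#' @param bin_size_mm Radial bin width in mm (default: one pixel, 0.776 mm).
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_angles = 128L, n_radial = 128L,
                                bin_size_mm = 0.776) {
  if (n_angles < 1 || n_radial < 2) stop("empty or degenerate geometry")
  structure(list(n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 bin_size_mm = bin_size_mm,
                 angles = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]),
            class = "projection_geometry")
}

#' Build the 2D system model
#'
#' Pixel-driven parallel-beam projector with linear interpolation between
#' radial bins: each pixel centre is projected onto the detector axis at each
#' angle and its value split between the two adjacent bins. Forward and back
#' projection are a sparse matrix and its exact transpose, so the operator
#' pair is adjoint by construction. Photon attenuation enters as per-ray
#' multiplicative survival factors `exp(-int mu dl)` computed by projecting
#' the attenuation map through the same matrix.
#'
#' @param geom A [projection_geometry()].
#' @param attn An `attenuation_map` (cm^-1), or `NULL` for no attenuation.
#' @param pixel_size_mm Pixel size in mm (taken from `attn` when available).
#' @param grid_size Image side in pixels (taken from `attn` when available).
#' @return An object of class `system_model`: sparse `A` (rays x pixels), its
#'   transpose `At`, per-ray attenuation factors `attn_factors`, `geom`.
#' @export
build_system_model <- function(geom = projection_geometry(), attn = NULL,
                               pixel_size_mm = NULL, grid_size = NULL) {
  stopifnot(inherits(geom, "projection_geometry"))
  if (!is.null(attn)) {
    grid_size <- nrow(attn)
    if (is.null(pixel_size_mm)) pixel_size_mm <- attr(attn, "pixel_size_mm")
  }
  if (is.null(pixel_size_mm)) pixel_size_mm <- geom$bin_size_mm
  if (is.null(grid_size)) stop("grid_size required when no attenuation map is given")
  n <- grid_size
  npix <- n * n
  nray <- geom$n_angles * geom$n_radial
  # pixel centres in mm, image centre at the origin; x right, y down
  cx <- ((0:(n - 1)) - (n - 1) / 2) * pixel_size_mm
  x <- rep(cx, times = n)       # varies along rows (first index)
  y <- rep(cx, each = n)
  half <- (geom$n_radial - 1) / 2
  ii <- vector("list", geom$n_angles)
  jj <- vector("list", geom$n_angles)
  xx <- vector("list", geom$n_angles)
  for (k in seq_len(geom$n_angles)) {
    th <- geom$angles[k]
    s <- x * cos(th) + y * sin(th)
    u <- s / geom$bin_size_mm + half
    i0 <- floor(u)
    w1 <- 1 - (u - i0)
    keep0 <- i0 >= 0 & i0 <= geom$n_radial - 1
    keep1 <- i0 + 1 >= 0 & i0 + 1 <= geom$n_radial - 1
    base <- (k - 1) * geom$n_radial + 1
    ii[[k]] <- c(base + i0[keep0], base + i0[keep1] + 1)
    jj[[k]] <- c(which(keep0), which(keep1))
    xx[[k]] <- c(w1[keep0], (1 - w1)[keep1])
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nray, npix))
  a <- rep(1, nray)
  if (!is.null(attn)) {
    # A mu ~ line integral of mu in units of bin traversals; one bin step is
    # bin_size_mm of path, mu is per cm
    path_cm <- as.vector(A %*% as.vector(unclass(attn))) * geom$bin_size_mm / 10
    a <- exp(-path_cm)
  }
  structure(list(A = A, At = Matrix::t(A), attn_factors = a, geom = geom,
                 grid_size = n, pixel_size_mm = pixel_size_mm),
            class = "system_model")
}

#' Strip attenuation from a system model
#' @param sys A `system_model`.
#' @return The same model with all attenuation factors set to 1.
#' @export
without_attenuation <- function(sys) {
  sys$attn_factors <- rep(1, length(sys$attn_factors))
  sys
}

forward_one <- function(sys, x, use_attn = TRUE) {
  v <- as.vector(sys$A %*% as.vector(x))
  if (use_attn) v * sys$attn_factors else v
}

back_one <- function(sys, y, use_attn = TRUE) {
  if (use_attn) y <- y * sys$attn_factors
  as.vector(sys$At %*% y)
}

#' Expected-count sinograms for a dynamic truth image
#'
#' Projects each (decayed) truth frame through the attenuated system model,
#' weights by frame duration, and rescales globally so the total expected
#' count over the whole scan equals the budget.
#'
#' @param truth Dynamic image array (nx, ny, frames) including physical
#'   decay.
#' @param sys A `system_model`.
#' @param framing A `time_framing` matching the third dimension.
#' @param budget Total expected counts over the scan (e.g. 1e7).
#' @return An object of class `frame_sinograms`: list with `lambda` (rays x
#'   frames), `counts` (NULL until sampled), `framing`, `budget`, `scale`.
#' @export
forward_project_frames <- function(truth, sys, framing, budget = 1e7) {
  stopifnot(length(dim(truth)) == 3L, dim(truth)[3] == nrow(framing))
  if (budget <= 0) stop("budget must be positive")
  if (all(truth == 0)) stop("all-zero truth image cannot be scaled to a count budget")
  X <- matrix(truth, ncol = dim(truth)[3])
  lam <- as.matrix(sys$A %*% X) * sys$attn_factors
  lam <- sweep(lam, 2, framing$duration_s, "*")
  scale <- budget / sum(lam)
  structure(list(lambda = lam * scale, counts = NULL, framing = framing,
                 budget = budget, scale = scale), class = "frame_sinograms")
}

#' Sample Poisson counts from expected sinograms
#'
#' @param expected A `frame_sinograms` with expected counts `lambda`.
#' @param seed Integer RNG seed (reproducible draws), or `NULL` to use the
#'   current RNG state.
#' @return The input with `counts` filled with independent Poisson draws.
#' @export
sample_poisson_counts <- function(expected, seed = NULL) {
  lam <- expected$lambda
  if (any(lam < 0)) stop("negative expected counts")
  if (!is.null(seed)) set.seed(seed)
  y <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
  expected$counts <- y
  expected
}

#' Write frame sinograms to NIfTI with a JSON sidecar
#'
#' Stores expected counts (and sampled counts when present) as a 2D+frames
#' NIfTI array of (radial bin, angle, frame), plus a JSON sidecar recording
#' the geometry and count budget.
#'
#' @param fs A `frame_sinograms`.
#' @param path Output .nii/.nii.gz path; the sidecar replaces the extension
#'   with .json.
#' @param sys The `system_model` used (for the geometry record).
#' @return `path`, invisibly.
#' @export
write_sinograms_nifti <- function(fs, path, sys = NULL) {
  nf <- ncol(fs$lambda)
  nr <- if (!is.null(sys)) sys$geom$n_radial else nrow(fs$lambda)
  na <- nrow(fs$lambda) / nr
  arr <- array(fs$lambda, dim = c(nr, na, 1, nf))
  if (!is.null(fs$counts)) arr <- abind2(arr, array(fs$counts, dim = c(nr, na, 1, nf)))
  RNifti::writeNifti(arr, path)
  jsonlite::write_json(list(
    n_radial = nr, n_angles = na, n_frames = nf, budget = fs$budget,
    has_counts = !is.null(fs$counts),
    start_s = fs$framing$start_s, end_s = fs$framing$end_s),
    sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

abind2 <- function(a, b) {
  d <- dim(a)
  array(c(a, b), dim = c(d[1], d[2], d[3], d[4] * 2))
}
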