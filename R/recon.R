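new_dynamic_image <- function(X, grid_size, framing, decay_corrected = FALSE) {
  img <- array(as.matrix(X), dim = c(grid_size, grid_size, nrow(framing)))
  attr(img, "framing") <- framing
  attr(img, "decay_corrected") <- decay_corrected
  class(img) <- "dynamic_image"
  img
}

eps_em <- 1e-12

#' Frame-independent MLEM reconstruction
#'
#' Classic maximum-likelihood expectation-maximization for Poisson data,
#' applied independently to every time frame (the IFR arm). Initialization is
#' a uniform positive image on the support of the sensitivity image; pixels
#' with zero sensitivity stay at zero. Frames with zero total counts return a
#' zero frame with a warning.
#'
#' @param frames A sampled `frame_sinograms`.
#' @param sys A `system_model`.
#' @param n_iter Number of EM iterations (default 300).
#' @return A `dynamic_image` (not decay-corrected).
#' @export
mlem_reconstruct <- function(frames, sys, n_iter = 300L) {
  if (is.null(frames$counts)) stop("frames have not been sampled; see sample_poisson_counts()")
  if (n_iter < 1) stop("n_iter must be >= 1")
  Y <- frames$counts
  nf <- ncol(Y)
  dur <- frames$framing$duration_s
  a <- sys$attn_factors
  sens <- as.vector(sys$At %*% a)            # per-pixel, per unit duration
  supp <- sens > 0
  zero_frames <- colSums(Y) == 0
  if (any(zero_frames))
    warning(sum(zero_frames), " frame(s) with zero counts; returned as zero")
  X <- matrix(0, length(sens), nf)
  X[supp, ] <- 1
  Sens <- outer(sens, dur)
  for (it in seq_len(n_iter)) {
    lam <- as.matrix(sys$A %*% X) * a
    lam <- sweep(lam, 2, dur, "*")
    R <- Y / pmax(lam, eps_em)
    Bp <- as.matrix(sys$At %*% (R * a))
    Bp <- sweep(Bp, 2, dur, "*")
    X <- X * Bp / pmax(Sens, eps_em)
    X[!supp, ] <- 0
  }
  X[, zero_frames] <- 0
  new_dynamic_image(X, sys$grid_size, frames$framing)
}

angle_subsets <- function(n_angles, n_subsets) {
  if (n_angles %% n_subsets != 0) {
    n_subsets <- max(1, round(n_angles / round(n_angles / n_subsets)))
    warning("subset count does not divide the angle count; using ", n_subsets)
  }
  lapply(seq_len(n_subsets), function(s) seq(s, n_angles, by = n_subsets))
}

#' Fast OSEM reconstruction for kernel frame features
#'
#' Ordered-subset EM with few (default one) iterations over interleaved angle
#' subsets and no attenuation correction, producing smooth low-noise frame
#' images used only as features for the temporal kernel.
#'
#' @param frames A sampled `frame_sinograms`.
#' @param sys A `system_model` (attenuation is ignored here).
#' @param n_subsets Number of angle subsets (default 16).
#' @param n_iter Number of full iterations (default 1).
#' @return A `dynamic_image` of frame features.
#' @export
osem_feature_reconstruct <- function(frames, sys, n_subsets = 16L, n_iter = 1L) {
  if (is.null(frames$counts)) stop("frames have not been sampled")
  Y <- frames$counts
  dur <- frames$framing$duration_s
  nr <- sys$geom$n_radial
  subs <- angle_subsets(sys$geom$n_angles, n_subsets)
  X <- matrix(1, ncol(sys$A), ncol(Y))
  for (it in seq_len(n_iter)) {
    for (s in subs) {
      rows <- as.vector(outer(seq_len(nr), (s - 1) * nr, "+"))
      As <- sys$A[rows, , drop = FALSE]
      sens <- as.vector(Matrix::colSums(As))
      supp <- sens > 0
      lam <- sweep(as.matrix(As %*% X), 2, dur, "*")
      R <- Y[rows, , drop = FALSE] / pmax(lam, eps_em)
      Bp <- sweep(as.matrix(Matrix::t(As) %*% R), 2, dur, "*")
      Sens <- outer(sens, dur)
      X <- X * Bp / pmax(Sens, eps_em)
      X[!supp, ] <- 0
    }
  }
  new_dynamic_image(X, sys$grid_size, frames$framing)
}

#' Extract a regional TAC from a dynamic image
#'
#' @param img A `dynamic_image` (or plain 3D array with a `framing`
#'   attribute).
#' @param mask Logical matrix; frame value is the mean over masked pixels.
#' @return A frame-kind `region_tac`.
#' @export
region_tac_extract <- function(img, mask) {
  if (!any(mask)) stop("empty mask")
  framing <- attr(img, "framing")
  flat <- matrix(img, ncol = dim(img)[3])
  vals <- colMeans(flat[which(mask), , drop = FALSE])
  new_region_tac(framing$mid_min, vals, kind = "frame",
                 decay_corrected = isTRUE(attr(img, "decay_corrected")),
                 framing = framing, frame = framing$frame)
}

#' Poisson log-likelihood of a dynamic image under the system model
#'
#' Used in tests to verify the EM monotonicity property.
#' @param img A `dynamic_image`.
#' @param frames A sampled `frame_sinograms`.
#' @param sys A `system_model`.
#' @return Scalar log-likelihood (up to the y! constant).
#' @export
poisson_loglik <- function(img, frames, sys) {
  X <- matrix(img, ncol = dim(img)[3])
  lam <- as.matrix(sys$A %*% X) * sys$attn_factors
  lam <- sweep(lam, 2, frames$framing$duration_s, "*")
  lam <- pmax(lam, eps_em)
  sum(frames$counts * log(lam) - lam)
}

#' Write a dynamic image as 4D NIfTI with a JSON framing sidecar
#' @param img A `dynamic_image`.
#' @param path Output .nii/.nii.gz path.
#' @return `path`, invisibly.
#' @export
write_dynamic_nifti <- function(img, path) {
  d <- dim(img)
  RNifti::writeNifti(array(img, dim = c(d[1], d[2], 1, d[3])), path)
  framing <- attr(img, "framing")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(
    start_s = framing$start_s, end_s = framing$end_s,
    decay_corrected = isTRUE(attr(img, "decay_corrected"))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dynamic image written by [write_dynamic_nifti()]
#' @param path NIfTI path.
#' @return A `dynamic_image`, with framing restored from the sidecar when
#'   present.
#' @export
read_dynamic_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  img <- array(as.numeric(arr), dim = c(d[1], d[2], d[4]))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    runs <- rle(m$end_s - m$start_s)
    attr(img, "framing") <- make_framing(
      mapply(c, runs$lengths, runs$values, SIMPLIFY = FALSE))
    attr(img, "decay_corrected") <- isTRUE(m$decay_corrected)
  }
  class(img) <- "dynamic_image"
  img
}
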