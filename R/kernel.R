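#' Kernel reconstruction configuration
#'
#' Hyperparameters of the spatial and temporal kernel matrices. Defaults
#' follow the method's standard settings: a 9x9 spatial neighbourhood window,
#' a radial-kernel value threshold of 0.8, 48 nearest neighbours, a temporal
#' neighbourhood of ts = 15 frames, and basis smoothing with a Gaussian of
#' sigma = ts/100 frames.
#'
#' @param window Odd spatial window side in pixels (default 9).
#' @param threshold Minimum retained kernel value, in (0, 1) (default 0.8).
#' @param knn Maximum number of retained neighbours per pixel (default 48).
#' @param ts Temporal neighbourhood size in frames (default 15).
#' @param sigma_frames Gaussian smoothing width for temporal basis functions,
#'   in frames (default `ts / 100`).
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(window = 9L, threshold = 0.8, knn = 48L, ts = 15L,
                          sigma_frames = ts / 100) {
  if (window %% 2 != 1) stop("window must be odd")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (knn < 0) stop("knn must be >= 0")
  if (ts < 3) stop("ts must be >= 3")
  structure(list(window = as.integer(window), threshold = threshold,
                 knn = as.integer(knn), ts = as.integer(ts),
                 sigma_frames = sigma_frames), class = "kernel_config")
}

#' Build the sparse spatial kernel matrix
#'
#' Voxel features are the three composite-frame intensities, each component
#' normalized by its population standard deviation over the ROI. For every
#' in-ROI pixel the Gaussian radial kernel `exp(-||f_p - f_q||^2 / 2)` is
#' evaluated over the spatial window; values below the threshold are dropped,
#' the `knn` largest are kept (ties: larger value first, then smaller pixel
#' index), the self-weight `exp(0) = 1` is always retained, and each row is
#' normalized to sum one. Rows outside the ROI are identity.
#'
#' @param features 3D array (nx, ny, n_features), typically 3 composite
#'   MLEM reconstructions.
#' @param cfg A [kernel_config()].
#' @param roi Logical matrix restricting kernel computation; `NULL` = all
#'   pixels.
#' @return A sparse row-stochastic `Matrix::dgCMatrix` (pixels x pixels) of
#'   class retained, with attribute `cfg`.
#' @export
build_spatial_kernel <- function(features, cfg = kernel_config(), roi = NULL) {
  stopifnot(length(dim(features)) == 3L)
  nx <- dim(features)[1]; ny <- dim(features)[2]; nfeat <- dim(features)[3]
  npix <- nx * ny
  if (is.null(roi)) roi <- matrix(TRUE, nx, ny)
  if (!any(roi)) stop("empty ROI")
  Fm <- matrix(features, ncol = nfeat)
  sds <- apply(Fm[which(roi), , drop = FALSE], 2, stats::sd)
  if (all(sds == 0) || all(Fm == 0)) {
    warning("all-zero/constant features; returning identity spatial kernel")
    return(identity_spatial_kernel(npix, cfg))
  }
  sds[sds == 0] <- 1
  Fm <- sweep(Fm, 2, sds, "/")
  hw <- (cfg$window - 1L) %/% 2L
  offs <- expand.grid(dx = -hw:hw, dy = -hw:hw)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  pix_x <- rep(seq_len(nx), times = ny)
  pix_y <- rep(seq_len(ny), each = nx)
  in_roi <- as.vector(roi)
  ii <- list(); jj <- list(); vv <- list()
  for (o in seq_len(nrow(offs))) {
    dx <- offs$dx[o]; dy <- offs$dy[o]
    qx <- pix_x + dx; qy <- pix_y + dy
    ok <- in_roi & qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
    p <- which(ok)
    q <- (qy[ok] - 1L) * nx + qx[ok]
    ok2 <- in_roi[q]
    p <- p[ok2]; q <- q[ok2]
    d2 <- rowSums((Fm[p, , drop = FALSE] - Fm[q, , drop = FALSE])^2)
    k <- exp(-d2 / 2)
    keep <- k >= cfg$threshold
    ii[[o]] <- p[keep]; jj[[o]] <- q[keep]; vv[[o]] <- k[keep]
  }
  i <- unlist(ii); j <- unlist(jj); v <- unlist(vv)
  if (length(i) > 0 && cfg$knn >= 1) {
    ord <- order(i, -v, j)
    i <- i[ord]; j <- j[ord]; v <- v[ord]
    rank_in_row <- stats::ave(v, i, FUN = seq_along)
    keep <- rank_in_row <= cfg$knn
    i <- i[keep]; j <- j[keep]; v <- v[keep]
  } else if (cfg$knn == 0) {
    i <- integer(0); j <- integer(0); v <- numeric(0)
  }
  # self-weights everywhere (identity rows outside the ROI)
  i <- c(i, seq_len(npix)); j <- c(j, seq_len(npix)); v <- c(v, rep(1, npix))
  K <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(npix, npix))
  rs <- Matrix::rowSums(K)
  K <- Matrix::Diagonal(x = 1 / rs) %*% K
  K <- methods::as(K, "CsparseMatrix")
  attr(K, "cfg") <- cfg
  K
}

identity_spatial_kernel <- function(npix, cfg = kernel_config()) {
  K <- Matrix::Diagonal(npix)
  K <- methods::as(K, "CsparseMatrix")
  attr(K, "cfg") <- cfg
  K
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Build the dense temporal kernel matrix
#'
#' Frame features are the in-mask pixel intensities of a fast low-iteration
#' OSEM reconstruction of each frame (optionally with point-source pixels
#' masked out). The Gaussian radial kernel
#' `exp(-d2(f, g) / (2 sigma_f sigma_g))` is evaluated for frame pairs
#' within a centred window of `ts` frames (zero outside), where `d2` is the
#' mean squared feature difference and `sigma_f` is the distance from frame
#' f to its nearest within-window neighbour — a locally scaled bandwidth
#' that blends only frames indistinguishable beyond the local noise floor
#' and preserves kinetic transitions. Each column (a temporal basis
#' function) is then smoothed along the frame axis with a Gaussian of
#' `sigma_frames` and renormalized to sum one.
#'
#' @param frame_features A `dynamic_image` from
#'   [osem_feature_reconstruct()].
#' @param cfg A [kernel_config()].
#' @param mask Logical matrix of pixels used as features (`NULL` = all);
#'   point sources should be excluded here.
#' @return A dense F x F matrix with columns summing to one; attribute
#'   `cfg`.
#' @export
build_temporal_kernel <- function(frame_features, cfg = kernel_config(),
                                  mask = NULL) {
  nf <- dim(frame_features)[3]
  if (nf < 3) stop("need at least 3 frames")
  flat <- matrix(frame_features, ncol = nf)
  if (!is.null(mask)) flat <- flat[which(mask), , drop = FALSE]
  s <- stats::sd(flat)
  if (s > 0) flat <- flat / s
  hw <- cfg$ts %/% 2L
  D2 <- matrix(NA_real_, nf, nf)
  for (f in seq_len(nf)) {
    g <- max(1, f - hw):min(nf, f + hw)
    D2[f, g] <- colMeans((flat[, g, drop = FALSE] - flat[, f])^2)
  }
  # locally scaled bandwidth: sigma_f is the distance from frame f to its
  # nearest within-window neighbour, so frames are blended only when they are
  # indistinguishable beyond the local noise floor; pairs across a kinetic
  # transition (uptake, a displacement challenge) are strongly down-weighted
  ok <- !is.na(D2)
  K <- matrix(0, nf, nf)
  if (all(D2[ok] == 0)) {
    K[ok] <- 1
  } else {
    sig <- vapply(seq_len(nf), function(f)
      sqrt(min(D2[f, -f], na.rm = TRUE)), numeric(1))
    sig[sig == 0] <- min(sig[sig > 0])
    S <- outer(sig, sig)
    K[ok] <- exp(-D2[ok] / (2 * S[ok]))
  }
  w <- gaussian_kernel_1d(cfg$sigma_frames)
  r <- (length(w) - 1L) %/% 2L
  Ks <- K
  for (col in seq_len(nf)) {
    padded <- c(rep(K[1, col], r), K[, col], rep(K[nf, col], r))
    Ks[, col] <- stats::filter(padded, w, sides = 2)[(r + 1):(r + nf)]
  }
  Ks <- pmax(Ks, 0)
  Ks <- sweep(Ks, 2, colSums(Ks), "/")
  attr(Ks, "cfg") <- cfg
  Ks
}

#' Spatiotemporal kernel-EM reconstruction
#'
#' EM iterations performed on a coefficient array Z with the dynamic image
#' represented as `X = K_s Z K_t'`. With identity kernels this is exactly
#' frame-wise MLEM. The returned image is X (not Z), nonnegative.
#'
#' @param frames A sampled `frame_sinograms`.
#' @param sys A `system_model`.
#' @param K_s Sparse spatial kernel (pixels x pixels).
#' @param K_t Dense temporal kernel (frames x frames).
#' @param n_iter Number of EM iterations (default 300).
#' @return A `dynamic_image` (not decay-corrected).
#' @export
kernel_em_reconstruct <- function(frames, sys, K_s, K_t, n_iter = 300L) {
  if (is.null(frames$counts)) stop("frames have not been sampled")
  Y <- frames$counts
  nf <- ncol(Y)
  npix <- ncol(sys$A)
  if (nrow(K_s) != npix || ncol(K_s) != npix) stop("spatial kernel dimension mismatch")
  if (nrow(K_t) != nf || ncol(K_t) != nf) stop("temporal kernel dimension mismatch")
  dur <- frames$framing$duration_s
  a <- sys$attn_factors
  sens <- as.vector(sys$At %*% a)
  Sens <- outer(sens, dur)
  Kst <- Matrix::t(K_s)
  D <- as.matrix(Kst %*% Sens %*% K_t)
  supp <- rowSums(D) > 0
  Z <- matrix(0, npix, nf)
  Z[supp, ] <- 1
  for (it in seq_len(n_iter)) {
    X <- as.matrix(K_s %*% Z %*% t(K_t))
    lam <- as.matrix(sys$A %*% X) * a
    lam <- sweep(lam, 2, dur, "*")
    R <- Y / pmax(lam, eps_em)
    Bp <- as.matrix(sys$At %*% (R * a))
    Bp <- sweep(Bp, 2, dur, "*")
    Z <- Z * as.matrix(Kst %*% Bp %*% K_t) / pmax(D, eps_em)
    Z[!supp, ] <- 0
  }
  X <- as.matrix(K_s %*% Z %*% t(K_t))
  new_dynamic_image(pmax(X, 0), sys$grid_size, frames$framing)
}

boxcar2d <- function(m, w) {
  hw <- (w - 1L) %/% 2L
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  for (dx in -hw:hw) for (dy in -hw:hw) {
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    xt <- xs - dx
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    yt <- ys - dy
    out[xt, yt] <- out[xt, yt] + m[xs, ys]
  }
  out
}

#' HYPR denoising of a dynamic image
#'
#' Highly constrained backprojection denoising: the time-weighted average of
#' all frames is the composite image C, and each frame is replaced by
#' `C * boxcar(frame) / boxcar(C)` with an epsilon-guarded division.
#'
#' @param img A `dynamic_image`.
#' @param window Odd boxcar side in pixels (default 3).
#' @return A denoised `dynamic_image` with the same attributes.
#' @export
hypr_denoise <- function(img, window = 3L) {
  if (window %% 2 != 1) stop("window must be odd")
  d <- dim(img)
  if (d[3] == 1) {
    warning("single-frame image; HYPR is a no-op")
    return(img)
  }
  framing <- attr(img, "framing")
  wdur <- framing$duration_s / sum(framing$duration_s)
  flat <- matrix(img, ncol = d[3])
  comp <- matrix(as.vector(flat %*% wdur), d[1], d[2])
  bc <- boxcar2d(comp, window)
  out <- array(0, dim = d)
  for (f in seq_len(d[3])) {
    bf <- boxcar2d(matrix(flat[, f], d[1], d[2]), window)
    out[, , f] <- comp * bf / pmax(bc, eps_em)
  }
  attributes(out) <- attributes(img)
  out
}

#' Export a kernel matrix as sparse triplet CSV
#'
#' @param K A spatial (sparse) or temporal (dense) kernel matrix.
#' @param path Output CSV path with columns `row`, `col`, `value`.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(K, path) {
  T <- methods::as(methods::as(K, "sparseMatrix"), "TsparseMatrix")
  d <- data.frame(row = T@i + 1L, col = T@j + 1L, value = T@x)
  d <- d[order(d$row, d$col), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
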