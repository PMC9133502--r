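#' Gamma-variate activation response function
#'
#' `h(t) = ((t - t_d)/(t_p - t_d))^alpha * exp(alpha * (1 - (t - t_d)/(t_p -
#' t_d)))` for `t > t_d`, zero before onset. Normalized so `h(t_p) = 1`.
#'
#' @param t Time(s) in min.
#' @param t_d Onset time (min).
#' @param t_p Peak time (min), `t_p > t_d`.
#' @param alpha Skewness (> 0).
#' @return Numeric vector of `h(t)`.
#' @export
gamma_variate_h <- function(t, t_d, t_p, alpha) {
  if (t_p <= t_d) stop("need t_p > t_d")
  if (alpha <= 0) stop("alpha must be positive")
  x <- (t - t_d) / (t_p - t_d)
  h <- ifelse(x > 0, x^alpha * exp(alpha * (1 - x)), 0)
  h[!is.finite(h)] <- 0
  h
}

#' Gamma-variate basis-function grid
#'
#' The exhaustive (t_d, t_p, alpha) grid of activation shapes: onset from 10
#' to 40 min in 1.5-min steps; for each onset, peak from `t_d + 1.5` up to
#' `t_end - 5 - 1.5` min in 1.5-min steps (the open-interval convention that
#' excludes the singular `t_p = t_d` and the upper endpoint); skewness 0.5 to
#' 3 in steps of 0.5. For a 60-min scan this yields exactly 2,394 shapes.
#'
#' @param t_end_min Scan end time in min (default 60).
#' @param t_d_min,t_d_max,t_step Onset range and step in min.
#' @param t_p_margin Exclusion margin before scan end in min (default 5).
#' @param alphas Skewness values.
#' @return A tibble of class `basis_grid` with columns `t_d`, `t_p`, `alpha`.
#' @export
basis_grid <- function(t_end_min = 60, t_d_min = 10, t_d_max = 40,
                       t_step = 1.5, t_p_margin = 5,
                       alphas = seq(0.5, 3, by = 0.5)) {
  t_d <- seq(t_d_min, t_d_max, by = t_step)
  t_p_max <- t_end_min - t_p_margin - t_step
  pairs <- purrr::map_dfr(t_d, function(td) {
    tp <- seq(td + t_step, t_p_max, by = t_step)
    tibble::tibble(t_d = td, t_p = tp)
  })
  out <- tidyr::crossing(pairs, alpha = alphas)
  out <- dplyr::arrange(out, .data$t_d, .data$t_p, .data$alpha)
  if (nrow(out) == 0) stop("empty basis grid")
  class(out) <- c("basis_grid", class(out))
  out
}

# trapezoid weights: values at c(0, t)  ->  cumulative integral at t
trapz_weights <- function(t) {
  t0 <- c(0, t)
  n <- length(t0)
  dt <- diff(t0)
  W <- matrix(0, n - 1, n)
  for (k in seq_len(n - 1)) {
    w <- numeric(n)
    w[1:k] <- w[1:k] + dt[1:k] / 2
    w[2:(k + 1)] <- w[2:(k + 1)] + dt[1:k] / 2
    W[k, ] <- w
  }
  W
}

#' Build the basis-function library for a tissue TAC
#'
#' Evaluates `B_i(t) = int_0^t C_T(u) h_i(u) du` for every grid shape by
#' cumulative trapezoidal integration on the frame mid-time grid (with
#' `C_T(0) = 0` prepended).
#'
#' @param C_T A frame-kind `region_tac` (decay-corrected).
#' @param grid A [basis_grid()].
#' @param engine Optional precomputed [basis_engine()] for the same time grid
#'   (avoids re-evaluating the shape functions when fitting many TACs).
#' @return An object of class `basis_library`: list with `B` (frames x shapes
#'   matrix), `grid`, `time_min`.
#' @export
build_basis_library <- function(C_T, grid = basis_grid(), engine = NULL) {
  if (nrow(grid) == 0) stop("empty basis grid")
  t <- C_T$time_min
  if (is.null(engine)) engine <- basis_engine(t, grid)
  B <- engine$W %*% (c(0, C_T$value) * engine$H0)
  structure(list(B = B, grid = grid, time_min = t), class = "basis_library")
}

#' Precompute grid-dependent pieces of the basis library
#'
#' The shape functions evaluated on the (0-prepended) frame grid and the
#' cumulative-trapezoid weight matrix depend only on the time grid, not on
#' the TAC; precomputing them makes voxel-wise fitting cheap.
#'
#' @param t Frame mid-times in min.
#' @param grid A [basis_grid()].
#' @return A list with `H0`, `W`, `grid`, `time_min`.
#' @export
basis_engine <- function(t, grid = basis_grid()) {
  list(H0 = basis_h_matrix(c(0, t), grid), W = trapz_weights(t),
       grid = grid, time_min = t)
}

basis_h_matrix <- function(t, grid) {
  n <- nrow(grid)
  H <- matrix(0, length(t), n)
  for (i in seq_len(n))
    H[, i] <- gamma_variate_h(t, grid$t_d[i], grid$t_p[i], grid$alpha[i])
  H
}

# Exact NNLS for a small design by support enumeration: solves
# min ||y - X theta||^2 s.t. theta >= 0 by least squares on every support set.
nnls_enum <- function(X, y) {
  p <- ncol(X)
  yy <- sum(y^2)
  best <- list(theta = numeric(p), sse = yy)
  for (m in 1:(2^p - 1)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0)
    XS <- X[, S, drop = FALSE]
    G <- crossprod(XS)
    sol <- tryCatch(solve(G, crossprod(XS, y)), error = function(e) NULL)
    if (is.null(sol) || any(sol < 0)) next
    # explicit residual: the y'y - c'theta shortcut loses ~1e-10 absolute
    # precision to cancellation at realistic TAC amplitudes
    sse <- sum((y - XS %*% sol)^2)
    if (sse < best$sse - 1e-12) {
      th <- numeric(p); th[S] <- sol
      best <- list(theta = th, sse = sse)
    }
  }
  best
}

# Vectorized exhaustive-basis NNLS: for fixed X0 = [C_R, int C_R, -int C_T]
# and candidate fourth columns Bneg (= -B_i), returns per-basis minimal SSE
# under theta >= 0, plus the basis-independent gamma = 0 solution.
fit_all_bases <- function(X0, Bneg, y, nonneg = TRUE) {
  n <- ncol(Bneg)
  yy <- sum(y^2)
  G <- crossprod(X0)
  c0 <- drop(crossprod(X0, y))
  U <- crossprod(X0, Bneg)                       # 3 x n
  w <- drop(crossprod(Bneg, y))                  # n
  q <- colSums(Bneg^2)                           # n
  subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L))

  # gamma = 0 candidates (shared across bases)
  sse0 <- yy
  for (S in subsets[-1]) {
    GS <- G[S, S, drop = FALSE]
    sol <- tryCatch(solve(GS, c0[S]), error = function(e) NULL)
    if (is.null(sol)) next
    if (nonneg && any(sol < 0)) next
    sse0 <- min(sse0, yy - sum(sol * c0[S]))
  }

  sse <- rep(Inf, n)
  for (S in subsets) {
    k <- length(S)
    if (k == 0) {
      th4 <- w / pmax(q, 1e-300)
      ok <- q > 1e-12 & (!nonneg | th4 >= 0)
      cand <- yy - w * th4
      cand[!ok] <- Inf
    } else {
      GS <- G[S, S, drop = FALSE]
      Gi <- tryCatch(solve(GS), error = function(e) NULL)
      if (is.null(Gi)) next
      a <- drop(Gi %*% c0[S])                    # k
      V <- U[S, , drop = FALSE]                  # k x n
      GiV <- Gi %*% V                            # k x n
      denom <- q - colSums(V * GiV)
      num <- w - colSums(V * a)
      th4 <- num / pmax(denom, 1e-300)
      thS <- matrix(a, k, n) - GiV * rep(th4, each = k)
      ok <- denom > 1e-12
      if (nonneg) ok <- ok & th4 >= 0 & colSums(thS < 0) == 0
      cand <- yy - (colSums(thS * c0[S]) + th4 * w)
      cand[!ok] <- Inf
    }
    sse <- pmin(sse, cand)
  }
  list(sse_by_basis = pmin(sse, sse0), sse_gamma0 = sse0)
}

#' Fit the lp-ntPET model by exhaustive basis search
#'
#' For each gamma-variate basis function, solves the linear model
#' `C_T = R1 C_R + k2 int C_R - k2a int C_T - gamma B_i` for the coefficient
#' vector `[R1, k2, k2a, gamma]` by non-negative least squares, and returns
#' the basis with the minimum squared error (ties broken by the smallest
#' basis index). With `sign_mode = "free"` the fit is ordinary least squares,
#' allowing positive and negative response magnitude when the direction of
#' the neurotransmitter change is unknown.
#'
#' @param C_T,C_R Frame-kind `region_tac`s on identical frame grids,
#'   decay-corrected.
#' @param grid A [basis_grid()].
#' @param sign_mode `"nonneg"` (default) or `"free"`.
#' @param basis Optional precomputed [build_basis_library()] for `C_T`.
#' @return An object of class `lpntpet_fit`.
#' @export
fit_lpntpet <- function(C_T, C_R, grid = basis_grid(),
                        sign_mode = c("nonneg", "free"), basis = NULL) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(length(C_T$time_min) == length(C_R$time_min))
  if (max(abs(C_T$time_min - C_R$time_min)) > 1e-9)
    stop("C_T and C_R must share the same frame grid")
  t <- C_T$time_min
  y <- C_T$value
  cr <- C_R$value
  IR <- frame_cumint(t, cr)
  IT <- frame_cumint(t, y)
  X0 <- cbind(cr, IR, -IT)
  if (is.null(basis)) basis <- build_basis_library(C_T, grid)
  Bneg <- -basis$B
  res <- fit_all_bases(X0, Bneg, y, nonneg = sign_mode == "nonneg")
  i_star <- which.min(res$sse_by_basis)
  X <- cbind(X0, Bneg[, i_star])
  if (sign_mode == "nonneg") {
    sol <- nnls_enum(X, y)
    theta <- sol$theta; sse <- sol$sse
  } else {
    theta <- tryCatch(drop(solve(crossprod(X), crossprod(X, y))),
                      error = function(e) rep(NA_real_, 4))
    sse <- sum((y - X %*% theta)^2)
  }
  dof <- length(y) - 4L
  XtX <- crossprod(X)
  cov_ok <- is.finite(rcond_safe(XtX)) && rcond_safe(XtX) > 1e-14
  se_gamma <- if (cov_ok && dof > 0) {
    s2 <- sse / dof
    sqrt(s2 * solve(XtX)[4, 4])
  } else Inf
  g <- grid[i_star, ]
  structure(list(
    R1 = theta[1], k2 = theta[2], k2a = theta[3], gamma = theta[4],
    t_d = g$t_d, t_p = g$t_p, alpha = g$alpha, basis_index = i_star,
    sse = sse, se_gamma = se_gamma,
    t_gamma = theta[4] / se_gamma,
    degenerate = !cov_ok,
    sign_mode = sign_mode,
    fitted = drop(X %*% theta),
    time_min = t, C_T = y, C_R = cr), class = "lpntpet_fit")
}

rcond_safe <- function(M) tryCatch(rcond(M), error = function(e) 0)

# cumulative trapezoid of frame values with (0, 0) prepended, evaluated at t
frame_cumint <- function(t, v) {
  t0 <- c(0, t); v0 <- c(0, v)
  n <- length(t0)
  cumsum(diff(t0) * (v0[-n] + v0[-1]) / 2)
}

#' @export
print.lpntpet_fit <- function(x, ...) {
  cat("<lpntpet_fit> (", x$sign_mode, " gamma)\n", sep = "")
  cat(sprintf("  R1 = %.4f  k2 = %.4f min^-1  k2a = %.4f min^-1\n",
              x$R1, x$k2, x$k2a))
  cat(sprintf("  gamma = %.4f min^-1  (t_d = %.1f, t_p = %.1f, alpha = %.1f)\n",
              x$gamma, x$t_d, x$t_p, x$alpha))
  cat(sprintf("  SSE = %.4g  SE(gamma) = %.4g  gamma/SE = %.3f\n",
              x$sse, x$se_gamma, x$t_gamma))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an lp-ntPET fit
#' @param x An `lpntpet_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`.
#' @export
#' @exportS3Method generics::tidy
tidy.lpntpet_fit <- function(x, ...) {
  tibble::tibble(
    term = c("R1", "k2", "k2a", "gamma", "t_d", "t_p", "alpha"),
    estimate = c(x$R1, x$k2, x$k2a, x$gamma, x$t_d, x$t_p, x$alpha))
}

#' One-row summary of an lp-ntPET fit
#' @param x An `lpntpet_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.lpntpet_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, se_gamma = x$se_gamma, t_gamma = x$t_gamma,
                 basis_index = x$basis_index, degenerate = x$degenerate,
                 n_frames = length(x$time_min))
}

#' Activation response profile of a fit
#'
#' `ARP(t) = 100 * gamma * h(t) / k2a`, the transient efflux change as a
#' percentage of baseline efflux. Peaks at exactly `100 * gamma / k2a` at
#' `t = t_p` since `h(t_p) = 1`.
#'
#' @param fit An `lpntpet_fit` (or any list with `gamma`, `k2a`, `t_d`,
#'   `t_p`, `alpha`).
#' @param time_min Time grid in minutes (default 0..60 by 0.1).
#' @return A tibble of class `arp_curve` with `time_min`, `arp_pct`.
#' @export
compute_arp <- function(fit, time_min = seq(0, 60, by = 0.1)) {
  if (fit$k2a <= 0) stop("k2a must be positive to express ARP in percent of baseline")
  h <- gamma_variate_h(time_min, fit$t_d, fit$t_p, fit$alpha)
  out <- tibble::tibble(time_min = time_min, arp_pct = 100 * fit$gamma * h / fit$k2a)
  class(out) <- c("arp_curve", class(out))
  out
}

#' Voxel-wise lp-ntPET parametric maps
#'
#' Fits the lp-ntPET model independently to every pixel TAC inside the mask
#' and assembles parametric maps of k2a, gamma, t_d, t_p and the gamma
#' t-statistic gamma/SE(gamma). SE(gamma) comes from the ordinary
#' least-squares covariance at the selected basis (non-negativity truncation
#' ignored). Pixels with an all-zero TAC are flagged and set to 0.
#'
#' @param img Dynamic image array (nx, ny, frames), decay-corrected.
#' @param C_R Frame-kind reference `region_tac`.
#' @param mask Logical matrix of pixels to fit.
#' @param grid A [basis_grid()].
#' @param sign_mode Passed to [fit_lpntpet()].
#' @return An object of class `parametric_maps`: list of matrices `k2a`,
#'   `gamma`, `t_d`, `t_p`, `t_gamma`, `sse`, logical `zero_tac`, plus a
#'   per-pixel tibble `fits`.
#' @export
fit_parametric_maps <- function(img, C_R, mask, grid = basis_grid(),
                                sign_mode = "nonneg") {
  stopifnot(length(dim(img)) == 3L, is.logical(mask))
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  nf <- dim(img)[3]
  t <- C_R$time_min
  stopifnot(length(t) == nf)
  eng <- basis_engine(t, grid)
  flat <- matrix(img, ncol = nf)   # pixels x frames
  empty <- matrix(NA_real_, nrow(mask), ncol(mask))
  maps <- list(k2a = empty, gamma = empty, t_d = empty, t_p = empty,
               t_gamma = empty, sse = empty,
               zero_tac = matrix(FALSE, nrow(mask), ncol(mask)))
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    p <- idx[j]
    yv <- flat[p, ]
    if (all(yv == 0)) {
      maps$zero_tac[p] <- TRUE
      maps$k2a[p] <- maps$gamma[p] <- maps$t_d[p] <- maps$t_p[p] <-
        maps$t_gamma[p] <- maps$sse[p] <- 0
      rows[[j]] <- tibble::tibble(pixel = p, k2a = 0, gamma = 0, t_d = 0,
                                  t_p = 0, t_gamma = 0, sse = 0)
      next
    }
    tac <- new_region_tac(t, yv, kind = "frame")
    f <- fit_lpntpet(tac, C_R, grid, sign_mode = sign_mode,
                     basis = build_basis_library(tac, grid, engine = eng))
    maps$k2a[p] <- f$k2a; maps$gamma[p] <- f$gamma
    maps$t_d[p] <- f$t_d; maps$t_p[p] <- f$t_p
    maps$t_gamma[p] <- f$t_gamma; maps$sse[p] <- f$sse
    rows[[j]] <- tibble::tibble(pixel = p, k2a = f$k2a, gamma = f$gamma,
                                t_d = f$t_d, t_p = f$t_p,
                                t_gamma = f$t_gamma, sse = f$sse)
  }
  maps$fits <- dplyr::bind_rows(rows)
  class(maps) <- "parametric_maps"
  maps
}

#' Write regional fits as CSV
#' @param fits A list of `lpntpet_fit`s (possibly named).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  tab <- purrr::map_dfr(fits, function(f)
    tibble::tibble(R1 = f$R1, k2 = f$k2, k2a = f$k2a, gamma = f$gamma,
                   t_d = f$t_d, t_p = f$t_p, alpha = f$alpha,
                   SSE = f$sse, SE_gamma = f$se_gamma), .id = "region")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
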