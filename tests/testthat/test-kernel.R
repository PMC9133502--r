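test_that("spatial kernel matches a brute-force enumeration on a toy image", {
  set.seed(21)
  nx <- 5
  feats <- array(runif(nx * nx * 3), dim = c(nx, nx, 3))
  cfg <- kernel_config(window = 3, threshold = 0.8, knn = 2)
  K <- build_spatial_kernel(feats, cfg)
  # oracle: exhaustive pairwise kernel values with the same conventions
  Fm <- matrix(feats, ncol = 3)
  Fm <- sweep(Fm, 2, apply(Fm, 2, sd), "/")
  px <- function(p) c((p - 1) %% nx + 1, (p - 1) %/% nx + 1)
  for (p in seq_len(nx * nx)) {
    xy <- px(p)
    cand <- c()
    for (q in seq_len(nx * nx)) {
      if (q == p) next
      d <- abs(px(q) - xy)
      if (max(d) > 1) next
      k <- exp(-sum((Fm[p, ] - Fm[q, ])^2) / 2)
      if (k >= 0.8) cand <- rbind(cand, c(q, k))
    }
    w <- stats::setNames(numeric(0), character(0))
    if (!is.null(cand)) {
      ord <- order(-cand[, 2], cand[, 1])
      cand <- cand[ord, , drop = FALSE][seq_len(min(2, nrow(cand))), , drop = FALSE]
      w <- stats::setNames(cand[, 2], cand[, 1])
    }
    w <- c(w, stats::setNames(1, p))
    w <- w / sum(w)
    row <- as.vector(K[p, ])
    expect_equal(sum(row > 0), length(w))
    expect_equal(row[as.integer(names(w))], unname(w), tolerance = 1e-12)
  }
})

test_that("spatial kernel rows are stochastic with bounded support", {
  s <- tiny_setup()
  set.seed(5)
  feats <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  cfg <- kernel_config(window = 9, threshold = 0.8, knn = 48)
  roi <- s$masks$brain
  K <- build_spatial_kernel(feats, cfg, roi = roi)
  expect_equal(Matrix::rowSums(K), rep(1, 1024), tolerance = 1e-12)
  expect_true(all(K@x >= 0))
  nnz_per_row <- tabulate(rep(seq_len(1024), diff(Matrix::t(K)@p))[TRUE], 1024)
  expect_true(all(Matrix::rowSums(K != 0) <= 49))
  # out-of-ROI rows are identity
  out_rows <- which(!roi)
  D <- Matrix::diag(K)
  expect_true(all(D[out_rows] == 1))
})

test_that("identical features give equal weights; knn = 0 gives the identity", {
  feats <- array(1, dim = c(4, 4, 3))
  expect_warning(K <- build_spatial_kernel(feats, kernel_config(window = 3, knn = 3)),
                 "constant")
  expect_equal(as.matrix(K), diag(16), ignore_attr = TRUE)
  set.seed(1)
  feats2 <- array(runif(48), dim = c(4, 4, 3))
  K0 <- build_spatial_kernel(feats2, kernel_config(window = 3, knn = 0))
  expect_equal(as.matrix(K0), diag(16), ignore_attr = TRUE)
})

test_that("temporal kernel matches exhaustive pairwise computation on a toy", {
  set.seed(8)
  nf <- 6
  feats <- array(runif(4 * 4 * nf), dim = c(4, 4, nf))
  cfg <- kernel_config(ts = 3, sigma_frames = 0.03)
  K <- build_temporal_kernel(feats, cfg)
  flat <- matrix(feats, ncol = nf) / sd(matrix(feats, ncol = nf))
  d2 <- matrix(NA_real_, nf, nf)
  for (f in 1:nf) for (g in 1:nf) {
    if (abs(f - g) <= 1) d2[f, g] <- mean((flat[, f] - flat[, g])^2)
  }
  sig <- sapply(1:nf, function(f) sqrt(min(d2[f, -f], na.rm = TRUE)))
  sig[sig == 0] <- min(sig[sig > 0])
  raw <- ifelse(is.na(d2), 0, exp(-d2 / (2 * outer(sig, sig))))
  # sigma 0.03 frames: the discrete smoothing kernel is numerically a delta
  oracle <- sweep(raw, 2, colSums(raw), "/")
  expect_equal(unclass(K), oracle, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(colSums(K), rep(1, nf))
  expect_error(build_temporal_kernel(feats[, , 1:2, drop = FALSE], cfg), "3 frames")
})

test_that("temporal kernel defaults follow ts = 15, sigma = ts/100", {
  cfg <- kernel_config()
  expect_equal(cfg$ts, 15L)
  expect_equal(cfg$sigma_frames, 0.15)
  expect_equal(cfg$window, 9L)
  expect_equal(cfg$threshold, 0.8)
  expect_equal(cfg$knn, 48L)
  expect_error(kernel_config(threshold = 1.2), "threshold")
  expect_error(kernel_config(ts = 2), "ts")
  # identical frame features: within-window entries of a column are equal
  feats <- array(rep(matrix(runif(16), 4, 4), 5), dim = c(4, 4, 5))
  K <- build_temporal_kernel(feats, kernel_config(ts = 3, sigma_frames = 0.03))
  mid <- K[, 3][K[, 3] > 1e-6]
  expect_equal(sd(mid), 0, tolerance = 1e-9)
  expect_length(mid, 3L)
})

test_that("kernel-EM with identity kernels equals frame-wise MLEM", {
  s <- tiny_setup(grid_size = 32, n_angles = 36,
                  framing = make_framing(list(c(4, 900))))
  fs <- sample_poisson_counts(
    forward_project_frames(s$truth, s$sys, s$framing, 2e6), seed = 2)
  K_s <- Matrix::Diagonal(32 * 32)
  K_t <- diag(4)
  kem <- kernel_em_reconstruct(fs, s$sys, K_s, K_t, n_iter = 20)
  mlem <- mlem_reconstruct(fs, s$sys, n_iter = 20)
  rel <- max(abs(kem - mlem)) / max(mlem)
  expect_lt(rel, 1e-8)
  expect_true(all(kem >= 0))
  expect_error(kernel_em_reconstruct(fs, s$sys, Matrix::Diagonal(10), K_t, 1),
               "spatial kernel dimension")
  expect_error(kernel_em_reconstruct(fs, s$sys, K_s, diag(3), 1),
               "temporal kernel dimension")
})

test_that("HYPR is exact for temporally constant images and homogeneous", {
  fr <- make_framing(list(c(3, 60)))
  set.seed(4)
  base <- matrix(runif(64, 1, 2), 8, 8)
  img <- array(rep(base, 3), dim = c(8, 8, 3))
  attr(img, "framing") <- fr
  out <- hypr_denoise(img)
  expect_equal(as.vector(out), as.vector(img), tolerance = 1e-9)
  # homogeneity
  img2 <- img
  img2[] <- img[] + array(runif(192, 0, 0.3), dim = dim(img))
  h1 <- hypr_denoise(img2)
  img3 <- img2; img3[] <- 7 * img2[]
  h7 <- hypr_denoise(img3)
  expect_equal(as.vector(h7), 7 * as.vector(h1), tolerance = 1e-9)
})

test_that("HYPR matches a hand-computed boxcar ratio on a 4x4 toy", {
  fr <- make_framing(list(c(3, 100)))
  set.seed(12)
  img <- array(runif(48, 0.5, 2), dim = c(4, 4, 3))
  attr(img, "framing") <- fr
  out <- hypr_denoise(img, window = 3)
  comp <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  box <- function(m) {
    o <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4)
      o[i, j] <- sum(m[max(1, i - 1):min(4, i + 1), max(1, j - 1):min(4, j + 1)])
    o
  }
  for (f in 1:3)
    expect_equal(out[, , f], comp * box(img[, , f]) / box(comp), tolerance = 1e-12)
  one <- img[, , 1, drop = FALSE]
  attr(one, "framing") <- make_framing(list(c(1, 100)))
  expect_warning(same <- hypr_denoise(one), "single-frame")
  expect_equal(same, one)
})

test_that("kernel matrices export as sorted triplet CSV", {
  set.seed(3)
  feats <- array(runif(48), dim = c(4, 4, 3))
  K <- build_spatial_kernel(feats, kernel_config(window = 3, knn = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_kernel_csv(K, path)
  d <- read.csv(path)
  expect_equal(nrow(d), Matrix::nnzero(K))
  expect_equal(sum(d$value), sum(K))
  got <- d[d$row == 6, ]
  expect_equal(sum(got$value), 1, tolerance = 1e-12)
})
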