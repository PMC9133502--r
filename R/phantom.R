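#' Phantom specification
#'
#' Parameterizes the 2D digital rat-brain phantom: an elliptical head (the
#' reference tissue), two mirror-symmetric striatal ellipses (left = rest,
#' right = active), all on a square pixel grid. Geometry is given in pixel
#' units of the grid centre; the default head ellipse covers roughly two
#' thirds of the field of view and each striatum spans well over 100 pixels,
#' consistent with the rat striatum extending over on the order of a hundred
#' image elements.
#'
#' @param grid_size Pixels per side (default 128).
#' @param pixel_size_mm Pixel size in mm (default 0.776).
#' @param head_center,head_axes Centre (x, y) and semi-axes of the head
#'   ellipse, in pixels relative to the grid centre.
#' @param striatum_offset Centre (x, y) of the *right* (active) striatum
#'   ellipse relative to the grid centre; the left (rest) striatum is its
#'   mirror image about the vertical midline.
#' @param striatum_axes Semi-axes of each striatal ellipse in pixels.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128L,
                         pixel_size_mm = 0.776,
                         head_center = c(0, 0),
                         head_axes = NULL,
                         striatum_offset = NULL,
                         striatum_axes = NULL) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 32L) stop("grid_size must be >= 32")
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  s <- grid_size / 128
  if (is.null(head_axes)) head_axes <- c(42, 52) * s
  if (is.null(striatum_offset)) striatum_offset <- c(16, -10) * s
  if (is.null(striatum_axes)) striatum_axes <- c(9, 13) * s
  if (any(head_axes <= 0)) stop("head axes must be positive")
  if (any(striatum_axes <= 0)) stop("striatum axes must be positive (zero-area striatum)")
  structure(list(grid_size = grid_size, pixel_size_mm = pixel_size_mm,
                 head_center = head_center, head_axes = head_axes,
                 striatum_offset = striatum_offset, striatum_axes = striatum_axes),
            class = "phantom_spec")
}

#' Phantom region labels
#' @format Integer codes used in the label map.
#' @keywords internal
.labels <- c(background = 0L, head = 1L, rest = 2L, active = 3L)

ellipse_mask <- function(n, center, axes) {
  # pixel-centred coordinates relative to grid centre; x right, y down
  cx <- (n - 1) / 2 + center[1]
  cy <- (n - 1) / 2 + center[2]
  x <- matrix(rep(0:(n - 1), n), nrow = n)          # column index along x
  y <- matrix(rep(0:(n - 1), each = n), nrow = n)   # row index along y
  ((x - cx) / axes[1])^2 + ((y - cy) / axes[2])^2 <= 1
}

#' Build the phantom label map
#'
#' Deterministically rasterizes the phantom regions into an integer label map
#' with values 0 = background, 1 = head (reference tissue), 2 = rest (left)
#' striatum, 3 = active (right) striatum. The rest mask is the exact mirror
#' image of the active mask about the vertical midline.
#'
#' @param spec A [phantom_spec()].
#' @return An integer matrix of class `label_map` (`grid_size` x `grid_size`)
#'   with attributes `spec` and `labels`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  head <- ellipse_mask(n, spec$head_center, spec$head_axes)
  active <- ellipse_mask(n, spec$striatum_offset, spec$striatum_axes)
  # mirror about the vertical midline: x -> n-1-x, i.e. reverse row order of
  # the x index (rows index x here since x varies along rows of the matrix)
  rest <- active[n:1, , drop = FALSE]
  if (any(active & !head) || any(rest & !head))
    stop("striatum ellipse extends outside the head outline")
  if (any(rest & active)) stop("rest and active striatum ellipses overlap")
  lab <- matrix(.labels[["background"]], n, n)
  lab[head] <- .labels[["head"]]
  lab[rest] <- .labels[["rest"]]
  lab[active] <- .labels[["active"]]
  structure(lab, class = c("label_map", "matrix"), spec = spec, labels = .labels)
}

#' Region mask from a label map
#'
#' @param labels A `label_map`.
#' @param region One of "head", "rest", "active", "reference", "brain".
#'   "reference" is head tissue excluding both striata; "brain" is every
#'   non-background pixel.
#' @return A logical matrix.
#' @export
region_mask <- function(labels, region = c("head", "rest", "active", "reference", "brain")) {
  region <- match.arg(region)
  m <- unclass(labels)
  switch(region,
    head = m == .labels[["head"]] | m == .labels[["rest"]] | m == .labels[["active"]],
    rest = m == .labels[["rest"]],
    active = m == .labels[["active"]],
    reference = m == .labels[["head"]],
    brain = m != .labels[["background"]])
}

#' Build the attenuation map
#'
#' Uniform soft-tissue linear attenuation over every non-background pixel
#' (default 0.096 cm^-1), zero outside the head.
#'
#' @param labels A `label_map`.
#' @param mu_tissue Linear attenuation coefficient in cm^-1.
#' @return A numeric matrix of class `attenuation_map` (cm^-1).
#' @export
make_attenuation_map <- function(labels, mu_tissue = 0.096) {
  stopifnot(inherits(labels, "label_map"))
  if (mu_tissue < 0) stop("mu_tissue must be non-negative")
  mu <- ifelse(region_mask(labels, "brain"), mu_tissue, 0)
  structure(mu, class = c("attenuation_map", "matrix"),
            pixel_size_mm = attr(labels, "spec")$pixel_size_mm)
}

#' Dynamic framing scheme
#'
#' Builds contiguous time frames from a run-length scheme. The default is the
#' 47-frame, 60-min dynamic protocol: 12 x 10 s, 6 x 20 s, 2 x 60 s,
#' 27 x 120 s.
#'
#' @param scheme A list of `c(count, duration_s)` pairs.
#' @return A tibble of class `time_framing` with columns `frame`, `start_s`,
#'   `end_s`, `duration_s`, `mid_s`, `mid_min`; attribute `t_end_min`.
#' @export
make_framing <- function(scheme = list(c(12, 10), c(6, 20), c(2, 60), c(27, 120))) {
  if (length(scheme) == 0) stop("empty framing scheme")
  counts <- vapply(scheme, `[`, numeric(1), 1)
  durs <- vapply(scheme, `[`, numeric(1), 2)
  if (any(counts < 1) || any(durs <= 0)) stop("counts must be >= 1 and durations > 0")
  duration_s <- rep(durs, times = counts)
  end_s <- cumsum(duration_s)
  start_s <- c(0, end_s[-length(end_s)])
  out <- tibble::tibble(
    frame = seq_along(duration_s),
    start_s = start_s, end_s = end_s, duration_s = duration_s,
    mid_s = (start_s + end_s) / 2, mid_min = (start_s + end_s) / 120)
  attr(out, "t_end_min") <- end_s[length(end_s)] / 60
  class(out) <- c("time_framing", class(out))
  out
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$grid_size, "x", x$grid_size,
      " grid, ", x$pixel_size_mm, " mm pixels\n", sep = "")
  invisible(x)
}

#' Write a label or attenuation map as NIfTI
#' @param x A matrix-like image.
#' @param path Output file path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(x, path) {
  RNifti::writeNifti(array(unclass(x), dim = c(dim(x), 1)), path)
  invisible(path)
}

#' Write a framing scheme as CSV
#' @param framing A `time_framing`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_framing_csv <- function(framing, path) {
  utils::write.csv(framing[, c("frame", "start_s", "end_s")], path, row.names = FALSE)
  invisible(path)
}
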