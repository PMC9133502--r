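#' Reference-region model
#'
#' Analytic reference-tissue time activity curve
#' `C_R(t) = A * (exp(-washout * t) - exp(-uptake * t))`, the standard
#' bi-exponential uptake-washout shape: zero at injection, a single maximum,
#' then monotone washout. Units are kBq/mL for activity and min^-1 for rates.
#'
#' @param amplitude Scale A in kBq/mL (default 40).
#' @param uptake Uptake rate in min^-1 (default 1.2); must exceed `washout`.
#' @param washout Washout rate in min^-1 (default 0.06).
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(amplitude = 40, uptake = 1.2, washout = 0.06) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (uptake <= washout || washout < 0) stop("need uptake > washout >= 0")
  structure(list(amplitude = amplitude, uptake = uptake, washout = washout),
            class = "reference_model")
}

#' Kinetic parameters of the reference-tissue model
#'
#' Baseline parameters of the time-varying-efflux reference-tissue model:
#' delivery ratio R1 (unitless), transfer rate k2 (min^-1), and apparent
#' baseline efflux k2a (min^-1). Defaults are the package's calibrated
#' generator baseline (see the methods vignette).
#'
#' @param R1,k2,k2a Non-negative model parameters.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(R1 = 1.0, k2 = 0.35, k2a = 0.0518) {
  if (any(c(R1, k2, k2a) < 0)) stop("kinetic parameters must be non-negative")
  structure(list(R1 = R1, k2 = k2, k2a = k2a), class = "kinetic_params")
}

#' Activation response shape
#'
#' Gamma-variate transient activation: magnitude `gamma` (min^-1), onset
#' `t_d` (min), peak `t_p` (min), skewness `alpha`. The generator default
#' emulates a challenge at 20 min with response peaking at 25 min.
#'
#' @param gamma Response magnitude in min^-1 (>= 0).
#' @param t_d,t_p Onset and peak times in min, `t_d < t_p`.
#' @param alpha Skewness parameter (> 0).
#' @return An object of class `activation_shape`.
#' @export
activation_shape <- function(gamma = 0.018, t_d = 20, t_p = 25, alpha = 1) {
  if (gamma < 0) stop("gamma must be non-negative")
  if (t_p <= t_d) stop("need t_d < t_p")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(gamma = gamma, t_d = t_d, t_p = t_p, alpha = alpha),
            class = "activation_shape")
}

new_region_tac <- function(time_min, value, kind, decay_corrected = TRUE,
                           framing = NULL, frame = NULL) {
  out <- tibble::tibble(time_min = time_min, value = value)
  if (!is.null(frame)) out <- tibble::add_column(out, frame = frame, .before = 1)
  attr(out, "kind") <- kind
  attr(out, "decay_corrected") <- decay_corrected
  attr(out, "framing") <- framing
  class(out) <- c("region_tac", class(out))
  out
}

#' Evaluate the reference TAC on a dense time grid
#'
#' @param model A [reference_model()].
#' @param t_end_min Scan length in min (default 60).
#' @param dt_s Dense sampling step in seconds (default 1).
#' @return A dense `region_tac` tibble with columns `time_min`, `value`.
#' @export
reference_tac <- function(model = reference_model(), t_end_min = 60, dt_s = 1) {
  stopifnot(inherits(model, "reference_model"))
  t <- seq(0, t_end_min, by = dt_s / 60)
  v <- model$amplitude * (exp(-model$washout * t) - exp(-model$uptake * t))
  new_region_tac(t, pmax(v, 0), kind = "dense")
}

cumtrapz0 <- function(t, v) {
  # cumulative trapezoid along t, assuming v[1] corresponds to t[1]
  n <- length(t)
  if (n == 1) return(0)
  c(0, cumsum(diff(t) * (v[-n] + v[-1]) / 2))
}

#' Simulate a tissue TAC with time-varying efflux
#'
#' Solves the time-varying-efflux reference-tissue model in its integral form,
#' `C_T = R1 C_R + k2 int C_R - k2a int C_T - gamma int C_T h`, by trapezoidal
#' collocation on the time grid of `C_R`. With `act = NULL` (or zero gamma)
#' this reduces to the constant-efflux reference-tissue model. The returned
#' curve satisfies the integral equation on its own grid to machine precision,
#' which makes noise-free parameter recovery exactly testable.
#'
#' @param kin A [kinetic_params()].
#' @param act An [activation_shape()] or `NULL` for a rest-region TAC.
#' @param C_R A dense `region_tac` for the reference region (must start at
#'   t = 0 with value 0).
#' @return A dense `region_tac` for the tissue region on the same grid.
#' @export
simulate_ntpet_tac <- function(kin = kinetic_params(), act = NULL,
                               C_R = reference_tac()) {
  stopifnot(inherits(kin, "kinetic_params"))
  t <- C_R$time_min
  cr <- C_R$value
  n <- length(t)
  g <- if (is.null(act)) 0 else act$gamma
  h <- if (is.null(act) || g == 0) numeric(n) else
    gamma_variate_h(t, act$t_d, act$t_p, act$alpha)
  IR <- cumtrapz0(t, cr)
  ct <- numeric(n)
  IT <- 0; B <- 0
  ct[1] <- kin$R1 * cr[1]
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    rhs <- kin$R1 * cr[i] + kin$k2 * IR[i] -
      kin$k2a * (IT + dt / 2 * ct[i - 1]) -
      g * (B + dt / 2 * ct[i - 1] * h[i - 1])
    ct[i] <- rhs / (1 + dt / 2 * (kin$k2a + g * h[i]))
    IT <- IT + dt / 2 * (ct[i - 1] + ct[i])
    B <- B + dt / 2 * (ct[i - 1] * h[i - 1] + ct[i] * h[i])
  }
  new_region_tac(t, ct, kind = "dense")
}

#' C-11 half-life in minutes
#' @export
HALF_LIFE_C11_MIN <- 20.364

#' Frame-averaged decay factors
#'
#' Mean of `exp(-lambda t)` over each frame interval, `lambda = log(2) /
#' half_life`.
#'
#' @param framing A `time_framing`.
#' @param half_life_min Isotope half-life in minutes.
#' @return Numeric vector, one factor per frame.
#' @export
decay_factors <- function(framing, half_life_min = HALF_LIFE_C11_MIN) {
  if (half_life_min <= 0) stop("half_life_min must be positive")
  lam <- log(2) / half_life_min
  t1 <- framing$start_s / 60
  t2 <- framing$end_s / 60
  (exp(-lam * t1) - exp(-lam * t2)) / (lam * (t2 - t1))
}

#' Average a dense TAC onto the framing grid
#'
#' Frame value = time average of the dense curve over the frame interval
#' (trapezoidal). When `decay_correct = FALSE` the frame values additionally
#' carry physical radioactive decay as a per-frame multiplicative factor
#' (frame-averaged `exp(-lambda t)`); with `decay_correct = TRUE` decay is
#' absent, as required before kinetic modeling.
#'
#' @param tac A dense `region_tac` (decay-free activity).
#' @param framing A `time_framing`; must lie within the dense grid.
#' @param half_life_min Isotope half-life in minutes.
#' @param decay_correct If `FALSE`, apply physical decay to the frame means.
#' @return A frame-kind `region_tac` with one row per frame.
#' @export
frame_activity <- function(tac, framing, half_life_min = HALF_LIFE_C11_MIN,
                           decay_correct = TRUE) {
  t <- tac$time_min; v <- tac$value
  if (max(framing$end_s) / 60 > max(t) + 1e-9 || min(framing$start_s) / 60 < min(t) - 1e-9)
    stop("framing extends beyond the dense time grid")
  means <- frame_means(t, v, framing$start_s / 60, framing$end_s / 60)
  if (!decay_correct) means <- means * decay_factors(framing, half_life_min)
  new_region_tac(framing$mid_min, means, kind = "frame",
                 decay_corrected = decay_correct, framing = framing,
                 frame = framing$frame)
}

frame_means <- function(t, v, a, b) {
  f <- stats::approxfun(t, v, rule = 2)
  vapply(seq_along(a), function(i) {
    inside <- t > a[i] & t < b[i]
    tt <- c(a[i], t[inside], b[i])
    vv <- c(f(a[i]), v[inside], f(b[i]))
    sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2) / (b[i] - a[i])
  }, numeric(1))
}

#' Remove physical decay from frame values
#'
#' Divides frame values by the frame-averaged decay factor; exact inverse of
#' the decay application in [frame_activity()].
#'
#' @param x A frame-kind `region_tac` or a dynamic image array (see
#'   [mlem_reconstruct()]).
#' @param framing A `time_framing`.
#' @param half_life_min Isotope half-life in minutes.
#' @return Same type as `x`, decay-corrected.
#' @export
decay_correct_frames <- function(x, framing, half_life_min = HALF_LIFE_C11_MIN) {
  d <- decay_factors(framing, half_life_min)
  if (inherits(x, "region_tac")) {
    x$value <- x$value / d
    attr(x, "decay_corrected") <- TRUE
    return(x)
  }
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(d))
  out <- sweep(x, 3, d, "/")
  attributes(out) <- attributes(x)
  attr(out, "decay_corrected") <- TRUE
  out
}

#' Map activation sweep level to response magnitude
#'
#' The activation-level sweep expresses the transient peak as a percentage of
#' the baseline level; the response magnitude scales linearly with the excess
#' over baseline, anchored so the 200% level equals `gamma_max`.
#'
#' @param level_pct Activation peak level in percent of baseline (e.g. 120).
#' @param gamma_max Magnitude at the 200% level (min^-1).
#' @return gamma in min^-1.
#' @export
activation_gamma <- function(level_pct, gamma_max = 0.018) {
  if (any(level_pct < 100)) stop("activation level is a percentage >= 100")
  gamma_max * (level_pct - 100) / 100
}

#' Write a TAC to CSV
#' @param tac A `region_tac`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(tac, path) {
  utils::write.csv(as.data.frame(tac), path, row.names = FALSE)
  invisible(path)
}

#' Read a TAC from CSV
#' @param path CSV with columns `time_min`, `value` (optional `frame`).
#' @param kind "dense" or "frame".
#' @return A `region_tac`.
#' @export
read_tac_csv <- function(path, kind = c("dense", "frame")) {
  kind <- match.arg(kind)
  d <- utils::read.csv(path)
  new_region_tac(d$time_min, d$value, kind = kind,
                 frame = if ("frame" %in% names(d)) d$frame)
}
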