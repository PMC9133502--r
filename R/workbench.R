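#' Assemble the full simulation setup
#'
#' Builds the phantom, framing, region TACs (reference, rest, active), the
#' decayed truth dynamic image and the attenuated system model — everything
#' that is shared across noise realizations of one study condition.
#'
#' @param spec A [phantom_spec()].
#' @param framing A [make_framing()] scheme.
#' @param ref A [reference_model()].
#' @param kin A [kinetic_params()] baseline.
#' @param act An [activation_shape()] for the active region.
#' @param geom A [projection_geometry()]; defaults to match the grid.
#' @param half_life_min Isotope half-life (min).
#' @param dt_s Dense TAC sampling step (s).
#' @return A list of class `sim_setup`.
#' @export
sim_setup <- function(spec = phantom_spec(), framing = make_framing(),
                      ref = reference_model(), kin = kinetic_params(),
                      act = activation_shape(), geom = NULL,
                      half_life_min = HALF_LIFE_C11_MIN, dt_s = 1) {
  labels <- make_phantom(spec)
  attn <- make_attenuation_map(labels)
  if (is.null(geom))
    geom <- projection_geometry(n_radial = spec$grid_size,
                                bin_size_mm = spec$pixel_size_mm)
  sys <- build_system_model(geom, attn)
  t_end <- attr(framing, "t_end_min")
  cr_dense <- reference_tac(ref, t_end_min = t_end, dt_s = dt_s)
  rest_dense <- simulate_ntpet_tac(kin, NULL, cr_dense)
  active_dense <- simulate_ntpet_tac(kin, act, cr_dense)
  dense <- list(reference = cr_dense, rest = rest_dense, active = active_dense)
  decayed <- purrr::map(dense, frame_activity, framing = framing,
                        half_life_min = half_life_min, decay_correct = FALSE)
  dc <- purrr::map(dense, frame_activity, framing = framing,
                   half_life_min = half_life_min, decay_correct = TRUE)
  masks <- list(reference = region_mask(labels, "reference"),
                rest = region_mask(labels, "rest"),
                active = region_mask(labels, "active"),
                brain = region_mask(labels, "brain"))
  truth <- region_dynamic_image(labels, decayed, framing, decay_corrected = FALSE)
  truth_dc <- region_dynamic_image(labels, dc, framing, decay_corrected = TRUE)
  structure(list(spec = spec, labels = labels, attn = attn, sys = sys,
                 framing = framing, ref = ref, kin = kin, act = act,
                 half_life_min = half_life_min,
                 dense = dense, decayed = decayed, dc = dc, masks = masks,
                 truth = truth, truth_dc = truth_dc), class = "sim_setup")
}

#' Paint region TACs into a dynamic image
#'
#' @param labels A `label_map`.
#' @param tacs Named list of frame-kind `region_tac`s: `reference`, `rest`,
#'   `active` (reference fills all non-striatal head tissue).
#' @param framing A `time_framing`.
#' @param decay_corrected Flag stored on the image.
#' @return A `dynamic_image`.
#' @export
region_dynamic_image <- function(labels, tacs, framing, decay_corrected = TRUE) {
  n <- nrow(labels)
  nf <- nrow(framing)
  X <- matrix(0, n * n, nf)
  for (r in c("reference", "rest", "active")) {
    m <- region_mask(labels, if (r == "reference") "reference" else r)
    X[which(m), ] <- matrix(tacs[[r]]$value, sum(m), nf, byrow = TRUE)
  }
  new_dynamic_image(X, n, framing, decay_corrected = decay_corrected)
}

roi_bounding_box <- function(mask, margin = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[max(1, min(idx[, 1]) - margin):min(nrow(mask), max(idx[, 1]) + margin),
      max(1, min(idx[, 2]) - margin):min(ncol(mask), max(idx[, 2]) + margin)] <- TRUE
  out
}

composite_sinograms <- function(fs, n_composites = 3L) {
  framing <- fs$framing
  t_end <- max(framing$end_s)
  edges <- seq(0, t_end, length.out = n_composites + 1)
  grp <- findInterval(framing$mid_s, edges, rightmost.closed = TRUE)
  agg <- function(M) sapply(seq_len(n_composites), function(g)
    rowSums(M[, grp == g, drop = FALSE]))
  cf <- make_framing(lapply(seq_len(n_composites), function(g)
    c(1, sum(framing$duration_s[grp == g]))))
  structure(list(lambda = agg(fs$lambda),
                 counts = if (!is.null(fs$counts)) agg(fs$counts),
                 framing = cf, budget = fs$budget, scale = fs$scale),
            class = "frame_sinograms")
}

#' Reconstruct one noise realization with the selected arms
#'
#' Arms: `"ifr"` (frame-independent MLEM), `"ifr_hypr"` (MLEM followed by
#' HYPR denoising), `"kernel"` (spatiotemporal kernel-EM with data-derived
#' spatial and temporal kernels). All returned images are decay-corrected.
#'
#' @param sampled A sampled `frame_sinograms`.
#' @param setup A [sim_setup()].
#' @param arms Character subset of `c("ifr", "ifr_hypr", "kernel")`.
#' @param n_iter EM iterations for the main reconstructions (default 300).
#' @param kcfg A [kernel_config()].
#' @param composite_iter MLEM iterations for the 3 composite feature images.
#' @return Named list of decay-corrected `dynamic_image`s.
#' @export
reconstruct_arms <- function(sampled, setup, arms = c("ifr", "ifr_hypr", "kernel"),
                             n_iter = 300L, kcfg = kernel_config(),
                             composite_iter = 30L) {
  arms <- match.arg(arms, c("ifr", "ifr_hypr", "kernel"), several.ok = TRUE)
  out <- list()
  dcf <- function(img) decay_correct_frames(img, setup$framing, setup$half_life_min)
  if (any(c("ifr", "ifr_hypr") %in% arms)) {
    ifr <- mlem_reconstruct(sampled, setup$sys, n_iter = n_iter)
    if ("ifr" %in% arms) out$ifr <- dcf(ifr)
    if ("ifr_hypr" %in% arms) out$ifr_hypr <- dcf(hypr_denoise(ifr))
  }
  if ("kernel" %in% arms) {
    comp <- composite_sinograms(sampled, 3L)
    feats <- mlem_reconstruct(comp, setup$sys, n_iter = composite_iter)
    roi <- roi_bounding_box(setup$masks$brain)
    K_s <- build_spatial_kernel(array(feats, dim = dim(feats)), kcfg, roi = roi)
    tf <- osem_feature_reconstruct(sampled, without_attenuation(setup$sys))
    K_t <- build_temporal_kernel(tf, kcfg)
    out$kernel <- dcf(kernel_em_reconstruct(sampled, setup$sys, K_s, K_t,
                                            n_iter = n_iter))
  }
  out
}

fit_region_params <- function(img, setup, regions = c("active", "rest"),
                              grid = basis_grid(), engine = NULL) {
  C_R <- region_tac_extract(img, setup$masks$reference)
  purrr::map_dfr(regions, function(r) {
    tac <- region_tac_extract(img, setup$masks[[r]])
    f <- fit_lpntpet(tac, C_R, grid,
                     basis = if (!is.null(engine))
                       build_basis_library(tac, grid, engine = engine))
    tibble::tibble(region = r, k2a = f$k2a, gamma = f$gamma, t_d = f$t_d,
                   t_p = f$t_p, R1 = f$R1, k2 = f$k2, sse = f$sse,
                   gamma_over_k2a = if (f$k2a > 0) f$gamma / f$k2a else NA_real_)
  })
}

#' Experiment configuration
#'
#' Defaults mirror the full study design: count budgets of 10, 40 and 80
#' million with 30 realizations each, a 120-200% activation sweep with 10
#' realizations at 40 million counts, three reconstruction arms, 300 EM
#' iterations. `scale` uniformly shrinks realizations and iterations for
#' desk-sized runs.
#'
#' @param budgets Total-count budgets.
#' @param n_realizations Realizations per count level.
#' @param activation_levels Activation peak levels (percent of baseline).
#' @param n_realizations_sweep Realizations per activation level.
#' @param sweep_budget Counts for the activation sweep.
#' @param arms Reconstruction arms.
#' @param n_iter EM iterations.
#' @param seed Base RNG seed.
#' @param pixel_level Also fit every pixel in the rest/active masks.
#' @param scale Desk-run scale factor in (0, 1]: multiplies realizations and
#'   iterations (rounded up).
#' @param checkpoint_dir Optional directory for per-realization checkpoints;
#'   interrupted runs resume from the files already present.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(budgets = c(1e7, 4e7, 8e7), n_realizations = 30L,
                              activation_levels = c(120, 140, 160, 180, 200),
                              n_realizations_sweep = 10L, sweep_budget = 4e7,
                              arms = c("ifr", "ifr_hypr", "kernel"),
                              n_iter = 300L, seed = 1L, pixel_level = FALSE,
                              scale = 1, checkpoint_dir = NULL) {
  if (length(arms) == 0) stop("need at least one reconstruction arm")
  n_realizations <- as.integer(ceiling(n_realizations * scale))
  n_realizations_sweep <- as.integer(ceiling(n_realizations_sweep * scale))
  n_iter <- as.integer(ceiling(n_iter * scale))
  if (n_realizations < 2) stop("need >= 2 realizations for COV statistics")
  structure(list(budgets = budgets, n_realizations = n_realizations,
                 activation_levels = activation_levels,
                 n_realizations_sweep = n_realizations_sweep,
                 sweep_budget = sweep_budget, arms = arms, n_iter = n_iter,
                 seed = as.integer(seed), pixel_level = pixel_level,
                 checkpoint_dir = checkpoint_dir),
            class = "experiment_config")
}

checkpointed <- function(dir, tag, compute) {
  if (is.null(dir)) return(compute())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(tag, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  res <- compute()
  saveRDS(res, path)
  res
}

#' Run the count-level Monte-Carlo experiment
#'
#' For each count budget and realization: Poisson-sample the expected
#' sinograms, reconstruct with every arm, extract regional (and optionally
#' pixel-level) TACs and fit the lp-ntPET model; a noise-free fit of the
#' truth image anchors the bias columns. Fully seeded: realization r at
#' budget index b uses seed `seed + 1000 * b + r`.
#'
#' @param cfg An [experiment_config()].
#' @param setup A [sim_setup()].
#' @param grid A [basis_grid()].
#' @return A list of class `sim_experiment` with `regional` (tibble of fits),
#'   `pixel` (tibble or NULL), `noisefree` (tibble), `summary` (regional
#'   summary table), `pixel_summary` (or NULL), `seeds`, `cfg`.
#' @export
run_simulation_experiment <- function(cfg = experiment_config(), setup = sim_setup(),
                                      grid = basis_grid(attr(setup$framing, "t_end_min"))) {
  eng <- basis_engine(setup$framing$mid_min, grid)
  nf_reg <- fit_region_params(setup$truth_dc, setup, grid = grid, engine = eng)
  seeds <- tibble::tibble()
  regional <- list(); pixel <- list()
  for (b in seq_along(cfg$budgets)) {
    budget <- cfg$budgets[b]
    expected <- forward_project_frames(setup$truth, setup$sys, setup$framing, budget)
    for (r in seq_len(cfg$n_realizations)) {
      seed <- cfg$seed + 1000L * b + r
      seeds <- dplyr::bind_rows(seeds, tibble::tibble(budget = budget,
                                                      realization = r, seed = seed))
      res <- checkpointed(cfg$checkpoint_dir, sprintf("b%d_r%03d", b, r), function() {
        sampled <- sample_poisson_counts(expected, seed = seed)
        imgs <- reconstruct_arms(sampled, setup, cfg$arms, n_iter = cfg$n_iter)
        reg <- purrr::map_dfr(imgs, fit_region_params, setup = setup,
                              grid = grid, engine = eng, .id = "arm")
        pix <- NULL
        if (cfg$pixel_level) {
          pix <- purrr::map_dfr(imgs, function(img) {
            C_R <- region_tac_extract(img, setup$masks$reference)
            purrr::map_dfr(c("active", "rest"), function(rg) {
              mp <- fit_parametric_maps(img, C_R, setup$masks[[rg]], grid)
              dplyr::mutate(mp$fits, region = rg)
            })
          }, .id = "arm")
        }
        list(reg = reg, pix = pix)
      })
      regional[[length(regional) + 1]] <-
        dplyr::mutate(res$reg, budget = budget, realization = r)
      if (!is.null(res$pix))
        pixel[[length(pixel) + 1]] <-
          dplyr::mutate(res$pix, budget = budget, realization = r)
    }
  }
  regional <- dplyr::bind_rows(regional)
  pixel <- if (length(pixel)) dplyr::bind_rows(pixel) else NULL
  out <- list(regional = regional, pixel = pixel, noisefree = nf_reg,
              seeds = seeds, cfg = cfg)
  out$summary <- summarize_cov_bias(
    tidyr::pivot_longer(dplyr::filter(regional, .data$region == "active"),
                        cols = c("k2a", "gamma", "t_d", "t_p"),
                        names_to = "param", values_to = "value"),
    noisefree_long(nf_reg))
  if (!is.null(pixel))
    out$pixel_summary <- summarize_cov_bias(
      tidyr::pivot_longer(dplyr::filter(pixel, .data$region == "active"),
                          cols = c("k2a", "gamma", "t_d", "t_p"),
                          names_to = "param", values_to = "value"),
      noisefree_long(nf_reg))
  class(out) <- "sim_experiment"
  out
}

noisefree_long <- function(nf_reg) {
  tidyr::pivot_longer(dplyr::filter(nf_reg, .data$region == "active"),
                      cols = c("k2a", "gamma", "t_d", "t_p"),
                      names_to = "param", values_to = "noisefree")[, c("param", "noisefree")]
}

#' Mean, COV and bias summary across realizations
#'
#' COV = 100 x SD / mean over the population (realizations, or pooled pixel
#' x realization values for pixel-level summaries); difference = 100 x
#' (mean - noise-free) / noise-free, undefined (NA) when the noise-free
#' value is zero.
#'
#' @param long Tibble with columns `arm` (or none), `param`, `value`, one
#'   row per realization (or pixel x realization).
#' @param noisefree Tibble with `param`, `noisefree`.
#' @return Summary tibble with `arm`, `param`, `mean`, `cov_pct`,
#'   `diff_pct`, `n`.
#' @export
summarize_cov_bias <- function(long, noisefree) {
  if (!"arm" %in% names(long)) long$arm <- "all"
  if (any(table(long$arm, long$param) < 2))
    stop("need >= 2 values per arm x parameter for COV")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$arm, .data$param),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(out, noisefree, by = "param")
  dplyr::mutate(out,
    cov_pct = 100 * .data$sd / .data$mean,
    diff_pct = ifelse(.data$noisefree == 0, NA_real_,
                      100 * (.data$mean - .data$noisefree) / .data$noisefree))
}

#' Run the activation-level sweep experiment
#'
#' Re-simulates the active region at each activation peak level, runs the
#' requested arms, and collects the relative activation magnitude gamma/k2a
#' of the rest and active regions per realization — the input of the paired
#' rest-versus-active significance test.
#'
#' @param cfg An [experiment_config()].
#' @param base_setup A [sim_setup()] at the baseline (its activation shape
#'   supplies onset/peak/skewness; its `gamma` is the 200%-level anchor).
#' @param grid A [basis_grid()].
#' @return List of class `sweep_experiment`: `ratios` tibble (level, arm,
#'   realization, rest/active gamma/k2a), `tests` tibble per arm x level.
#' @export
run_activation_sweep <- function(cfg = experiment_config(), base_setup = sim_setup(),
                                 grid = basis_grid(attr(base_setup$framing, "t_end_min"))) {
  eng <- basis_engine(base_setup$framing$mid_min, grid)
  rows <- list()
  for (li in seq_along(cfg$activation_levels)) {
    lev <- cfg$activation_levels[li]
    act <- base_setup$act
    act$gamma <- activation_gamma(lev, gamma_max = base_setup$act$gamma)
    setup <- level_setup(base_setup, act)
    expected <- forward_project_frames(setup$truth, setup$sys, setup$framing,
                                       cfg$sweep_budget)
    for (r in seq_len(cfg$n_realizations_sweep)) {
      seed <- cfg$seed + 100000L + 1000L * li + r
      res <- checkpointed(cfg$checkpoint_dir, sprintf("sweep_l%d_r%03d", li, r),
        function() {
          sampled <- sample_poisson_counts(expected, seed = seed)
          imgs <- reconstruct_arms(sampled, setup, cfg$arms, n_iter = cfg$n_iter)
          purrr::map_dfr(imgs, fit_region_params, setup = setup, grid = grid,
                         engine = eng, .id = "arm")
        })
      rows[[length(rows) + 1]] <- dplyr::mutate(res, level = lev, realization = r)
    }
  }
  ratios <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(
    ratios[, c("arm", "level", "realization", "region", "gamma_over_k2a")],
    names_from = "region", values_from = "gamma_over_k2a")
  tests <- dplyr::group_modify(
    dplyr::group_by(wide, .data$arm, .data$level),
    function(d, g) paired_activation_test(d$rest, d$active))
  structure(list(ratios = ratios, tests = dplyr::ungroup(tests), cfg = cfg),
            class = "sweep_experiment")
}

level_setup <- function(base_setup, act) {
  s <- base_setup
  s$act <- act
  active_dense <- simulate_ntpet_tac(s$kin, act, s$dense$reference)
  s$dense$active <- active_dense
  s$decayed$active <- frame_activity(active_dense, s$framing, s$half_life_min,
                                     decay_correct = FALSE)
  s$dc$active <- frame_activity(active_dense, s$framing, s$half_life_min,
                                decay_correct = TRUE)
  s$truth <- region_dynamic_image(s$labels, s$decayed, s$framing,
                                  decay_corrected = FALSE)
  s$truth_dc <- region_dynamic_image(s$labels, s$dc, s$framing,
                                     decay_corrected = TRUE)
  s
}

#' Paired rest-versus-active significance test
#'
#' Two-sided paired t-test on per-realization gamma/k2a ratios. When the
#' paired differences have zero variance the p-value is undefined and the
#' result is flagged.
#'
#' @param rest,active Equal-length numeric vectors paired by realization.
#' @return One-row tibble: `difference` (mean active - rest), `t`, `p`,
#'   `n`, `zero_variance`.
#' @export
paired_activation_test <- function(rest, active) {
  stopifnot(length(rest) == length(active), length(rest) >= 2)
  d <- active - rest
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1))
    return(tibble::tibble(difference = mean(d), t = NA_real_, p = NA_real_,
                          n = length(d), zero_variance = TRUE))
  tt <- stats::t.test(active, rest, paired = TRUE)
  tibble::tibble(difference = mean(d), t = unname(tt$statistic),
                 p = tt$p.value, n = length(d), zero_variance = FALSE)
}

#' Write experiment outputs to a directory
#'
#' Writes the summary and per-realization CSV tables, a JSON run manifest
#' (configuration and every seed used), and a plain-text log.
#'
#' @param results A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(results, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  utils::write.csv(results$summary, file.path(dir, "summary_regional.csv"),
                   row.names = FALSE)
  utils::write.csv(results$regional, file.path(dir, "fits_regional.csv"),
                   row.names = FALSE)
  if (!is.null(results$pixel)) {
    utils::write.csv(results$pixel_summary, file.path(dir, "summary_pixel.csv"),
                     row.names = FALSE)
    utils::write.csv(results$pixel, file.path(dir, "fits_pixel.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(results$noisefree, file.path(dir, "fits_noisefree.csv"),
                   row.names = FALSE)
  cfg <- results$cfg
  jsonlite::write_json(list(
    config = cfg[setdiff(names(cfg), "checkpoint_dir")],
    seeds = results$seeds,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("petkern"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(paste("petkern run", format(Sys.time())),
               paste("realizations:", cfg$n_realizations),
               paste("budgets:", paste(cfg$budgets, collapse = ", ")),
               paste("arms:", paste(cfg$arms, collapse = ", "))),
             file.path(dir, "run.log"))
  invisible(dir)
}
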