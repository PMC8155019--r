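#' Configuration of a synthetic experiment
#'
#' Collects every constant needed to generate a complete synthetic
#' experiment with the statistical structure the analysis pipeline assumes.
#' Defaults reproduce the published experimental scale: 20 cells imaged
#' for 200 min at 1-min resolution, shot-noise multipliers
#' (1.98, 1.42, 0.41), a 130-site nascent mRNA count sample, and channel
#' centroid offsets targeting median pairwise separations of
#' (181, 148, 93) nm for (ctd-mrna, ser5ph-mrna, ctd-ser5ph) with 30 nm
#' per-frame localization noise.
#'
#' @param params True kinetic rates ([rate_params()]).
#' @param variant Model variant.
#' @param n_cells,duration,dt Imaging scale (cells, minutes, sampling
#'   interval).
#' @param shot_noise Channel shot-noise SD multipliers.
#' @param separations Target pairwise centroid separations \[nm\], named
#'   `ctd-mrna`, `ser5ph-mrna`, `ctd-ser5ph` (must satisfy the triangle
#'   inequality).
#' @param loc_noise_nm Per-frame, per-axis localization noise SD \[nm\].
#' @param n_mrna_sites Size of the nascent mRNA count sample.
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(params = rate_params(), variant = "base",
                              n_cells = 20, duration = 200, dt = 1,
                              shot_noise = c(ctd = 1.98, ser5ph = 1.42,
                                             mrna = 0.41),
                              separations = c("ctd-mrna" = 181,
                                              "ser5ph-mrna" = 148,
                                              "ctd-ser5ph" = 93),
                              loc_noise_nm = 30, n_mrna_sites = 130,
                              seed = 1) {
  stopifnot(inherits(params, "rate_params"), n_cells >= 1, duration > 0,
            dt > 0, n_mrna_sites >= 30)
  s <- sort(unname(separations), decreasing = TRUE)
  if (s[1] > s[2] + s[3])
    stop("separations violate the triangle inequality", call. = FALSE)
  structure(list(params = params, variant = variant, n_cells = n_cells,
                 duration = duration, dt = dt,
                 shot_noise = .match_channels(shot_noise),
                 separations = separations, loc_noise_nm = loc_noise_nm,
                 n_mrna_sites = n_mrna_sites, seed = seed),
            class = "experiment_config")
}

#' Generate synthetic intensity traces
#'
#' Runs the stochastic simulator at the configured scale and returns the
#' trace table together with the ground-truth parameters and seed (as
#' attributes), so recovery studies can close the loop.
#'
#' @param config An [experiment_config()].
#' @return A `trace_set` tibble (see [sample_traces()]) with attribute
#'   `ground_truth` (list of true parameters, variant and seed).
#' @export
make_traces <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  model <- build_model(config$variant, config$params)
  tr <- sample_traces(model, n_cells = config$n_cells,
                      duration = config$duration, dt = config$dt,
                      shot_noise = config$shot_noise, seed = config$seed)
  attr(tr, "ground_truth") <- list(params = config$params,
                                   variant = config$variant,
                                   seed = config$seed)
  tr
}

#' Generate a synthetic nascent mRNA count sample
#'
#' Draws steady-state values of the mRNA observable from long stochastic
#' simulations (spaced far apart relative to the correlation time, so
#' draws are effectively independent) rather than from any parametric
#' distribution: the count distribution's shape is a model prediction, not
#' an assumption.
#'
#' @inheritParams make_traces
#' @param spacing Time between retained draws \[min\].
#' @return List of class `mrna_counts`: `counts` (integer vector),
#'   `summary` (an [mrna_summary()]), and the seed.
#' @export
make_mrna_counts <- function(config = experiment_config(), spacing = 50) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  model <- build_model(config$variant, config$params)
  n <- config$n_mrna_sites
  path <- ssa_run(model, t_end = n * spacing, dt = spacing)
  cm <- model$c_obs["mrna", ]
  counts <- drop(as.matrix(path[model$state_names]) %*% cm)[-1]
  counts <- counts[seq_len(n)]
  s2 <- var(counts)
  eps <- .Machine$double.eps  # keep SEMs positive for degenerate samples
  summ <- mrna_summary(mean = mean(counts), var = s2,
                       sem_mean = max(sd(counts) / sqrt(n), eps),
                       sem_var = max(s2 * sqrt(2 / (n - 1)), eps), n = n)
  structure(list(counts = counts, summary = summ, seed = config$seed),
            class = "mrna_counts")
}

# place three points in the plane with the configured pairwise distances
.triangle_offsets <- function(separations) {
  d_cm <- separations[["ctd-mrna"]]
  d_sm <- separations[["ser5ph-mrna"]]
  d_cs <- separations[["ctd-ser5ph"]]
  # mrna at origin, ctd on the x axis, ser5ph by trilateration
  sx <- if (d_cm > 0) (d_sm^2 + d_cm^2 - d_cs^2) / (2 * d_cm) else 0
  sy2 <- d_sm^2 - sx^2
  sy <- sqrt(max(sy2, 0))
  list(mrna = c(0, 0), ctd = c(d_cm, 0), ser5ph = c(sx, sy))
}

#' Generate synthetic centroid position tracks
#'
#' The mRNA centroid performs a bounded (mean-reverting) random walk; the
#' CTD and Ser5ph centroids sit at fixed offsets chosen to satisfy the
#' configured pairwise separations, and every channel receives iid
#' per-frame localization noise. After the 50-frame moving average used by
#' [pairwise_distances()], the recovered median separations match the
#' configured targets.
#'
#' @inheritParams make_traces
#' @param walk_sd Per-frame step SD of the anchor random walk \[nm\].
#' @param revert Mean-reversion factor of the anchor walk (0-1).
#' @return Long tibble `cell_id`, `time`, `channel`, `x_nm`, `y_nm`.
#' @export
make_positions <- function(config = experiment_config(), walk_sd = 15,
                           revert = 0.95) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  off <- .triangle_offsets(config$separations)
  n_t <- length(seq(0, config$duration, by = config$dt))
  purrr::map_dfr(seq_len(config$n_cells), function(i) {
    anchor <- matrix(0, n_t, 2)
    for (t in 2:n_t)
      anchor[t, ] <- revert * anchor[t - 1, ] + rnorm(2, sd = walk_sd)
    # random rigid rotation per cell so offsets have no preferred axis
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    purrr::map_dfr(.channels, function(ch) {
      pos <- anchor +
        matrix(rep(drop(R %*% off[[ch]]), each = n_t), n_t, 2) +
        matrix(rnorm(2 * n_t, sd = config$loc_noise_nm), n_t, 2)
      tibble(cell_id = sprintf("cell_%02d", i),
             time = seq(0, config$duration, by = config$dt),
             channel = ch, x_nm = pos[, 1], y_nm = pos[, 2])
    })
  })
}

#' Generate a synthetic inhibitor run
#'
#' Wraps [perturb()] at the configured experimental scale, stamping the
#' drug time and mode on the result.
#'
#' @inheritParams make_traces
#' @param mode Perturbation mode (see [perturb()]).
#' @param t_drug Drug addition time \[min\].
#' @param duration Total duration \[min\].
#' @param reduction_fraction Fractional `k_c` reduction in `*_reduce_kc`
#'   modes.
#' @return A `trace_set` tibble with attributes `t_drug` and `mode`.
#' @export
make_inhibitor_run <- function(config = experiment_config(), mode,
                               t_drug = 5, duration = t_drug + 30,
                               reduction_fraction = 0) {
  stopifnot(inherits(config, "experiment_config"))
  if (t_drug <= 0 || t_drug > duration)
    stop("`t_drug` outside the simulation window", call. = FALSE)
  model <- build_model(config$variant, config$params)
  perturb(model, mode = mode, t_drug = t_drug,
          reduction_fraction = reduction_fraction,
          n_cells = config$n_cells, duration = duration, dt = config$dt,
          shot_noise = config$shot_noise, seed = config$seed)
}
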