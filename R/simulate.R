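#' Exact stochastic simulation of a bursting model
#'
#' Runs the Gillespie direct method on a [build_model()] specification and
#' samples the species counts on a uniform time grid. A burn-in period of
#' ten times the slowest kinetic time scale (by default) is simulated and
#' discarded before `t = 0`, so the returned path is a steady-state sample.
#'
#' @param model A [build_model()] specification.
#' @param t_end Simulated duration after burn-in \[min\].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param dt Sampling interval \[min\].
#' @param burn_in Burn-in duration \[min\], or `"auto"` for
#'   `10 / min(positive rates)`.
#' @param record_events If `TRUE`, the event log (times and reaction
#'   indices) is attached as attributes `event_times` / `event_reaction`.
#' @param x0 Initial state (defaults to all zeros).
#' @param max_count Abort threshold on the total species count, guarding
#'   against unstable parameterizations.
#' @return A tibble with column `time` and one column per species.
#' @examples
#' ssa_run(build_model("base"), t_end = 50, seed = 1)
#' @export
ssa_run <- function(model, t_end, seed = NULL, dt = 1, burn_in = "auto",
                    record_events = FALSE, x0 = NULL, max_count = 1e7) {
  stopifnot(inherits(model, "model_spec"), t_end > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (identical(burn_in, "auto")) burn_in <- .auto_burn_in(model)
  if (is.null(x0)) x0 <- rep(0, model$n_species)
  grid <- seq(0, t_end, by = dt)
  res <- ssa_core(model$S, model$W1, model$w0, as.numeric(x0),
                  -burn_in, t_end, grid, record_events, max_count)
  out <- as_tibble(as.data.frame(res$states))
  names(out) <- model$state_names
  out <- dplyr::bind_cols(tibble(time = grid), out)
  if (record_events) {
    keep <- res$event_times >= 0
    attr(out, "event_times") <- res$event_times[keep]
    attr(out, "event_reaction") <- res$event_reaction[keep]
  }
  out
}

.auto_burn_in <- function(model) {
  p <- model$params
  rates <- c(p$omega, p$k_off, p$k_ab, p$k_esc, p$k_c,
             unlist(p$variant_extras))
  rates <- rates[rates > 0]
  if (!length(rates)) return(0)
  10 / min(rates)
}

#' Simulate multi-channel intensity traces with shot noise
#'
#' Samples `n_cells` independent steady-state trajectories, maps species to
#' the CTD / Ser5ph / mRNA observables through the model's observation
#' matrix, adds channel-specific shot noise (iid Gaussian with standard
#' deviation equal to `shot_noise[ch]` times the ensemble standard deviation
#' of the noiseless channel), and normalizes each channel by its pooled 95th
#' percentile, mirroring how measured intensities are scaled.
#'
#' @inheritParams ssa_run
#' @param n_cells Number of cells (independent trajectories).
#' @param duration Trace duration per cell \[min\].
#' @param shot_noise Named multipliers for channels `ctd`, `ser5ph`, `mrna`.
#'   The defaults are the experimentally measured values 1.98, 1.42, 0.41.
#' @param normalize Divide each channel by its pooled 95th percentile.
#' @return A long tibble (`cell_id`, `time`, `channel`, `intensity`) of
#'   class `trace_set`, with attributes `params`, `variant`, `shot_noise`,
#'   `noiseless_sd`, `scale_95`, `dt` and `seed`.
#' @examples
#' tr <- sample_traces(build_model("base"), n_cells = 2, duration = 50, seed = 1)
#' @export
sample_traces <- function(model, n_cells = 20, duration = 200, dt = 1,
                          shot_noise = c(ctd = 1.98, ser5ph = 1.42,
                                         mrna = 0.41),
                          seed = NULL, burn_in = "auto", normalize = TRUE) {
  stopifnot(inherits(model, "model_spec"), n_cells >= 1, dt > 0,
            all(shot_noise >= 0))
  shot_noise <- .match_channels(shot_noise)
  if (!is.null(seed)) set.seed(seed)
  if (identical(burn_in, "auto")) burn_in <- .auto_burn_in(model)
  grid <- seq(0, duration, by = dt)
  cells <- purrr::map(seq_len(n_cells), function(i) {
    path <- ssa_run(model, t_end = duration, dt = dt, burn_in = burn_in,
                    seed = NULL)
    x <- as.matrix(path[model$state_names])
    x %*% t(model$c_obs)  # columns ctd, ser5ph, mrna
  })
  noiseless_sd <- vapply(seq_along(.channels), function(j) {
    sd(unlist(lapply(cells, function(m) m[, j])))
  }, numeric(1))
  names(noiseless_sd) <- .channels
  bad <- noiseless_sd == 0 & shot_noise > 0
  if (any(bad))
    stop("zero-variance channel(s) with nonzero shot noise: ",
         paste(.channels[bad], collapse = ", "), call. = FALSE)
  noisy <- purrr::map(cells, function(m) {
    m + matrix(rnorm(length(m), sd = rep(shot_noise * noiseless_sd,
                                         each = nrow(m))),
               nrow(m), 3)
  })
  scale_95 <- vapply(seq_along(.channels), function(j) {
    unname(quantile(unlist(lapply(noisy, function(m) m[, j])), 0.95))
  }, numeric(1))
  names(scale_95) <- .channels
  if (normalize) {
    if (any(scale_95 <= 0))
      stop("non-positive 95th percentile; cannot normalize", call. = FALSE)
    noisy <- purrr::map(noisy, function(m) sweep(m, 2, scale_95, "/"))
  }
  out <- purrr::imap_dfr(noisy, function(m, i) {
    tibble(cell_id = sprintf("cell_%02d", i),
           time = rep(grid, 3),
           channel = rep(.channels, each = length(grid)),
           intensity = as.vector(m))
  })
  structure(out, class = c("trace_set", class(out)),
            params = model$params, variant = model$variant,
            shot_noise = shot_noise, noiseless_sd = noiseless_sd,
            scale_95 = scale_95, dt = dt, seed = seed)
}

.match_channels <- function(x) {
  if (is.null(names(x))) names(x) <- .channels
  stopifnot(all(.channels %in% names(x)))
  x[.channels]
}

#' Default gene geometry for simulated ChIP
#'
#' The elongation rate (4.1 kb/min) and 3'-end processing rate (0.27/min)
#' are taken from independent measurements at this locus; the gene length
#' defaults to the value that makes elongation plus processing time equal
#' the fitted completion time `1/k_c`.
#'
#' @param k_c Completion rate used to derive the default gene length.
#' @param elongation_kb_per_min Elongation rate \[kb/min\].
#' @param k_processing 3'-end processing rate \[1/min\].
#' @param gene_length_kb Gene length \[kb\].
#' @return A list with the three geometry fields.
#' @export
chip_geometry <- function(k_c = 1 / 5.032, elongation_kb_per_min = 4.1,
                          k_processing = 0.27,
                          gene_length_kb = elongation_kb_per_min *
                            (1 / k_c - 1 / k_processing)) {
  stopifnot(gene_length_kb > 0, elongation_kb_per_min > 0, k_processing > 0)
  list(gene_length_kb = gene_length_kb,
       elongation_kb_per_min = elongation_kb_per_min,
       k_processing = k_processing)
}

#' Simulated ChIP occupancy profile along the gene
#'
#' Maps the stochastic simulation onto 10 equal gene-position bins
#' (promoter to 3' end). Cluster RNAP2 occupies bin 1; each polymerase
#' escaping in the simulation traverses the gene deterministically at the
#' elongation rate and then dwells in the 3' bin for an exponential
#' processing time (rate `k_processing`). When the geometry is consistent
#' with the model (`1/k_c` equals traversal plus processing time, checked
#' with a 5% tolerance), the mean occupancy summed over bins equals the
#' mean total RNAP2 at the site. Optional occupancy weighting averages
#' frames weighted by their total RNAP2 content, emulating the enrichment
#' bias of ChIP toward highly occupied genes.
#'
#' @inheritParams ssa_run
#' @param geometry A [chip_geometry()] list.
#' @param n_cells Number of independent simulated cells.
#' @param duration Sampled duration per cell \[min\].
#' @param weighting `"none"` or `"by_occupancy"`.
#' @param strict Error (rather than warn) when `1/k_c` differs from
#'   elongation + processing time by more than 5%.
#' @return A tibble `bin`, `form` (`ctd`, `ser5ph`), `occupancy` of class
#'   `chip_profile`, with the geometry attached as an attribute.
#' @export
simulate_chip <- function(model, geometry = chip_geometry(model$params$k_c),
                          n_cells = 20, duration = 200, dt = 0.1,
                          seed = NULL, weighting = c("none", "by_occupancy"),
                          strict = FALSE) {
  stopifnot(inherits(model, "model_spec"))
  weighting <- match.arg(weighting)
  if (!is.null(seed)) set.seed(seed)
  tau_pos <- geometry$gene_length_kb / geometry$elongation_kb_per_min +
    1 / geometry$k_processing
  tau_c <- 1 / model$params$k_c
  if (abs(tau_pos - tau_c) / tau_c > 0.05) {
    msg <- sprintf(
      "geometry traversal+processing time (%.2f min) differs from 1/k_c (%.2f min) by > 5%%",
      tau_pos, tau_c)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  n_bins <- 10L
  bin_width <- geometry$gene_length_kb / n_bins
  v <- geometry$elongation_kb_per_min
  esc_rx <- model$reactions[["escape"]]
  cluster_states <- which(abs(model$c_obs["ctd", ] -
                              model$c_obs["mrna", ]) > 0)
  occ_sum <- numeric(n_bins)
  wt_sum <- 0
  burn <- .auto_burn_in(model)
  grid <- seq(0, duration, by = dt)
  trav <- geometry$gene_length_kb / v
  for (i in seq_len(n_cells)) {
    # events are kept from the start of burn-in so polymerases already on
    # the gene at t = 0 carry their true escape times
    res <- ssa_core(model$S, model$W1, model$w0,
                    numeric(model$n_species), -burn, duration, grid,
                    TRUE, 1e7)
    path <- as_tibble(as.data.frame(res$states))
    names(path) <- model$state_names
    path$time <- grid
    ev_t <- res$event_times
    ev_r <- res$event_reaction
    t_esc <- ev_t[ev_r == esc_rx]
    # deterministic traversal then an exponential 3'-processing dwell
    t_done <- t_esc + trav + stats::rexp(length(t_esc),
                                         geometry$k_processing)
    cl <- rowSums(as.matrix(path[model$state_names])[, cluster_states,
                                                     drop = FALSE])
    for (s in seq_along(path$time)) {
      tt <- path$time[s]
      onb <- numeric(n_bins)
      onb[1] <- cl[s]
      act <- which(t_esc <= tt & t_done > tt)
      if (length(act)) {
        pos <- pmin(v * (tt - t_esc[act]), geometry$gene_length_kb)
        b <- pmin(floor(pos / bin_width) + 1L, n_bins)
        tb <- tabulate(b, n_bins)
        onb <- onb + tb
      }
      w <- if (weighting == "by_occupancy") sum(onb) else 1
      occ_sum <- occ_sum + w * onb
      wt_sum <- wt_sum + w
    }
  }
  prof <- occ_sum / wt_sum
  out <- tibble(bin = rep(seq_len(n_bins), 2),
                form = rep(c("ctd", "ser5ph"), each = n_bins),
                occupancy = rep(prof, 2))
  structure(out, class = c("chip_profile", class(out)),
            geometry = geometry, weighting = weighting, n_cells = n_cells)
}

.perturb_modes <- c("block_burst", "block_escape",
                    "block_escape_reduce_kc", "block_burst_reduce_kc")

.perturbed_params <- function(params, mode, reduction_fraction) {
  p <- params
  if (mode %in% c("block_burst", "block_burst_reduce_kc")) p$omega <- 0
  if (mode %in% c("block_escape", "block_escape_reduce_kc")) p$k_esc <- 0
  if (mode %in% c("block_escape_reduce_kc", "block_burst_reduce_kc"))
    p$k_c <- (1 - reduction_fraction) * p$k_c
  class(p) <- "rate_params"
  p
}

#' Simulate an inhibitor perturbation
#'
#' Simulates an ensemble of cells at steady state, switches one or more
#' rates off (or down) at `t_drug`, and returns per-cell channel traces.
#' Modes: `block_burst` sets the burst frequency to zero (initiation
#' inhibition), `block_escape` sets the promoter escape rate to zero, and
#' the `*_reduce_kc` modes additionally reduce the completion rate by
#' `reduction_fraction`.
#'
#' @inheritParams sample_traces
#' @param mode One of `r paste0('"', .perturb_modes, '"', collapse = ", ")`.
#' @param t_drug Drug addition time within `(0, duration)` \[min\].
#' @param reduction_fraction Fractional reduction of `k_c` in the
#'   `*_reduce_kc` modes (0.3 reproduces the "reduce by 30%" scenario).
#' @return A `trace_set` tibble as in [sample_traces()] (shot noise defaults
#'   to zero here), with attribute `t_drug`.
#' @seealso [perturbation_response()] for ensemble means.
#' @export
perturb <- function(model, mode, t_drug, reduction_fraction = 0,
                    n_cells = 20, duration = t_drug + 30, dt = 1,
                    shot_noise = c(ctd = 0, ser5ph = 0, mrna = 0),
                    seed = NULL, normalize = TRUE) {
  stopifnot(inherits(model, "model_spec"))
  if (!mode %in% .perturb_modes)
    stop("unknown perturbation mode: ", mode, call. = FALSE)
  if (t_drug <= 0 || t_drug > duration)
    stop("`t_drug` must lie inside the simulation window", call. = FALSE)
  shot_noise <- .match_channels(shot_noise)
  if (!is.null(seed)) set.seed(seed)
  post <- build_model(model$variant,
                      .perturbed_params(model$params, mode,
                                        reduction_fraction))
  burn <- .auto_burn_in(model)
  grid <- seq(0, duration, by = dt)
  pre_grid <- grid[grid <= t_drug]
  post_grid <- grid[grid > t_drug]
  cells <- purrr::map(seq_len(n_cells), function(i) {
    r1 <- ssa_core(model$S, model$W1, model$w0,
                   numeric(model$n_species), -burn, t_drug,
                   c(pre_grid, t_drug), FALSE, 1e7)
    x_at_drug <- r1$states[nrow(r1$states), ]
    pre <- r1$states[seq_len(length(pre_grid)), , drop = FALSE]
    y_pre <- pre %*% t(model$c_obs)
    if (length(post_grid)) {
      r2 <- ssa_core(post$S, post$W1, post$w0, x_at_drug,
                     t_drug, max(post_grid), post_grid, FALSE, 1e7)
      y_post <- r2$states %*% t(post$c_obs)
      rbind(y_pre, y_post)
    } else y_pre
  })
  noiseless_sd <- vapply(seq_along(.channels), function(j)
    sd(unlist(lapply(cells, function(m) m[, j]))), numeric(1))
  names(noiseless_sd) <- .channels
  noisy <- purrr::map(cells, function(m) {
    m + matrix(rnorm(length(m), sd = rep(shot_noise * noiseless_sd,
                                         each = nrow(m))), nrow(m), 3)
  })
  scale_95 <- vapply(seq_along(.channels), function(j)
    unname(quantile(unlist(lapply(noisy, function(m) m[, j])), 0.95)),
    numeric(1))
  names(scale_95) <- .channels
  if (normalize && all(scale_95 > 0))
    noisy <- purrr::map(noisy, function(m) sweep(m, 2, scale_95, "/"))
  out <- purrr::imap_dfr(noisy, function(m, i) {
    tibble(cell_id = sprintf("cell_%02d", i),
           time = rep(grid, 3),
           channel = rep(.channels, each = length(grid)),
           intensity = as.vector(m))
  })
  structure(out, class = c("trace_set", class(out)),
            params = model$params, variant = model$variant,
            shot_noise = shot_noise, t_drug = t_drug, mode = mode,
            dt = dt, seed = seed)
}

#' Ensemble mean response of a perturbation
#'
#' @param traces A `trace_set`, typically from [perturb()].
#' @return Tibble `time`, `channel`, `mean`, `sem`.
#' @export
perturbation_response <- function(traces) {
  traces |>
    dplyr::group_by(.data$time, .data$channel) |>
    dplyr::summarise(sem = sd(.data$intensity) /
                       sqrt(dplyr::n()),
                     mean = mean(.data$intensity), .groups = "drop") |>
    dplyr::select("time", "channel", "mean", "sem")
}

#' Simulation-based uncertainty of correlation dwell times
#'
#' Repeats the full experiment-plus-analysis loop: each replicate simulates
#' a dataset with [sample_traces()], estimates correlation functions with
#' [correlate_traces()], and extracts the per-channel dwell time (lag at
#' which the normalized autocovariance falls below 20%). Returns the spread
#' across replicates.
#'
#' @inheritParams sample_traces
#' @param n_datasets Number of replicate datasets.
#' @param max_lag Maximum lag used in the correlation analysis \[min\].
#' @return Tibble `channel`, `mean_dwell`, `sd_dwell`, `n_censored`;
#'   channels where more than half the replicates never cross the threshold
#'   are flagged in `censored_flag`.
#' @export
dwell_uncertainty <- function(model, n_datasets = 400, n_cells = 20,
                              duration = 200, dt = 1,
                              shot_noise = c(ctd = 1.98, ser5ph = 1.42,
                                             mrna = 0.41),
                              max_lag = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- purrr::map_dfr(seq_len(n_datasets), function(i) {
    tr <- sample_traces(model, n_cells = n_cells, duration = duration,
                        dt = dt, shot_noise = shot_noise)
    cs <- correlate_traces(tr, max_lag = max_lag)
    dw <- dwell_times(cs)
    dw$dataset <- i
    dw
  })
  res |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      mean_dwell = mean(.data$dwell[!.data$censored]),
      sd_dwell = sd(.data$dwell[!.data$censored]),
      n_censored = sum(.data$censored), .groups = "drop") |>
    dplyr::mutate(censored_flag = .data$n_censored > n_datasets / 2)
}
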