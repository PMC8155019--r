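#' Background-subtracted, smoothed raw intensity
#'
#' Computes the per-frame transcription-site intensity as the background
#' ring mean subtracted from the TS-mask mean, smoothed with a centred
#' three-point moving average (edge windows shrink to the available
#' frames). The normalized variant divides by a supplied scale, typically
#' the average 95th-percentile TS intensity across cells; normalized traces
#' may legitimately dip below zero when background exceeds the site.
#'
#' @param i_ts,i_bg Per-frame TS-mask and background-ring mean intensities.
#' @param scale Optional normalization divisor.
#' @return Numeric vector of smoothed (optionally normalized) intensities.
#' @examples
#' raw_intensity(c(1, 4, 7, 10), rep(0, 4))  # 2.5 4 7 8.5
#' @export
raw_intensity <- function(i_ts, i_bg, scale = NULL) {
  stopifnot(length(i_ts) == length(i_bg))
  if (length(i_ts) < 3) stop("need at least 3 frames", call. = FALSE)
  out <- zoo::rollapply(i_ts - i_bg, 3, mean, partial = TRUE)
  if (!is.null(scale)) out <- out / scale
  out
}

# local minima: strictly lower than the previous value and lower than the
# next distinct value; plateaus contribute their leftmost point
.local_minima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer())
  idx <- which(r$values[2:(k - 1)] < r$values[1:(k - 2)] &
                 r$values[2:(k - 1)] < r$values[3:k]) + 1L
  starts[idx]
}

#' Detect mRNA minima events in normalized traces
#'
#' Finds local minima of each cell's mRNA channel that fall at or below
#' `threshold` (normalized intensity), and extracts aligned windows of
#' `half_window` samples on each side of the event for all three channels.
#' Events closer than `half_window` samples to a trace end are dropped.
#'
#' @param traces Long trace tibble (`cell_id`, `time`, `channel`,
#'   `intensity`) with a normalized `mrna` channel.
#' @param threshold Event threshold on the normalized mRNA intensity.
#' @param half_window Samples kept on each side of the minimum (default 7,
#'   i.e. a 15-point window at 1-min sampling).
#' @return Tibble `cell_id`, `event_time`, `offset` (samples relative to
#'   the minimum), `channel`, `intensity`; zero rows when no events.
#' @export
find_minima_events <- function(traces, threshold = 0.20, half_window = 7L) {
  cells <- split(traces, traces$cell_id)
  purrr::map_dfr(cells, function(cell) {
    m <- .trace_matrix(cell)
    tgrid <- sort(unique(cell$time))
    x <- m[, "mrna"]
    n <- length(x)
    cand <- .local_minima(x)
    cand <- cand[x[cand] <= threshold]
    cand <- cand[cand > half_window & cand <= n - half_window]
    purrr::map_dfr(cand, function(i) {
      idx <- (i - half_window):(i + half_window)
      tibble(cell_id = cell$cell_id[1],
             event_time = tgrid[i],
             offset = rep(idx - i, 3),
             channel = rep(.channels, each = length(idx)),
             intensity = as.vector(m[idx, .channels]))
    })
  })
}

#' Align minima events and fit channel-averaged valleys
#'
#' Averages the aligned event windows per channel, fits an inverted
#' Gaussian (baseline minus negative-amplitude bump) by least squares, and
#' reports the fitted minimum time, its standard error, and the depth. A
#' control analysis repeats the windowing at random time points of the same
#' traces and compares the observed window minima against the control by a
#' two-sided Mann-Whitney test.
#'
#' @param events Event table from [find_minima_events()].
#' @param traces The traces the events came from (used for the
#'   random-timepoint control; omit to skip the control).
#' @param n_control Number of random control time points.
#' @param dt Sampling interval \[min\] (converts sample offsets to time).
#' @param seed Seed for the control draw.
#' @return Tibble `channel`, `min_time`, `min_time_se`, `depth`,
#'   `baseline`, `converged`, and (when `traces` given) `p_control` from
#'   the Mann-Whitney comparison of window depths vs. control.
#' @export
align_and_fit_minima <- function(events, traces = NULL, n_control = 200,
                                 dt = 1, seed = 1) {
  n_events <- length(unique(paste(events$cell_id, events$event_time)))
  if (n_events < 5) stop("need at least 5 events", call. = FALSE)
  avg <- events |>
    dplyr::group_by(.data$channel, .data$offset) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
  half_window <- max(events$offset)

  ctrl <- NULL
  if (!is.null(traces)) {
    set.seed(seed)
    cells <- split(traces, traces$cell_id)
    ctrl <- purrr::map_dfr(seq_len(n_control), function(i) {
      cell <- cells[[sample(length(cells), 1)]]
      m <- .trace_matrix(cell)
      n <- nrow(m)
      c0 <- sample((half_window + 1):(n - half_window), 1)
      idx <- (c0 - half_window):(c0 + half_window)
      tibble(control = i,
             offset = rep(idx - c0, 3),
             channel = rep(.channels, each = length(idx)),
             intensity = as.vector(m[idx, .channels]))
    })
  }

  purrr::map_dfr(.channels, function(ch) {
    d <- avg[avg$channel == ch, ]
    tt <- d$offset * dt
    y <- d$intensity
    b0 <- max(y); a0 <- max(b0 - min(y), 1e-6)
    try_fit <- function(t0_start) tryCatch(
      minpack.lm::nlsLM(
        y ~ b - a * exp(-(tt - t0)^2 / (2 * w^2)),
        start = list(b = b0, a = a0, t0 = t0_start,
                     w = max(2 * dt, diff(range(tt)) / 6)),
        lower = c(-Inf, 0, min(tt), dt / 4),
        upper = c(Inf, Inf, max(tt), diff(range(tt))),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    fit <- try_fit(tt[which.min(y)])
    # a perfectly symmetric valley makes the location gradient vanish at
    # the start; a small nudge restores a usable gradient
    if (is.null(fit)) fit <- try_fit(tt[which.min(y)] + 0.3 * dt)
    if (is.null(fit)) {
      out <- tibble(channel = ch, min_time = NA_real_,
                    min_time_se = NA_real_, depth = NA_real_,
                    baseline = NA_real_, converged = FALSE)
    } else {
      cf <- coef(fit)
      se <- tryCatch(sqrt(diag(vcov(fit)))[["t0"]],
                     error = function(e) NA_real_)
      out <- tibble(channel = ch, min_time = cf[["t0"]],
                    min_time_se = se, depth = cf[["a"]],
                    baseline = cf[["b"]], converged = TRUE)
    }
    if (!is.null(ctrl)) {
      ev_min <- events |>
        dplyr::filter(.data$channel == ch) |>
        dplyr::group_by(.data$cell_id, .data$event_time) |>
        dplyr::summarise(m = min(.data$intensity), .groups = "drop")
      ct_min <- ctrl |>
        dplyr::filter(.data$channel == ch) |>
        dplyr::group_by(.data$control) |>
        dplyr::summarise(m = min(.data$intensity), .groups = "drop")
      out$p_control <- wilcox.test(ev_min$m, ct_min$m, exact = FALSE,
                                   correct = TRUE)$p.value
    }
    out
  })
}

#' Pairwise centroid distance statistics
#'
#' Smooths each channel's centroid track with a moving average (default 50
#' frames, edge windows shrunken), samples the smoothed positions every
#' `sample_every` minutes, and computes the Euclidean distances between the
#' three channel pairs, pooled over cells. Reports medians, quartiles and
#' pairwise Mann-Whitney comparisons between the distance distributions.
#'
#' @param positions Long tibble `cell_id`, `time`, `channel`, `x_nm`,
#'   `y_nm` on a common frame grid per cell.
#' @param window Moving-average window in frames.
#' @param sample_every Sampling interval of smoothed positions \[min\].
#' @return List with `distances` (tibble `pair`, `cell_id`, `time`,
#'   `distance`), `summary` (tibble `pair`, `median`, `q25`, `q75`, `n`)
#'   and `tests` (tibble of pairwise Mann-Whitney p-values).
#' @export
pairwise_distances <- function(positions, window = 50L, sample_every = 10) {
  stopifnot(all(c("cell_id", "time", "channel", "x_nm", "y_nm") %in%
                  names(positions)))
  cells <- split(positions, positions$cell_id)
  prs <- list(c("ctd", "mrna"), c("ser5ph", "mrna"), c("ctd", "ser5ph"))
  dists <- purrr::map_dfr(cells, function(cell) {
    tgrid <- sort(unique(cell$time))
    if (length(tgrid) < window)
      stop("track shorter than the smoothing window", call. = FALSE)
    sm <- purrr::map(.channels, function(ch) {
      d <- dplyr::arrange(cell[cell$channel == ch, ], .data$time)
      cbind(zoo::rollapply(d$x_nm, window, mean, partial = TRUE),
            zoo::rollapply(d$y_nm, window, mean, partial = TRUE))
    })
    names(sm) <- .channels
    frac <- tgrid / sample_every
    keep <- which(abs(frac - round(frac)) < 1e-9)
    purrr::map_dfr(prs, function(pr) {
      dxy <- sm[[pr[1]]][keep, , drop = FALSE] -
        sm[[pr[2]]][keep, , drop = FALSE]
      tibble(pair = .pair_id(pr[1], pr[2]), cell_id = cell$cell_id[1],
             time = tgrid[keep], distance = sqrt(rowSums(dxy^2)))
    })
  })
  summary <- dists |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(median = median(.data$distance),
                     q25 = quantile(.data$distance, 0.25),
                     q75 = quantile(.data$distance, 0.75),
                     n = dplyr::n(), .groups = "drop")
  ids <- unique(dists$pair)
  cmb <- utils::combn(ids, 2)
  tests <- purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
    a <- dists$distance[dists$pair == cmb[1, j]]
    b <- dists$distance[dists$pair == cmb[2, j]]
    tibble(pair_a = cmb[1, j], pair_b = cmb[2, j],
           p_value = wilcox.test(a, b, exact = FALSE,
                                 correct = TRUE)$p.value)
  })
  list(distances = dists, summary = summary, tests = tests)
}

#' On-target vs off-target covariance controls
#'
#' Computes the covariance between all channel pairs per cell, for traces
#' measured at the transcription site ("on-target") and at a matched
#' control point ("off-target"), and compares the per-cell covariances by
#' a two-sided Mann-Whitney test per pair.
#'
#' @param on_traces,off_traces Long trace tibbles with matching cells.
#' @return Tibble `pair`, `mean_cov_on`, `mean_cov_off`, `p_value`.
#' @export
covariance_controls <- function(on_traces, off_traces) {
  ids_on <- sort(unique(on_traces$cell_id))
  ids_off <- sort(unique(off_traces$cell_id))
  if (!identical(ids_on, ids_off))
    stop("on- and off-target traces must be paired by cell", call. = FALSE)
  prs <- list(c("ctd", "mrna"), c("ctd", "ser5ph"), c("ser5ph", "mrna"))
  cov_tbl <- function(traces, site) {
    cells <- split(traces, traces$cell_id)
    purrr::map_dfr(cells, function(cell) {
      m <- .trace_matrix(cell)
      purrr::map_dfr(prs, function(pr)
        tibble(site = site, cell_id = cell$cell_id[1],
               pair = .pair_id(pr[1], pr[2]),
               covariance = stats::cov(m[, pr[1]], m[, pr[2]])))
    })
  }
  both <- dplyr::bind_rows(cov_tbl(on_traces, "on"),
                           cov_tbl(off_traces, "off"))
  purrr::map_dfr(prs, function(pr) {
    id <- .pair_id(pr[1], pr[2])
    a <- both$covariance[both$pair == id & both$site == "on"]
    b <- both$covariance[both$pair == id & both$site == "off"]
    tibble(pair = id, mean_cov_on = mean(a), mean_cov_off = mean(b),
           p_value = wilcox.test(a, b, exact = FALSE,
                                 correct = TRUE)$p.value)
  })
}

# tanh-form decay fit y = A - B * tanh((t - t_half) / w); returns NULL for
# non-decaying traces
.tanh_decay_fit <- function(time, y, t_drug) {
  rng <- diff(range(y))
  if (rng <= 0) return(NULL)
  a0 <- mean(range(y)); b0 <- rng / 2
  t0 <- time[which.min(abs(y - a0))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A - B * tanh((time - th) / w),
      start = list(A = a0, B = b0, th = max(t0, t_drug), w = 2),
      lower = c(-Inf, 0, min(time), 0.1),
      upper = c(Inf, Inf, max(time), diff(range(time))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (cf[["B"]] <= 1e-6 * max(abs(y), 1)) return(NULL)  # no real decay
  fit
}

#' Align and quantify inhibitor run-off decays
#'
#' Fits each cell's per-channel decay with the sigmoidal form
#' `A - B tanh((t - t_half)/w)` (the inverse-tanh half-decay time `t_half`
#' is the fitted location), aligns cells by their reference-channel
#' `t_half`, averages the aligned traces per channel, refits the averaged
#' curves weighted by the inverse variance across cells, and reports
#' per-channel half-decay times and delays relative to the reference
#' channel. Cells whose reference channel shows no decay are excluded and
#' counted in `n_excluded`.
#'
#' @param traces A `trace_set` spanning pre- and post-drug periods (e.g.
#'   from [perturb()]).
#' @param t_drug Drug addition time \[min\] (defaults to the trace
#'   attribute).
#' @param reference Channel used to align cells (default `"ctd"`).
#' @return List with `per_cell` (tibble `cell_id`, `channel`, `t_half`),
#'   `channels` (tibble `channel`, `t_half`, `se`, `delay`), and
#'   `n_excluded`.
#' @export
runoff_alignment <- function(traces, t_drug = attr(traces, "t_drug"),
                             reference = "ctd") {
  if (is.null(t_drug)) stop("`t_drug` is required", call. = FALSE)
  cells <- split(traces, traces$cell_id)
  per_cell <- list()
  aligned <- list()
  n_excluded <- 0L
  for (cell in cells) {
    m <- .trace_matrix(cell)
    tgrid <- sort(unique(cell$time))
    fits <- purrr::map(.channels,
                       ~ .tanh_decay_fit(tgrid, m[, .x], t_drug))
    names(fits) <- .channels
    if (is.null(fits[[reference]])) {
      n_excluded <- n_excluded + 1L
      next
    }
    th <- vapply(.channels, function(ch) {
      if (is.null(fits[[ch]])) NA_real_ else coef(fits[[ch]])[["th"]]
    }, numeric(1))
    per_cell[[cell$cell_id[1]]] <-
      tibble(cell_id = cell$cell_id[1], channel = .channels, t_half = th)
    # shift by the reference half-decay time, rounded to the sampling grid
    # so aligned traces stay on a common lattice
    dt <- min(diff(tgrid))
    shift <- round(th[[reference]] / dt) * dt
    aligned[[cell$cell_id[1]]] <-
      tibble(cell_id = cell$cell_id[1],
             time = rep(tgrid - shift, 3),
             channel = rep(.channels, each = length(tgrid)),
             intensity = as.vector(m[, .channels]))
  }
  if (!length(aligned))
    stop("no cell shows a decay in the reference channel", call. = FALSE)
  per_cell <- dplyr::bind_rows(per_cell)
  al <- dplyr::bind_rows(aligned) |>
    dplyr::group_by(.data$channel, .data$time) |>
    dplyr::summarise(mean = mean(.data$intensity),
                     var = stats::var(.data$intensity),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= max(2, length(aligned) / 2))
  channels <- purrr::map_dfr(.channels, function(ch) {
    d <- al[al$channel == ch, ]
    # inverse-variance weights, capped so near-constant stretches of the
    # averaged trace cannot dominate the fit
    w <- 1 / pmax(d$var, 0.05 * stats::median(d$var))
    rng <- diff(range(d$mean))
    th0 <- approx(d$mean, d$time, xout = mean(range(d$mean)),
                  ties = mean)$y
    if (is.na(th0)) th0 <- 0
    fit <- tryCatch(
      minpack.lm::nlsLM(
        mean ~ A - B * tanh((time - th) / wd), data = d,
        start = list(A = mean(range(d$mean)), B = rng / 2, th = th0,
                     wd = 2),
        weights = w,
        lower = c(-Inf, 0, min(d$time), 0.1),
        upper = c(Inf, Inf, max(d$time), diff(range(d$time))),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit))
      return(tibble(channel = ch, t_half = NA_real_, se = NA_real_))
    tibble(channel = ch, t_half = coef(fit)[["th"]],
           se = tryCatch(sqrt(diag(vcov(fit)))[["th"]],
                         error = function(e) NA_real_))
  })
  channels$delay <- channels$t_half -
    channels$t_half[channels$channel == reference]
  list(per_cell = per_cell, channels = channels, n_excluded = n_excluded)
}
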