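#' Cross-covariance of two equal-length traces
#'
#' Computes `G(tau) = <da(t) db(t + tau)>` with the temporal mean of each
#' trace removed, averaging over the overlapping samples at each lag. The
#' auto case (`b` missing or identical to `a`) is symmetric in `tau`; the
#' cross case need not be.
#'
#' @param a,b Numeric vectors of equal length (>= 2). `b` defaults to `a`.
#' @param max_lag Largest lag in samples (default: length - 1).
#' @return Tibble `lag` (in samples, `-max_lag..max_lag`), `value`.
#' @examples
#' trace_covariance(sin(1:50 / 3), max_lag = 10)
#' @export
trace_covariance <- function(a, b = a, max_lag = length(a) - 1L) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2) stop("need at least two time points", call. = FALSE)
  if (all(is.na(a)) || all(is.na(b))) stop("all-NA trace", call. = FALSE)
  n <- length(a)
  max_lag <- min(max_lag, n - 1L)
  da <- a - mean(a)
  db <- b - mean(b)
  g_fwd <- vapply(0:max_lag, function(k)
    sum(da[seq_len(n - k)] * db[seq_len(n - k) + k]) / (n - k), numeric(1))
  g_bwd <- vapply(1:max_lag, function(k)
    sum(db[seq_len(n - k)] * da[seq_len(n - k) + k]) / (n - k), numeric(1))
  tibble(lag = c(-(max_lag:1), 0:max_lag), value = c(rev(g_bwd), g_fwd))
}

#' Shot-noise estimate from a single-replica autocovariance
#'
#' Shot noise is uncorrelated in time, so it contributes only at zero lag.
#' The "true" zero-lag autocovariance is estimated by extrapolating a
#' straight line fitted through the three shortest nonzero lags back to
#' `tau = 0`; the shot-noise variance is the excess of the measured `G(0)`
#' over that extrapolation (clipped at zero with a warning).
#'
#' @param lags Lag grid including 0 and at least three nonzero lags \[min\].
#' @param g Autocovariance values on `lags`.
#' @return List with `g0_true` (extrapolated zero-lag value) and `shot_var`.
#' @export
estimate_shot_noise <- function(lags, g) {
  stopifnot(length(lags) == length(g))
  pos <- which(lags > 0)
  if (length(pos) < 3) stop("need at least 3 nonzero lags", call. = FALSE)
  i0 <- which(lags == 0)
  if (!length(i0)) stop("zero lag missing", call. = FALSE)
  use <- pos[order(lags[pos])][1:3]
  fit <- lm(g[use] ~ lags[use])
  g0_true <- unname(coef(fit)[1])
  shot_var <- g[i0] - g0_true
  if (shot_var < 0) {
    warning("negative shot-noise estimate clipped to 0", call. = FALSE)
    shot_var <- 0
  }
  list(g0_true = g0_true, shot_var = shot_var)
}

#' Replica-averaged normalized correlation functions
#'
#' Computes the six auto- and cross-covariance functions per cell, removes
#' shot noise from the zero-lag autocovariances by linear interpolation
#' through the three shortest nonzero lags (per replica, prior to
#' averaging), normalizes every pair by its zero-lag value averaged over
#' replicas, and returns the replica mean with `SEM = SD/sqrt(N)` at each
#' lag.
#'
#' @param traces Long trace tibble (`cell_id`, `time`, `channel`,
#'   `intensity`), e.g. from [sample_traces()]. All cells must share a
#'   uniform time grid across channels; missing points are not supported.
#' @param max_lag Largest lag \[min\].
#' @return A tibble (`pair`, `lag`, `value`, `sem`) of class
#'   `correlation_set`, with attributes `n_cells`, `dt` and `shot_noise` (a
#'   tibble of per-channel shot-noise variance, corrected zero-lag
#'   covariance, and the shot-to-signal SD ratio).
#' @examples
#' tr <- sample_traces(build_model("base"), n_cells = 4, duration = 80, seed = 1)
#' correlate_traces(tr, max_lag = 10)
#' @export
correlate_traces <- function(traces, max_lag = 30) {
  stopifnot(all(c("cell_id", "time", "channel", "intensity") %in%
                  names(traces)))
  cells <- split(traces, traces$cell_id)
  if (length(cells) < 2)
    stop("need at least 2 cells (SEM undefined for one replica)",
         call. = FALSE)
  mats <- purrr::map(cells, .trace_matrix)
  dt <- attr(mats[[1]], "dt")
  k_max <- max(1L, round(max_lag / dt))
  k_max <- min(k_max, nrow(mats[[1]]) - 1L)
  lag_grid <- (0:k_max) * dt

  per_pair <- purrr::map(.pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    raw <- purrr::map(mats, function(m) {
      g <- trace_covariance(m[, a], m[, b], max_lag = k_max)
      g$value
    })
    lags_full <- ((-k_max):k_max) * dt
    i0 <- k_max + 1L
    if (a == b) {
      corr0 <- vapply(raw, function(v) suppressWarnings(
        estimate_shot_noise(lag_grid, v[i0:length(v)])$g0_true), numeric(1))
      shot <- vapply(seq_along(raw), function(i)
        max(raw[[i]][i0] - corr0[i], 0), numeric(1))
      num <- vapply(raw, function(v) v[i0:length(v)], numeric(k_max + 1L))
      num[1, ] <- corr0  # zero lag carries the shot-corrected value
      den <- corr0
      lags_out <- lag_grid
      shot_info <- list(channel = a, shot_var = mean(shot),
                        g0_true = mean(corr0))
    } else {
      num <- vapply(raw, identity, numeric(2L * k_max + 1L))
      den <- num[i0, ]
      lags_out <- lags_full
      shot_info <- NULL
    }
    n_rep <- length(den)
    # ratio estimator with a replica-averaged denominator; the O(1/N)
    # ratio bias is removed by the jackknife
    theta <- rowMeans(num) / mean(den)
    loo <- vapply(seq_len(n_rep), function(j)
      rowMeans(num[, -j, drop = FALSE]) / mean(den[-j]),
      numeric(nrow(num)))
    value <- n_rep * theta - (n_rep - 1) * rowMeans(loo)
    cm <- num / mean(den)  # per-replica normalized curves, for the SEM
    tibble(pair = .pair_id(a, b), lag = lags_out,
           value = value,
           sem = apply(cm, 1, sd) / sqrt(n_rep)) |>
      structure(shot_info = shot_info)
  })

  shot_tbl <- purrr::map_dfr(per_pair, function(x) {
    si <- attr(x, "shot_info")
    if (is.null(si)) return(NULL)
    tibble(channel = si$channel, shot_var = si$shot_var,
           g0_true = si$g0_true,
           shot_sd_ratio = sqrt(max(si$shot_var, 0) / si$g0_true))
  })
  out <- dplyr::bind_rows(per_pair)
  structure(out, class = c("correlation_set", class(out)),
            n_cells = length(cells), n_time = nrow(mats[[1]]), dt = dt,
            shot_noise = shot_tbl)
}

.trace_matrix <- function(cell) {
  w <- tidyr::pivot_wider(cell[c("time", "channel", "intensity")],
                          names_from = "channel",
                          values_from = "intensity")
  w <- dplyr::arrange(w, .data$time)
  if (anyNA(w)) stop("missing time points are not supported", call. = FALSE)
  dts <- diff(w$time)
  if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-8 * max(dts)))
    stop("non-uniform sampling within a cell", call. = FALSE)
  m <- as.matrix(w[setdiff(names(w), "time")])
  attr(m, "dt") <- dts[1]
  m
}

#' Per-channel shot-noise estimates of a correlation set
#'
#' @param corr_set A [correlate_traces()] result.
#' @return Tibble `channel`, `shot_var`, `g0_true`, `shot_sd_ratio`.
#' @export
shot_noise_estimates <- function(corr_set) {
  attr(corr_set, "shot_noise")
}

#' Dwell time of a normalized autocovariance curve
#'
#' The dwell time is the first lag at which the curve (normalized to start
#' at 1 after shot-noise correction) drops below `threshold`, linearly
#' interpolated between the bracketing lags.
#'
#' @param lag,value Normalized autocovariance curve on nonnegative lags.
#' @param threshold Crossing threshold (default 0.2, i.e. 20% of zero lag).
#' @return List `dwell` (min; `NA` when censored) and `censored` (`TRUE`
#'   when the curve never drops below the threshold within the grid).
#' @examples
#' dwell_time(0:20, exp(-(0:20) / 5))  # = 5 * log(5)
#' @export
dwell_time <- function(lag, value, threshold = 0.2) {
  stopifnot(length(lag) == length(value), all(lag >= 0))
  below <- which(value < threshold)
  if (!length(below)) return(list(dwell = NA_real_, censored = TRUE))
  i <- below[1]
  if (i == 1) return(list(dwell = lag[1], censored = FALSE))
  x0 <- lag[i - 1]; x1 <- lag[i]
  y0 <- value[i - 1]; y1 <- value[i]
  list(dwell = x0 + (threshold - y0) * (x1 - x0) / (y1 - y0),
       censored = FALSE)
}

#' Dwell times for all auto channels of a correlation set
#'
#' @inheritParams shot_noise_estimates
#' @inheritParams dwell_time
#' @return Tibble `channel`, `dwell`, `censored`.
#' @export
dwell_times <- function(corr_set, threshold = 0.2) {
  purrr::map_dfr(.channels, function(ch) {
    cur <- corr_set[corr_set$pair == .pair_id(ch, ch), ]
    dw <- dwell_time(cur$lag, cur$value, threshold)
    tibble(channel = ch, dwell = dw$dwell, censored = dw$censored)
  })
}

#' Peak lag of a cross-correlation curve
#'
#' Finds the lag of the curve maximum with sub-sample precision by fitting
#' a quadratic through the discrete peak and its two neighbours.
#'
#' @param lag,value Cross-correlation curve on a symmetric lag window.
#' @return Peak lag (same units as `lag`).
#' @examples
#' cross_delay(-5:5, dnorm(-5:5, mean = 1))
#' @export
cross_delay <- function(lag, value) {
  stopifnot(length(lag) == length(value), length(lag) >= 3)
  if (diff(range(value)) <= 0)
    stop("flat curve: peak lag undefined", call. = FALSE)
  i <- which.max(value)
  if (i == 1 || i == length(value)) return(lag[i])
  y0 <- value[i - 1]; y1 <- value[i]; y2 <- value[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(lag[i])
  lag[i] + 0.5 * (lag[i] - lag[i - 1]) * (y0 - y2) / denom
}

#' Peak lags for the three cross pairs of a correlation set
#'
#' Positive delay for pair `a-b` means the `b` signal lags the `a` signal.
#'
#' @inheritParams shot_noise_estimates
#' @return Tibble `pair`, `delay`.
#' @export
cross_delays <- function(corr_set) {
  crosses <- purrr::keep(.pairs, ~ .x[1] != .x[2])
  purrr::map_dfr(crosses, function(pr) {
    cur <- corr_set[corr_set$pair == .pair_id(pr[1], pr[2]), ]
    tibble(pair = .pair_id(pr[1], pr[2]),
           delay = cross_delay(cur$lag, cur$value))
  })
}

#' Photobleaching correction for fast single-plane imaging traces
#'
#' Single-plane fast imaging bleaches the observed signal approximately
#' exponentially. This divides the trace by a fitted `A exp(-t / tau_b)`
#' and rescales so the temporal mean is preserved. A trace with no
#' detectable decay is returned unchanged.
#'
#' @param time,intensity Trace (>= 50 points).
#' @return Corrected intensity vector.
#' @export
bleach_correct <- function(time, intensity) {
  stopifnot(length(time) == length(intensity))
  if (length(time) < 50) stop("need >= 50 points", call. = FALSE)
  df <- data.frame(t = time - time[1], y = intensity)
  a0 <- mean(df$y[seq_len(max(5, length(time) %/% 10))])
  sl <- unname(coef(lm(y ~ t, df))[2])
  if (a0 <= 0) stop("non-positive initial amplitude", call. = FALSE)
  tau0 <- if (sl < 0) max(a0 / -sl, diff(range(df$t)) / 10) else Inf
  if (!is.finite(tau0) || sl >= 0) return(intensity)  # no decay
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                      start = list(A = a0, tau = tau0),
                      lower = c(1e-12, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(intensity)
  cf <- coef(fit)
  if (cf[["A"]] <= 0) stop("non-positive fit amplitude", call. = FALSE)
  corr <- intensity / exp(-df$t / cf[["tau"]])
  corr * mean(intensity) / mean(corr)
}
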