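test_that("trace covariance matches a brute-force double loop", {
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  g <- trace_covariance(a, b, max_lag = 19)
  da <- a - mean(a); db <- b - mean(b)
  for (tau in c(-12, -3, 0, 1, 7, 19)) {
    acc <- 0; cnt <- 0
    for (t in seq_along(a)) {
      if (t + tau >= 1 && t + tau <= length(a)) {
        acc <- acc + da[t] * db[t + tau]
        cnt <- cnt + 1
      }
    }
    expect_equal(g$value[g$lag == tau], acc / cnt, tolerance = 1e-12)
  }
})

test_that("trace covariance basics: constant, symmetry, antisymmetry", {
  expect_true(all(abs(trace_covariance(rep(3, 10))$value) < 1e-14))
  x <- sin(1:40 / 3) + rnorm(40, sd = 0.1)
  g <- trace_covariance(x)
  expect_equal(g$value, rev(g$value))  # autocovariance symmetric
  y <- cos(1:40 / 4)
  gxy <- trace_covariance(x, y)
  gyx <- trace_covariance(y, x)
  expect_equal(gxy$value, rev(gyx$value), tolerance = 1e-12)
  expect_error(trace_covariance(1:5, 1:6), "length")
  expect_error(trace_covariance(rep(NA_real_, 5)), "NA")
})

test_that("shot-noise estimator separates white noise from signal", {
  # noiseless exponential autocovariance: the estimator reports exactly the
  # curvature deficit of the linear extrapolation, which shrinks with the
  # decay time
  curv_err <- function(tau_decay) {
    g <- exp(-(0:10) / tau_decay)
    y <- g[2:4]
    slope <- (y[3] - y[1]) / 2
    analytic <- g[1] - (mean(y) - slope * 2)
    est <- estimate_shot_noise(0:10, g)
    expect_equal(est$shot_var, analytic, tolerance = 1e-10)
    est$shot_var / g[1]
  }
  expect_lt(curv_err(10), 0.03)
  expect_lt(curv_err(20), curv_err(5))
  # iid noise of variance v adds to the curvature deficit at lag zero
  set.seed(8)
  v <- 0.5
  phi <- 0.8
  curves <- replicate(400, {
    x <- as.numeric(arima.sim(list(ar = phi), 300)) +
      rnorm(300, sd = sqrt(v))
    trace_covariance(x, max_lag = 5)$value[6:11]
  })
  g_true <- phi^(0:5) / (1 - phi^2)
  delta <- g_true[1] -
    (mean(g_true[2:4]) - (g_true[4] - g_true[2]) / 2 * 2)
  est2 <- estimate_shot_noise(0:5, rowMeans(curves))
  expect_equal(est2$shot_var, v + delta, tolerance = 0.1)
  expect_gt(est2$shot_var, v * 0.9)
  expect_error(estimate_shot_noise(0:2, c(1, 0.5, 0.3)), "3 nonzero")
})

test_that("replica aggregation: identical cells, scaling, one-cell error", {
  tr <- small_traces()
  one <- tr[tr$cell_id == "cell_01", ]
  dup <- dplyr::bind_rows(one,
                          dplyr::mutate(one, cell_id = "cell_02"),
                          dplyr::mutate(one, cell_id = "cell_03"))
  cs <- correlate_traces(dup, max_lag = 10)
  expect_true(all(cs$sem < 1e-12))
  # global gain and per-cell offsets leave normalized curves invariant
  scaled <- dplyr::mutate(
    tr, intensity = 3.7 * intensity +
      dplyr::if_else(cell_id == "cell_01", 2, -1))
  cs1 <- correlate_traces(tr, max_lag = 10)
  cs2 <- correlate_traces(scaled, max_lag = 10)
  expect_equal(cs1$value, cs2$value, tolerance = 1e-10)
  expect_equal(cs1$sem, cs2$sem, tolerance = 1e-10)
  expect_error(correlate_traces(one, max_lag = 10), "2 cells")
})

test_that("20-cell curves agree with model predictions within 3 SEM", {
  tr <- experiment_scale_traces()
  cs <- correlate_traces(tr, max_lag = 14)
  sn <- shot_noise_estimates(cs)
  pred <- expected_correlations(
    base_model(), n_time = attr(cs, "n_time"), max_lag = 14,
    shot_ratio = setNames(sn$shot_var / sn$g0_true, sn$channel))
  d <- dplyr::inner_join(as.data.frame(cs), pred, by = c("pair", "lag"),
                         suffix = c("_d", "_m"))
  d <- d[d$lag %in% c(2, 5, 10) & d$pair %in%
           c("ctd-ctd", "mrna-mrna", "ctd-mrna"), ]
  expect_true(all(abs(d$value_d - d$value_m) < 3 * d$sem))
})

test_that("shot-noise recovery matches the estimator's predicted ratios", {
  tr <- experiment_scale_traces()
  cs <- correlate_traces(tr, max_lag = 14)
  sn <- shot_noise_estimates(cs)
  pred <- predicted_shot_ratio(base_model())
  for (ch in c("ctd", "ser5ph", "mrna")) {
    expect_equal(sn$shot_sd_ratio[sn$channel == ch],
                 pred$predicted[pred$channel == ch], tolerance = 0.15)
  }
  # the mRNA channel decays slowly, so its ratio is nearly unbiased
  expect_equal(sn$shot_sd_ratio[sn$channel == "mrna"], 0.41,
               tolerance = 0.15)
})

test_that("dwell time: closed form, interpolation, censoring", {
  tau <- 7
  curve <- exp(-(0:30) / tau)
  dw <- dwell_time(0:30, curve)
  expect_false(dw$censored)
  expect_equal(dw$dwell, tau * log(5), tolerance = 0.01)
  cens <- dwell_time(0:10, seq(1, 0.25, length.out = 11))
  expect_true(cens$censored)
  expect_true(is.na(cens$dwell))
})

test_that("cross delay: zero for identical, recovers constructed shifts", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.9), 600))
  g_same <- trace_covariance(x, x, max_lag = 20)
  expect_equal(cross_delay(g_same$lag, g_same$value), 0, tolerance = 1e-6)
  shift <- 5
  y <- dplyr::lag(x, shift)
  keep <- !is.na(y)
  # y lags x by `shift` samples, so the x-vs-y peak sits at +shift
  g <- trace_covariance(x[keep], y[keep], max_lag = 20)
  expect_equal(cross_delay(g$lag, g$value), shift, tolerance = 0.6)
  expect_error(cross_delay(0:5, rep(1, 6)), "flat")
})

test_that("a seconds-scale phosphorylation step shifts the cross peak", {
  # ctd-ser5ph cross-correlation peak at 150-ms sampling: positive (Ser5ph
  # later), below the mean phosphorylation time, and increasing with it;
  # phosphorylation times of 5-10 s land the peak in the observed 3-6 s
  # window
  delay_for <- function(t_phos_s) {
    m <- build_model("phospho_step",
                     rate_params(k_phos = 60 / t_phos_s))
    pred <- model_correlations(m, max_lag = 1, dt = 0.0025)
    cur <- pred[pred$pair == "ctd-ser5ph", ]
    cross_delay(cur$lag, cur$value) * 60
  }
  d45 <- delay_for(4.5)
  d75 <- delay_for(7.5)
  expect_gt(d45, 0)
  expect_lt(d45, 4.5)
  expect_gt(d75, d45)
  expect_gte(d75, 3)
  expect_lte(d75, 6)
})

test_that("bleach correction removes an exponential envelope", {
  t <- 0:299
  expect_equal(bleach_correct(t, rep(2, 300)), rep(2, 300))
  y <- 5 * exp(-t / 120)
  corr <- bleach_correct(t, y)
  expect_lt(diff(range(corr)) / mean(corr), 1e-6)
  # simulated bleached burst trace: residual trend < 1% of mean / 100 frames
  set.seed(9)
  m <- base_model()
  path <- ssa_run(m, t_end = 299, dt = 1)
  sig <- (path$x2 + path$x3 + 5) * exp(-t / 150)
  corr2 <- bleach_correct(t, sig)
  slope <- unname(coef(lm(corr2 ~ t))[2])
  expect_lt(abs(slope) * 100 / mean(corr2), 1)
  expect_error(bleach_correct(1:10, rnorm(10)), "50")
})
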