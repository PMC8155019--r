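test_that("SSA respects trivial limits and seed determinism", {
  m0 <- build_model("base", rate_params(omega = 0))
  p <- ssa_run(m0, t_end = 50, seed = 1, record_events = TRUE)
  expect_true(all(as.matrix(p[c("x1", "x2", "x3")]) == 0))
  expect_length(attr(p, "event_times"), 0)
  m <- base_model()
  p1 <- ssa_run(m, t_end = 100, seed = 42, record_events = TRUE)
  p2 <- ssa_run(m, t_end = 100, seed = 42, record_events = TRUE)
  expect_identical(p1, p2)
})

test_that("SSA inter-arrival statistics match the exponential law", {
  # promoter nearly always ON: recruitment is a Poisson process
  p <- suppressWarnings(rate_params(omega = 1e5, k_off = 1, beta = 20,
                                    k_ab = 1, k_esc = 1, k_c = 1))
  m <- build_model("base", p)
  path <- ssa_run(m, t_end = 600, seed = 3, record_events = TRUE)
  rec <- attr(path, "event_times")[attr(path, "event_reaction") ==
                                     m$reactions[["recruit"]]]
  gaps <- diff(rec)[1:10000]
  ks <- suppressWarnings(ks.test(gaps, "pexp", rate = 20))
  expect_gt(ks$p.value, 0.01)
})

test_that("long SSA time averages match the moment equations", {
  m <- base_model()
  path <- ssa_run(m, t_end = 5e4, seed = 7, dt = 1)
  mu <- steady_state_mean(m)
  Sg <- steady_state_covariance(m)
  for (sp in c("x2", "x3")) {
    sem <- batch_sem(path[[sp]])
    expect_lt(abs(mean(path[[sp]]) - mu[[sp]]), 3 * sem)
  }
  # covariance of (x2, x3) against the Lyapunov solution
  b <- cut(seq_len(nrow(path)), 20, labels = FALSE)
  cv <- vapply(1:20, function(i)
    cov(path$x2[b == i], path$x3[b == i]), numeric(1))
  expect_lt(abs(mean(cv) - Sg["x2", "x3"]), 3 * sd(cv) / sqrt(20))
})

test_that("sampled traces map states to channels with optional noise", {
  m <- base_model()
  tr0 <- sample_traces(m, n_cells = 3, duration = 60, seed = 5,
                       shot_noise = c(ctd = 0, ser5ph = 0, mrna = 0),
                       normalize = FALSE)
  w <- tidyr::pivot_wider(tr0[tr0$cell_id == "cell_01", ],
                          names_from = "channel",
                          values_from = "intensity")
  # noiseless channels are exact linear transforms of the states
  expect_equal(w$ctd, w$ser5ph)
  expect_true(all(w$ctd >= w$mrna))
  expect_true(all(w$mrna == round(w$mrna)))
  tr <- sample_traces(m, n_cells = 3, duration = 60, seed = 5)
  expect_equal(nrow(tr), 3 * 61 * 3)
  # normalization by the pooled 95th percentile
  q95 <- tapply(tr$intensity, tr$channel, quantile, 0.95)
  expect_equal(as.numeric(q95), rep(1, 3), tolerance = 1e-10)
  expect_error(
    sample_traces(build_model("base", rate_params(omega = 0)),
                  n_cells = 2, duration = 30),
    "zero-variance")
})

test_that("simulated ChIP peaks at both gene ends and conserves RNAP2", {
  m <- base_model()
  chip <- simulate_chip(m, n_cells = 8, duration = 120, seed = 2)
  d <- chip$occupancy[chip$form == "ctd"]
  expect_true(all(d[1] > d[2:9]))
  expect_true(all(d[10] > d[2:9]))
  # occupancy conservation: bins sum to the mean total RNAP2
  mu_tot <- derived_quantities(m$params)$mu_total
  expect_equal(sum(d), mu_tot, tolerance = 0.15)
  # fast processing: no 3' accumulation, profile flat after bin 1
  geom <- chip_geometry(k_c = m$params$k_c, k_processing = 1e3)
  chip2 <- suppressWarnings(
    simulate_chip(m, geometry = geom, n_cells = 4, duration = 80,
                  seed = 3))
  d2 <- chip2$occupancy[chip2$form == "ctd"]
  expect_lt(d2[10], d2[1])
  expect_equal(unname(d2[10]), unname(mean(d2[2:9])), tolerance = 0.5)
  # inconsistent geometry: strict mode errors, default warns
  geom_bad <- chip_geometry(k_c = m$params$k_c, gene_length_kb = 1)
  expect_error(
    simulate_chip(m, geometry = geom_bad, n_cells = 2, duration = 30,
                  strict = TRUE),
    "5%")
})

test_that("occupancy weighting enriches for high-occupancy frames", {
  m <- base_model()
  c1 <- simulate_chip(m, n_cells = 6, duration = 100, seed = 4)
  c2 <- simulate_chip(m, n_cells = 6, duration = 100, seed = 4,
                      weighting = "by_occupancy")
  # weighting by total occupancy raises the promoter-bin signal
  expect_gt(c2$occupancy[c2$form == "ctd"][1],
            c1$occupancy[c1$form == "ctd"][1])
})

test_that("perturbation modes switch the right rates at the right time", {
  m <- base_model()
  expect_error(perturb(m, "unknown_mode", t_drug = 5), "unknown")
  expect_error(perturb(m, "block_burst", t_drug = -1), "window")
  # reduction_fraction = 0 reduces to the pure block (same seed, same path)
  t1 <- perturb(m, "block_escape", t_drug = 5, n_cells = 2, duration = 20,
                seed = 9)
  t2 <- perturb(m, "block_escape_reduce_kc", t_drug = 5,
                reduction_fraction = 0, n_cells = 2, duration = 20,
                seed = 9)
  expect_equal(t1$intensity, t2$intensity)
})

test_that("burst block clears all signals; escape block spares cluster", {
  m <- base_model()
  tb <- perturb(m, "block_burst", t_drug = 5, n_cells = 40, duration = 35,
                seed = 4)
  pr <- perturbation_response(tb)
  rel_end <- function(p, ch) {
    d <- p[p$channel == ch, ]
    d$mean[which.max(d$time)] / mean(d$mean[d$time <= 5])
  }
  expect_lt(rel_end(pr, "mrna"), 0.2)
  expect_lt(rel_end(pr, "ctd"), 0.2)
  # mRNA decays last, on the 1/k_c time scale
  mr <- pr[pr$channel == "mrna", ]
  base_lvl <- mean(mr$mean[mr$time <= 5])
  t_half_mrna <- approx(mr$mean[mr$time >= 5], mr$time[mr$time >= 5],
                        xout = base_lvl / 2, ties = mean)$y
  expect_gt(t_half_mrna - 5, 1)
  expect_lt(t_half_mrna - 5, 3 / m$params$k_c)
  # escape block: recruitment continues, so the cluster persists (the
  # steady cluster level even rises once escape stops) while mRNA runs off
  te <- perturb(m, "block_escape", t_drug = 5, n_cells = 40,
                duration = 35, seed = 5)
  pe <- perturbation_response(te)
  expect_gt(rel_end(pe, "ctd"), 0.3)
  expect_lt(rel_end(pe, "mrna"), 0.1)
})

test_that("dwell-time uncertainty is reproducible and ordered", {
  m <- base_model()
  dw1 <- dwell_uncertainty(m, n_datasets = 30, n_cells = 8,
                           duration = 120, seed = 21)
  dw2 <- dwell_uncertainty(m, n_datasets = 30, n_cells = 8,
                           duration = 120, seed = 22)
  expect_true(all(!dw1$censored_flag))
  # mRNA dwell exceeds the RNAP2 channel dwells on average
  expect_gt(dw1$mean_dwell[dw1$channel == "mrna"],
            dw1$mean_dwell[dw1$channel == "ser5ph"])
  # SD estimate stable between two disjoint batches
  for (ch in dw1$channel) {
    s1 <- dw1$sd_dwell[dw1$channel == ch]
    s2 <- dw2$sd_dwell[dw2$channel == ch]
    expect_lt(abs(s1 - s2) / s1, 0.5)
  }
})
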