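# shared fixtures, built once per test run

default_params <- function() rate_params()

base_model <- function(params = default_params()) build_model("base", params)

# table-derived default rates, used to assert closed forms
.tab <- list(omega = 0.43, beta = 15.4, k_ab = 0.4615 / 0.692 *
               (1 - 0.4615) / 0.4615,
             k_esc = 0.4615 / 0.692, k_c = 1 / 5.032)

# a small simulated trace set shared across tests (cached per session)
.fixture_env <- new.env(parent = emptyenv())

small_traces <- function() {
  if (is.null(.fixture_env$tr))
    .fixture_env$tr <- sample_traces(base_model(), n_cells = 6,
                                     duration = 120, seed = 11)
  .fixture_env$tr
}

experiment_scale_traces <- function() {
  if (is.null(.fixture_env$tr20))
    .fixture_env$tr20 <- make_traces(experiment_config(seed = 7))
  .fixture_env$tr20
}

# build a correlation_set directly from noise-free model predictions with
# constant SEMs: "data" that the model fits exactly
model_exact_corr_set <- function(model, max_lag = 30, n_time = 201,
                                 sem = 0.02) {
  pred <- expected_correlations(model, n_time = n_time, max_lag = max_lag)
  pred$sem <- sem
  structure(pred, class = c("correlation_set", class(pred)),
            n_cells = 20, n_time = n_time, dt = 1,
            shot_noise = tibble::tibble(channel = character(),
                                        shot_var = numeric(),
                                        g0_true = numeric(),
                                        shot_sd_ratio = numeric()))
}

model_exact_mrna <- function(model, sem_mean = 0.93, sem_var = 14) {
  mm <- model_mrna_moments(model)
  mrna_summary(mean = mm$mean, var = mm$var, sem_mean = sem_mean,
               sem_var = sem_var)
}

# batch-mean SEM of a long SSA statistic
batch_sem <- function(x, n_batches = 20) {
  b <- split(x, cut(seq_along(x), n_batches, labels = FALSE))
  means <- vapply(b, mean, numeric(1))
  sd(means) / sqrt(n_batches)
}
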