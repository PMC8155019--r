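#' Nascent mRNA count summary
#'
#' Summary statistics of a per-transcription-site nascent mRNA count sample
#' (in units of mature mRNA), as used to constrain the model fit.
#'
#' @param mean,var Sample mean and variance.
#' @param sem_mean Standard error of the mean.
#' @param sem_var Standard error of the variance (Gaussian approximation
#'   `var * sqrt(2 / (n - 1))` when computed from a sample).
#' @param n Sample size.
#' @return A list of class `mrna_summary`.
#' @export
mrna_summary <- function(mean, var, sem_mean, sem_var, n = NA_integer_) {
  if (sem_mean <= 0 || sem_var <= 0)
    stop("SEMs must be positive", call. = FALSE)
  structure(list(mean = mean, var = var, sem_mean = sem_mean,
                 sem_var = sem_var, n = n), class = "mrna_summary")
}

#' Published nascent-mRNA summary for the HIV-1 reporter
#'
#' Mean 15.5 and SD 10.55 mRNA with standard errors 0.93 (mean) and 14
#' (variance), as used for the published fit.
#'
#' @return An [mrna_summary()] object.
#' @export
reference_mrna_summary <- function() {
  mrna_summary(mean = 15.5, var = 10.55^2, sem_mean = 0.93, sem_var = 14)
}

# lag windows of the composite likelihood: first `n_auto` lags of each
# autocovariance and the cross lags in [-cross_range, cross_range]
.loglik_windows <- function(dt, n_auto = 15, cross_range = 10) {
  list(auto_lags = (seq_len(n_auto) - 1) * dt,
       cross_lags = seq(-cross_range, cross_range, by = dt))
}

#' Correlation-curve log-likelihood
#'
#' Gaussian log-likelihood (constants dropped) of the measured normalized
#' correlation curves given model predictions:
#' `-1/2 sum((G_D - G_M)^2 / SEM^2)` over the first `n_auto` lag times of
#' each of the three autocovariances and the cross lags within
#' `[-cross_range, cross_range]`. The model curves are the finite-sample
#' expectations of the estimator ([expected_correlations()]), evaluated at
#' the data's trace length and shot-noise level, so data and model are on
#' identical footing; zero-lag auto points carry the shot-noise-corrected
#' values on both sides.
#'
#' @param model A [build_model()] specification.
#' @param corr_set A [correlate_traces()] result.
#' @param n_auto Number of auto lags (default 15, i.e. 0..14 min at 1-min
#'   sampling).
#' @param cross_range Half-width of the cross-lag window \[min\] (default 10,
#'   i.e. 21 lags at 1-min sampling).
#' @return Scalar log-likelihood (0 is the attainable maximum).
#' @export
loglik_correlations <- function(model, corr_set, n_auto = 15,
                                cross_range = 10) {
  ctx <- .loglik_ctx(corr_set, n_auto, cross_range)
  .loglik_G(model, ctx)
}

# precompute the data-side pieces of the correlation likelihood once
.loglik_ctx <- function(corr_set, n_auto, cross_range) {
  dt <- attr(corr_set, "dt")
  if (is.null(dt)) dt <- min(diff(sort(unique(corr_set$lag))))
  win <- .loglik_windows(dt, n_auto, cross_range)
  sn <- attr(corr_set, "shot_noise")
  shot_ratio <- if (!is.null(sn) && nrow(sn))
    setNames(sn$shot_var / sn$g0_true, sn$channel) else NULL
  max_lag <- max(win$auto_lags, win$cross_lags)
  K <- round(max_lag / dt)
  pairs_dat <- purrr::map(.pairs, function(pr) {
    id <- .pair_id(pr[1], pr[2])
    auto <- pr[1] == pr[2]
    lags <- if (auto) win$auto_lags else win$cross_lags
    d <- corr_set[corr_set$pair == id, ]
    id_d <- match(round(lags / dt), round(d$lag / dt))
    # model curve index: autos run 0..K, crosses -K..K
    id_m <- if (auto) round(lags / dt) + 1L else round(lags / dt) + K + 1L
    if (anyNA(id_d))
      stop("lag grid does not cover the likelihood windows", call. = FALSE)
    sem <- d$sem[id_d]
    if (any(sem <= 0)) stop("non-positive SEM", call. = FALSE)
    list(value = d$value[id_d], sem = sem, id_m = id_m)
  })
  names(pairs_dat) <- vapply(.pairs, function(pr) .pair_id(pr[1], pr[2]),
                             character(1))
  list(dt = dt, max_lag = max_lag, n_time = attr(corr_set, "n_time"),
       shot_ratio = shot_ratio, pairs = pairs_dat)
}

.loglik_G <- function(model, ctx) {
  if (is.null(ctx$n_time)) {
    pred <- model_correlations(model, max_lag = ctx$max_lag, dt = ctx$dt)
    curves <- lapply(split(pred, pred$pair), function(d)
      list(lag = d$lag, value = d$value))
  } else {
    curves <- .expected_pair_curves(model, ctx$n_time, ctx$dt,
                                    ctx$max_lag, ctx$shot_ratio)
  }
  ll <- 0
  for (id in names(ctx$pairs)) {
    p <- ctx$pairs[[id]]
    mv <- curves[[id]]$value[p$id_m]
    ll <- ll - 0.5 * sum((p$value - mv)^2 / p$sem^2)
  }
  ll
}

#' mRNA mean/variance log-likelihood
#'
#' Gaussian penalties (constants dropped) on the model's steady-state mRNA
#' mean and variance given the measured sample summaries and their standard
#' errors.
#'
#' @inheritParams loglik_correlations
#' @param mrna An [mrna_summary()] object.
#' @return Scalar log-likelihood.
#' @export
loglik_mrna <- function(model, mrna) {
  stopifnot(inherits(mrna, "mrna_summary"))
  mm <- model_mrna_moments(model)
  -0.5 * ((mrna$mean - mm$mean) / mrna$sem_mean)^2 -
    0.5 * ((mrna$var - mm$var) / mrna$sem_var)^2
}

.free_params <- function(variant) {
  base <- c("omega", "beta", "k_ab", "k_esc", "k_c")
  extra <- switch(variant, base = character(),
                  phospho_step = "k_phos",
                  fractional_phospho = "fraction",
                  mrna_retention = "k_release")
  c(base, extra)
}

.param_bounds <- function(variant) {
  lo <- c(omega = 1e-3, beta = 1, k_ab = 1e-3, k_esc = 1e-3, k_c = 1e-2,
          k_phos = 1e-2, fraction = 1e-3, k_release = 1e-2)
  hi <- c(omega = 10, beta = 200, k_ab = 10, k_esc = 10, k_c = 2,
          k_phos = 100, fraction = 0.999, k_release = 10)
  nm <- .free_params(variant)
  list(lower = lo[nm], upper = hi[nm])
}

.theta_to_params <- function(theta, variant, k_off = 1000) {
  v <- exp(theta)
  nm <- .free_params(variant)
  names(v) <- nm
  extras <- as.list(v[setdiff(nm, c("omega", "beta", "k_ab", "k_esc",
                                    "k_c"))])
  kc <- unname(v["k_c"])
  args <- c(list(omega = unname(v["omega"]), k_off = k_off,
                 beta = unname(v["beta"]), k_ab = unname(v["k_ab"]),
                 k_esc = unname(v["k_esc"]), k_c = kc), extras)
  suppressWarnings(do.call(rate_params, args))
}

.default_init <- function(variant) {
  init <- c(omega = 0.5, beta = 10, k_ab = 1, k_esc = 1, k_c = 0.2,
            k_phos = 5, fraction = 0.5, k_release = 1)
  init[.free_params(variant)]
}

#' Composite maximum-likelihood fit of the bursting model
#'
#' Maximizes the total log-likelihood
#' `logL_G + logL_mu + logL_sigma2` ([loglik_correlations()] +
#' [loglik_mrna()]) over the free rates of the chosen variant, in
#' log-parameter space, with `k_off` fixed at 1000/min. Optimization uses
#' iterated rounds of Nelder-Mead, restarting the simplex from the
#' incumbent until the improvement between rounds falls below `tol`
#' (mirroring iterated `fminsearch` practice); the result is deterministic
#' given the data and starting point. Box bounds keep the rates in a
#' physically plausible range.
#'
#' @inheritParams loglik_correlations
#' @inheritParams loglik_mrna
#' @param variant Model variant name (see [build_model()]).
#' @param init Optional named vector of starting rates (natural scale) for
#'   the free parameters.
#' @param tol Between-round improvement threshold for convergence.
#' @param max_rounds Maximum number of Nelder-Mead rounds.
#' @param seed Stored for reproducibility metadata (the optimizer itself is
#'   deterministic).
#' @return An object of class `burst_fit`: list with `variant`, `params`
#'   (MLE [rate_params()]), `logL` components, `BIC` (with `k` free
#'   parameters and `n = 8` independent data signals), `convergence`
#'   diagnostics and the data used.
#' @export
fit_mle <- function(variant = "base", corr_set, mrna, init = NULL,
                    n_auto = 15, cross_range = 10, tol = 1e-4,
                    max_rounds = 25, seed = NULL) {
  stopifnot(inherits(mrna, "mrna_summary"))
  nm <- .free_params(variant)
  bounds <- .param_bounds(variant)
  if (is.null(init)) init <- .default_init(variant)
  init <- init[nm]
  if (anyNA(init)) stop("`init` must name all free parameters", call. = FALSE)
  init <- pmin(pmax(init, bounds$lower), bounds$upper)
  llo <- log(bounds$lower); lhi <- log(bounds$upper)
  ctx <- .loglik_ctx(corr_set, n_auto, cross_range)

  negll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    pen <- sum(pmax(theta - lhi, 0)^2 + pmax(llo - theta, 0)^2)
    th <- pmin(pmax(theta, llo), lhi)
    p <- .theta_to_params(th, variant)
    m <- tryCatch(build_model(variant, p), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- tryCatch(
      .loglik_G(m, ctx) + loglik_mrna(m, mrna),
      error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll + 1e4 * pen
  }

  theta <- log(init)
  best <- negll(theta)
  rounds <- 0L
  improvement <- Inf
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    opt <- optim(theta, negll, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-8))
    improvement <- best - opt$value
    theta <- opt$par
    best <- opt$value
    if (improvement >= 0 && improvement < tol) break
  }
  converged <- improvement < tol
  if (!converged)
    warning("fit did not converge within `max_rounds` rounds",
            call. = FALSE)
  theta <- pmin(pmax(theta, llo), lhi)
  params <- .theta_to_params(theta, variant)
  model <- build_model(variant, params)
  ll_g <- loglik_correlations(model, corr_set, n_auto, cross_range)
  ll_m <- -0.5 * ((mrna$mean - model_mrna_moments(model)$mean) /
                    mrna$sem_mean)^2
  ll_v <- -0.5 * ((mrna$var - model_mrna_moments(model)$var) /
                    mrna$sem_var)^2
  k <- length(nm)
  n_bic <- 8
  ll_tot <- ll_g + ll_m + ll_v
  structure(list(
    variant = variant, params = params, theta = setNames(theta, nm),
    logL_G = ll_g, logL_mu = ll_m, logL_var = ll_v, logL_total = ll_tot,
    k = k, n = n_bic, BIC = k * log(n_bic) - 2 * ll_tot,
    convergence = list(converged = converged, rounds = rounds,
                       improvement = improvement),
    data = list(corr_set = corr_set, mrna = mrna,
                n_auto = n_auto, cross_range = cross_range),
    seed = seed), class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("<burst_fit: %s> logL = %.2f (G %.2f, mu %.2f, var %.2f), BIC = %.2f\n",
              x$variant, x$logL_total, x$logL_G, x$logL_mu, x$logL_var,
              x$BIC))
  print(signif(exp(x$theta), 4))
  invisible(x)
}

#' @rdname fit_mle
#' @param x A `burst_fit` object.
#' @param ... Unused.
#' @export
tidy.burst_fit <- function(x, ...) {
  out <- tibble(term = names(x$theta), estimate = unname(exp(x$theta)))
  if (!is.null(x$samples)) {
    ci <- credible_intervals(x$samples)
    out <- dplyr::left_join(out, ci, by = "term")
  }
  out
}

#' @rdname fit_mle
#' @export
glance.burst_fit <- function(x, ...) {
  tibble(variant = x$variant, logL_G = x$logL_G, logL_mu = x$logL_mu,
         logL_var = x$logL_var, logL_total = x$logL_total, k = x$k,
         n = x$n, BIC = x$BIC, converged = x$convergence$converged)
}

#' Sample parameter uncertainty around a fit
#'
#' Random-walk Metropolis sampling of the composite likelihood surface in
#' log-parameter space, started at the MLE. The proposal scale is adapted
#' toward ~25% acceptance during burn-in only. 95% credible intervals are
#' the 2.5/97.5 percentiles of the retained samples.
#'
#' @param fit A [fit_mle()] result.
#' @param n_samples Retained samples after burn-in.
#' @param burn_in Burn-in iterations (with proposal adaptation).
#' @param seed Integer seed (required for reproducibility).
#' @param proposal_sd Initial log-scale proposal SD.
#' @return The `fit` with element `samples` added: a tibble of parameter
#'   draws (natural scale) with attribute `acceptance`.
#' @export
sample_uncertainty <- function(fit, n_samples = 10000, burn_in = 2000,
                               seed = 1, proposal_sd = 0.05) {
  stopifnot(inherits(fit, "burst_fit"))
  set.seed(seed)
  nm <- names(fit$theta)
  bounds <- .param_bounds(fit$variant)
  llo <- log(bounds$lower); lhi <- log(bounds$upper)
  ctx <- .loglik_ctx(fit$data$corr_set, fit$data$n_auto,
                     fit$data$cross_range)
  ll_fun <- function(theta) {
    if (any(theta < llo) || any(theta > lhi)) return(-Inf)
    p <- .theta_to_params(theta, fit$variant)
    m <- tryCatch(build_model(fit$variant, p), error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    ll <- tryCatch(.loglik_G(m, ctx) + loglik_mrna(m, fit$data$mrna),
                   error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
  theta <- fit$theta
  ll <- ll_fun(theta)
  sdp <- proposal_sd
  total <- burn_in + n_samples
  draws <- matrix(NA_real_, n_samples, length(nm),
                  dimnames = list(NULL, nm))
  acc <- 0L
  acc_win <- 0L
  for (i in seq_len(total)) {
    prop <- theta + rnorm(length(nm), sd = sdp)
    llp <- ll_fun(prop)
    if (is.finite(llp) && log(runif(1)) < llp - ll) {
      theta <- prop; ll <- llp
      if (i > burn_in) acc <- acc + 1L
      acc_win <- acc_win + 1L
    }
    if (i <= burn_in && i %% 100 == 0) {  # adapt toward ~25% acceptance
      rate <- acc_win / 100
      sdp <- sdp * exp(rate - 0.25)
      acc_win <- 0L
    }
    if (i > burn_in) draws[i - burn_in, ] <- theta
  }
  acc_rate <- acc / n_samples
  if (acc_rate < 0.05 || acc_rate > 0.8)
    warning(sprintf("MCMC acceptance rate %.2f outside [0.05, 0.8]",
                    acc_rate), call. = FALSE)
  samples <- as_tibble(exp(draws))
  attr(samples, "acceptance") <- acc_rate
  fit$samples <- samples
  fit
}

#' 95% credible intervals from parameter samples
#'
#' @param samples Tibble of parameter draws (natural scale), as produced by
#'   [sample_uncertainty()].
#' @param level Interval mass (default 0.95).
#' @return Tibble `term`, `lower`, `upper`.
#' @export
credible_intervals <- function(samples, level = 0.95) {
  a <- (1 - level) / 2
  purrr::imap_dfr(samples, function(v, nm)
    tibble(term = nm, lower = unname(quantile(v, a)),
           upper = unname(quantile(v, 1 - a))))
}

#' Compare fitted model variants by BIC
#'
#' Ranks fits of different variants to the same data by
#' `BIC = k log(n) - 2 logL_total` with `n = 8` independent data signals;
#' `k` counts only the free parameters (fixed rates and measured shot-noise
#' magnitudes are excluded).
#'
#' @param ... Two or more [fit_mle()] results fitted to identical data.
#' @return Tibble `variant`, `k`, `logL_total`, `BIC`, `delta_bic`, sorted
#'   by BIC (best first).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "burst_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "burst_fit")))
  ref <- fits[[1]]$data$corr_set
  same <- vapply(fits[-1], function(f)
    isTRUE(all.equal(as.data.frame(f$data$corr_set), as.data.frame(ref))),
    logical(1))
  if (!all(same))
    stop("variants were fitted to different data", call. = FALSE)
  out <- purrr::map_dfr(fits, function(f)
    tibble(variant = f$variant, k = f$k, logL_total = f$logL_total,
           BIC = f$BIC))
  out <- dplyr::arrange(out, .data$BIC)
  out$delta_bic <- out$BIC - out$BIC[1]
  out
}
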