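#' Build a bursting-model specification
#'
#' Assembles the stoichiometry matrix `S`, linear propensity coefficients
#' (`W1`, `w0`) and observation matrix for one variant of the RNAP2 bursting
#' model, so that reaction propensities are `W1 %*% x + w0` and observables
#' are `c_obs %*% x`.
#'
#' The `base` variant has three species (promoter state `x1`, cluster RNAP2
#' `x2`, transcribing RNAP2 `x3`) and six reactions: promoter activation
#' (`omega`), deactivation (`k_off`), recruitment (`beta * k_off` while ON),
#' abortive loss (`k_ab`), promoter escape (`k_esc`) and completion (`k_c`).
#' Cluster RNAP2 is treated as already Ser5-phosphorylated, so the CTD and
#' Ser5ph observables share the row `x2 + x3` and the mRNA observable is
#' `x3`.
#'
#' Variants (each one extra state and parameter):
#' * `phospho_step`: arrivals enter an unphosphorylated cluster state that is
#'   phosphorylated at `k_phos` (or aborts at `k_ab`); only the
#'   phosphorylated form escapes. CTD reports all forms, Ser5ph only the
#'   phosphorylated ones.
#' * `fractional_phospho`: a fraction `fraction` of arrivals is
#'   pre-phosphorylated; the remainder stays unphosphorylated and can only
#'   abort.
#' * `mrna_retention`: completed transcripts enter a retained-mRNA state,
#'   released at `k_release`; the mRNA observable includes the retained
#'   state.
#'
#' @param variant One of `"base"`, `"phospho_step"`, `"fractional_phospho"`,
#'   `"mrna_retention"`.
#' @param params A [rate_params()] object; variants read their extra rate
#'   from `params$variant_extras`.
#' @return A list of class `model_spec` with elements `variant`, `params`,
#'   `n_species`, `state_names`, `S`, `W1`, `w0`, `c_obs` (rows `ctd`,
#'   `ser5ph`, `mrna`) and `reactions` (named roles, used for per-polymerase
#'   bookkeeping).
#' @examples
#' m <- build_model("base", rate_params())
#' m$S
#' @export
build_model <- function(variant = c("base", "phospho_step",
                                    "fractional_phospho", "mrna_retention"),
                        params = rate_params()) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "rate_params"))
  p <- params
  ex <- p$variant_extras
  need <- function(name) {
    if (is.null(ex[[name]]))
      stop(sprintf("variant '%s' needs variant extra `%s`", variant, name),
           call. = FALSE)
    ex[[name]]
  }

  if (variant == "base") {
    states <- c("x1", "x2", "x3")
    S <- matrix(c(
      1, -1, 0,  0,  0,  0,
      0,  0, 1, -1, -1,  0,
      0,  0, 0,  0,  1, -1), nrow = 3, byrow = TRUE,
      dimnames = list(states, NULL))
    W1 <- matrix(0, 6, 3, dimnames = list(NULL, states))
    W1[1, 1] <- -p$omega
    W1[2, 1] <- p$k_off
    W1[3, 1] <- p$beta * p$k_off
    W1[4, 2] <- p$k_ab
    W1[5, 2] <- p$k_esc
    W1[6, 3] <- p$k_c
    w0 <- c(p$omega, 0, 0, 0, 0, 0)
    c_obs <- matrix(c(0, 1, 1,
                      0, 1, 1,
                      0, 0, 1), nrow = 3, byrow = TRUE,
                    dimnames = list(c("ctd", "ser5ph", "mrna"), states))
    reactions <- c(activate = 1, deactivate = 2, recruit = 3,
                   abort = 4, escape = 5, complete = 6)
  } else if (variant == "phospho_step") {
    k_phos <- need("k_phos")
    states <- c("x1", "xu", "xs", "xtr")
    # reactions: on, off, recruit->xu, xu abort, xu->xs phos, xs abort,
    # xs escape, complete
    S <- matrix(c(
      1, -1, 0,  0,  0,  0,  0,  0,
      0,  0, 1, -1, -1,  0,  0,  0,
      0,  0, 0,  0,  1, -1, -1,  0,
      0,  0, 0,  0,  0,  0,  1, -1), nrow = 4, byrow = TRUE,
      dimnames = list(states, NULL))
    W1 <- matrix(0, 8, 4, dimnames = list(NULL, states))
    W1[1, 1] <- -p$omega
    W1[2, 1] <- p$k_off
    W1[3, 1] <- p$beta * p$k_off
    W1[4, 2] <- p$k_ab
    W1[5, 2] <- k_phos
    W1[6, 3] <- p$k_ab
    W1[7, 3] <- p$k_esc
    W1[8, 4] <- p$k_c
    w0 <- c(p$omega, rep(0, 7))
    c_obs <- matrix(c(0, 1, 1, 1,
                      0, 0, 1, 1,
                      0, 0, 0, 1), nrow = 3, byrow = TRUE,
                    dimnames = list(c("ctd", "ser5ph", "mrna"), states))
    reactions <- c(activate = 1, deactivate = 2, recruit = 3,
                   abort = 4, phosphorylate = 5, abort_phos = 6,
                   escape = 7, complete = 8)
  } else if (variant == "fractional_phospho") {
    frac <- need("fraction")
    if (frac < 0 || frac > 1) stop("`fraction` must lie in [0, 1]",
                                   call. = FALSE)
    states <- c("x1", "xu", "xs", "xtr")
    # reactions: on, off, recruit unphos, recruit phos, xu abort, xs abort,
    # xs escape, complete
    S <- matrix(c(
      1, -1, 0, 0,  0,  0,  0,  0,
      0,  0, 1, 0, -1,  0,  0,  0,
      0,  0, 0, 1,  0, -1, -1,  0,
      0,  0, 0, 0,  0,  0,  1, -1), nrow = 4, byrow = TRUE,
      dimnames = list(states, NULL))
    W1 <- matrix(0, 8, 4, dimnames = list(NULL, states))
    W1[1, 1] <- -p$omega
    W1[2, 1] <- p$k_off
    W1[3, 1] <- (1 - frac) * p$beta * p$k_off
    W1[4, 1] <- frac * p$beta * p$k_off
    W1[5, 2] <- p$k_ab
    W1[6, 3] <- p$k_ab
    W1[7, 3] <- p$k_esc
    W1[8, 4] <- p$k_c
    w0 <- c(p$omega, rep(0, 7))
    c_obs <- matrix(c(0, 1, 1, 1,
                      0, 0, 1, 1,
                      0, 0, 0, 1), nrow = 3, byrow = TRUE,
                    dimnames = list(c("ctd", "ser5ph", "mrna"), states))
    reactions <- c(activate = 1, deactivate = 2, recruit_unphos = 3,
                   recruit_phos = 4, abort = 5, abort_phos = 6,
                   escape = 7, complete = 8)
  } else { # mrna_retention
    k_release <- need("k_release")
    states <- c("x1", "x2", "x3", "xret")
    # reactions: on, off, recruit, abort, escape, complete->retained, release
    S <- matrix(c(
      1, -1, 0,  0,  0,  0,  0,
      0,  0, 1, -1, -1,  0,  0,
      0,  0, 0,  0,  1, -1,  0,
      0,  0, 0,  0,  0,  1, -1), nrow = 4, byrow = TRUE,
      dimnames = list(states, NULL))
    W1 <- matrix(0, 7, 4, dimnames = list(NULL, states))
    W1[1, 1] <- -p$omega
    W1[2, 1] <- p$k_off
    W1[3, 1] <- p$beta * p$k_off
    W1[4, 2] <- p$k_ab
    W1[5, 2] <- p$k_esc
    W1[6, 3] <- p$k_c
    W1[7, 4] <- k_release
    w0 <- c(p$omega, rep(0, 6))
    c_obs <- matrix(c(0, 1, 1, 0,
                      0, 1, 1, 0,
                      0, 0, 1, 1), nrow = 3, byrow = TRUE,
                    dimnames = list(c("ctd", "ser5ph", "mrna"), states))
    reactions <- c(activate = 1, deactivate = 2, recruit = 3,
                   abort = 4, escape = 5, complete = 6, release = 7)
  }

  structure(list(variant = variant, params = params,
                 n_species = length(states), state_names = states,
                 S = S, W1 = W1, w0 = w0, c_obs = c_obs,
                 reactions = reactions),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s> %d species (%s), %d reactions\n",
              x$variant, x$n_species, paste(x$state_names, collapse = ", "),
              ncol(x$S)))
  invisible(x)
}

# drift matrix A = S W1 of the first-moment ODE
.drift <- function(model) model$S %*% model$W1

#' Steady-state mean of the bursting model
#'
#' Solves the linear steady-state condition `S W1 E[x] + S w0 = 0` of the
#' first-moment equation.
#'
#' @param model A [build_model()] specification.
#' @return Named numeric vector of steady-state species means.
#' @examples
#' steady_state_mean(build_model("base"))
#' @export
steady_state_mean <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  A <- .drift(model)
  b <- -drop(model$S %*% model$w0)
  if (rcond_est(A) < 1e-12)
    stop("unstable/degenerate model: S W1 is numerically singular",
         call. = FALSE)
  setNames(drop(solve(A, b)), model$state_names)
}

rcond_est <- function(A) {
  s <- svd(A, nu = 0, nv = 0)$d
  if (min(s) <= 0) 0 else min(s) / max(s)
}

#' Steady-state covariance of the bursting model
#'
#' Solves the algebraic Lyapunov equation
#' `A Sigma + Sigma A' + S diag(W1 E[x] + w0) S' = 0` with `A = S W1`, via
#' the Kronecker-product linear system (the state dimension is at most 4).
#'
#' @inheritParams steady_state_mean
#' @return Symmetric positive-semidefinite covariance matrix of the species.
#' @examples
#' steady_state_covariance(build_model("base"))
#' @export
steady_state_covariance <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  A <- .drift(model)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= -1e-12))
    stop("unstable/degenerate model: drift eigenvalues must be negative",
         call. = FALSE)
  mu <- steady_state_mean(model)
  Q <- model$S %*% diag(drop(model$W1 %*% mu + model$w0),
                        nrow = length(model$w0)) %*% t(model$S)
  n <- nrow(A)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  Sigma <- matrix(solve(K, -as.vector(Q)), n, n)
  Sigma <- (Sigma + t(Sigma)) / 2
  lam <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8 * max(abs(lam)))
    stop("Lyapunov solution is indefinite", call. = FALSE)
  dimnames(Sigma) <- list(model$state_names, model$state_names)
  Sigma
}

#' Lagged covariance functions of the bursting model
#'
#' Computes the species-level lagged covariance
#' `Sigma_x(tau) = expm(A tau) %*% Sigma_SS` (exact for this linear system)
#' and the observable-level `Sigma_y(tau) = c Sigma_x(tau) c'` on a grid of
#' nonnegative lags. Negative cross-covariance lags follow from
#' `Sigma_ab(-tau) = Sigma_ba(tau)`.
#'
#' @inheritParams steady_state_mean
#' @param lags Sorted nonnegative lag grid \[min\].
#' @return List with `lags`, `lag_cov_x` (array species x species x lag) and
#'   `lag_cov_y` (array channels x channels x lag).
#' @examples
#' lagged_covariance(build_model("base"), 0:10)$lag_cov_y["mrna", "mrna", ]
#' @export
lagged_covariance <- function(model, lags) {
  stopifnot(inherits(model, "model_spec"))
  if (is.unsorted(lags) || any(lags < 0))
    stop("`lags` must be sorted and nonnegative", call. = FALSE)
  A <- .drift(model)
  Sigma0 <- steady_state_covariance(model)
  n <- nrow(A)
  eg <- eigen(A)
  lag_x <- array(NA_real_, c(n, n, length(lags)),
                 dimnames = list(model$state_names, model$state_names, NULL))
  use_eigen <- rcond_est(eg$vectors) > 1e-8
  if (use_eigen) {
    # Sigma_x(tau)[i,j] = sum_k B_k[i,j] exp(lambda_k tau): one flat
    # matrix product covers the whole lag grid
    V <- eg$vectors + 0i
    Vi <- solve(V)
    M2 <- Vi %*% Sigma0
    Bmat <- vapply(seq_len(n), function(k)
      as.vector(outer(V[, k], M2[k, ])), complex(n * n))
    ev <- exp(outer(eg$values + 0i, lags))   # n x n_lags
    lag_x[] <- Re(matrix(Bmat %*% ev, n, n * length(lags)))
  } else {
    for (k in seq_along(lags)) {
      E <- pracma::expm(A * lags[k])  # fallback for defective drift
      lag_x[, , k] <- E %*% Sigma0
    }
  }
  cy <- model$c_obs
  cyt <- t(cy)
  lag_y <- array(NA_real_, c(nrow(cy), nrow(cy), length(lags)),
                 dimnames = list(rownames(cy), rownames(cy), NULL))
  for (k in seq_along(lags)) lag_y[, , k] <- cy %*% lag_x[, , k] %*% cyt
  list(lags = lags, lag_cov_x = lag_x, lag_cov_y = lag_y)
}

#' Model-predicted normalized correlation curves
#'
#' Evaluates the model's auto- and cross-covariance functions on a lag grid
#' and normalizes each signal pair by its own zero-lag value, matching how
#' measured curves are normalized (the model contains no shot noise, so its
#' zero-lag value is the "true", shot-noise-free one).
#'
#' @inheritParams steady_state_mean
#' @param max_lag Largest lag \[min\].
#' @param dt Lag spacing \[min\].
#' @param zero_lag How the auto zero-lag normalizer is computed. With
#'   `"estimated"` (the default, and what the likelihood uses) the model
#'   curve is passed through the same zero-lag estimator applied to the
#'   data — a straight line through the three shortest nonzero lags
#'   extrapolated to `tau = 0` — so model and data curves are directly
#'   comparable even when fast covariance components decay within one
#'   sampling interval. `"exact"` normalizes by the model's true zero-lag
#'   covariance.
#' @return A tibble with columns `pair`, `lag`, `value`; auto pairs on
#'   `0..max_lag`, cross pairs on `-max_lag..max_lag` with the convention
#'   that `G_ab(tau) = <da(t) db(t+tau)>`.
#' @export
model_correlations <- function(model, max_lag = 30, dt = 1,
                               zero_lag = c("estimated", "exact")) {
  zero_lag <- match.arg(zero_lag)
  max_lag <- max(max_lag, 3 * dt)
  lags <- seq(0, max_lag, by = dt)
  lc <- lagged_covariance(model, lags)$lag_cov_y
  out <- purrr::map_dfr(.pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    # Sigma_x(tau) = expm(A tau) Sigma0 gives <x(t+tau) x(t)'>- mu mu', so
    # G_ab(tau) = <da(t) db(t+tau)> = lag_cov[b, a, tau]
    fwd <- lc[b, a, ]
    if (a == b) {
      if (zero_lag == "estimated") {
        g0 <- suppressWarnings(estimate_shot_noise(lags, fwd)$g0_true)
        fwd[1] <- g0
      } else {
        g0 <- fwd[1]
      }
      tibble(pair = .pair_id(a, b), lag = lags, value = fwd / g0)
    } else {
      bwd <- lc[a, b, ]  # G_ab(-tau) = G_ba(tau)
      tibble(pair = .pair_id(a, b),
             lag = c(-rev(lags[-1]), lags),
             value = c(rev(bwd[-1]), fwd) / fwd[1])
    }
  })
  out
}

# Exact expectation of the per-trace covariance estimator
# Ghat(k) = (1/(n-k)) sum_t (a_t - abar)(b_{t+k} - bbar)
# for a stationary pair with cross-covariance g(l) = Cov(a_t, b_{t+l}),
# supplied on lags -(n-1)..(n-1). Mean subtraction removes slow covariance
# mass, so E[Ghat] sits below g; the deficit is exactly computable.
.expected_xcov <- function(g_full, n, K) {
  stopifnot(length(g_full) == 2 * n - 1)
  cums <- c(0, cumsum(g_full))          # cums[i+1] = sum of first i entries
  ls <- -(n - 1):(n - 1)
  S_all <- sum((n - abs(ls)) * g_full) / n^2
  t_seq <- seq_len(n)
  # F(t) sums lags (1-t)..(n-t): positions (n+1-t)..(2n-t) in g_full
  Fv <- (cums[2 * n - t_seq + 1] - cums[n - t_seq + 1]) / n
  # H(s) sums lags (s-n)..(s-1): positions s..(s+n-1)
  Hv <- (cums[t_seq + n] - cums[t_seq]) / n
  cF <- cumsum(Fv)
  cH <- cumsum(Hv)
  ks <- 0:K
  nk <- n - ks
  avgF <- cF[nk] / nk
  avgH <- (cH[n] - c(0, cH[ks[-1]])) / nk
  g_full[ks + n] - avgF - avgH + S_all
}

#' Expected measured correlation curves under the model
#'
#' Computes what the replica-averaged, normalized covariance estimator is
#' expected to report for finite traces generated by the model: the exact
#' finite-sample expectation of the per-trace mean-subtracted covariance
#' estimator (which sits below the true covariance because the per-trace
#' mean soaks up slow fluctuations), plus the shot-noise contribution on
#' the auto curves, passed through the same zero-lag
#' extrapolation-and-normalization steps applied to data. Use these curves
#' (not the raw model covariances) when comparing the model to measured
#' curves; with `n_time = NULL` the infinite-trace limit is returned.
#'
#' @inheritParams model_correlations
#' @param n_time Number of time points per trace (finite-sample bias is
#'   modeled exactly for this length); `NULL` for the infinite-trace limit.
#' @param shot_ratio Optional named per-channel ratio of shot-noise
#'   variance to (extrapolated) signal variance, as estimated by
#'   [shot_noise_estimates()]; accounts for the small bias shot noise
#'   induces through mean subtraction.
#' @return A tibble `pair`, `lag`, `value` like [model_correlations()].
#' @export
expected_correlations <- function(model, n_time, dt = 1, max_lag = 30,
                                  shot_ratio = NULL) {
  if (is.null(n_time))
    return(model_correlations(model, max_lag = max_lag, dt = dt))
  curves <- .expected_pair_curves(model, n_time, dt, max_lag, shot_ratio)
  dplyr::bind_rows(purrr::imap(curves, function(cv, id)
    tibble(pair = id, lag = cv$lag, value = cv$value)))
}

# least-squares line through the three smallest positive lags,
# extrapolated to lag 0 (closed form; hot path of the likelihood)
.extrap0 <- function(lags, g) {
  pos <- which(lags > 0)
  use <- pos[order(lags[pos])][1:3]
  x <- lags[use]; y <- g[use]
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  yb - slope * xb
}

# list of expected normalized curves per pair id (no tibble overhead)
.expected_pair_curves <- function(model, n_time, dt, max_lag,
                                  shot_ratio = NULL) {
  n <- as.integer(n_time)
  K <- min(round(max_lag / dt), n - 1L)
  lags_all <- (0:(n - 1)) * dt
  lc <- lagged_covariance(model, lags_all)$lag_cov_y
  lag_grid <- (0:K) * dt
  out <- purrr::map(.pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    fwd <- lc[b, a, ]   # g_ab(l), l >= 0
    bwd <- lc[a, b, ]   # g_ab(-l) = g_ba(l)
    g_full <- c(rev(bwd[-1]), fwd)
    if (a == b && !is.null(shot_ratio)) {
      v <- shot_ratio[[a]] * fwd[1]  # noise variance on the model scale
      g_full[n] <- g_full[n] + v
    }
    e_fwd <- .expected_xcov(g_full, n, K)
    if (a == b) {
      g0 <- .extrap0(lag_grid, e_fwd)
      e_fwd[1] <- g0
      list(lag = lag_grid, value = e_fwd / g0)
    } else {
      e_bwd <- .expected_xcov(rev(g_full), n, K)
      list(lag = c(-rev(lag_grid[-1]), lag_grid),
           value = c(rev(e_bwd[-1]), e_fwd) / e_fwd[1])
    }
  })
  names(out) <- vapply(.pairs, function(pr) .pair_id(pr[1], pr[2]),
                       character(1))
  out
}

#' Predicted shot-noise ratio under the zero-lag estimator
#'
#' The interpolation-based shot-noise estimator attributes any covariance
#' component that decays within the first sampling interval to shot noise.
#' Given a model and the injected shot-noise multipliers, this computes the
#' ratio the estimator is expected to report for each channel:
#' `sqrt((mult^2 sigma^2 + delta) / (sigma^2 - delta))`, where `sigma^2` is
#' the channel's true signal variance and `delta` the curvature deficit of
#' the linear extrapolation.
#'
#' @inheritParams steady_state_mean
#' @param multipliers Injected shot-noise SD multipliers (named
#'   `ctd`, `ser5ph`, `mrna`).
#' @param dt Sampling interval \[min\].
#' @return Tibble `channel`, `injected`, `predicted`.
#' @export
predicted_shot_ratio <- function(model, multipliers = c(ctd = 1.98,
                                                        ser5ph = 1.42,
                                                        mrna = 0.41),
                                 dt = 1) {
  multipliers <- .match_channels(multipliers)
  lags <- (0:3) * dt
  lc <- lagged_covariance(model, lags)$lag_cov_y
  purrr::map_dfr(.channels, function(ch) {
    g <- lc[ch, ch, ]
    g0_est <- suppressWarnings(estimate_shot_noise(lags, g)$g0_true)
    delta <- g[1] - g0_est
    m2 <- multipliers[[ch]]^2
    tibble(channel = ch, injected = multipliers[[ch]],
           predicted = sqrt((m2 * g[1] + delta) / (g[1] - delta)))
  })
}

#' Model-predicted mRNA summary moments
#'
#' Steady-state mean and variance of the mRNA (transcribing RNAP2)
#' observable, the quantities constrained by the nascent-mRNA counting data.
#'
#' @inheritParams steady_state_mean
#' @return A list with `mean` and `var`.
#' @export
model_mrna_moments <- function(model) {
  mu <- steady_state_mean(model)
  Sigma <- steady_state_covariance(model)
  cm <- model$c_obs["mrna", ]
  list(mean = drop(cm %*% mu), var = drop(cm %*% Sigma %*% cm))
}
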