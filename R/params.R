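#' Kinetic rate parameters of the bursting model
#'
#' Bundles the rates of the RNAP2 bursting model. Time is in minutes and all
#' rates in 1/min. The promoter switches ON at burst frequency `omega` and OFF
#' at `k_off`; while ON it recruits RNAP2 at `beta * k_off`, so each
#' (short-lived) ON period delivers a geometric burst of mean size `beta`.
#' Cluster RNAP2 is lost (aborts) at `k_ab` or escapes into productive
#' elongation at `k_esc`; escaped RNAP2 completes elongation plus 3'-end
#' processing at `k_c`.
#'
#' Defaults are the fitted values for the HIV-1 reporter gene, back-derived
#' from the published derived-quantity table: `omega = 0.43`, `beta = 15.4`,
#' `k_esc + k_ab = 1/0.692`, `k_esc = 0.4615/0.692`, `k_c = 1/5.032`.
#' `k_off` is fixed at 1000/min, which puts the model in the geometric-burst
#' regime (`k_off >> omega`); a warning is raised when that time-scale
#' separation is violated.
#'
#' @param omega Burst frequency k_on \[1/min\].
#' @param k_off Burst termination rate \[1/min\]; conventionally fixed large.
#' @param beta Mean burst size \[molecules\].
#' @param k_ab Abortive loss rate from the promoter-proximal cluster \[1/min\].
#' @param k_esc Promoter escape rate \[1/min\].
#' @param k_c Completion (elongation + processing) rate \[1/min\].
#' @param ... Optional variant-specific rates: `k_phos` (Ser5
#'   phosphorylation, phospho_step variant), `fraction` (pre-phosphorylated
#'   arrival fraction, fractional_phospho), `k_release` (retained-mRNA release
#'   rate, mrna_retention; there `k_c` plays the role of the completion rate
#'   into the retained state).
#'
#' @return A list of class `rate_params`.
#' @examples
#' rate_params()
#' rate_params(omega = 0.3, beta = 20)
#' @export
rate_params <- function(omega = 0.43, k_off = 1000, beta = 15.4,
                        k_ab = 0.4615 / 0.692 * (1 - 0.4615) / 0.4615,
                        k_esc = 0.4615 / 0.692, k_c = 1 / 5.032, ...) {
  extras <- list(...)
  p <- list(omega = omega, k_off = k_off, beta = beta,
            k_ab = k_ab, k_esc = k_esc, k_c = k_c,
            variant_extras = extras)
  core <- unlist(p[c("omega", "k_off", "beta", "k_ab", "k_esc", "k_c")])
  if (any(!is.finite(core)) || any(core < 0))
    stop("all rates must be finite and nonnegative", call. = FALSE)
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  if (omega > 0 && k_off < 100 * omega)
    warning("k_off < 100 * omega: the geometric-burst reduction is inaccurate",
            call. = FALSE)
  if (length(extras) && any(!is.finite(unlist(extras))))
    stop("variant extras must be finite", call. = FALSE)
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params> (1/min)\n")
  core <- unlist(x[c("omega", "k_off", "beta", "k_ab", "k_esc", "k_c")])
  print(signif(core, 4))
  if (length(x$variant_extras)) {
    cat("extras:\n")
    print(signif(unlist(x$variant_extras), 4))
  }
  invisible(x)
}

#' Derived burst-cycle quantities
#'
#' Computes the summary quantities that characterise the fitted burst cycle,
#' each by its defining formula: arrival rate r `= omega * beta`; cluster
#' residence time `tau_cluster = 1/(k_esc + k_ab)`; mean cluster occupancy
#' `mu_cluster = r * tau_cluster`; escape probability
#' `f = k_esc/(k_esc + k_ab)`; mRNA burst size `beta_mrna = f * beta`; mRNA
#' production rate `r_mrna = mu_cluster * k_esc`; mean transcribing RNAP2
#' `mu_mrna = mu_cluster * k_esc / k_c`; total `mu_total`; and completion
#' time `tau_mrna = 1/k_c`.
#'
#' @param params A [rate_params()] object (or anything coercible via
#'   `do.call(rate_params, ...)`).
#' @return A one-row tibble with columns `r`, `tau_cluster`, `mu_cluster`,
#'   `f`, `beta_mrna`, `r_mrna`, `mu_mrna`, `mu_total`, `tau_mrna`.
#' @examples
#' derived_quantities(rate_params())
#' @export
derived_quantities <- function(params = rate_params()) {
  stopifnot(inherits(params, "rate_params"))
  r <- params$omega * params$beta
  tau_cluster <- 1 / (params$k_esc + params$k_ab)
  mu_cluster <- r * tau_cluster
  f <- params$k_esc / (params$k_esc + params$k_ab)
  mu_mrna <- mu_cluster * params$k_esc / params$k_c
  tibble(
    r = r,
    tau_cluster = tau_cluster,
    mu_cluster = mu_cluster,
    f = f,
    beta_mrna = f * params$beta,
    r_mrna = mu_cluster * params$k_esc,
    mu_mrna = mu_mrna,
    mu_total = mu_cluster + mu_mrna,
    tau_mrna = 1 / params$k_c
  )
}

#' Published 95% confidence ranges for the derived quantities
#'
#' Lower/upper 95% CI bounds of the fitted derived quantities for the HIV-1
#' reporter, used by parameter-recovery studies to judge whether a refitted
#' dataset lands inside the published uncertainty.
#'
#' @return A tibble with columns `quantity`, `value`, `lower`, `upper`.
#' @export
reference_ci_table <- function() {
  tibble(
    quantity = c("beta", "omega", "r", "tau_cluster", "mu_cluster", "f",
                 "beta_mrna", "r_mrna", "mu_mrna", "mu_total", "tau_mrna"),
    value = c(15.4, 0.43, 6.622, 0.692, 4.624, 0.4615,
              7.11, 3.083, 15.512, 20.136, 5.032),
    lower = c(11.76, 0.33, 5.74, 0.02, 0.46, 0.10,
              4.90, 2.49, 13.69, 14.62, 4.59),
    upper = c(61.83, 0.66, 27.43, 0.79, 5.26, 0.56,
              8.26, 3.52, 17.34, 21.28, 5.91)
  )
}
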