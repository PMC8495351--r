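# Internal helpers: classed conditions and truncated-normal sampling.

dmi_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dmi_error", "error", "condition")))
}

stop_invalid <- function(msg) dmi_stop(msg, "dmi_invalid_input")
stop_missing_predictor <- function(msg) dmi_stop(msg, "dmi_missing_predictor")
stop_config <- function(msg) dmi_stop(msg, "dmi_config_error")
stop_schema <- function(msg) dmi_stop(msg, "dmi_schema_error")
stop_design <- function(msg) dmi_stop(msg, "dmi_design_error")
stop_data <- function(msg) dmi_stop(msg, "dmi_data_error")
stop_fit <- function(msg) dmi_stop(msg, "dmi_fit_error")
stop_degenerate <- function(msg) dmi_stop(msg, "dmi_degenerate_input")

#' Sample from a truncated normal distribution
#'
#' Rejection sampler used by the synthetic-data generators. Draws from
#' Normal(mean, sd) conditional on `lower <= x <= upper`.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (`sd >= 0`; `sd = 0` returns the mean,
#'   which must then lie inside the bounds).
#' @param lower,upper truncation bounds.
#' @param max_attempts rejection attempts allowed per retained value before
#'   the sampler gives up (guards against infeasible truncation regions).
#' @return numeric vector of length `n`.
#' @export
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_attempts = 1e4) {
  if (n == 0) return(numeric(0))
  if (sd < 0) stop_invalid("sd must be non-negative")
  if (lower >= upper) stop_config("lower truncation bound must be below upper")
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop_config("degenerate sd = 0 with mean outside the truncation bounds")
    }
    return(rep(mean, n))
  }
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (mass < 1e-6) {
    stop_config(sprintf(
      "infeasible truncation: Normal(%.3g, %.3g) places %.2g mass in [%.3g, %.3g]",
      mean, sd, mass, lower, upper))
  }
  out <- numeric(n)
  need <- seq_len(n)
  for (attempt in seq_len(max_attempts)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (length(need) == 0) return(out)
  }
  stop_config("truncated-normal rejection sampling exceeded max_attempts")
}

# Derive a reproducible stream seed from a base seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483629)
}
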