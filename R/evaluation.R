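# Model evaluation: RMSPE, observed-on-predicted regression, and the
# residual-regression bias decomposition (mean and slope bias with t-test
# p-values), plus multi-model comparison tables.

check_pairs <- function(observed, predicted, min_n = 1) {
  if (length(observed) != length(predicted)) {
    stop_invalid("observed and predicted must have equal length")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop_invalid("observed and predicted must be complete")
  }
  if (length(observed) < min_n) {
    stop_data(sprintf("need at least %d observation(s)", min_n))
  }
}

#' Root mean square prediction error
#'
#' `sqrt(mean((observed - predicted)^2))`: the average vertical distance of
#' the points to the predictions in a residual plot.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return RMSPE in the units of the response (kg/d for DMI).
#' @export
rmspe <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 1)
  sqrt(mean((observed - predicted)^2))
}

#' Regression of observed on predicted values
#'
#' Classical precision summary: OLS of observed on predicted with its R^2.
#'
#' @param observed,predicted numeric vectors (n >= 3, predictions not
#'   constant).
#' @return list with `intercept`, `slope`, `r2`.
#' @export
observed_on_predicted <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 3)
  if (stats::sd(predicted) == 0) {
    stop_degenerate("predictions are constant; regression is degenerate")
  }
  fit <- stats::lm(observed ~ predicted)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}

#' Mean and slope bias from the residual regression
#'
#' Centers the predictions on their mean, then regresses the residuals
#' (observed minus predicted) on the centered predictions. The intercept of
#' that regression is the mean bias (exactly the arithmetic mean residual,
#' by the centering identity) and the slope is the slope bias; both carry
#' two-sided t-test p-values against zero.
#'
#' @param observed,predicted numeric vectors (n >= 3, predictions not
#'   constant).
#' @return list with `mean_bias`, `p_mean`, `slope_bias`, `p_slope`,
#'   `pred_mean` (the centering constant).
#' @export
bias_decomposition <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 3)
  if (stats::sd(predicted) == 0) {
    stop_degenerate("predictions are constant; bias regression is degenerate")
  }
  resid <- observed - predicted
  centered <- predicted - mean(predicted)
  fit <- stats::lm(resid ~ centered)
  sm <- summary(fit)$coefficients
  list(mean_bias = unname(sm[1, "Estimate"]),
       p_mean = unname(sm[1, "Pr(>|t|)"]),
       slope_bias = unname(sm[2, "Estimate"]),
       p_slope = unname(sm[2, "Pr(>|t|)"]),
       pred_mean = mean(predicted))
}

#' Three-way decomposition of the squared prediction error
#'
#' Splits `RMSPE^2` into squared mean bias, a slope (regression) term
#' `(1 - b)^2 Var(pred)` and a random dispersion term `(1 - r^2) Var(obs)`,
#' where `b` is the slope of observed on predicted and variances are
#' population (divide-by-n) moments. The three terms sum exactly to the
#' mean squared prediction error.
#'
#' @param observed,predicted numeric vectors (n >= 3, predictions not
#'   constant).
#' @return named numeric vector `c(mean_bias_sq, slope_term, dispersion)`.
#' @export
rmspe_decomposition <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 3)
  n <- length(observed)
  vp <- stats::var(predicted) * (n - 1) / n
  vo <- stats::var(observed) * (n - 1) / n
  if (vp == 0) stop_degenerate("predictions are constant")
  cv <- stats::cov(observed, predicted) * (n - 1) / n
  b <- cv / vp
  r2 <- if (vo > 0) cv^2 / (vp * vo) else 0
  c(mean_bias_sq = mean(observed - predicted)^2,
    slope_term = (1 - b)^2 * vp,
    dispersion = (1 - r2) * vo)
}

#' Full evaluation statistics for one model on one dataset
#'
#' @param observed,predicted numeric vectors (n >= 3).
#' @param model optional model label carried into the output.
#' @return one-row data frame: `model`, `n`, `lin_intercept`, `lin_slope`,
#'   `r2`, `rmspe`, `mean_bias`, `p_mean`, `slope_bias`, `p_slope`,
#'   `pred_mean`.
#' @export
eval_stats <- function(observed, predicted, model = NA_character_) {
  lin <- observed_on_predicted(observed, predicted)
  bias <- bias_decomposition(observed, predicted)
  data.frame(model = model, n = length(observed),
             lin_intercept = lin$intercept, lin_slope = lin$slope,
             r2 = lin$r2, rmspe = rmspe(observed, predicted),
             mean_bias = bias$mean_bias, p_mean = bias$p_mean,
             slope_bias = bias$slope_bias, p_slope = bias$p_slope,
             pred_mean = bias$pred_mean)
}

month_season <- function(month) {
  cold <- c("Nov", "Dec", "Jan")
  warm <- c("Mar", "Apr", "May", "Jun")
  ifelse(month %in% cold, "cold", ifelse(month %in% warm, "warm", "other"))
}

#' Compare DMI models on a common record set
#'
#' Evaluates each model on the identical rows: records lacking any
#' predictor required by any of the requested models are dropped listwise
#' first, so every row of the comparison shares the same n.
#'
#' @param records record table in the canonical schema with observed
#'   `dmi_kg_d`.
#' @param models character vector of model ids (see [predict_dmi()]), e.g.
#'   `c("kfsd", "nrc_lag3", "nrc_lag2", "cncps_lag2", "cncps_lag3", "jfs")`.
#' @param season optional `"cold"` (Nov–Jan) or `"warm"` (Mar–Jun) filter
#'   applied through the records' `month` column before evaluation.
#' @param coef KFSD coefficients used where a `kfsd` variant is requested.
#' @return data frame with one [eval_stats()] row per model.
#' @export
compare_models <- function(records, models, season = NULL,
                           coef = kfsd_coefficients()) {
  if (!"dmi_kg_d" %in% names(records)) {
    stop_schema("records must carry observed dmi_kg_d")
  }
  if (!is.null(season)) {
    if (!"month" %in% names(records)) {
      stop_schema("season filtering requires a month column")
    }
    records <- records[month_season(records$month) == season, , drop = FALSE]
  }
  req <- unique(unlist(lapply(models, model_required_columns)))
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop_schema(sprintf("records lack required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  keep <- !is.na(records$dmi_kg_d) &
    stats::complete.cases(records[, req, drop = FALSE])
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 3) {
    stop_data("fewer than 3 complete records shared by all models")
  }
  rows <- lapply(models, function(m) {
    pred <- predict_dmi(records, model = m, coef = coef)
    ok <- attr(pred, "status") == "ok"
    if (!all(ok)) stop_data(sprintf("model %s failed on %d record(s)",
                                    m, sum(!ok)))
    eval_stats(records$dmi_kg_d, as.numeric(pred), model = m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
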