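# Two-phase model development: phase one fits study-random coefficient
# models (random intercept + independent random slopes per study, i.e. a
# diagonal G block for every study) and selects the predictor subset with
# the lowest AIC (BIC tie-break); phase two re-estimates the selected fixed
# effects by ordinary least squares.

#' Derive short-name predictors from a record table
#'
#' Maps the canonical schema onto the predictor ids used during model
#' development (`dmi`, `bw`, `mbw`, `my`, `fcm`, `ndf`, `cp`, `adf`,
#' `starch`, `fpdm`, `wol`), deriving metabolic body weight and 4%
#' fat-corrected milk on the way.
#'
#' @param records data frame in the canonical schema.
#' @return data frame of response and candidate predictors.
#' @export
derive_predictors <- function(records) {
  out <- data.frame(row.names = seq_len(nrow(records)))
  pick <- function(col) if (col %in% names(records)) records[[col]] else
    rep(NA_real_, nrow(records))
  out$dmi <- pick("dmi_kg_d")
  out$bw <- pick("bw_kg")
  out$mbw <- ifelse(is.na(out$bw) | out$bw <= 0, NA_real_, out$bw^0.75)
  out$my <- pick("my_kg_d")
  fat <- pick("fat_pct")
  out$fcm <- ifelse(is.na(out$my) | is.na(fat) | fat <= 0 | fat >= 15,
                    NA_real_, 0.4 * out$my + 15 * (fat / 100) * out$my)
  out$ndf <- pick("ndf_pct_dm")
  out$cp <- pick("cp_pct_dm")
  out$adf <- pick("adf_pct_dm")
  out$starch <- pick("starch_pct_dm")
  out$fpdm <- pick("fpdm_pct")
  out$wol <- pick("wol")
  if ("study_id" %in% names(records)) out$study_id <- records$study_id
  out
}

#' Fit a study-random coefficient model by REML
#'
#' Fits `y = X beta + Z u + e` where each study contributes an independent
#' random intercept and an independent random slope per predictor column
#' (one variance component per fixed-effect column; no covariances — a
#' diagonal per-study G block), and `e ~ N(0, sigma^2 I)`. Estimation is
#' REML via [lme4::lmer()]. With a single study the between-study variances
#' are unidentifiable: the fit collapses to OLS with all variance
#' components at the zero boundary.
#'
#' Information criteria count only the variance parameters
#' (`q = ncol(X) + 2`: intercept variance, one slope variance per predictor,
#' and the residual variance): `AIC = -2 l_REML + 2 q`,
#' `BIC = -2 l_REML + q log(s)` with `s` the number of studies (switch
#' `bic_n = "obs"` for the N-based variant).
#'
#' @param y numeric response vector (observed DMI, kg/d).
#' @param X numeric matrix of predictors (no intercept column; syntactic
#'   column names).
#' @param study study identifiers, one per observation.
#' @param bic_n `"studies"` (default) or `"obs"`: sample size used in BIC.
#' @return an object of class `mixed_fit` with elements `beta`, `u` (one row
#'   per study), `g_var`, `sigma2`, `n_obs`, `n_studies`, `n_params`,
#'   `loglik_reml`, `aic`, `bic`.
#' @export
fit_random_coefficient <- function(y, X, study, bic_n = c("studies", "obs")) {
  bic_n <- match.arg(bic_n)
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (length(y) != nrow(X) || length(study) != length(y)) {
    stop_design("y, X and study must have matching lengths")
  }
  if (anyNA(y) || anyNA(X)) stop_design("y and X must be complete")
  study <- factor(study)
  s <- nlevels(study)
  n <- length(y)
  p <- ncol(X) + 1L
  if (n <= s) stop_design("need more observations than studies (N > s)")
  if (qr(cbind(1, X))$rank < p) stop_design("design matrix is rank deficient")
  q <- p + 1L  # variance parameters: p random-effect variances + sigma^2
  if (s == 1L) {
    # single study: between-study variances sit at the boundary; beta = OLS
    ols <- fit_ols(y, X)
    beta <- ols$coefficients
    sigma2 <- ols$sigma^2
    u <- matrix(0, 1, p, dimnames = list(levels(study),
                                         c("(Intercept)", colnames(X))))
    ll <- NA_real_
    return(structure(list(beta = beta, u = u,
                          g_var = stats::setNames(rep(0, p),
                                                  c("(Intercept)", colnames(X))),
                          sigma2 = sigma2, n_obs = n, n_studies = 1L,
                          n_params = p, loglik_reml = ll,
                          aic = NA_real_, bic = NA_real_,
                          fitted = ols$fitted, singular = TRUE),
                     class = "mixed_fit"))
  }
  dat <- data.frame(.y = y, X, .study = study, check.names = FALSE)
  preds <- colnames(X)
  re_terms <- c("(1 | .study)",
                if (length(preds) > 0) sprintf("(0 + %s | .study)", preds))
  fml <- stats::reformulate(c(preds, re_terms), response = ".y")
  fit <- tryCatch(
    lme4::lmer(fml, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) stop_fit(paste("random-coefficient fit failed:",
                                       conditionMessage(e))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  resid_var <- vc$vcov[vc$grp == "Residual"]
  re_rows <- vc[vc$grp != "Residual", , drop = FALSE]
  g_var <- stats::setNames(re_rows$vcov, re_rows$var1)
  g_var <- g_var[c("(Intercept)", preds)]
  re_list <- lme4::ranef(fit)
  u <- matrix(0, s, p, dimnames = list(levels(study),
                                       c("(Intercept)", preds)))
  for (re in re_list) {
    for (cn in colnames(re)) u[rownames(re), cn] <- u[rownames(re), cn] + re[[cn]]
  }
  ll <- as.numeric(stats::logLik(fit, REML = TRUE))
  bic_size <- if (bic_n == "studies") s else n
  structure(list(beta = lme4::fixef(fit), u = u, g_var = g_var,
                 sigma2 = resid_var, n_obs = n, n_studies = s, n_params = p,
                 loglik_reml = ll, aic = -2 * ll + 2 * q,
                 bic = -2 * ll + q * log(bic_size),
                 fitted = stats::fitted(fit),
                 singular = lme4::isSingular(fit)),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Study-random coefficient model: %d obs, %d studies\n",
              x$n_obs, x$n_studies))
  cat("Fixed effects:\n"); print(round(x$beta, 4))
  cat("Variance components (diagonal G block):\n"); print(round(x$g_var, 4))
  cat(sprintf("Residual variance: %.4f | AIC %.2f | BIC %.2f\n",
              x$sigma2, x$aic, x$bic))
  invisible(x)
}

#' Default predictor exclusion pairs
#'
#' Pairs of near-collinear candidates never co-selected in one subset:
#' body weight with metabolic body weight, and milk yield with
#' fat-corrected milk (each pair measures one quantity on two scales).
#'
#' @return list of character pairs.
#' @export
default_exclusion_pairs <- function() {
  list(c("bw", "mbw"), c("my", "fcm"))
}

#' Enumerate predictor subsets and select by AIC/BIC
#'
#' Fits every admissible subset of the candidate predictors (respecting
#' exclusion pairs, up to `max_size` predictors) with
#' [fit_random_coefficient()] on a common complete-case row set, and ranks
#' the subsets by AIC with BIC as tie-break. Aligning all fits on the same
#' rows keeps the information criteria comparable.
#'
#' @param records record table (canonical schema) or a data frame already
#'   holding the short-name predictors of [derive_predictors()].
#' @param candidates character vector of candidate predictor ids.
#' @param exclusion_pairs list of id pairs never co-selected.
#' @param max_size largest subset size fitted (full enumeration is
#'   exponential otherwise).
#' @param criterion `"aic"` (default) or `"bic"` as the primary ranking key.
#' @return data frame of subsets with columns `subset`, `size`, `aic`,
#'   `bic`, `loglik`, sorted best-first; the winning predictor ids in
#'   attribute `"selected"` and its `mixed_fit` in attribute `"best_fit"`.
#' @export
enumerate_and_select <- function(records, candidates,
                                 exclusion_pairs = default_exclusion_pairs(),
                                 max_size = 4, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  d <- if (all(c("dmi", candidates) %in% names(records))) records else
    derive_predictors(records)
  missing_cand <- setdiff(candidates, names(d))
  if (length(missing_cand) > 0) {
    stop_config(sprintf("unknown candidate predictor(s): %s",
                        paste(missing_cand, collapse = ", ")))
  }
  if (!"study_id" %in% names(d)) stop_schema("records must carry study_id")
  cc <- stats::complete.cases(d[, c("dmi", candidates), drop = FALSE]) &
    !is.na(d$study_id)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) == 0) stop_data("no complete-case rows for the candidate set")
  subsets <- list()
  for (k in seq_len(min(max_size, length(candidates)))) {
    for (idx in utils::combn(length(candidates), k, simplify = FALSE)) {
      sub <- candidates[idx]
      blocked <- any(vapply(exclusion_pairs,
                            function(pr) all(pr %in% sub), logical(1)))
      if (!blocked) subsets[[length(subsets) + 1L]] <- sub
    }
  }
  if (length(subsets) == 0) stop_config("no admissible predictor subset")
  fits <- lapply(subsets, function(sub) {
    fit_random_coefficient(d$dmi, as.matrix(d[, sub, drop = FALSE]),
                           d$study_id)
  })
  tab <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik_reml, numeric(1)))
  ord <- if (criterion == "aic") order(tab$aic, tab$bic) else
    order(tab$bic, tab$aic)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, selected = subsets[[ord[1]]], best_fit = fits[[ord[1]]],
            n_rows_used = nrow(d))
}

#' Ordinary least squares fit (phase two)
#'
#' Estimates the selected fixed effects by OLS with classical standard
#' errors, as in the second development phase where the study random effects
#' are dropped and the equation coefficients are re-estimated by a general
#' linear model.
#'
#' @param y numeric response.
#' @param X numeric predictor matrix (no intercept column).
#' @return an object of class `ols_fit`: `coefficients`, `se`, `r2`,
#'   `sigma` (residual SD), `n`, `fitted`, `residuals`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (length(y) != nrow(X)) stop_design("y and X must have matching lengths")
  p <- ncol(X) + 1L
  if (length(y) <= p) stop_design("need N > p observations")
  if (qr(cbind(1, X))$rank < p) stop_design("design matrix is rank deficient")
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- if (ncol(X) > 0) stats::reformulate(colnames(X), response = ".y") else
    stats::as.formula(.y ~ 1)
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 r2 = sm$r.squared, sigma = sm$sigma, n = length(y),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.3f, residual SD = %.3f\n",
              x$n, x$r2, x$sigma))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  invisible(x)
}
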