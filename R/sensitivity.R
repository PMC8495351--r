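# Monte-Carlo sensitivity analysis of a prediction equation: fit input
# distributions (chi-square / Kolmogorov-Smirnov / Anderson-Darling ranked
# over seven candidate families), sample by Latin hypercube, iterate batches
# to <1% convergence of the output mean and SD, and rank inputs by
# standardized regression coefficients.

dist_families <- function() {
  c("normal", "lognormal", "gamma", "weibull", "logistic", "uniform",
    "triangular")
}

#' Construct an input distribution specification
#'
#' @param family one of `"normal"` (mean, sd), `"lognormal"` (meanlog,
#'   sdlog), `"gamma"` (shape, rate), `"weibull"` (shape, scale),
#'   `"logistic"` (location, scale), `"uniform"` (min, max),
#'   `"triangular"` (min, mode, max).
#' @param ... the family's parameters, named as above.
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, dist_families())
  params <- list(...)
  need <- switch(family,
    normal = c("mean", "sd"), lognormal = c("meanlog", "sdlog"),
    gamma = c("shape", "rate"), weibull = c("shape", "scale"),
    logistic = c("location", "scale"), uniform = c("min", "max"),
    triangular = c("min", "mode", "max"))
  if (!all(need %in% names(params))) {
    stop_config(sprintf("%s distribution needs parameters: %s", family,
                        paste(need, collapse = ", ")))
  }
  params <- params[need]
  ok <- switch(family,
    normal = params$sd > 0, lognormal = params$sdlog > 0,
    gamma = params$shape > 0 && params$rate > 0,
    weibull = params$shape > 0 && params$scale > 0,
    logistic = params$scale > 0, uniform = params$min < params$max,
    triangular = params$min <= params$mode && params$mode <= params$max &&
      params$min < params$max)
  if (!isTRUE(ok)) stop_config(sprintf("invalid %s parameters", family))
  structure(list(family = family, params = params), class = "dist_spec")
}

# Triangular distribution (not provided by stats): density, CDF, quantile.
dtriangular <- function(x, min, mode, max) {
  d <- numeric(length(x))
  up <- x >= min & x <= mode
  dn <- x > mode & x <= max
  if (mode > min) d[up] <- 2 * (x[up] - min) / ((max - min) * (mode - min))
  else d[x == min] <- 2 / (max - min)
  if (max > mode) d[dn] <- 2 * (max - x[dn]) / ((max - min) * (max - mode))
  d
}

ptriangular <- function(q, min, mode, max) {
  p <- numeric(length(q))
  p[q >= max] <- 1
  up <- q > min & q <= mode
  dn <- q > mode & q < max
  if (mode > min) p[up] <- (q[up] - min)^2 / ((max - min) * (mode - min))
  if (max > mode) p[dn] <- 1 - (max - q[dn])^2 / ((max - min) * (max - mode))
  p
}

qtriangular <- function(p, min, mode, max) {
  pc <- (mode - min) / (max - min)
  ifelse(p <= pc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

#' Quantile function of a distribution specification
#' @param spec a [dist_spec()] or fitted distribution.
#' @param p probabilities in `[0, 1]`.
#' @return quantiles.
#' @export
q_dist <- function(spec, p) {
  pr <- spec$params
  switch(spec$family,
    normal = stats::qnorm(p, pr$mean, pr$sd),
    lognormal = stats::qlnorm(p, pr$meanlog, pr$sdlog),
    gamma = stats::qgamma(p, shape = pr$shape, rate = pr$rate),
    weibull = stats::qweibull(p, shape = pr$shape, scale = pr$scale),
    logistic = stats::qlogis(p, pr$location, pr$scale),
    uniform = stats::qunif(p, pr$min, pr$max),
    triangular = qtriangular(p, pr$min, pr$mode, pr$max))
}

p_dist <- function(spec, q) {
  pr <- spec$params
  switch(spec$family,
    normal = stats::pnorm(q, pr$mean, pr$sd),
    lognormal = stats::plnorm(q, pr$meanlog, pr$sdlog),
    gamma = stats::pgamma(q, shape = pr$shape, rate = pr$rate),
    weibull = stats::pweibull(q, shape = pr$shape, scale = pr$scale),
    logistic = stats::plogis(q, pr$location, pr$scale),
    uniform = stats::punif(q, pr$min, pr$max),
    triangular = ptriangular(q, pr$min, pr$mode, pr$max))
}

r_dist <- function(spec, n) q_dist(spec, stats::runif(n))

n_dist_params <- function(spec) length(spec$params)

# MLE fits per family; returns a dist_spec or NULL when infeasible.
fit_family_mle <- function(x, family) {
  n <- length(x)
  tryCatch(switch(family,
    normal = dist_spec("normal", mean = mean(x),
                       sd = sqrt(mean((x - mean(x))^2))),
    lognormal = {
      if (any(x <= 0)) return(NULL)
      lx <- log(x)
      dist_spec("lognormal", meanlog = mean(lx),
                sdlog = sqrt(mean((lx - mean(lx))^2)))
    },
    gamma = {
      if (any(x <= 0)) return(NULL)
      f <- fitdistrplus::fitdist(x, "gamma", method = "mle")
      dist_spec("gamma", shape = f$estimate[["shape"]],
                rate = f$estimate[["rate"]])
    },
    weibull = {
      if (any(x <= 0)) return(NULL)
      f <- fitdistrplus::fitdist(x, "weibull", method = "mle")
      dist_spec("weibull", shape = f$estimate[["shape"]],
                scale = f$estimate[["scale"]])
    },
    logistic = {
      f <- fitdistrplus::fitdist(x, "logis", method = "mle",
                                 start = list(location = mean(x),
                                              scale = stats::sd(x) * sqrt(3) / pi))
      dist_spec("logistic", location = f$estimate[["location"]],
                scale = f$estimate[["scale"]])
    },
    uniform = {
      pad <- diff(range(x)) / n
      dist_spec("uniform", min = min(x) - pad, max = max(x) + pad)
    },
    triangular = {
      pad <- diff(range(x)) / n
      a <- min(x) - pad; b <- max(x) + pad
      nll <- function(m) -sum(log(pmax(dtriangular(x, a, m, b), 1e-300)))
      m <- stats::optimize(nll, c(a, b))$minimum
      dist_spec("triangular", min = a, mode = m, max = b)
    }), error = function(e) NULL)
}

# Goodness-of-fit statistics against a fitted distribution.
ks_stat <- function(x, spec) {
  n <- length(x)
  Fz <- p_dist(spec, sort(x))
  max(max(seq_len(n) / n - Fz), max(Fz - (seq_len(n) - 1) / n))
}

ad_stat <- function(x, spec) {
  n <- length(x)
  Fz <- pmin(pmax(p_dist(spec, sort(x)), 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(Fz) + log(1 - rev(Fz))))
}

chisq_gof <- function(x, spec) {
  n <- length(x)
  m <- max(3L, ceiling(2 * n^0.4))  # equal-probability bins
  breaks <- q_dist(spec, seq(0, 1, length.out = m + 1))
  breaks[1] <- -Inf; breaks[m + 1] <- Inf
  breaks <- unique(breaks)
  obs <- as.integer(table(cut(x, breaks)))
  expd <- n * diff(p_dist(spec, breaks))
  expd[1] <- n * p_dist(spec, breaks[2])
  expd[length(expd)] <- n * (1 - p_dist(spec, breaks[length(breaks) - 1]))
  stat <- sum((obs - expd)^2 / pmax(expd, 1e-12))
  df <- max(1L, length(obs) - 1L - n_dist_params(spec))
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fit a probability distribution to an input variable
#'
#' Fits each candidate family by maximum likelihood, computes three
#' goodness-of-fit statistics (chi-square on equal-probability bins,
#' Kolmogorov-Smirnov, Anderson-Darling) and ranks the families by each
#' statistic. The variable is declared normal when all three tests fail to
#' reject normality at `alpha` (KS and AD p-values are calibrated by a
#' parametric bootstrap, because parameters are estimated from the data);
#' otherwise the family with the best mean rank across the three statistics
#' is selected.
#'
#' @param x numeric sample (n >= 30, positive variance).
#' @param candidates candidate families (subset of
#'   `normal, lognormal, gamma, weibull, logistic, uniform, triangular`).
#' @param alpha significance level of the normality gate.
#' @param n_boot parametric-bootstrap resamples calibrating the KS and AD
#'   p-values under the fitted normal.
#' @param seed optional seed for the bootstrap.
#' @return an object of class `fitted_distribution`: the selected family
#'   and parameters, the GOF table (`gof`), the normality-gate p-values and
#'   a selection `rationale` (`"normal-by-default"` or `"best-ranked"`).
#' @export
fit_input_distribution <- function(x, candidates = dist_families(),
                                   alpha = 0.05, n_boot = 500, seed = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 30) stop_data("need at least 30 non-missing samples")
  if (stats::sd(x) == 0) stop_degenerate("constant sample: no distribution to fit")
  candidates <- match.arg(candidates, dist_families(), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)

  fits <- lapply(candidates, function(f) fit_family_mle(x, f))
  names(fits) <- candidates
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  if (length(fits) == 0) stop_fit("no candidate family could be fitted")
  gof <- data.frame(
    family = names(fits),
    chisq = vapply(fits, function(f) chisq_gof(x, f)$stat, numeric(1)),
    ks = vapply(fits, function(f) ks_stat(x, f), numeric(1)),
    ad = vapply(fits, function(f) ad_stat(x, f), numeric(1)))
  gof$rank_chisq <- rank(gof$chisq)
  gof$rank_ks <- rank(gof$ks)
  gof$rank_ad <- rank(gof$ad)
  gof$mean_rank <- (gof$rank_chisq + gof$rank_ks + gof$rank_ad) / 3
  rownames(gof) <- NULL

  normal_p <- c(chisq = NA_real_, ks = NA_real_, ad = NA_real_)
  is_normal <- FALSE
  if ("normal" %in% names(fits)) {
    nf <- fits[["normal"]]
    normal_p[["chisq"]] <- chisq_gof(x, nf)$p
    ks_obs <- ks_stat(x, nf)
    ad_obs <- ad_stat(x, nf)
    boot <- vapply(seq_len(n_boot), function(b) {
      xb <- stats::rnorm(n, nf$params$mean, nf$params$sd)
      fb <- fit_family_mle(xb, "normal")
      c(ks_stat(xb, fb), ad_stat(xb, fb))
    }, numeric(2))
    normal_p[["ks"]] <- mean(boot[1, ] >= ks_obs)
    normal_p[["ad"]] <- mean(boot[2, ] >= ad_obs)
    is_normal <- all(normal_p > alpha)
  }
  chosen <- if (is_normal) "normal" else
    gof$family[order(gof$mean_rank, gof$ad)][1]
  spec <- fits[[chosen]]
  structure(list(family = spec$family, params = spec$params, gof = gof,
                 normal_pvalues = normal_p,
                 rationale = if (is_normal) "normal-by-default" else
                   "best-ranked", n = n),
            class = c("fitted_distribution", "dist_spec"))
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat(sprintf("Fitted distribution: %s (%s; n = %d)\n", x$family,
              x$rationale, x$n))
  cat("Parameters:", paste(names(x$params), signif(unlist(x$params), 5),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# Iman-Conover rank-correlation induction on a uniform LHS matrix.
iman_conover <- function(u, target) {
  k <- ncol(u)
  if (!isTRUE(all.equal(target, t(target))) || nrow(target) != k) {
    stop_invalid("correlation target must be a symmetric k x k matrix")
  }
  ch <- tryCatch(chol(target),
                 error = function(e) stop_invalid(
                   "correlation target must be positive definite"))
  n <- nrow(u)
  scores <- stats::qnorm(seq_len(n) / (n + 1))
  M <- vapply(seq_len(k), function(j) sample(scores), numeric(n))
  Mstar <- M %*% solve(chol(stats::cor(M))) %*% ch
  out <- u
  for (j in seq_len(k)) out[, j] <- sort(u[, j])[rank(Mstar[, j],
                                                      ties.method = "first")]
  out
}

#' Latin hypercube sample from a set of distributions
#'
#' Draws exactly one value per equal-probability stratum `[(k-1)/n, k/n)`
#' for every variable (perfect marginal stratification), pairing strata
#' across variables at random. If a rank-correlation matrix is supplied,
#' the pairing is rearranged by Iman-Conover induction instead of being
#' independent.
#'
#' @param distributions named list of [dist_spec()] /
#'   [fit_input_distribution()] objects.
#' @param n number of samples (>= 2).
#' @param seed optional integer seed.
#' @param correlation optional target rank-correlation matrix (k x k,
#'   positive definite), variable order matching `distributions`.
#' @return data frame with one column per variable and `n` rows.
#' @export
lhs_sample <- function(distributions, n, seed = NULL, correlation = NULL) {
  if (n < 2) stop_invalid("need n >= 2 Latin hypercube samples")
  if (is.null(names(distributions)) || any(names(distributions) == "")) {
    stop_config("distributions must be a named list")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(distributions)
  u <- lhs::randomLHS(n, k)
  if (!is.null(correlation)) u <- iman_conover(u, correlation)
  out <- as.data.frame(mapply(function(d, j) q_dist(d, u[, j]),
                              distributions, seq_len(k), SIMPLIFY = FALSE))
  names(out) <- names(distributions)
  out
}

#' Standardized regression coefficients
#'
#' OLS of the output on z-scored inputs, each coefficient divided by the
#' output SD: the slope in output-SDs per input-SD used to rank input
#' influence (tornado-plot values).
#'
#' @param inputs data frame of model inputs.
#' @param output numeric model output, one value per row of `inputs`.
#' @return named numeric vector of standardized coefficients.
#' @export
standardized_coefficients <- function(inputs, output) {
  if (nrow(inputs) != length(output)) {
    stop_invalid("inputs and output must have matching lengths")
  }
  z <- scale(as.matrix(inputs))
  fit <- stats::lm.fit(cbind(1, z), output)
  stats::setNames(fit$coefficients[-1] / stats::sd(output), colnames(inputs))
}

#' Latin-hypercube sensitivity analysis of a prediction equation
#'
#' Appends Latin-hypercube batches until the running mean and SD of the
#' model output each change by less than `tolerance_pct` percent between
#' consecutive batches (at least 3 batches), then ranks the inputs by the
#' absolute standardized regression coefficient of the pooled sample.
#'
#' @param model function taking the (transformed) sample data frame and
#'   returning a numeric output per row; must be deterministic.
#' @param distributions named list of input distributions (>= 2 inputs
#'   after transformation).
#' @param batch_size samples per batch.
#' @param tolerance_pct convergence tolerance on the output mean and SD
#'   (percent change between consecutive batches).
#' @param seed optional integer seed (each batch derives its own stream).
#' @param max_samples cap on total samples; reaching it without convergence
#'   sets `converged = FALSE`.
#' @param correlation optional rank-correlation matrix for the sampled
#'   variables.
#' @param transform optional function applied to each sampled batch before
#'   the model is evaluated and before standardization (e.g. converting
#'   body weight to metabolic body weight); it receives and returns a data
#'   frame.
#' @return an object of class `sensitivity_result`: `coefficients`
#'   (standardized, named), `ranking` (variables by decreasing absolute
#'   coefficient), `n_samples`, `trace` (per-batch cumulative mean/SD),
#'   `converged`.
#' @export
run_sensitivity <- function(model, distributions, batch_size = 1000,
                            tolerance_pct = 1, seed = NULL,
                            max_samples = 1e6, correlation = NULL,
                            transform = identity) {
  if (length(distributions) < 1) stop_config("need at least one input")
  inputs <- NULL
  outputs <- numeric(0)
  trace <- data.frame(batch = integer(0), n = integer(0),
                      mean = numeric(0), sd = numeric(0))
  converged <- FALSE
  b <- 0L
  prev <- NULL
  while (length(outputs) < max_samples) {
    b <- b + 1L
    bseed <- if (is.null(seed)) NULL else derive_seed(seed, b)
    batch <- lhs_sample(distributions, batch_size, seed = bseed,
                        correlation = correlation)
    batch <- transform(batch)
    if (ncol(batch) < 2) stop_config("need >= 2 model inputs")
    out_b <- model(batch)
    if (anyNA(out_b)) stop_fit("model returned missing outputs")
    inputs <- rbind(inputs, batch)
    outputs <- c(outputs, out_b)
    cur <- c(mean = mean(outputs), sd = stats::sd(outputs))
    trace <- rbind(trace, data.frame(batch = b, n = length(outputs),
                                     mean = cur[["mean"]], sd = cur[["sd"]]))
    if (!is.null(prev) && b >= 3) {
      dmean <- abs(cur[["mean"]] - prev[["mean"]]) / abs(prev[["mean"]]) * 100
      dsd <- abs(cur[["sd"]] - prev[["sd"]]) / abs(prev[["sd"]]) * 100
      if (dmean < tolerance_pct && dsd < tolerance_pct) {
        converged <- TRUE
        break
      }
    }
    prev <- cur
  }
  coefs <- standardized_coefficients(inputs, outputs)
  structure(list(coefficients = coefs,
                 ranking = names(sort(abs(coefs), decreasing = TRUE)),
                 n_samples = length(outputs), trace = trace,
                 converged = converged),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("LHS sensitivity: %d samples, converged = %s\n",
              x$n_samples, x$converged))
  cat("Standardized regression coefficients (ranked):\n")
  print(round(x$coefficients[x$ranking], 3))
  invisible(x)
}

#' Pooled input distributions for the KFSD sensitivity analysis
#'
#' Normal input distributions at the pooled development + evaluation
#' database moments: BW ~ N(642, 50^2) kg, FCM ~ N(31.5, 6.8^2) kg/d,
#' NDF ~ N(33.4, 4.5^2) % DM. Body weight is sampled on the BW scale and
#' converted to metabolic body weight by the analysis transform.
#'
#' @return named list of [dist_spec()] objects (`bw`, `fcm`, `ndf`).
#' @export
pooled_input_distributions <- function() {
  list(bw = dist_spec("normal", mean = 642, sd = 50),
       fcm = dist_spec("normal", mean = 31.5, sd = 6.8),
       ndf = dist_spec("normal", mean = 33.4, sd = 4.5))
}

#' Sensitivity-analysis helpers for the KFSD equation
#'
#' `kfsd_sensitivity_transform()` converts a sampled `bw` column to `mbw`;
#' `kfsd_sensitivity_model()` returns a function evaluating the KFSD
#' equation (no lag) on a data frame with `mbw`, `fcm`, `ndf` columns.
#'
#' @param coef KFSD coefficients.
#' @return a transform function / a model function.
#' @export
kfsd_sensitivity_model <- function(coef = kfsd_coefficients()) {
  function(d) predict_kfsd(d$mbw, d$fcm, d$ndf, coef = coef)
}

#' @rdname kfsd_sensitivity_model
#' @export
kfsd_sensitivity_transform <- function() {
  function(d) {
    if ("bw" %in% names(d)) {
      d$mbw <- metabolic_bw(d$bw)
      d$bw <- NULL
      d <- d[, c("mbw", setdiff(names(d), "mbw")), drop = FALSE]
    }
    d
  }
}
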