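# Seeded synthetic-data generators with known ground truth:
# (a) literature-like study-clustered treatment means drawn around the
#     development-database moments, with DMI generated from a known
#     equation plus study random intercepts and residual noise;
# (b) farm-trial-like monthly per-cow records with an optional cold-season
#     intake offset.

#' Configuration for the literature-database generator
#'
#' Defaults reproduce the development-database conditions: 103 studies and
#' 458 treatment means with 4–5 observations per study; body weight, milk
#' yield, milk fat and dietary composition drawn from truncated normals at
#' the development-database moments (BW 640.33 ± 50.29 kg, MY 34.43 ± 5.81
#' kg/d, fat 3.49 ± 0.46 %, NDF 33.35 ± 4.51 % DM, FpDM 53.35 ± 12.82 %,
#' CP 16.93 ± 1.76 %, ADF 20.27 ± 3.39 %, starch 24.31 ± 6.28 %); FCM
#' derived from MY and fat so milk variables stay mutually consistent; DMI
#' generated from the KFSD equation plus study intercepts (SD 1.5 kg/d) and
#' residual noise (SD 1.0 kg/d). Truncation bounds enforce the inclusion
#' filters (NDF >= 25, FpDM in [30, 100)), so generated tables pass the
#' filters by construction.
#'
#' @param n_studies number of studies.
#' @param n_obs total number of treatment means; allocated as evenly as
#'   possible across studies within `obs_per_study`.
#' @param obs_per_study allowed range `c(min, max)` of observations per
#'   study.
#' @param coef true generating coefficients ([kfsd_coefficients()]).
#' @param study_sd SD of the study random intercept (kg/d).
#' @param residual_sd residual SD (kg/d).
#' @param moments named list of `c(mean, sd)` pairs for `bw`, `my`, `fat`,
#'   `ndf`, `fpdm`, `cp`, `adf`, `starch`, `wol`.
#' @param apply_lag multiply the deterministic equation by the `Lag[2]`
#'   early-lactation multiplier.
#' @param prop_primiparous proportion of primiparous records.
#' @param seed integer seed.
#' @return an object of class `literature_gen_config`.
#' @export
literature_gen_config <- function(n_studies = 103, n_obs = 458,
                                  obs_per_study = c(4, 5),
                                  coef = kfsd_coefficients(),
                                  study_sd = 1.5, residual_sd = 1.0,
                                  moments = list(
                                    bw = c(640.33, 50.29),
                                    my = c(34.43, 5.81),
                                    fat = c(3.49, 0.46),
                                    ndf = c(33.35, 4.51),
                                    fpdm = c(53.35, 12.82),
                                    cp = c(16.93, 1.76),
                                    adf = c(20.27, 3.39),
                                    starch = c(24.31, 6.28),
                                    wol = c(15, 8)),
                                  apply_lag = FALSE,
                                  prop_primiparous = 0.3, seed = NULL) {
  if (n_studies < 1 || n_obs < n_studies) {
    stop_config("need n_obs >= n_studies >= 1")
  }
  if (study_sd < 0 || residual_sd < 0) stop_config("SDs must be >= 0")
  if (n_obs < n_studies * obs_per_study[1] ||
      n_obs > n_studies * obs_per_study[2]) {
    stop_config("n_obs not attainable within obs_per_study range")
  }
  need <- c("bw", "my", "fat", "ndf", "fpdm", "cp", "adf", "starch", "wol")
  if (!all(need %in% names(moments))) {
    stop_config(sprintf("moments must include: %s", paste(need, collapse = ", ")))
  }
  structure(list(n_studies = n_studies, n_obs = n_obs,
                 obs_per_study = obs_per_study, coef = coef,
                 study_sd = study_sd, residual_sd = residual_sd,
                 moments = moments, apply_lag = apply_lag,
                 prop_primiparous = prop_primiparous, seed = seed),
            class = "literature_gen_config")
}

#' Generate a literature-like treatment-mean table
#'
#' Draws study-clustered treatment means under the configured moments and
#' generates observed DMI as `deterministic equation + study intercept +
#' residual`. Ground-truth components are carried in dot-prefixed columns
#' (`.mu`, `.study_effect`, `.resid`) so recovery can be checked exactly;
#' records whose sampled DMI would violate the `DMIpBW >= 2` inclusion rule
#' (or be non-positive) have their residual redrawn, keeping every
#' generated record inside the filtered domain.
#'
#' @param config a [literature_gen_config()].
#' @return data frame in the canonical record schema (plus `breed`,
#'   `treatment_id` and the truth columns).
#' @export
generate_literature <- function(config) {
  stopifnot(inherits(config, "literature_gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- config$n_studies
  lo <- config$obs_per_study[1]
  sizes <- rep(lo, ns)
  extra <- config$n_obs - sum(sizes)
  if (extra > 0) {
    bump <- config$obs_per_study[2] - lo
    take <- rep(seq_len(ns), each = bump)[seq_len(extra)]
    for (i in take) sizes[i] <- sizes[i] + 1L
  }
  n <- sum(sizes)
  mo <- config$moments
  tn <- function(v, lower = -Inf, upper = Inf) {
    rtrunc_norm(n, mo[[v]][1], mo[[v]][2], lower, upper)
  }
  bw <- tn("bw", lower = 300, upper = 1000)
  my <- tn("my", lower = 5)
  fat <- tn("fat", lower = 1, upper = 7)
  ndf <- tn("ndf", lower = 25, upper = 66)
  fpdm <- tn("fpdm", lower = 30, upper = 99.9)
  cp <- tn("cp", lower = 5)
  adf <- pmin(tn("adf", lower = 3), ndf - 0.5)
  starch <- tn("starch", lower = 1)
  wol <- pmax(1, round(tn("wol", lower = 1, upper = 45)))
  parity <- ifelse(stats::runif(n) < config$prop_primiparous,
                   "primiparous", "multiparous")
  study_id <- rep(sprintf("S%03d", seq_len(ns)), times = sizes)
  fcm <- fcm_4pct(my, fat)
  mbw <- metabolic_bw(bw)
  b <- config$coef$coefficients
  mu <- b[["intercept"]] + b[["b_mbw"]] * mbw + b[["b_fcm"]] * fcm +
    b[["b_ndf"]] * ndf
  if (config$apply_lag) mu <- mu * lag_multiplier(lag_spec(2), wol)
  u <- rep(stats::rnorm(ns, 0, config$study_sd), times = sizes)
  e <- stats::rnorm(n, 0, config$residual_sd)
  dmi <- mu + u + e
  # keep records inside the filtered domain (DMIpBW >= 2, DMI > 0)
  for (attempt in seq_len(1e4)) {
    bad <- dmi <= 0 | 100 * dmi / bw < 2
    if (!any(bad)) break
    e[bad] <- stats::rnorm(sum(bad), 0, config$residual_sd)
    dmi[bad] <- mu[bad] + u[bad] + e[bad]
    if (config$residual_sd == 0) {
      stop_config("deterministic DMI violates the inclusion filters")
    }
  }
  data.frame(study_id = study_id,
             treatment_id = paste0(study_id, "-T",
                                   unlist(lapply(sizes, seq_len))),
             cow_id = NA_character_, breed = "Holstein",
             bw_kg = bw, my_kg_d = my, fat_pct = fat, wol = wol,
             parity = parity, ndf_pct_dm = ndf, cp_pct_dm = cp,
             adf_pct_dm = adf, starch_pct_dm = starch, fpdm_pct = fpdm,
             dmi_kg_d = dmi, .mu = mu, .study_effect = u, .resid = e,
             stringsAsFactors = FALSE)
}

#' Configuration for the farm-trial generator
#'
#' Defaults emulate a November–June feeding trial (February removed) on 32
#' Holstein cows milked and fed automatically, at the trial's monthly
#' moments: BW 751 ± 79.5 kg, MY 31.2 ± 7.13 kg/d, fat 4.2 ± 0.63 %,
#' dietary NDF 40.0 ± 0.98 % DM. Observed DMI is generated from the KFSD
#' equation plus residual noise (SD 2.4 kg/d) and, in cold-season months
#' (Nov–Jan), an additive intake offset (default 0) emulating
#' cold-weather intake above the thermoneutral prediction.
#'
#' @param n_cows number of cows.
#' @param months month labels, a subset of Nov–Jun without Feb.
#' @param moments named list of `c(mean, sd)` for `bw`, `my`, `fat`, `ndf`.
#' @param residual_sd residual SD of observed DMI around the generating
#'   equation (kg/d).
#' @param cold_offset additive DMI offset in Nov–Jan records (kg/d).
#' @param n_primiparous number of primiparous cows.
#' @param coef generating coefficients.
#' @param seed integer seed.
#' @return an object of class `farm_gen_config`.
#' @export
farm_gen_config <- function(n_cows = 32,
                            months = c("Nov", "Dec", "Jan", "Mar", "Apr",
                                       "May", "Jun"),
                            moments = list(bw = c(751, 79.5),
                                           my = c(31.2, 7.13),
                                           fat = c(4.2, 0.63),
                                           ndf = c(40.0, 0.98)),
                            residual_sd = 2.4, cold_offset = 0,
                            n_primiparous = 11,
                            coef = kfsd_coefficients(), seed = NULL) {
  valid <- c("Nov", "Dec", "Jan", "Mar", "Apr", "May", "Jun")
  if (n_cows < 1 || length(months) == 0) {
    stop_config("need at least one cow and one month")
  }
  if (!all(months %in% valid)) {
    stop_config(sprintf("months must be in: %s", paste(valid, collapse = ", ")))
  }
  if (!is.finite(cold_offset)) stop_config("cold_offset must be finite")
  structure(list(n_cows = n_cows, months = months, moments = moments,
                 residual_sd = residual_sd, cold_offset = cold_offset,
                 n_primiparous = min(n_primiparous, n_cows), coef = coef,
                 seed = seed),
            class = "farm_gen_config")
}

#' Generate a farm-trial-like monthly record table
#'
#' One record per cow per month: cow-level body weight and milk level
#' persist across months (with small monthly wander), the shared ration
#' NDF varies by month, week of lactation advances by ~4.3 weeks/month
#' from a cow-specific start, and observed DMI is the KFSD prediction plus
#' residual noise plus the cold-season offset in Nov–Jan. DMI is split
#' into TMR and concentrate components (reported but unused by the
#' prediction equations), and records beyond 3 SD of the cow's own mean
#' DMI are flagged in the `outlier` column.
#'
#' @param config a [farm_gen_config()].
#' @return data frame in the canonical schema plus `month`, `season`,
#'   `tmr_dmi_kg_d`, `conc_dmi_kg_d`, `outlier` and truth column `.mu`.
#' @export
generate_farm <- function(config) {
  stopifnot(inherits(config, "farm_gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nc <- config$n_cows
  months <- config$months
  nm <- length(months)
  mo <- config$moments
  cow_bw <- rtrunc_norm(nc, mo$bw[1], mo$bw[2], 400, 1100)
  cow_my <- rtrunc_norm(nc, mo$my[1], mo$my[2], 3, 60)
  cow_fat <- rtrunc_norm(nc, mo$fat[1], mo$fat[2], 1.5, 8)
  cow_wol0 <- sample(1:30, nc, replace = TRUE)
  parity <- c(rep("primiparous", config$n_primiparous),
              rep("multiparous", nc - config$n_primiparous))
  month_ndf <- rtrunc_norm(nm, mo$ndf[1], mo$ndf[2], 30, 50)
  grid <- expand.grid(cow = seq_len(nc), m = seq_len(nm))
  bw <- pmax(400, cow_bw[grid$cow] + stats::rnorm(nrow(grid), 0, 10))
  my <- pmax(1, cow_my[grid$cow] + stats::rnorm(nrow(grid), 0, 2))
  fat <- pmin(8, pmax(1.5, cow_fat[grid$cow] +
                        stats::rnorm(nrow(grid), 0, 0.15)))
  ndf <- month_ndf[grid$m]
  wol <- cow_wol0[grid$cow] + round(4.345 * (grid$m - 1))
  fcm <- fcm_4pct(my, fat)
  b <- config$coef$coefficients
  mu <- b[["intercept"]] + b[["b_mbw"]] * metabolic_bw(bw) +
    b[["b_fcm"]] * fcm + b[["b_ndf"]] * ndf
  month <- months[grid$m]
  cold <- month %in% c("Nov", "Dec", "Jan")
  dmi <- mu + stats::rnorm(nrow(grid), 0, config$residual_sd) +
    ifelse(cold, config$cold_offset, 0)
  dmi <- pmax(dmi, 1)
  tmr_share <- pmin(0.95, pmax(0.6, stats::rnorm(nrow(grid), 0.79, 0.04)))
  out <- data.frame(study_id = "farm",
                    cow_id = sprintf("C%02d", grid$cow),
                    breed = "Holstein", month = month,
                    season = ifelse(cold, "cold", "warm"),
                    bw_kg = bw, my_kg_d = my, fat_pct = fat, wol = wol,
                    parity = parity[grid$cow], ndf_pct_dm = ndf,
                    cp_pct_dm = 12.5, adf_pct_dm = 24.5,
                    starch_pct_dm = NA_real_, fpdm_pct = NA_real_,
                    dmi_kg_d = dmi,
                    tmr_dmi_kg_d = tmr_share * dmi,
                    conc_dmi_kg_d = (1 - tmr_share) * dmi,
                    .mu = mu, stringsAsFactors = FALSE)
  cow_mean <- stats::ave(out$dmi_kg_d, out$cow_id)
  cow_sd <- stats::ave(out$dmi_kg_d, out$cow_id,
                       FUN = function(x) if (length(x) > 1) stats::sd(x) else Inf)
  out$outlier <- abs(out$dmi_kg_d - cow_mean) > 3 * cow_sd
  out[order(out$cow_id, match(out$month, months)), ]
}
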