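# Closed-form prediction equations, lag multipliers and unit conversions.

test_that("fat-corrected milk follows the Gaines form and its identities", {
  expect_identical(fcm_4pct(30, 4), 30)          # identity at 4% fat
  expect_identical(fcm_4pct(0, 3.5), 0)
  # independent scalar arithmetic: 0.4*MY + 15*(fat/100)*MY
  expect_equal(fcm_4pct(33.89, 3.60), 0.4 * 33.89 + 15 * 0.036 * 33.89)
  expect_equal(round(fcm_4pct(33.89, 3.60), 2), 31.86)
  # linear in MY at fixed fat
  my <- c(1, 5, 20, 41)
  expect_equal(fcm_4pct(3 * my, 3.2), 3 * fcm_4pct(my, 3.2))
  expect_error(fcm_4pct(-1, 4), class = "dmi_invalid_input")
  expect_error(fcm_4pct(10, 0), class = "dmi_invalid_input")
  expect_error(fcm_4pct(10, 15), class = "dmi_invalid_input")
})

test_that("metabolic body weight is BW^0.75", {
  expect_identical(metabolic_bw(1), 1)
  expect_equal(metabolic_bw(16), 8)
  expect_equal(metabolic_bw(640), exp(0.75 * log(640)))
  expect_error(metabolic_bw(0), class = "dmi_invalid_input")
  expect_error(metabolic_bw(-5), class = "dmi_invalid_input")
})

test_that("lag multipliers match the printed constants and stay in (0, 1)", {
  l2 <- lag_spec(2)
  l3 <- lag_spec(3)
  expect_equal(l2$rate, 0.316)
  expect_equal(l2$offset, 2.36)
  expect_equal(lag_multiplier(l2, 4), 1 - exp(-0.316 * 6.36))
  expect_equal(round(lag_multiplier(l2, 4), 3), 0.866)
  expect_equal(lag_multiplier(l3, 20), 1 - exp(-0.192 * 23.67))
  expect_equal(round(lag_multiplier(l3, 20), 4), 0.9894)
  # rate override supports the 0.318 variant
  expect_equal(lag_spec(2, rate = 0.318)$rate, 0.318)
  expect_error(lag_multiplier(l2, 0.5), class = "dmi_invalid_input")
})

test_that("lag multipliers are strictly increasing and converge to 1", {
  wol <- 1:60
  for (spec in list(lag_spec(2), lag_spec(3))) {
    m <- lag_multiplier(spec, wol)
    expect_true(all(diff(m) > 0))
    expect_true(all(m > 0 & m < 1))
  }
  # predictions with lag converge to the no-lag value
  base <- predict_kfsd(127.25, 31.2, 33.4)
  lagged <- predict_kfsd(127.25, 31.2, 33.4, lag = lag_spec(2), wol = 60)
  expect_lt(abs(base - lagged), 1e-6)
})

test_that("KFSD prediction reproduces the published coefficient arithmetic", {
  expect_equal(predict_kfsd(127.25, 31.2, 33.4),
               4.103 + 0.112 * 127.25 + 0.284 * 31.2 - 0.119 * 33.4)
  expect_equal(round(predict_kfsd(127.25, 31.2, 33.4), 2), 23.24)
  degen <- kfsd_coefficients(b_mbw = 0, b_fcm = 0, b_ndf = 0,
                             se = c(intercept = 0, b_mbw = 0, b_fcm = 0,
                                    b_ndf = 0))
  expect_equal(predict_kfsd(127.25, 31.2, 33.4, coef = degen), 4.103)
  expect_error(predict_kfsd(NA, 31.2, 33.4), class = "dmi_missing_predictor")
  expect_error(predict_kfsd(127.25, NA, 33.4), class = "dmi_missing_predictor")
  expect_error(predict_kfsd(127.25, 31.2, NA), class = "dmi_missing_predictor")
  # negative linear predictions clamp at 0 with a warning
  neg <- kfsd_coefficients(intercept = -100, b_mbw = 0, b_fcm = 0, b_ndf = 0,
                           se = c(intercept = 0, b_mbw = 0, b_fcm = 0,
                                  b_ndf = 0))
  expect_warning(p <- predict_kfsd(127.25, 31.2, 33.4, coef = neg),
                 "clamped")
  expect_identical(p, 0)
})

test_that("comparator equations match independent scalar oracles", {
  expect_identical(predict_nrc(0, 0, lag = NULL), 0)
  expect_identical(predict_cncps(0, 0, lag = NULL), 0)
  expect_equal(predict_nrc(640, 32, lag = NULL), 0.372 * 32 + 0.0968 * 640^0.75)
  expect_equal(round(predict_nrc(640, 32, lag = NULL), 2), 24.22)
  expect_equal(predict_nrc(640, 32, wol = 20, lag = lag_spec(3)),
               (0.372 * 32 + 0.0968 * 640^0.75) * (1 - exp(-0.192 * 23.67)))
  expect_equal(round(predict_nrc(640, 32, wol = 20, lag = lag_spec(3)), 1),
               24.0)
  expect_equal(predict_cncps(640, 32, lag = NULL), 0.0185 * 640 + 0.305 * 32)
  expect_equal(round(predict_cncps(640, 32, wol = 4, lag = lag_spec(2)), 2),
               round(21.6 * (1 - exp(-0.316 * 6.36)), 2))
  # JFS parity-specific forms, lactation adjustment saturated at large WOL
  expect_equal(predict_jfs(1, 0, 1000, "multiparous"), 1.3922 + 0.05839,
               tolerance = 1e-7)
  expect_equal(predict_jfs(640, 32, 1e4, "multiparous"),
               1.3922 + 0.05839 * 640^0.75 + 0.40497 * 32, tolerance = 1e-7)
  expect_equal(predict_jfs(640, 32, 1e4, "primiparous"),
               1.9120 + 0.07031 * 640^0.75 + 0.34923 * 32 * 1.3671,
               tolerance = 1e-7)
  expect_error(predict_jfs(640, 32, 10, "heifer"),
               class = "dmi_invalid_input")
})

test_that("no-lag predictions are homogeneous in their coefficients", {
  set.seed(11)
  n <- 1000
  mbw <- runif(n, 80, 160)
  fcm <- runif(n, 10, 50)
  ndf <- runif(n, 25, 60)
  co <- kfsd_coefficients()
  doubled <- kfsd_coefficients(intercept = 2 * 4.103, b_mbw = 2 * 0.112,
                               b_fcm = 2 * 0.284, b_ndf = 2 * -0.119)
  expect_equal(predict_kfsd(mbw, fcm, ndf, coef = doubled),
               2 * predict_kfsd(mbw, fcm, ndf, coef = co))
  # brute-force scalar oracle, elementwise
  oracle <- 4.103 + 0.112 * mbw + 0.284 * fcm - 0.119 * ndf
  expect_equal(predict_kfsd(mbw, fcm, ndf), oracle)
})

test_that("batch prediction equals mapped scalar prediction bit-for-bit", {
  empty <- make_record()[0, ]
  expect_length(as.numeric(predict_dmi(empty, "kfsd")), 0)

  one <- make_record()
  p1 <- predict_dmi(one, "kfsd")
  expect_identical(as.numeric(p1),
                   predict_kfsd(metabolic_bw(one$bw_kg),
                                fcm_4pct(one$my_kg_d, one$fat_pct),
                                one$ndf_pct_dm))

  set.seed(21)
  recs <- do.call(rbind, replicate(100, make_record(
    bw_kg = runif(1, 450, 850), my_kg_d = runif(1, 15, 50),
    fat_pct = runif(1, 2.5, 5), wol = sample(1:40, 1),
    ndf_pct_dm = runif(1, 25, 50),
    parity = sample(c("primiparous", "multiparous"), 1)),
    simplify = FALSE))
  for (model in c("kfsd", "kfsd_lag2", "nrc", "cncps", "jfs")) {
    batch <- as.numeric(predict_dmi(recs, model))
    scalar <- vapply(seq_len(nrow(recs)), function(i) {
      as.numeric(predict_dmi(recs[i, ], model))
    }, numeric(1))
    expect_identical(batch, scalar)
  }
})

test_that("batch prediction flags bad records instead of aborting", {
  recs <- rbind(make_record(),
                make_record(ndf_pct_dm = NA),
                make_record(bw_kg = -5))
  p <- predict_dmi(recs, "kfsd")
  st <- attr(p, "status")
  expect_identical(st[1], "ok")
  expect_match(st[2], "ndf_pct_dm")
  expect_match(st[3], "bw_kg")
  expect_true(!is.na(p[1]) && all(is.na(p[2:3])))
  expect_error(predict_dmi(recs, "frobnicate"), class = "dmi_config_error")
  expect_error(predict_dmi(recs[, setdiff(names(recs), "ndf_pct_dm")], "kfsd"),
               class = "dmi_schema_error")
})
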