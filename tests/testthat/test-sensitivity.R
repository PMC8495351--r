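# Distribution fitting, Latin hypercube sampling and the standardized
# regression sensitivity analysis.

test_that("distribution specs validate parameters and invert correctly", {
  expect_error(dist_spec("normal", mean = 0, sd = -1),
               class = "dmi_config_error")
  expect_error(dist_spec("uniform", min = 2, max = 1),
               class = "dmi_config_error")
  expect_error(dist_spec("gamma", shape = 2), class = "dmi_config_error")
  tri <- dist_spec("triangular", min = 0, mode = 2, max = 10)
  p <- seq(0.01, 0.99, by = 0.01)
  q <- q_dist(tri, p)
  expect_true(all(diff(q) > 0))
  expect_equal(kfsdmi:::p_dist(tri, q), p, tolerance = 1e-10)
})

test_that("Latin hypercube sampling stratifies every margin perfectly", {
  d <- list(u = dist_spec("uniform", min = 0, max = 1))
  x <- lhs_sample(d, 4, seed = 61)$u
  expect_identical(as.integer(table(cut(x, seq(0, 1, 0.25)))),
                   rep(1L, 4))
  # general case: back-transformed probabilities hit each stratum once
  dists <- list(bw = dist_spec("normal", mean = 642, sd = 50),
                fcm = dist_spec("gamma", shape = 20, rate = 0.6))
  n <- 200
  smp <- lhs_sample(dists, n, seed = 62)
  for (v in names(dists)) {
    u <- kfsdmi:::p_dist(dists[[v]], smp[[v]])
    strata <- findInterval(u, seq(0, 1, length.out = n + 1),
                           rightmost.closed = TRUE)
    expect_identical(sort(strata), 1:n)
  }
  # seeded determinism
  expect_identical(lhs_sample(dists, 50, seed = 63),
                   lhs_sample(dists, 50, seed = 63))
  expect_error(lhs_sample(dists, 1), class = "dmi_invalid_input")
})

test_that("LHS variance reduction: the sample mean is extremely tight", {
  d <- list(x = dist_spec("normal", mean = 31.5, sd = 6.8))
  x <- lhs_sample(d, 10000, seed = 64)$x
  expect_lt(abs(mean(x) - 31.5), 0.02 * 6.8)
})

test_that("Iman-Conover induces the requested rank correlation", {
  dists <- list(a = dist_spec("normal", mean = 0, sd = 1),
                b = dist_spec("lognormal", meanlog = 0, sdlog = 0.5))
  target <- matrix(c(1, 0.7, 0.7, 1), 2)
  smp <- lhs_sample(dists, 500, seed = 65, correlation = target)
  expect_lt(abs(cor(smp$a, smp$b, method = "spearman") - 0.7), 0.05)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(lhs_sample(dists, 100, seed = 65, correlation = bad),
               class = "dmi_invalid_input")
})

test_that("normal data is recognised as normal with recovered parameters", {
  set.seed(66)
  x <- rnorm(2000, 33.4, 4.5)
  fd <- fit_input_distribution(x, n_boot = 200, seed = 67)
  expect_identical(fd$family, "normal")
  expect_identical(fd$rationale, "normal-by-default")
  expect_lt(abs(fd$params$mean - 33.4), 2 * 4.5 / sqrt(2000))
  expect_lt(abs(fd$params$sd - 4.5), 2 * 4.5 / sqrt(2 * 2000))
})

test_that("heavily skewed data rejects normality and picks a skewed family", {
  set.seed(68)
  x <- rlnorm(2000, meanlog = 1, sdlog = 0.9)
  fd <- fit_input_distribution(x, n_boot = 200, seed = 69)
  expect_false(fd$family == "normal")
  expect_identical(fd$rationale, "best-ranked")
  # GOF ranks are a permutation over the fitted families
  expect_setequal(fd$gof$rank_ad, seq_len(nrow(fd$gof)))
  expect_error(fit_input_distribution(rep(5, 100)),
               class = "dmi_degenerate_input")
  expect_error(fit_input_distribution(rnorm(10)), class = "dmi_data_error")
})

test_that("standardized coefficients match the closed form for linear models", {
  dists <- list(x1 = dist_spec("normal", mean = 10, sd = 2),
                x2 = dist_spec("normal", mean = 5, sd = 4),
                x3 = dist_spec("normal", mean = 0, sd = 1))
  model <- function(d) 3 + 2 * d$x1 - 0.5 * d$x2   # x3 ignored
  smp <- lhs_sample(dists, 5000, seed = 70)
  out <- model(smp)
  sc <- standardized_coefficients(smp, out)
  sd_out <- sqrt((2 * 2)^2 + (0.5 * 4)^2)
  expect_equal(sc[["x1"]], 2 * 2 / sd_out, tolerance = 0.02)
  expect_equal(sc[["x2"]], -0.5 * 4 / sd_out, tolerance = 0.02)
  expect_lt(abs(sc[["x3"]]), 0.02)
  # squared coefficients sum to ~1 for a deterministic linear model
  expect_equal(sum(sc^2), 1, tolerance = 0.01)
})

test_that("ranking is invariant to affine rescaling of an input", {
  dists_a <- list(x1 = dist_spec("normal", mean = 10, sd = 2),
                  x2 = dist_spec("normal", mean = 5, sd = 4))
  model_a <- function(d) 2 * d$x1 + 0.8 * d$x2
  # rescale x2 -> 10*x2 + 3 and compensate in the model
  dists_b <- list(x1 = dist_spec("normal", mean = 10, sd = 2),
                  x2 = dist_spec("normal", mean = 53, sd = 40))
  model_b <- function(d) 2 * d$x1 + 0.08 * (d$x2 - 3)
  sa <- standardized_coefficients(s_a <- lhs_sample(dists_a, 3000, seed = 71),
                                  model_a(s_a))
  sb <- standardized_coefficients(s_b <- lhs_sample(dists_b, 3000, seed = 71),
                                  model_b(s_b))
  expect_equal(unname(sa), unname(sb), tolerance = 1e-8)
})

test_that("the batch loop converges and is reproducible", {
  res <- run_sensitivity(kfsd_sensitivity_model(),
                         pooled_input_distributions(),
                         batch_size = 500, seed = 72,
                         transform = kfsd_sensitivity_transform())
  expect_true(res$converged)
  expect_gte(nrow(res$trace), 3)
  expect_identical(res$ranking[1], "fcm")
  res2 <- run_sensitivity(kfsd_sensitivity_model(),
                          pooled_input_distributions(),
                          batch_size = 500, seed = 72,
                          transform = kfsd_sensitivity_transform())
  expect_identical(res$coefficients, res2$coefficients)
  # an unreachable tolerance leaves converged = FALSE with a full trace
  res3 <- run_sensitivity(kfsd_sensitivity_model(),
                          pooled_input_distributions(),
                          batch_size = 500, tolerance_pct = 1e-8,
                          seed = 73, max_samples = 2000,
                          transform = kfsd_sensitivity_transform())
  expect_false(res3$converged)
  expect_identical(res3$n_samples, 2000L)
})
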