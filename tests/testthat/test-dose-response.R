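# 4PL fitting, inhibition summaries and the control comparison.

make_noiseless <- function(bottom = 0, top = 83, ic50 = 27.32, slope = 1.5,
                           conc = 10^seq(0, 2, length.out = 6), reps = 2) {
  mu <- bottom + (top - bottom) / (1 + (conc / ic50)^slope)
  data.frame(concentration = rep(conc, each = reps),
             response = rep(mu, each = reps))
}

test_that("noiseless 4PL data are recovered to 1e-6 relative error", {
  truth <- c(bottom = 5, top = 83, ic50 = 27.32, slope = 1.5)
  fit <- fit_4pl(make_noiseless(5, 83, 27.32, 1.5))
  expect_true(fit$converged)
  expect_equal(coef(fit), truth, tolerance = 1e-6)
  expect_lt(fit$residual_sse, 1e-8)
})

test_that("IC50 is equivariant under concentration rescaling", {
  d <- make_noiseless()
  f1 <- fit_4pl(d)
  d10 <- transform(d, concentration = concentration * 10)
  f2 <- fit_4pl(d10)
  expect_equal(coef(f2)[["ic50"]], 10 * coef(f1)[["ic50"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["slope"]], coef(f1)[["slope"]], tolerance = 1e-6)
})

test_that("refitting on fitted values is a fixed point", {
  d <- generate_dose_response(c(bottom = 0, top = 83, ic50 = 25, slope = 1.5),
                              10^seq(0, 2, length.out = 6), n_reps = 4,
                              noise_sd = 2, seed = 12)
  names(d)[names(d) == "response"] <- "response"
  f1 <- fit_4pl(d)
  d2 <- data.frame(concentration = d$concentration, response = predict(f1))
  f2 <- fit_4pl(d2)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-5)
})

test_that("degenerate dose-response data are rejected, not fitted", {
  flat <- data.frame(concentration = rep(c(1, 3, 10, 30), each = 3),
                     response = 50)
  expect_error(fit_4pl(flat), class = "herbnet_fit_error")
  few <- data.frame(concentration = rep(c(1, 10, 100), each = 4),
                    response = c(80, 80, 80, 80, 40, 40, 40, 40, 5, 5, 5, 5))
  expect_error(fit_4pl(few), class = "herbnet_fit_error")
  neg <- data.frame(concentration = c(-1, 1, 10, 100), response = 1:4)
  expect_error(fit_4pl(neg), class = "herbnet_domain_error")
})

test_that("noisy IC50 recovery is accurate at assay-realistic noise", {
  errs <- vapply(1:10, function(s) {
    d <- generate_dose_response(c(bottom = 0, top = 83, ic50 = 25, slope = 1.5),
                                10^seq(0, 2, length.out = 6), n_reps = 4,
                                noise_sd = 2, seed = s)
    abs(coef(fit_4pl(d))[["ic50"]] - 25) / 25
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("tidy, glance and autoplot expose the fit", {
  f <- fit_4pl(make_noiseless())
  td <- tidy(f)
  expect_identical(td$term, c("bottom", "top", "ic50", "slope"))
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$ic50, coef(f)[["ic50"]])
  expect_s3_class(autoplot(f), "ggplot")
  expect_output(print(f), "IC50")
})

test_that("simulated replicates follow the 4PL with truncated Gaussian noise", {
  conc <- 10^seq(0, 2, length.out = 6)
  # zero noise: exact closed form, midpoint identity at c = ic50
  d0 <- generate_dose_response(c(bottom = 10, top = 80, ic50 = 20, slope = 2),
                               conc, n_reps = 3, noise_sd = 0, seed = 1)
  mu <- 10 + (80 - 10) / (1 + (d0$concentration / 20)^2)
  expect_equal(d0$response, mu, tolerance = 1e-12)
  mid <- generate_dose_response(c(bottom = 10, top = 80, ic50 = 20, slope = 2),
                                20, n_reps = 5, noise_sd = 0, seed = 1)
  expect_equal(mid$response, rep(45, 5))

  # determinism and truncation
  d1 <- generate_dose_response(c(bottom = 0, top = 83, ic50 = 27, slope = 1.5),
                               conc, n_reps = 4, noise_sd = 2, seed = 3)
  d2 <- generate_dose_response(c(bottom = 0, top = 83, ic50 = 27, slope = 1.5),
                               conc, n_reps = 4, noise_sd = 2, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$response >= 0 & d1$response <= 100))

  expect_error(generate_dose_response(c(bottom = 0, top = 83, ic50 = -1,
                                        slope = 1), conc),
               class = "herbnet_domain_error")
  expect_error(generate_dose_response(c(bottom = 0, top = 83, ic50 = 10,
                                        slope = 1), c(0, 1)),
               class = "herbnet_domain_error")
})

test_that("per-concentration replicate SD stays near the nominal noise", {
  conc <- seq(1, 100, length.out = 20)
  frac_in <- vapply(1:200, function(s) {
    d <- generate_dose_response(c(bottom = 0, top = 83, ic50 = 27.32,
                                  slope = 1.5), conc, n_reps = 4,
                                noise_sd = 2, seed = s)
    sds <- tapply(d$response, d$concentration, sd)
    mean(sds >= 0.5 & sds <= 5)
  }, numeric(1))
  expect_gte(mean(frac_in), 0.95)
})

test_that("percent inhibition interpolates between agonist and baseline", {
  expect_equal(percent_inhibition(120, 120, 1), 0)
  expect_equal(percent_inhibition(120, 1, 1), 100)
  expect_equal(percent_inhibition(120.09, 28.23, 1.12),
               (120.09 - 28.23) / (120.09 - 1.12) * 100, tolerance = 1e-12)
  # monotone decreasing in the treated mean
  vals <- vapply(seq(1.12, 120, length.out = 20), function(tr) {
    percent_inhibition(120.09, tr, 1.12)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_warning(out <- percent_inhibition(100, 120, 0), "clipping")
  expect_equal(out, 0)
  expect_error(percent_inhibition(1, 5, 2), class = "herbnet_domain_error")
})

test_that("control comparison assigns stars at the printed thresholds", {
  same <- compare_to_control(c(10, 10, 10, 10), c(10, 10, 10, 10))
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "")

  sep <- compare_to_control(c(10, 10.1, 9.9, 10), c(80, 80.2, 79.9, 80.1))
  expect_lt(sep$p_value, 0.001)
  expect_identical(sep$stars, "**")

  rank_based <- compare_to_control(c(1, 2, 3, 4), c(10, 11, 12, 13),
                                   method = "wilcoxon")
  expect_lt(rank_based$p_value, 0.05)
  expect_error(compare_to_control(1, c(1, 2)), class = "herbnet_input_error")
})

test_that("inhibition summaries reproduce condition-level arithmetic", {
  withr::with_seed(44, {
    tab <- rbind(
      data.frame(condition = "baseline", value = rnorm(4, 1.12, 0.2)),
      data.frame(condition = "collagen", value = rnorm(4, 120.1, 5)),
      data.frame(condition = "drug32", value = rnorm(4, 28.2, 2.4)))
    out <- summarize_inhibition(tab, agonist = "collagen", baseline = "baseline")
    expect_identical(out$condition, "drug32")
    expect_equal(out$mean, mean(tab$value[tab$condition == "drug32"]))
    manual <- percent_inhibition(mean(tab$value[tab$condition == "collagen"]),
                                 out$mean,
                                 mean(tab$value[tab$condition == "baseline"]))
    expect_equal(out$percent_inhibition, manual)
    expect_lt(out$p_value, 0.05)
  })
  expect_error(summarize_inhibition(data.frame(condition = "a", value = 1),
                                    "x", "y"),
               class = "herbnet_input_error")
})
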