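noise_free_dr <- function(hb_max = 30, ec50 = 5,
                          conc = c(0, 1.3, 2.6, 5.2, 13, 26, 52)) {
  data.frame(fe_conc = conc, hb = hb_max * conc / (ec50 + conc))
}

test_that("noise-free hyperbolic data are recovered to 1e-8", {
  fit <- fit_hyperbolic(noise_free_dr())
  expect_true(fit$converged)
  expect_equal(coef(fit)[["hb_max"]], 30, tolerance = 1e-8)
  expect_equal(coef(fit)[["ec50"]], 5, tolerance = 1e-8)
  expect_equal(predict_hb(fit, noise_free_dr()$fe_conc), noise_free_dr()$hb,
               tolerance = 1e-8)
  # different truths, including EC50 outside the design range
  for (p in list(c(12, 1.1), c(45, 20), c(30, 0.5))) {
    f <- fit_hyperbolic(noise_free_dr(p[1], p[2]))
    expect_equal(unname(coef(f)), p, tolerance = 1e-7)
  }
})

test_that("predictions follow the hyperbolic model structure", {
  fit <- fit_hyperbolic(noise_free_dr())
  cf <- coef(fit)
  expect_equal(predict_hb(fit, 0), 0)
  expect_equal(predict_hb(fit, cf[["ec50"]]), cf[["hb_max"]] / 2,
               tolerance = 1e-10)
  expect_equal(predict_hb(fit, 100 * cf[["ec50"]]), cf[["hb_max"]],
               tolerance = 0.01)
  cc <- seq(0, 60, by = 0.5)
  expect_true(all(diff(predict_hb(fit, cc)) >= 0))
})

test_that("a zero-concentration record with positive response is absorbed as residual", {
  d <- noise_free_dr()
  d$hb[d$fe_conc == 0] <- 1.5
  fit <- fit_hyperbolic(d)
  expect_true(fit$converged)
  expect_equal(predict_hb(fit, 0), 0)
  expect_gt(fit$rss, 0)
})

test_that("degenerate dose-response inputs raise errors rather than junk", {
  expect_error(fit_hyperbolic(data.frame(fe_conc = c(5, 5, 5), hb = c(1, 2, 3))),
               class = "ferrispec_validation_error")
  expect_error(fit_hyperbolic(data.frame(fe_conc = c(0, 5, 10), hb = c(0, 0, 0))),
               class = "ferrispec_validation_error")
  expect_error(fit_hyperbolic(data.frame(fe_conc = c(0, 5), hb = c(0, 1))),
               class = "ferrispec_validation_error")
  expect_error(fit_hyperbolic(data.frame(fe_conc = c(-1, 5, 10), hb = c(0, 1, 2))),
               class = "ferrispec_validation_error")
})

test_that("fit is invariant to record order and to duplicating every record", {
  d <- gen_dose_response(synthetic_config(seed = 11))
  f1 <- fit_hyperbolic(d)
  f2 <- fit_hyperbolic(d[rev(seq_len(nrow(d))), ])
  f3 <- fit_hyperbolic(rbind(d, d))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-7)
  expect_equal(f3$rss, 2 * f1$rss, tolerance = 1e-6)
})

test_that("seeded noisy datasets recover the generator truth within 10%", {
  errs <- t(vapply(1:40, function(s) {
    d <- gen_dose_response(synthetic_config(seed = s))
    tr <- manifest(d)$truth
    cf <- coef(fit_hyperbolic(d))
    c(abs(cf[["hb_max"]] - tr$hb_max) / tr$hb_max,
      abs(cf[["ec50"]] - tr$ec50) / tr$ec50)
  }, c(0, 0)))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("noise-free Hill curves are recovered exactly and the two P50 estimators agree", {
  po2 <- seq(2, 150, by = 4)
  for (p in list(c(26.8, 2.7), c(24.2, 2.4), c(28.0, 3.0))) {
    curve <- data.frame(po2 = po2,
                        saturation = po2^p[2] / (p[1]^p[2] + po2^p[2]))
    fit <- fit_hill(curve)
    expect_equal(coef(fit)[["p50"]], p[1], tolerance = 1e-7)
    expect_equal(coef(fit)[["hill_n"]], p[2], tolerance = 1e-7)
    expect_equal(fit$p50_interp, coef(fit)[["p50"]], tolerance = 0.02)
  }
})

test_that("saturation curves not spanning 0.5 are rejected", {
  flat <- data.frame(po2 = seq(0, 100, by = 10),
                     saturation = rep(0.2, 11))
  expect_error(fit_hill(flat), class = "ferrispec_validation_error")
  expect_error(fit_hill(data.frame(po2 = 1:5, saturation = c(0.6, 0.7, 0.8, 0.9, 1))),
               class = "ferrispec_validation_error")
})
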