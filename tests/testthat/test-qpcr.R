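test_that("fit_standard_curve recovers perfect doubling chemistry", {
  curve <- ideal_curve()
  expect_equal(curve$slope, -3.3219)
  expect_equal(curve$intercept, 40)
  expect_equal(curve$r2, 1)
  expect_equal(curve$efficiency, 1, tolerance = 1e-3)
})

test_that("fit_standard_curve equals the closed-form OLS solution", {
  set.seed(7)
  for (rep in 1:5) {
    copies <- 10^(2:6)
    cq <- 39 - 3.4 * log10(copies) + rnorm(5, 0, 0.3)
    curve <- fit_standard_curve(data.frame(copies = copies, cq = cq))
    x <- log10(copies)
    slope <- sum((x - mean(x)) * (cq - mean(cq))) / sum((x - mean(x))^2)
    intercept <- mean(cq) - slope * mean(x)
    expect_equal(curve$slope, slope, tolerance = 1e-9)
    expect_equal(curve$intercept, intercept, tolerance = 1e-9)
  }
})

test_that("a fixture built to R2 = 0.99 reports R2 = 0.99", {
  # residuals orthogonal to the regressor leave slope untouched and set
  # SS_err / SS_reg exactly; scale them so R2 = SS_reg / (SS_reg + SS_err) = 0.99
  x <- 2:6
  cq0 <- 40 - 3.3219 * x
  e <- c(1, -1, 0, 1, -1)
  e <- e - mean(e)
  e <- e - sum(e * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  ss_reg <- sum((cq0 - mean(cq0))^2)
  e <- e * sqrt((0.01 / 0.99) * ss_reg / sum(e^2))
  curve <- fit_standard_curve(data.frame(copies = 10^x, cq = cq0 + e))
  expect_equal(curve$r2, 0.99, tolerance = 1e-10)
})

test_that("fit_standard_curve rejects bad standards", {
  expect_error(fit_standard_curve(data.frame(copies = c(10, 100), cq = c(1, 2))),
               "insufficient")
  expect_error(fit_standard_curve(data.frame(copies = c(-1, 10, 100),
                                             cq = c(3, 2, 1))), "positive")
})

test_that("quantify inverts the curve and maps no-amplification to zero", {
  curve <- ideal_curve()
  expect_equal(quantify(curve$intercept, curve), 1)
  for (c0 in c(10, 1e3, 1e6)) {
    cq <- curve$intercept + curve$slope * log10(c0)
    expect_equal(quantify(cq, curve), c0)
  }
  expect_identical(quantify(NA_real_, curve), 0)
  expect_error(quantify(Inf, curve), "finite")
})

test_that("quantify-simulate identity holds over random valid curves", {
  set.seed(11)
  for (i in 1:200) {
    slope <- runif(1, -4.5, -2.9)
    intercept <- runif(1, 35, 42)
    x <- 2:6
    curve <- fit_standard_curve(
      data.frame(copies = 10^x, cq = intercept + slope * x))
    copies <- 10^runif(1, 0.5, 7.5)
    cq <- intercept + slope * log10(copies)
    expect_equal(quantify(cq, curve), copies, tolerance = 1e-9)
  }
})

test_that("replicate-mean quantification bias follows the delta prediction", {
  # averaging Cq before back-transforming vs averaging copies: both carry a
  # lognormal mean bias; their ratio is predicted by the noise variance
  curve <- ideal_curve()
  noise <- 0.2
  sd_ln <- log(10) * noise / abs(curve$slope)
  predicted_ratio <- exp(sd_ln^2 / 2) / exp(sd_ln^2 / 6)  # mean-of-copies / copies-of-mean
  set.seed(13)
  c0 <- 1e4
  n <- 2e4
  cq <- matrix(curve$intercept + curve$slope * log10(c0) +
                 rnorm(3 * n, 0, noise), nrow = 3)
  mean_of_copies <- mean(colMeans(matrix(quantify(as.numeric(cq), curve), nrow = 3)))
  copies_of_mean <- mean(quantify(colMeans(cq), curve))
  observed_ratio <- mean_of_copies / copies_of_mean
  expect_equal(observed_ratio - 1, predicted_ratio - 1, tolerance = 0.5)
})

test_that("qc_assay applies the efficiency, CV and R2 gates", {
  curve <- ideal_curve()
  rep3 <- c(100, 105, 95)
  qc <- qc_assay(curve, rep3)
  expect_true(qc$efficiency_pass && qc$cv_pass && qc$r2_pass)
  expect_equal(qc$replicate_cv, sd(rep3) / mean(rep3))

  qc_id <- qc_assay(curve, c(100, 100, 100))
  expect_equal(qc_id$replicate_cv, 0)
  expect_true(qc_id$cv_pass)

  # slope -3.9 gives efficiency 10^(1/3.9) - 1, about 0.805: below the gate
  x <- 2:6
  shallow <- fit_standard_curve(data.frame(copies = 10^x, cq = 40 - 3.9 * x))
  expect_equal(shallow$efficiency, 10^(1 / 3.9) - 1, tolerance = 1e-12)
  expect_false(qc_assay(shallow, rep3)$efficiency_pass)

  qc0 <- qc_assay(curve, c(0, 0, 0))
  expect_false(qc0$cv_pass)
  expect_true("cv_undefined_all_zero" %in% qc0$flags)
})

test_that("sum_geoA_groups sums, is permutation-invariant and monotone", {
  expect_equal(sum_geoA_groups(c(g1 = 100, g3 = 0, g4 = 50, g5 = 0)), 150)
  expect_equal(sum_geoA_groups(c(g1 = 0, g3 = 0, g4 = 0, g5 = 0)), 0)
  set.seed(3)
  for (i in 1:20) {
    v <- stats::setNames(runif(4, 0, 1e4), c("g1", "g3", "g4", "g5"))
    perm <- sample(4)
    expect_equal(sum_geoA_groups(v[perm]), sum_geoA_groups(v))
    j <- sample(4, 1)
    bump <- v; bump[j] <- bump[j] + 10
    expect_gte(sum_geoA_groups(bump), sum_geoA_groups(v))
  }
  expect_error(sum_geoA_groups(c(g1 = -1)), "non-negative")
  expect_error(sum_geoA_groups(c(g2 = 1)), "g1, g3, g4, g5")
})

test_that("normalize_concentration scales linearly and checks units", {
  expect_equal(as.numeric(normalize_concentration(100, 1, "mL",
                                                  template_scaling = 10)), 1000)
  # farm-4-like mucous extraction: 9 cm2 patch at 4.32e5 copies/cm2
  conc <- normalize_concentration(4.32e5 * 9, 9, "cm2", compartment = "mucous")
  expect_equal(as.numeric(conc), 4.32e5)
  expect_equal(attr(conc, "unit"), "cm2")
  base <- as.numeric(normalize_concentration(50, 2, "g"))
  expect_equal(as.numeric(normalize_concentration(100, 2, "g")), 2 * base)
  expect_equal(as.numeric(normalize_concentration(50, 1, "g")), 2 * base)
  expect_error(normalize_concentration(1, 1, "mL", compartment = "digesta"),
               "does not match")
})

test_that("quantify_plate fits per-assay curves and sums geoA groups", {
  q <- stats::setNames(c(1200, 3.5e5), c("sA", "sB"))
  set.seed(5)
  plate <- rbind(
    simulate_qpcr_plate(q * 0.6, noise_sd = 0, assay_id = "geoA_g1"),
    simulate_qpcr_plate(q * 0.4, noise_sd = 0, assay_id = "geoA_g4"),
    simulate_qpcr_plate(q * 50, noise_sd = 0, assay_id = "bact16S"))
  res <- quantify_plate(plate)
  expect_equal(res$samples$geoA_total[match(c("sA", "sB"), res$samples$sample_id)],
               unname(q), tolerance = 1e-9)
  expect_equal(res$samples$bact16S[match("sA", res$samples$sample_id)],
               50 * 1200, tolerance = 1e-9)
  expect_s3_class(res$curves$geoA_g1, "standard_curve")
})
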