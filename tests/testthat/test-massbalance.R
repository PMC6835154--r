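test_that("per_cell_yield splits culture geosmin into free and bound yields", {
  y <- per_cell_yield(73e-9, 67e-9, 1e9)
  expect_equal(y$free_g_per_cell, 73e-18)
  expect_equal(y$bound_g_per_cell, 67e-18)
  expect_equal(y$total_g_per_cell, 140e-18)

  expect_equal(per_cell_yield(0, 5e-9, 1e8)$free_g_per_cell, 0)
  half <- per_cell_yield(73e-9, 67e-9, 2e9)
  expect_equal(half$free_g_per_cell, y$free_g_per_cell / 2)
  expect_equal(half$bound_g_per_cell, y$bound_g_per_cell / 2)
  expect_error(per_cell_yield(1e-9, 1e-9, 0), "positive")
})

test_that("compartment_production converts to compartment-native units", {
  y <- paper_yield()
  expect_equal(as.numeric(compartment_production(0, y, "water")), 0)
  # 8643 copies/mL of water -> about 1.21 ng/L at 140e-18 g/cell
  w <- compartment_production(8643, y, "water")
  expect_equal(as.numeric(w), 8643 * 1000 * 140e-18 * 1e9, tolerance = 1e-12)
  expect_equal(as.numeric(w), 1.21, tolerance = 0.002)
  expect_equal(attr(w, "unit"), "ng/L")
  # invert the mucous area that turns 4.32e5 copies/cm2 into 186 ng/intestine
  area <- 186e-9 / (4.32e5 * 140e-18)
  m <- compartment_production(4.32e5, y, "mucous", size = area)
  expect_equal(as.numeric(m), 186, tolerance = 1e-9)
  expect_equal(attr(m, "unit"), "ng/intestine")
  expect_equal(attr(compartment_production(100, y, "digesta"), "unit"), "pg/g")
  expect_equal(attr(compartment_production(100, y, "fin"), "unit"), "ng/cm2")
})

test_that("production is linear in density, yield and size", {
  y <- paper_yield()
  y2 <- per_cell_yield(2 * 73e-9, 2 * 67e-9, 1e9)
  d <- 1234.5
  base <- as.numeric(compartment_production(d, y, "mucous", size = 10))
  expect_equal(as.numeric(compartment_production(3 * d, y, "mucous", size = 10)),
               3 * base)
  expect_equal(as.numeric(compartment_production(d, y2, "mucous", size = 10)),
               2 * base)
  expect_equal(as.numeric(compartment_production(d, y, "mucous", size = 20)),
               2 * base)
  # one geoA copy per cell is the default; 2 copies halve the cell count
  expect_equal(as.numeric(compartment_production(d, y, "mucous", size = 10,
                                                 copies_per_cell = 2)),
               base / 2)
})

test_that("contribution_to_flesh reproduces the printed percent column", {
  expect_equal(contribution_to_flesh(94, 351), 26.8, tolerance = 0.002)
  expect_equal(contribution_to_flesh(114, 408), 27.9, tolerance = 0.002)
  expect_equal(contribution_to_flesh(0, 100), 0)
  expect_warning(na <- contribution_to_flesh(10, 0), "undefined")
  expect_true(is.na(na))
  # invariance under (p, c*k, m/k)
  set.seed(61)
  for (i in 1:20) {
    p <- runif(1, 1, 500); c0 <- runif(1, 50, 800); k <- runif(1, 0.1, 10)
    expect_equal(contribution_to_flesh(p, c0 * k, 1 / k),
                 contribution_to_flesh(p, c0, 1))
  }
})

test_that("contribution_to_water handles the zero-measurement farm", {
  expect_equal(contribution_to_water(1.21, 2.7), 100 * 1.21 / 2.7)
  expect_equal(contribution_to_water(0, 5), 0)
  expect_equal(contribution_to_water(3, 3), 100)
  expect_equal(contribution_to_water(0, 0), 0)
  expect_warning(na <- contribution_to_water(0.5, 0), "undefined")
  expect_true(is.na(na))
})

test_that("propagate_se matches closed forms for sums and products", {
  s <- propagate_se(function(a, b) a + b, c(a = 10, b = 20), c(a = 3, b = 4))
  expect_equal(s$se, 5, tolerance = 1e-6)
  p <- propagate_se(function(a, b) a * b, c(a = 50, b = 8),
                    c(a = 5, b = 0.8))  # 10% relative each
  expect_equal(p$se / p$value, sqrt(0.02), tolerance = 1e-6)
  q <- propagate_se(function(a, b) a / b, c(a = 50, b = 8), c(a = 5, b = 0.8))
  expect_equal(q$se / q$value, sqrt(0.02), tolerance = 1e-4)
  z <- propagate_se(function(a, b) a * b, c(a = 0, b = 8), c(a = 1, b = 0.8))
  expect_true("zero_value_with_nonzero_se" %in% z$flags)
  expect_error(propagate_se(function(a, b) a + b, c(a = 1, b = 2), c(x = 1, y = 2)),
               "same names")
})

test_that("delta-method SEs track Monte-Carlo SDs on a product chain", {
  set.seed(67)
  f <- function(a, b, c) a * b / c
  vals <- c(a = 120, b = 0.8, c = 40)
  ses <- vals * c(0.10, 0.08, 0.12)
  d <- propagate_se(f, vals, ses)
  n <- 2e4
  mc <- sd(f(rnorm(n, vals["a"], ses["a"]), rnorm(n, vals["b"], ses["b"]),
             rnorm(n, vals["c"], ses["c"])))
  expect_equal(d$se, mc, tolerance = 0.1)
})

test_that("build_contribution_table assembles per-farm rows with flags", {
  y <- paper_yield()
  dens0 <- expand.grid(farm = 1, compartment = c("water", "mucous", "digesta", "fin"),
                       stringsAsFactors = FALSE)
  dens0$density <- 0; dens0$se <- 0
  meas <- data.frame(farm = 1, compartment = c("flesh", "water"),
                     value = c(300, 2), se = c(10, 0.2),
                     unit = c("ng/kg", "ng/L"), stringsAsFactors = FALSE)
  t0 <- build_contribution_table(dens0, meas, y, mucous_area_cm2 = 3000)
  expect_equal(t0$mucous_production_ng, 0)
  expect_equal(t0$contribution_flesh_pct, 0)
  expect_equal(t0$contribution_water_pct, 0)

  # farm-6-like fixture: density chosen so production = 94 ng/intestine
  area <- 3000
  dens6 <- dens0
  dens6$density[dens6$compartment == "mucous"] <- 94e-9 / (area * 140e-18)
  meas6 <- meas; meas6$value[1] <- 351
  t6 <- build_contribution_table(dens6, meas6, y, mucous_area_cm2 = area)
  expect_equal(t6$mucous_production_ng, 94, tolerance = 1e-9)
  expect_equal(t6$contribution_flesh_pct, 26.8, tolerance = 0.002)

  # missing compartment is flagged, not fatal
  t_missing <- build_contribution_table(
    dens6[dens6$compartment != "fin", ], meas6, y, mucous_area_cm2 = area)
  expect_true(grepl("missing_fin", t_missing$flags))
  expect_true(is.na(t_missing$fin_ng_per_cm2))
})
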