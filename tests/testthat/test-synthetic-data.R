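test_that("sim_config validates its invariants", {
  expect_s3_class(small_config(), "sim_config")
  expect_error(sim_config(uptake_fraction = 1.5), "uptake_fraction")
  expect_error(sim_config(otu_depth = 0), "otu_depth")
  expect_error(sim_config(cq_noise_sd = -1), "non-negative")
  expect_error(sim_config(fish_mass_kg = NaN), "non-finite")
  expect_error(sim_config(compartments = character(0)), "at least one|must be")
})

test_that("simulate_qpcr_plate generates the closed-form Cq", {
  curve <- ideal_curve()
  plate <- simulate_qpcr_plate(c(s1 = 1e6), curve, noise_sd = 0, replicates = 2)
  cq <- plate$cq[!plate$is_standard]
  expect_equal(cq, rep(20.0686, 2), tolerance = 1e-4)
  # zero copies: no-amplification flag, not a numeric Cq
  p0 <- simulate_qpcr_plate(c(s0 = 0), curve, noise_sd = 0)
  expect_true(all(is.na(p0$cq[!p0$is_standard])))
  expect_error(simulate_qpcr_plate(c(s1 = 10), curve, noise_sd = -0.1),
               "non-negative")
})

test_that("simulated Cq noise has the stated standard deviation", {
  set.seed(71)
  plate <- simulate_qpcr_plate(c(s1 = 1e4), ideal_curve(), noise_sd = 0.2,
                               replicates = 1000)
  sd_obs <- sd(plate$cq[!plate$is_standard])
  expect_equal(sd_obs, 0.2, tolerance = 0.1)
})

test_that("seeded runs are bit-reproducible", {
  a <- simulate_farm_system(small_config(seed = 9))
  b <- simulate_farm_system(small_config(seed = 9))
  expect_identical(a, b)
  c <- simulate_farm_system(small_config(seed = 10))
  expect_false(identical(a$qpcr_plate$cq, c$qpcr_plate$cq))
})

test_that("with no uptake and no noise, flesh geosmin equals the water route", {
  cfg <- noise_free(small_config(seed = 2, uptake_fraction = 0))
  ds <- simulate_farm_system(cfg)
  flesh <- ds$measurements[ds$measurements$compartment == "flesh", ]
  water_route <- cfg$water_uptake_L_per_kg * ds$truth$farms$water_geosmin
  expect_equal(flesh$value, water_route, tolerance = 1e-12)
})

test_that("a farm-4-like configuration yields the expected mucous production", {
  area <- 186e-9 / (4.32e5 * 140e-18)
  cfg <- noise_free(small_config(
    seed = 3,
    producer_fraction = c(water = 0.002, mucous = 4.32e5 / 1e8,
                          digesta = 0.001, fin = 0.0014),
    mucous_area_cm2 = area))
  ds <- simulate_farm_system(cfg)
  res <- analyze_dataset(ds, stages = c("qpcr", "census", "massbalance"))
  expect_equal(res$contribution$mucous_production_ng, rep(186, 3),
               tolerance = 1e-6)
})

test_that("simulate_otu_table hits target fractions without overdispersion", {
  # producer_fraction = 0: the screen reports 0% producers
  sim0 <- simulate_otu_table(stats::setNames(rep(0.1, 10), paste0("b", 1:10)),
                             producer_fraction = 0, depth = 1000, n_samples = 3,
                             seed = 5)
  tab0 <- producer_abundance_table(sim0$counts, sim0$taxonomy, rep("w", 3))
  expect_equal(max(tab0$max_pct), 0)

  # multinomial limit: empirical fraction within 3 SE of the target
  depth <- 2e5
  sim <- simulate_otu_table(stats::setNames(rep(0.1, 10), paste0("b", 1:10)),
                            producer_fraction = 0.2, depth = depth,
                            n_samples = 1, seed = 6, concentration = Inf)
  prod_ids <- grep("^OTU_(act|cya|myx|sor)", rownames(sim$counts))
  frac <- sum(sim$counts[prod_ids, 1]) / depth
  se <- sqrt(0.2 * 0.8 / depth)
  expect_lt(abs(frac - 0.2), 3 * se)

  # across samples the mean screened abundance stays near the target
  set.seed(7)
  sim50 <- simulate_otu_table(stats::setNames(rep(0.1, 10), paste0("b", 1:10)),
                              producer_fraction = 0.2, depth = 5000,
                              n_samples = 50, concentration = 200)
  fr <- colSums(sim50$counts[prod_ids, ]) / 5000
  ci <- 3 * sd(fr) / sqrt(50)
  expect_lt(abs(mean(fr) - 0.2), ci + 0.01)
  expect_error(simulate_otu_table(c(b = 1), 0.1, depth = 0, n_samples = 1),
               "depth")
  expect_error(simulate_otu_table(c(b = 0.5), 0.1, depth = 10, n_samples = 1),
               "sum to 1")
})

test_that("synthetic OTU producer fractions track the latent geoA fractions", {
  ## full study design (6 farms x 10 fish) for adequate power: the per-sample
  ## producer signal is only tens of reads at realistic depth
  ds <- simulate_farm_system(sim_config(otu_depth = 10000,
                                        n_background_otus = 60, seed = 12))
  prod_ids <- grep("^OTU_(act|cya|myx|sor)", rownames(ds$otu_table))
  obs <- colSums(ds$otu_table[prod_ids, ]) / colSums(ds$otu_table)
  latent <- ds$truth$samples$fraction[match(colnames(ds$otu_table),
                                            ds$truth$samples$sample_id)]
  ## at realistic depth each sample carries only tens of producer reads, so
  ## the association is noisy but must be positive and well calibrated
  ct <- cor.test(obs, latent)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-3)
  expect_equal(mean(obs), mean(latent), tolerance = 0.25)
})

test_that("every otu_table sample has metadata", {
  ds <- simulate_farm_system(small_config(seed = 13))
  expect_true(all(colnames(ds$otu_table) %in% ds$metadata$sample_id))
  expect_true(all(ds$qpcr_plate$sample_id[!ds$qpcr_plate$is_standard] %in%
                    ds$metadata$sample_id))
})
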