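#' Configuration of the synthetic multi-farm cage system
#'
#' Defaults emulate the magnitudes observed across six freshwater cage farms:
#' producer (geoA) densities of order 1e2/mL in water, 1e5/cm2 in intestinal
#' mucous, 1e3/g in digesta and 1e4-1e5/cm2 on fins, producer fractions of
#' roughly 0.1-0.2% of total bacteria, per-cell yields of 73e-18 g (free) and
#' 67e-18 g (cell-bound), flesh geosmin of a few hundred ng/kg and water
#' geosmin of a few ng/L. Latent densities are lognormal (abundances are
#' right-skewed); flesh geosmin follows the weakest linear two-route mixture:
#' an intestinal route scaled by `uptake_fraction` plus a water route scaled
#' by `water_uptake_L_per_kg`. All lognormal draws are mean-centered
#' (meanlog = log(mean) - sigma^2/2) so expectations equal the stated means.
#'
#' @param n_farms,fish_per_farm study design (defaults 6 farms x 10 fish).
#' @param compartments sampled environments; non-empty subset of
#'   water/mucous/digesta/fin.
#' @param producer_fraction named per-compartment mean fraction of bacteria
#'   carrying geoA (dimensionless), with `fraction_sigma` its lognormal sigma.
#' @param total16S_density named per-compartment mean total-bacteria density
#'   (copies per mL/cm2/g) with lognormal `density_sigma`; producer density is
#'   the product fraction x total.
#' @param farm_sigma_density,farm_sigma_fraction between-farm lognormal sigmas.
#' @param yield_free,yield_bound per-cell geosmin yields, g/cell.
#' @param uptake_fraction fraction of intestinal geosmin reaching flesh,
#'   between 0 and 1.
#' @param water_uptake_L_per_kg water-route bioconcentration (L/kg).
#' @param background_water_geosmin ng/L of geosmin not from local producers.
#' @param fish_mass_kg,mucous_area_cm2,digesta_mass_g compartment extents.
#' @param cq_noise_sd per-well Cq noise (cycles).
#' @param measurement_sigma lognormal sigma of geosmin measurement noise.
#' @param otu_depth reads per sample; `n_background_otus` background OTUs.
#' @param dm_concentration Dirichlet-multinomial concentration; `Inf` =
#'   pure multinomial (no overdispersion).
#' @param producer_clade_fractions relative weights of producer clades.
#' @param group_weights split of geoA copies across the g1/g3/g4/g5 assays.
#' @param sampled_size extraction extent per compartment (mL, cm2, g);
#'   9 cm2 patches for fins and mucous by default.
#' @param water_samples_per_farm water samples per farm.
#' @param seed integer; fixes all downstream randomness.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_farms = 6, fish_per_farm = 10,
                       compartments = c("water", "mucous", "digesta", "fin"),
                       producer_fraction = c(water = 0.002, mucous = 0.002,
                                             digesta = 0.001, fin = 0.0014),
                       fraction_sigma = 0.5,
                       total16S_density = c(water = 2.5e5, mucous = 1e8,
                                            digesta = 1.5e6, fin = 5e7),
                       density_sigma = 0.6,
                       farm_sigma_density = 0.3, farm_sigma_fraction = 0.5,
                       yield_free = 73e-18, yield_bound = 67e-18,
                       uptake_fraction = 0.35, water_uptake_L_per_kg = 120,
                       background_water_geosmin = 1.5,
                       fish_mass_kg = 1, mucous_area_cm2 = 3000,
                       digesta_mass_g = 50,
                       cq_noise_sd = 0.15, measurement_sigma = 0.1,
                       otu_depth = 25000, n_background_otus = 300,
                       dm_concentration = 200,
                       producer_clade_fractions = c(Actinomycetales = 0.5,
                                                    Cyanobacteria = 0.4,
                                                    Myxococcales = 0.08,
                                                    Sorangium = 0.02),
                       group_weights = c(g1 = 0.4, g3 = 0.3, g4 = 0.2, g5 = 0.1),
                       sampled_size = c(water = 1, mucous = 9, digesta = 0.2, fin = 9),
                       water_samples_per_farm = 3, seed = 0) {
  compartments <- match.arg(compartments,
                            c("water", "mucous", "digesta", "fin"),
                            several.ok = TRUE)
  if (length(compartments) == 0) stop("at least one compartment is required")
  cfg <- list(n_farms = n_farms, fish_per_farm = fish_per_farm,
              compartments = compartments,
              producer_fraction = producer_fraction,
              fraction_sigma = fraction_sigma,
              total16S_density = total16S_density,
              density_sigma = density_sigma,
              farm_sigma_density = farm_sigma_density,
              farm_sigma_fraction = farm_sigma_fraction,
              yield_free = yield_free, yield_bound = yield_bound,
              uptake_fraction = uptake_fraction,
              water_uptake_L_per_kg = water_uptake_L_per_kg,
              background_water_geosmin = background_water_geosmin,
              fish_mass_kg = fish_mass_kg, mucous_area_cm2 = mucous_area_cm2,
              digesta_mass_g = digesta_mass_g,
              cq_noise_sd = cq_noise_sd, measurement_sigma = measurement_sigma,
              otu_depth = otu_depth, n_background_otus = n_background_otus,
              dm_concentration = dm_concentration,
              producer_clade_fractions = producer_clade_fractions,
              group_weights = group_weights, sampled_size = sampled_size,
              water_samples_per_farm = water_samples_per_farm,
              seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), c("compartments", "dm_concentration"))])
  if (any(!is.finite(num))) stop("non-finite configuration value")
  if (any(c(cfg$producer_fraction, cfg$total16S_density) < 0))
    stop("densities and fractions must be non-negative")
  if (cfg$uptake_fraction < 0 || cfg$uptake_fraction > 1)
    stop("uptake_fraction must lie in [0, 1]")
  if (cfg$otu_depth < 1) stop("otu_depth must be >= 1")
  if (cfg$cq_noise_sd < 0) stop("cq_noise_sd must be non-negative")
  missing_comp <- setdiff(compartments,
                          names(cfg$producer_fraction))
  if (length(missing_comp) > 0)
    stop("no producer_fraction for: ", paste(missing_comp, collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Zero all noise terms of a configuration
#'
#' Convenience for round-trip tests: with every sigma and noise SD at zero
#' the full pipeline must return the simulator truth exactly.
#'
#' @param config a `sim_config`.
#' @return the configuration with all stochastic spread parameters set to 0.
#' @export
noise_free <- function(config) {
  config$fraction_sigma <- 0
  config$density_sigma <- 0
  config$farm_sigma_density <- 0
  config$farm_sigma_fraction <- 0
  config$cq_noise_sd <- 0
  config$measurement_sigma <- 0
  config$dm_concentration <- Inf
  config
}

## mean-centered lognormal: E[X] = mean
rlnorm_mean <- function(n, mean, sigma) {
  if (all(mean == 0)) return(rep(0, n))
  mean * stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

## reference assay curve used by the simulator (perfect-efficiency chemistry)
default_assay_curve <- function() {
  structure(list(slope = -3.3219, intercept = 40, r2 = 1,
                 efficiency = 10^(1 / 3.3219) - 1, n_points = 0),
            class = "standard_curve")
}

#' Simulate a qPCR plate from known copy numbers
#'
#' Generates `Cq = intercept + slope * log10(copies) + N(0, noise_sd)` wells
#' for each sample, plus a standard dilution series. Zero-copy samples emit
#' no-amplification wells (Cq = NA), encoding "below one copy per reaction".
#'
#' @param quantities named numeric: copies per reaction per sample.
#' @param curve a `standard_curve` used as the generating relation.
#' @param noise_sd per-well Cq noise, >= 0.
#' @param replicates technical replicates per sample, >= 1.
#' @param assay_id assay label stamped on the wells.
#' @param standards copy levels of the dilution series.
#' @param standard_replicates replicates per standard level.
#' @return data.frame: sample_id, assay_id, replicate, cq, is_standard,
#'   standard_copies.
#' @export
simulate_qpcr_plate <- function(quantities, curve = default_assay_curve(),
                                noise_sd = 0, replicates = 3,
                                assay_id = "assay",
                                standards = 10^(1:8), standard_replicates = 3) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (replicates < 1) stop("replicates must be >= 1")
  assert_nonneg(quantities, "copy numbers")
  cq_of <- function(copies, n) {
    cq <- curve$intercept + curve$slope * log10(copies) +
      stats::rnorm(n, 0, noise_sd)
    cq[rep(copies, length.out = n) == 0] <- NA_real_
    cq
  }
  std <- do.call(rbind, lapply(standards, function(s) data.frame(
    sample_id = sprintf("std_%g", s), assay_id = assay_id,
    replicate = seq_len(standard_replicates),
    cq = cq_of(s, standard_replicates),
    is_standard = TRUE, standard_copies = s, stringsAsFactors = FALSE)))
  unk <- do.call(rbind, lapply(seq_along(quantities), function(i) data.frame(
    sample_id = names(quantities)[i], assay_id = assay_id,
    replicate = seq_len(replicates),
    cq = cq_of(quantities[i], replicates),
    is_standard = FALSE, standard_copies = NA_real_, stringsAsFactors = FALSE)))
  rbind(std, unk)
}

producer_otu_catalog <- function() {
  data.frame(
    otu_id = c("OTU_act_hgcI", "OTU_act_acidimicro", "OTU_act_microbact",
               "OTU_cya_synecho", "OTU_cya_limnothrix", "OTU_cya_familyI",
               "OTU_myx_uncl", "OTU_myx_haliangium",
               "OTU_sor_cellulosum"),
    clade = c(rep("Actinomycetales", 3), rep("Cyanobacteria", 3),
              rep("Myxococcales", 2), "Sorangium"),
    weight = c(0.5, 0.3, 0.2, 0.5, 0.3, 0.2, 0.6, 0.4, 1),
    lineage = c(
      "k__Bacteria;p__Actinobacteria;c__Actinobacteria;o__Actinomycetales;f__Sporichthyaceae;g__hgcI clade",
      "k__Bacteria;p__Actinobacteria;c__Acidimicrobiia;o__Actinomycetales;f__Acidimicrobiaceae;g__",
      "k__Bacteria;p__Actinobacteria;c__Actinobacteria;o__Actinomycetales;f__Microbacteriaceae;g__",
      "k__Bacteria;p__Cyanobacteria;c__Cyanophyceae;o__Synechococcales;f__Synechococcaceae;g__Synechococcus",
      "k__Bacteria;p__Cyanobacteria;c__Cyanophyceae;o__Oscillatoriales;f__Microcoleaceae;g__Limnothrix",
      "k__Bacteria;p__Cyanobacteria;c__Cyanophyceae;o__;f__;g__",
      "k__Bacteria;p__Proteobacteria;c__Deltaproteobacteria;o__Myxococcales;f__;g__",
      "k__Bacteria;p__Proteobacteria;c__Deltaproteobacteria;o__Myxococcales;f__Kofleriaceae;g__Haliangium",
      "k__Bacteria;p__Proteobacteria;c__Deltaproteobacteria;o__Myxococcales;f__Polyangiaceae;g__Sorangium"),
    stringsAsFactors = FALSE)
}

background_otu_catalog <- function(n, seed) {
  named <- data.frame(
    otu_id = c("OTU_bg_cetobacterium", "OTU_bg_porphyromonad",
               "OTU_bg_clostridium", "OTU_bg_betaproteo", "OTU_bg_trueperella"),
    weight = c(50, 6, 4, 3, 2),
    lineage = c(
      "k__Bacteria;p__Fusobacteria;c__Fusobacteriia;o__Fusobacteriales;f__Fusobacteriaceae;g__Cetobacterium",
      "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Porphyromonadaceae;g__",
      "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Clostridiaceae;g__Clostridium",
      "k__Bacteria;p__Proteobacteria;c__Betaproteobacteria;o__;f__;g__",
      "k__Bacteria;p__Actinobacteria;c__Actinobacteria;o__Corynebacteriales;f__Actinomycetaceae;g__Trueperella"),
    stringsAsFactors = FALSE)
  n_extra <- max(0, n - nrow(named))
  extra <- data.frame(
    otu_id = sprintf("OTU_bg_%04d", seq_len(n_extra)),
    weight = exp(stats::rnorm(n_extra, 0, 1.5)),
    lineage = "k__Bacteria;p__Proteobacteria;c__;o__;f__;g__",
    stringsAsFactors = FALSE)
  out <- rbind(named, extra)[seq_len(min(n, nrow(named) + n_extra)), ]
  out$weight <- out$weight / sum(out$weight)
  out
}

#' Simulate an OTU count table with embedded producer clades
#'
#' Per sample, producer-clade OTUs are scaled to the sample's producer
#' fraction and the background composition is renormalized to the remainder;
#' counts are drawn Dirichlet-multinomial at the stated depth
#' (`concentration = Inf` collapses to a pure multinomial). Producer OTUs are
#' assigned Actinomycetales / Cyanobacteria / Myxococcales / Sorangium
#' lineages.
#'
#' @param base_composition named numeric background composition, sums to 1.
#' @param producer_fraction scalar or per-sample vector in `[0, 1)`.
#' @param depth reads per sample, >= 1.
#' @param n_samples number of samples.
#' @param seed optional seed applied before drawing.
#' @param concentration Dirichlet-multinomial concentration (default 200).
#' @param clade_fractions relative weights of the producer clades.
#' @param sample_ids optional sample names.
#' @return list: `counts` (OTUs x samples integer matrix), `taxonomy`
#'   (data.frame otu_id, lineage).
#' @export
simulate_otu_table <- function(base_composition, producer_fraction, depth,
                               n_samples, seed = NULL, concentration = 200,
                               clade_fractions = c(Actinomycetales = 0.5,
                                                   Cyanobacteria = 0.4,
                                                   Myxococcales = 0.08,
                                                   Sorangium = 0.02),
                               sample_ids = NULL) {
  if (depth < 1) stop("depth must be >= 1")
  if (abs(sum(base_composition) - 1) > 1e-8)
    stop("base_composition must sum to 1")
  pf <- rep(producer_fraction, length.out = n_samples)
  if (any(pf < 0 | pf >= 1)) stop("producer_fraction must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  prod_cat <- producer_otu_catalog()
  prod_w <- prod_cat$weight * clade_fractions[prod_cat$clade]
  prod_w <- prod_w / sum(prod_w)
  otu_ids <- c(prod_cat$otu_id, names(base_composition))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n_samples))
  counts <- matrix(0L, nrow = length(otu_ids), ncol = n_samples,
                   dimnames = list(otu_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    target <- c(pf[j] * prod_w, (1 - pf[j]) * base_composition)
    p <- if (is.finite(concentration)) {
      a <- stats::rgamma(length(target), shape = concentration * target, rate = 1)
      if (sum(a) == 0) target else a / sum(a)
    } else target
    counts[, j] <- stats::rmultinom(1, size = depth, prob = p)[, 1]
  }
  taxonomy <- data.frame(
    otu_id = otu_ids,
    lineage = c(prod_cat$lineage,
                rep("k__Bacteria;p__Proteobacteria;c__;o__;f__;g__",
                    length(base_composition))),
    stringsAsFactors = FALSE)
  ## carry the curated background lineages when the composition provides them
  bg_lin <- attr(base_composition, "lineage")
  if (!is.null(bg_lin))
    taxonomy$lineage[match(names(base_composition), taxonomy$otu_id)] <- bg_lin
  list(counts = counts, taxonomy = taxonomy)
}

#' Forward-simulate the complete multi-farm dataset
#'
#' Draws latent per-sample total-bacteria densities and producer fractions
#' (lognormal, with farm-level effects), generates the qPCR plate (geoA group
#' assays + total 16S), the OTU tables whose producer-clade fractions track
#' the latent geoA fractions, and the geosmin measurements produced by the
#' forward mass balance: per fish,
#' `flesh = uptake_fraction * intestinal_production / fish_mass + water_uptake * water_geosmin`,
#' with the intestinal production being (mucous + digesta) producer cells
#' times the total per-cell yield. All latents are recorded in `$truth`.
#'
#' @param config a `sim_config`.
#' @return list of class `synthetic_dataset`: `qpcr_plate`, `otu_table`,
#'   `taxonomy`, `metadata`, `measurements`, `water_geosmin` (per water
#'   sample), `truth`, `config`.
#' @export
simulate_farm_system <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  cfg <- config
  yield_total <- cfg$yield_free + cfg$yield_bound

  ## --- latent densities -------------------------------------------------
  set.seed(stage_seed(cfg$seed, "latents"))
  samples <- list()
  for (farm in seq_len(cfg$n_farms)) {
    farm_mult_d <- stats::rlnorm(1, -cfg$farm_sigma_density^2 / 2,
                                 cfg$farm_sigma_density)
    farm_mult_f <- stats::rlnorm(1, -cfg$farm_sigma_fraction^2 / 2,
                                 cfg$farm_sigma_fraction)
    for (comp in cfg$compartments) {
      n_i <- if (comp == "water") cfg$water_samples_per_farm else cfg$fish_per_farm
      dens16 <- rlnorm_mean(n_i, cfg$total16S_density[comp] * farm_mult_d,
                            cfg$density_sigma)
      frac <- rlnorm_mean(n_i, cfg$producer_fraction[comp] * farm_mult_f,
                          cfg$fraction_sigma)
      frac <- pmin(frac, 0.95)
      samples[[length(samples) + 1]] <- data.frame(
        sample_id = sprintf("F%02d_%s_%02d", farm, comp, seq_len(n_i)),
        farm = farm,
        fish = if (comp == "water") NA_integer_ else seq_len(n_i),
        compartment = comp,
        sampled_size = unname(cfg$sampled_size[comp]),
        size_unit = unname(compartment_units[comp]),
        dens_16S = dens16,
        dens_geoA = dens16 * frac,
        fraction = frac,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samples)

  ## --- qPCR plate -------------------------------------------------------
  set.seed(stage_seed(cfg$seed, "qpcr"))
  curve <- default_assay_curve()
  geoA_rxn <- samples$dens_geoA * samples$sampled_size
  s16_rxn <- samples$dens_16S * samples$sampled_size
  plates <- list()
  for (g in names(cfg$group_weights)) {
    q <- stats::setNames(geoA_rxn * cfg$group_weights[g], samples$sample_id)
    plates[[g]] <- simulate_qpcr_plate(q, curve, cfg$cq_noise_sd,
                                       assay_id = paste0("geoA_", g))
  }
  plates$s16 <- simulate_qpcr_plate(
    stats::setNames(s16_rxn, samples$sample_id), curve, cfg$cq_noise_sd,
    assay_id = "bact16S")
  qpcr_plate <- do.call(rbind, plates)
  rownames(qpcr_plate) <- NULL

  ## --- OTU tables -------------------------------------------------------
  set.seed(stage_seed(cfg$seed, "otu"))
  bg <- background_otu_catalog(cfg$n_background_otus, cfg$seed)
  base_comp <- stats::setNames(bg$weight, bg$otu_id)
  attr(base_comp, "lineage") <- bg$lineage
  otu <- simulate_otu_table(base_comp, pmin(samples$fraction, 0.9),
                            depth = cfg$otu_depth, n_samples = nrow(samples),
                            concentration = cfg$dm_concentration,
                            clade_fractions = cfg$producer_clade_fractions,
                            sample_ids = samples$sample_id)

  ## --- geosmin measurements (forward mass balance) ----------------------
  set.seed(stage_seed(cfg$seed, "measurements"))
  ng_per_cell <- yield_total * 1e9
  water_rows <- samples$compartment == "water"
  measurements <- list()
  water_geosmin <- NULL
  truth_farm <- list()
  for (farm in seq_len(cfg$n_farms)) {
    fs <- samples[samples$farm == farm, , drop = FALSE]
    w <- fs[fs$compartment == "water", , drop = FALSE]
    ## exposure concentration the fish integrate: the farm's mean water latents
    water_latent <- cfg$background_water_geosmin +
      w$dens_geoA * 1000 * ng_per_cell
    water_obs <- rlnorm_mean(length(water_latent), 1, cfg$measurement_sigma) *
      water_latent
    farm_water <- mean(water_latent)
    if (length(water_obs) > 0)
      water_geosmin <- rbind(water_geosmin, data.frame(
        sample_id = w$sample_id, farm = farm, geosmin_ng_per_L = water_obs,
        stringsAsFactors = FALSE))
    muc <- fs[fs$compartment == "mucous", , drop = FALSE]
    dig <- fs[fs$compartment == "digesta", , drop = FALSE]
    n_fish <- max(nrow(muc), nrow(dig))
    intestinal <- rep(0, n_fish)
    if (nrow(muc) > 0)
      intestinal <- intestinal + muc$dens_geoA * cfg$mucous_area_cm2 * ng_per_cell
    if (nrow(dig) > 0)
      intestinal <- intestinal + dig$dens_geoA * cfg$digesta_mass_g * ng_per_cell
    flesh_latent <- cfg$uptake_fraction * intestinal / cfg$fish_mass_kg +
      cfg$water_uptake_L_per_kg * farm_water
    flesh_obs <- rlnorm_mean(length(flesh_latent), 1, cfg$measurement_sigma) *
      flesh_latent
    se_of <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    measurements[[length(measurements) + 1]] <- data.frame(
      farm = farm,
      compartment = c("flesh", "water"),
      value = c(mean(flesh_obs), if (length(water_obs)) mean(water_obs) else NA),
      se = c(se_of(flesh_obs), se_of(water_obs)),
      unit = c("ng/kg", "ng/L"), stringsAsFactors = FALSE)
    muc_mean <- if (nrow(muc) > 0) mean(muc$dens_geoA) else NA_real_
    truth_farm[[farm]] <- data.frame(
      farm = farm,
      mucous_mean_density = muc_mean,
      measured_flesh = mean(flesh_obs),
      potential_contribution_pct = if (is.na(muc_mean)) NA_real_ else
        100 * (muc_mean * cfg$mucous_area_cm2 * ng_per_cell) /
          (mean(flesh_obs) * cfg$fish_mass_kg),
      water_geosmin = farm_water, stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, measurements)
  truth_farm <- do.call(rbind, truth_farm)

  ## generative expectations (what parameter-recovery runs compare against)
  exp_flesh <- cfg$uptake_fraction *
    (cfg$producer_fraction["mucous"] * cfg$total16S_density["mucous"] *
       cfg$mucous_area_cm2 +
     cfg$producer_fraction["digesta"] * cfg$total16S_density["digesta"] *
       cfg$digesta_mass_g) * ng_per_cell / cfg$fish_mass_kg +
    cfg$water_uptake_L_per_kg *
      (cfg$background_water_geosmin +
       cfg$producer_fraction["water"] * cfg$total16S_density["water"] *
         1000 * ng_per_cell)
  expected <- list(
    fraction_pct = 100 * cfg$producer_fraction,
    flesh_ng_per_kg = unname(exp_flesh),
    contribution_pct = unname(
      100 * cfg$producer_fraction["mucous"] * cfg$total16S_density["mucous"] *
        cfg$mucous_area_cm2 * ng_per_cell / (exp_flesh * cfg$fish_mass_kg)))

  structure(list(
    qpcr_plate = qpcr_plate,
    otu_table = otu$counts,
    taxonomy = otu$taxonomy,
    metadata = samples[, c("sample_id", "farm", "fish", "compartment",
                           "sampled_size", "size_unit")],
    measurements = measurements,
    water_geosmin = water_geosmin,
    truth = list(samples = samples, farms = truth_farm, expected = expected,
                 yield_free = cfg$yield_free, yield_bound = cfg$yield_bound,
                 uptake_fraction = cfg$uptake_fraction),
    config = cfg), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic fish-farm dataset: %d farms, %d samples, %d qPCR wells, %d OTUs\n",
    x$config$n_farms, nrow(x$metadata), nrow(x$qpcr_plate), nrow(x$otu_table)))
  invisible(x)
}
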