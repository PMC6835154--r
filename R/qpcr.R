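#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies). The slope of a well-behaved
#' assay is close to -3.32 (perfect doubling each cycle); amplification
#' efficiency is derived as `10^(-1/slope) - 1`.
#'
#' @param points data.frame with columns `copies` (known standard copy
#'   numbers, > 0) and `cq` (observed quantification cycles).
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept` (Cq at 1 copy), `r2`, `efficiency` and `n_points`.
#' @examples
#' std <- data.frame(copies = 10^(2:6), cq = 40 - 3.3219 * (2:6))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(points) {
  if (!is.data.frame(points) || !all(c("copies", "cq") %in% names(points)))
    stop("points must be a data.frame with columns 'copies' and 'cq'")
  copies <- points$copies
  cq <- points$cq
  assert_finite(cq, "standard Cq values")
  if (!all(is.finite(copies)) || any(copies <= 0))
    stop("standard copies must be positive and finite")
  if (length(unique(copies)) < 3)
    stop("insufficient standards: need >= 3 distinct copy levels")
  x <- log10(copies)
  fit <- stats::lm.fit(cbind(1, x), cq)
  intercept <- unname(fit$coefficients[1])
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve slope must be negative (Cq decreases with copies)")
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(
    list(slope = slope, intercept = intercept, r2 = r2,
         efficiency = 10^(-1 / slope) - 1, n_points = length(cq)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f %+.4f * log10(copies)\n  efficiency = %.1f%%, R2 = %.4f, n = %d\n",
    x$intercept, x$slope, 100 * x$efficiency, x$r2, x$n_points))
  invisible(x)
}

#' Convert Cq values to absolute copy numbers
#'
#' Inverts a fitted standard curve: `copies = 10^((cq - intercept)/slope)`.
#' Wells with no amplification (Cq = `NA`) map to 0 copies, encoding
#' "below one copy per reaction".
#'
#' @param cq numeric vector of quantification cycles; `NA` = no amplification.
#' @param curve a `standard_curve`.
#' @return numeric vector of copies per reaction.
#' @export
quantify <- function(cq, curve) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve")
  if (any(!is.na(cq) & !is.finite(cq)))
    stop("Cq values must be finite or NA (no amplification)")
  out <- 10^((cq - curve$intercept) / curve$slope)
  out[is.na(cq)] <- 0
  out
}

#' Quality control of a qPCR assay
#'
#' Applies the acceptance gates used for the geoA and 16S assays:
#' amplification efficiency above `efficiency_min` (> 90%), replicate
#' coefficient of variation below `cv_max` (< 30%), and standard-curve R2 at
#' least `r2_min`.
#'
#' @param curve a `standard_curve`.
#' @param replicate_copies numeric vector (>= 2) of replicate copy estimates.
#' @param efficiency_min,cv_max,r2_min thresholds; defaults 0.90, 0.30, 0.98.
#' @return list of class `qc_report`: metrics, pass booleans, and `flags`.
#' @export
qc_assay <- function(curve, replicate_copies,
                     efficiency_min = 0.90, cv_max = 0.30, r2_min = 0.98) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve")
  assert_nonneg(replicate_copies, "replicate copies")
  if (length(replicate_copies) < 2)
    stop("need >= 2 replicates to compute a CV")
  flags <- character(0)
  m <- mean(replicate_copies)
  if (m == 0) {
    cv <- NA_real_
    cv_pass <- FALSE
    flags <- c(flags, "cv_undefined_all_zero")
  } else {
    cv <- stats::sd(replicate_copies) / m
    cv_pass <- cv < cv_max
  }
  eff_pass <- curve$efficiency > efficiency_min
  r2_pass <- !is.na(curve$r2) && curve$r2 >= r2_min
  if (!eff_pass) flags <- c(flags, "efficiency_low")
  if (!r2_pass) flags <- c(flags, "r2_low")
  structure(list(efficiency = curve$efficiency, efficiency_pass = eff_pass,
                 replicate_cv = cv, cv_pass = cv_pass,
                 r2 = curve$r2, r2_pass = r2_pass, flags = flags),
            class = "qc_report")
}

#' Sum geoA group assays into a total
#'
#' The geoA census uses four primer-group assays (g1, g3, g4, g5); total geoA
#' is their arithmetic sum. Missing groups count as absent (0 copies).
#'
#' @param group_copies named numeric; names must be a subset of
#'   `c("g1","g3","g4","g5")`.
#' @return total copies (scalar).
#' @export
sum_geoA_groups <- function(group_copies) {
  groups <- c("g1", "g3", "g4", "g5")
  if (length(group_copies) == 0) return(0)
  if (is.null(names(group_copies)) || !all(names(group_copies) %in% groups))
    stop("geoA groups must be named and within {g1, g3, g4, g5}")
  assert_nonneg(group_copies, "geoA group copies")
  sum(group_copies)
}

#' Normalize copies per reaction to a compartment concentration
#'
#' Converts a per-reaction copy number into copies per mL (water), per cm2
#' (mucous/fin surface) or per g (digesta):
#' `concentration = copies * template_scaling / (extraction_yield * sampled_size)`.
#' `template_scaling` is the elution-volume / template-fraction calibration
#' knob (default 1, i.e. the reaction template represents the whole extract).
#'
#' @param copies_per_reaction copies in the reaction template.
#' @param sampled_size extent sampled (mL, cm2 or g), > 0.
#' @param unit one of "mL", "cm2", "g".
#' @param template_scaling,extraction_yield calibration factors, > 0.
#' @param compartment optional compartment name; if given, the unit is checked
#'   against the compartment convention (water->mL, mucous/fin->cm2, digesta->g).
#' @return concentration with attribute `unit`.
#' @export
normalize_concentration <- function(copies_per_reaction, sampled_size,
                                    unit = c("mL", "cm2", "g"),
                                    template_scaling = 1, extraction_yield = 1,
                                    compartment = NULL) {
  unit <- match.arg(unit)
  assert_nonneg(copies_per_reaction, "copies per reaction")
  if (any(!is.finite(sampled_size)) || any(sampled_size <= 0))
    stop("sampled_size must be positive")
  if (template_scaling <= 0 || extraction_yield <= 0)
    stop("template_scaling and extraction_yield must be positive")
  if (!is.null(compartment)) {
    expected <- compartment_units[compartment]
    if (any(is.na(expected)) || any(expected != unit))
      stop("unit '", unit, "' does not match compartment '", compartment, "'")
  }
  conc <- copies_per_reaction * template_scaling / (extraction_yield * sampled_size)
  attr(conc, "unit") <- unit
  conc
}

#' Quantify a full qPCR plate
#'
#' Per assay: fits the standard curve from wells flagged `is_standard`,
#' converts unknown-well Cq values to copies, and averages replicates on the
#' linear (copies) scale. geoA group assays are summed per sample.
#'
#' @param plate data.frame with columns `sample_id`, `assay_id`, `replicate`,
#'   `cq` (NA = no amplification), `is_standard`, `standard_copies`.
#' @param geoA_assays assay ids holding the geoA groups.
#' @param assay_16s assay id of the total-bacteria 16S assay (or NULL).
#' @return list with `curves` (per assay), `qc` (per assay `qc_report`), and
#'   `samples`: data.frame of per-sample mean copies per reaction per assay,
#'   plus `geoA_total`.
#' @export
quantify_plate <- function(plate,
                           geoA_assays = c("geoA_g1", "geoA_g3", "geoA_g4", "geoA_g5"),
                           assay_16s = "bact16S") {
  need <- c("sample_id", "assay_id", "replicate", "cq", "is_standard", "standard_copies")
  if (!all(need %in% names(plate)))
    stop("plate is missing columns: ", paste(setdiff(need, names(plate)), collapse = ", "))
  assays <- unique(plate$assay_id)
  curves <- list()
  qc <- list()
  sample_ids <- unique(plate$sample_id[!plate$is_standard])
  out <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (a in assays) {
    pa <- plate[plate$assay_id == a, , drop = FALSE]
    std <- pa[pa$is_standard, , drop = FALSE]
    if (nrow(std) < 3) stop("assay ", a, ": fewer than 3 standard wells")
    curves[[a]] <- fit_standard_curve(
      data.frame(copies = std$standard_copies, cq = std$cq))
    unk <- pa[!pa$is_standard, , drop = FALSE]
    copies <- quantify(unk$cq, curves[[a]])
    mean_copies <- tapply(copies, unk$sample_id, mean)
    col <- rep(NA_real_, nrow(out))
    idx <- match(names(mean_copies), out$sample_id)
    col[idx] <- as.numeric(mean_copies)
    out[[a]] <- col
    ## QC on the replicate structure of the first multi-replicate sample
    first <- unk$sample_id[1]
    reps <- copies[unk$sample_id == first]
    qc[[a]] <- if (length(reps) >= 2) qc_assay(curves[[a]], reps) else NULL
  }
  geoA_present <- intersect(geoA_assays, assays)
  if (length(geoA_present) > 0) {
    m <- as.matrix(out[, geoA_present, drop = FALSE])
    m[is.na(m)] <- 0
    out$geoA_total <- rowSums(m)
  }
  list(curves = curves, qc = qc, samples = out)
}
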