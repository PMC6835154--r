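#' Read / write an OTU count table
#'
#' TSV dialect: first column `otu_id`, remaining columns per-sample integer
#' counts; UTF-8, Unix newlines.
#'
#' @param path file path.
#' @return integer matrix, OTUs x samples, rownames = otu ids.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "otu_id") stop("first column must be 'otu_id'")
  ids <- df$otu_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate otu_id: ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    col <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(col) | col != round(col))
    if (length(bad) > 0)
      stop(sprintf("non-integer count at row %d, column '%s'",
                   bad[1], colnames(m)[j]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_otu_table
#' @param otu_table OTUs x samples matrix with rownames.
#' @export
write_otu_table <- function(otu_table, path) {
  df <- data.frame(otu_id = rownames(otu_table), otu_table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write taxonomy assignments
#'
#' TSV with columns `otu_id` and `lineage` (semicolon-delimited, greengenes
#' rank prefixes accepted).
#'
#' @param path file path.
#' @return data.frame `otu_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(df)))
    stop("taxonomy file needs columns otu_id and lineage")
  df
}

#' @rdname read_taxonomy
#' @param taxonomy data.frame `otu_id`, `lineage`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write geosmin measurement records
#'
#' CSV with columns `farm`, `compartment`, `value`, `se`, `unit`; the unit
#' must come from the closed vocabulary (ng/kg, ng/L, pg/g, ng/cm2,
#' ng/intestine, copies/mL). A missing SE is recorded as `NA`, not 0.
#'
#' @param path file path.
#' @return data.frame of measurement records.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("farm", "compartment", "value", "unit")
  if (!all(need %in% names(df)))
    stop("measurements file needs columns: ", paste(need, collapse = ", "))
  if (!"se" %in% names(df)) df$se <- NA_real_
  df$value <- as.numeric(df$value)
  df$se <- as.numeric(df$se)
  bad <- setdiff(unique(df$unit), measurement_units)
  if (length(bad) > 0)
    stop("unknown unit(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(measurement_units, collapse = ", "))
  df
}

#' @rdname read_measurements
#' @param measurements data.frame of measurement records.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a qPCR plate
#'
#' CSV with columns `sample_id`, `assay_id`, `replicate`, `cq` (empty = no
#' amplification), `is_standard`, `standard_copies`.
#'
#' @param path file path.
#' @return data.frame plate.
#' @export
read_qpcr_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_id", "replicate", "cq", "is_standard",
            "standard_copies")
  if (!all(need %in% names(df)))
    stop("plate file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$cq <- as.numeric(df$cq)
  df$is_standard <- as.logical(df$is_standard)
  df
}

#' @rdname read_qpcr_plate
#' @param plate data.frame plate.
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic dataset in the dialects the readers accept
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    qpcr_plate = file.path(dir, "qpcr_plate.csv"),
    otu_table = file.path(dir, "otu_table.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "sample_metadata.tsv"),
    measurements = file.path(dir, "measurements.csv"),
    water_geosmin = file.path(dir, "water_geosmin.csv"))
  write_qpcr_plate(dataset$qpcr_plate, paths["qpcr_plate"])
  write_otu_table(dataset$otu_table, paths["otu_table"])
  write_taxonomy(dataset$taxonomy, paths["taxonomy"])
  utils::write.table(dataset$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_measurements(dataset$measurements, paths["measurements"])
  utils::write.csv(dataset$water_geosmin, paths["water_geosmin"],
                   row.names = FALSE, quote = FALSE)
  paths
}

read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "farm", "compartment", "sampled_size", "size_unit")
  if (!all(need %in% names(df)))
    stop("metadata file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Serialize a contribution table, rounding percentages as printed
#'
#' Percent columns are rounded to one decimal at serialization only.
#'
#' @param table a `contribution_table`.
#' @param path file path (TSV).
#' @export
write_contribution_table <- function(table, path) {
  out <- as.data.frame(table)
  for (col in c("contribution_flesh_pct", "contribution_water_pct"))
    out[[col]] <- round(out[[col]], 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
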