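## lineage rank order used throughout
lineage_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Parse semicolon-delimited lineages into a rank matrix
#'
#' Accepts greengenes-style rank prefixes (`k__`, `p__`, ...) and strips
#' them. Ranks may be empty from any point downward; a filled rank below an
#' empty one (a gap) is malformed.
#'
#' @param lineages character vector, e.g.
#'   `"k__Bacteria;p__Cyanobacteria;c__;o__;f__;g__"`.
#' @return character matrix with columns kingdom..genus ("" = unassigned).
#' @export
parse_lineage <- function(lineages) {
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  m <- matrix("", nrow = length(parts), ncol = length(lineage_ranks),
              dimnames = list(NULL, lineage_ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[kpcofgs]__", "", p)
    p <- p[seq_len(min(length(p), ncol(m)))]
    m[i, seq_along(p)] <- p
  }
  m
}

check_lineage <- function(ranks) {
  filled <- nzchar(ranks) & !is.na(ranks)
  if (any(filled) && any(!filled)) {
    last <- max(which(filled))
    if (any(!filled[seq_len(last)]))
      stop("malformed lineage: filled rank below an empty one (",
           paste(ranks, collapse = ";"), ")")
  }
  invisible(ranks)
}

#' Default putative-producer screening rules
#'
#' Ordered most-specific-rank-first so genus-level carve-outs (Streptomyces,
#' Sorangium) take precedence over their parent orders, matching the group
#' columns the screen reports: Actinomycetales, Streptomyces, Cyanobacteria,
#' Myxococcales, Sorangium.
#'
#' @return data.frame with columns `rank`, `name`, `group_label`.
#' @export
default_producer_rules <- function() {
  data.frame(
    rank = c("genus", "genus", "order", "order", "phylum"),
    name = c("Streptomyces", "Sorangium", "Myxococcales",
             "Actinomycetales", "Cyanobacteria"),
    group_label = c("Streptomyces", "Sorangium", "Myxococcales",
                    "Actinomycetales", "Cyanobacteria"),
    stringsAsFactors = FALSE)
}

#' Flag a lineage as a putative geosmin producer
#'
#' First matching rule wins (rules are ordered, most specific first);
#' matching is case-insensitive exact on the rank name. Taxa outside the
#' producer clades (e.g. the ubiquitous Cetobacterium) return `NA`.
#'
#' @param lineage named character vector of ranks (kingdom..genus) or a
#'   single lineage string parseable by [parse_lineage()].
#' @param rules data.frame as from [default_producer_rules()].
#' @return the matched `group_label`, or `NA_character_`.
#' @export
flag_putative_producer <- function(lineage, rules = default_producer_rules()) {
  if (nrow(rules) < 1) stop("rules must be non-empty")
  if (is.character(lineage) && is.null(names(lineage)) && length(lineage) == 1)
    lineage <- parse_lineage(lineage)[1, ]
  ranks <- lineage[lineage_ranks]
  names(ranks) <- lineage_ranks
  ranks[is.na(ranks)] <- ""
  check_lineage(ranks)
  for (i in seq_len(nrow(rules))) {
    have <- ranks[[rules$rank[i]]]
    if (nzchar(have) && tolower(have) == tolower(rules$name[i]))
      return(rules$group_label[i])
  }
  NA_character_
}

rel_abundance <- function(otu_table) {
  totals <- colSums(otu_table)
  sweep(otu_table, 2, totals, "/")
}

#' Producer-group relative abundance ranges per sample type
#'
#' Per sample, the relative abundance of each producer group is the summed
#' read count of its OTUs over the sample total; per sample type the min-max
#' range across samples is reported. Groups with zero reads everywhere are
#' reported as 0%.
#'
#' @param otu_table integer matrix, OTUs x samples (rownames = otu ids).
#' @param taxonomy data.frame with columns `otu_id` and `lineage`.
#' @param sample_groups character vector (length = ncol) assigning each
#'   sample to a type (e.g. compartment).
#' @param rules producer rules, see [default_producer_rules()].
#' @return data.frame: `group`, `sample_type`, `min_pct`, `max_pct`.
#' @export
producer_abundance_table <- function(otu_table, taxonomy, sample_groups,
                                     rules = default_producer_rules()) {
  if (any(otu_table < 0)) stop("counts must be non-negative")
  if (length(sample_groups) != ncol(otu_table))
    stop("sample_groups must assign every sample a type")
  zero <- colSums(otu_table) == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " sample(s) with zero total reads")
    otu_table <- otu_table[, !zero, drop = FALSE]
    sample_groups <- sample_groups[!zero]
  }
  lin <- parse_lineage(taxonomy$lineage)
  flags <- vapply(seq_len(nrow(lin)),
                  function(i) flag_putative_producer(lin[i, ], rules) %||% NA_character_,
                  character(1))
  names(flags) <- taxonomy$otu_id
  flags <- flags[rownames(otu_table)]
  ra <- rel_abundance(otu_table)
  groups <- unique(rules$group_label)
  types <- unique(sample_groups)
  res <- expand.grid(group = groups, sample_type = types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$min_pct <- res$max_pct <- NA_real_
  for (i in seq_len(nrow(res))) {
    sel_otu <- !is.na(flags) & flags == res$group[i]
    sel_smp <- sample_groups == res$sample_type[i]
    per_sample <- if (any(sel_otu))
      colSums(ra[sel_otu, sel_smp, drop = FALSE]) else rep(0, sum(sel_smp))
    res$min_pct[i] <- 100 * min(per_sample)
    res$max_pct[i] <- 100 * max(per_sample)
  }
  res
}

#' Top-n most abundant OTUs as mean proportions per sample type
#'
#' OTUs are ranked by mean relative abundance across all samples; ties are
#' broken by total reads, then otu id. Returns the mean per-sample-type
#' proportions for the top n.
#'
#' @param otu_table OTUs x samples count matrix with rownames.
#' @param n how many OTUs (default 15).
#' @param sample_groups optional per-sample types; omitted = one overall column.
#' @return list: `ranking` (otu ids, ranked) and `matrix` (top-n x types mean
#'   proportions). If n exceeds the number of OTUs all are returned and the
#'   attribute `truncated` on the result is set TRUE.
#' @export
top_taxa <- function(otu_table, n = 15, sample_groups = NULL) {
  if (n < 1) stop("n must be >= 1")
  ra <- rel_abundance(otu_table)
  mean_ra <- rowMeans(ra)
  tot <- rowSums(otu_table)
  ord <- order(-mean_ra, -tot, rownames(otu_table))
  flag <- n > nrow(otu_table)
  if (flag) {
    warning("n exceeds the number of OTUs; returning all")
    n <- nrow(otu_table)
  }
  top <- ord[seq_len(n)]
  if (is.null(sample_groups)) sample_groups <- rep("all", ncol(ra))
  types <- unique(sample_groups)
  m <- sapply(types, function(ty)
    rowMeans(ra[top, sample_groups == ty, drop = FALSE]))
  m <- matrix(m, nrow = n, dimnames = list(rownames(otu_table)[top], types))
  out <- list(ranking = rownames(otu_table)[ord], matrix = m)
  attr(out, "truncated") <- flag
  out
}

#' Observed richness and the Chao1 estimator
#'
#' Bias-corrected Chao1: `S_obs + F1*(F1-1) / (2*(F2+1))`, with F1 the number
#' of singletons and F2 the number of doubletons; this form stays defined
#' when no doubletons are observed.
#'
#' @param counts non-negative integer vector of per-OTU counts in one sample.
#' @return list `observed_otus`, `chao1`.
#' @export
richness <- function(counts) {
  assert_nonneg(counts, "counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  list(observed_otus = s_obs, chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
}
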