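#' Redundancy analysis (constrained ordination)
#'
#' Classical RDA: the (optionally transformed) community matrix is
#' column-centered to Y and the standardized constraints X are regressed onto
#' it; the fitted values are eigen-analysed. The constrained variance percent
#' is `100 * trace(Yhat'Yhat) / trace(Y'Y)`. OTU "loadings" are reported as
#' correlations of the (transformed, centered) OTU columns with the
#' constrained site scores, matching the way top-loading taxa are read off an
#' RDA biplot.
#'
#' @param community numeric matrix, samples x OTUs (colnames = otu ids).
#' @param constraints numeric matrix/data.frame, samples x k.
#' @param transform community pre-transform: `"hellinger"` (square root of
#'   row proportions, the default), `"proportion"`, or `"none"`.
#' @return object of class `rda_result`: `constrained_variance_pct`,
#'   `axis_eigenvalues`, `site_scores`, `otu_loadings`, `constraint_names`,
#'   `transform`, `total_variance`.
#' @export
rda_constrained <- function(community, constraints,
                            transform = c("hellinger", "proportion", "none")) {
  transform <- match.arg(transform)
  community <- as.matrix(community)
  constraints <- as.matrix(constraints)
  if (is.null(colnames(constraints)))
    colnames(constraints) <- paste0("constraint", seq_len(ncol(constraints)))
  n <- nrow(community)
  k <- ncol(constraints)
  if (nrow(constraints) != n) stop("community and constraints disagree on samples")
  if (n < k + 2) stop("need at least k + 2 samples for k constraints")
  Y <- switch(transform,
    hellinger = {
      rs <- rowSums(community)
      if (any(rs <= 0)) stop("hellinger transform needs positive row sums")
      sqrt(community / rs)
    },
    proportion = {
      rs <- rowSums(community)
      if (any(rs <= 0)) stop("proportion transform needs positive row sums")
      community / rs
    },
    none = community)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  const_col <- apply(Y, 2, function(col) all(col == 0))
  if (any(const_col)) {
    warning("dropping ", sum(const_col), " constant OTU column(s)")
    Y <- Y[, !const_col, drop = FALSE]
  }
  if (ncol(Y) == 0) stop("no variable OTU columns left")
  X <- scale(constraints, center = TRUE, scale = TRUE)
  if (any(!is.finite(X))) stop("constraints contain a constant or non-finite column")
  qx <- qr(X)
  if (qx$rank < k) stop("collinear (rank-deficient) constraints")
  Yhat <- qr.fitted(qx, Y)
  sv <- svd(Yhat, nu = 0)
  eig <- sv$d^2 / (n - 1)
  total_var <- sum(Y^2) / (n - 1)
  keep <- which(eig > total_var * 1e-12)
  keep <- keep[seq_len(min(length(keep), k))]
  if (length(keep) == 0) {
    scores <- matrix(numeric(0), nrow = n, ncol = 0,
                     dimnames = list(rownames(community), NULL))
    loadings <- matrix(numeric(0), nrow = ncol(Y), ncol = 0,
                       dimnames = list(colnames(Y), NULL))
  } else {
    V <- sv$v[, keep, drop = FALSE]
    scores <- Yhat %*% V
    colnames(scores) <- paste0("RDA", seq_along(keep))
    rownames(scores) <- rownames(community)
    loadings <- suppressWarnings(stats::cor(Y, scores))
    rownames(loadings) <- colnames(Y)
  }
  structure(list(
    constrained_variance_pct = 100 * sum(Yhat^2) / sum(Y^2),
    axis_eigenvalues = eig[keep],
    site_scores = scores,
    otu_loadings = loadings,
    constraint_names = colnames(constraints),
    transform = transform,
    total_variance = total_var),
    class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA (%s transform): %.2f%% of community variance constrained by %s\n",
              x$transform, x$constrained_variance_pct,
              paste(x$constraint_names, collapse = " + ")))
  cat("Constrained eigenvalues:", signif(x$axis_eigenvalues, 4), "\n")
  invisible(x)
}

#' Strongest-loading OTUs on an RDA axis
#'
#' Ranks OTUs by absolute loading (correlation with the axis scores); ties
#' are broken by otu id. Returns the signed loadings.
#'
#' @param result an `rda_result`.
#' @param n how many OTUs (default 10).
#' @param axis axis index (default 1).
#' @return data.frame `otu_id`, `loading`, ranked.
#' @export
top_loadings <- function(result, n = 10, axis = 1) {
  if (!inherits(result, "rda_result")) stop("result must be an rda_result")
  if (n < 1) stop("n must be >= 1")
  if (axis > ncol(result$otu_loadings)) stop("axis exceeds available axes")
  l <- result$otu_loadings[, axis]
  if (is.null(names(l))) names(l) <- rownames(result$otu_loadings)
  ord <- order(-abs(l), names(l))
  n <- min(n, length(l))
  data.frame(otu_id = names(l)[ord][seq_len(n)],
             loading = unname(l[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}
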