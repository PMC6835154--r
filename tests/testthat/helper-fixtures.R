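## shared fixtures, all generated in code

# ideal perfect-doubling curve: Cq = 40 - 3.3219 * log10(copies)
ideal_curve <- function() {
  fit_standard_curve(data.frame(copies = 10^(2:6), cq = 40 - 3.3219 * (2:6)))
}

paper_yield <- function() per_cell_yield(73e-9, 67e-9, 1e9)

# small fast simulator configuration for pipeline-level tests
small_config <- function(seed = 1, otu_depth = 2000, n_background_otus = 60, ...) {
  sim_config(n_farms = 3, fish_per_farm = 6, water_samples_per_farm = 3,
             otu_depth = otu_depth, n_background_otus = n_background_otus,
             seed = seed, ...)
}

# random valid OTU count matrix
random_otu_table <- function(n_otu, n_samp, depth = 1000) {
  m <- matrix(stats::rpois(n_otu * n_samp, depth / n_otu), nrow = n_otu,
              dimnames = list(sprintf("OTU_%03d", seq_len(n_otu)),
                              sprintf("S%02d", seq_len(n_samp))))
  storage.mode(m) <- "integer"
  m
}

# brute-force RDA oracle: explicit projection matrix + full eigendecomposition
rda_oracle <- function(community, constraints, transform = "hellinger") {
  Y <- as.matrix(community)
  if (transform == "hellinger") Y <- sqrt(Y / rowSums(Y))
  if (transform == "proportion") Y <- Y / rowSums(Y)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Y <- Y[, apply(Y, 2, function(c) any(c != 0)), drop = FALSE]
  X <- scale(as.matrix(constraints), center = TRUE, scale = TRUE)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  Yhat <- H %*% Y
  ev <- eigen(t(Yhat) %*% Yhat / (nrow(Y) - 1), symmetric = TRUE)$values
  list(constrained_variance_pct = 100 * sum(Yhat^2) / sum(Y^2),
       eigenvalues = ev[ev > max(ev) * 1e-10])
}
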