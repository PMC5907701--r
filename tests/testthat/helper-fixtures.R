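# Shared fixtures, built in code at test time.

# Analytic Gaussian ridge of amplitude A and cross-section std s through the
# grid point (c0, c0) at angle theta (x = row axis).
analytic_ridge <- function(L, theta, A = 1, s = 1.5, c0 = L / 2) {
  outer(seq_len(L), seq_len(L), function(i, j) {
    d <- -(i - c0) * sin(theta) + (j - c0) * cos(theta)
    A * exp(-d^2 / (2 * s^2))
  })
}

# On-axis interior cells of the ridge above (distance < eps from the line).
on_axis_cells <- function(L, theta, c0 = L / 2, margin = 8L, eps = 0.01) {
  i <- rep(seq_len(L), L); j <- rep(seq_len(L), each = L)
  d <- -(i - c0) * sin(theta) + (j - c0) * cos(theta)
  keep <- abs(d) < eps & i > margin & i <= L - margin &
    j > margin & j <= L - margin
  cbind(i[keep], j[keep])
}

# Small shared training set + bundle, built once per test run (lazy).
.fixture_env <- new.env(parent = emptyenv())

tiny_config <- function() br_config(n_trees = 25L, seed = 101L)

tiny_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    cfg <- tiny_config()
    raw <- generate_dataset(8, c(50, 70), seed = 101)
    .fixture_env$ds <- lapply(raw, function(p)
      prepare_protein(p$map, p$ss_profile, p$truth, cfg, id = p$id))
    .fixture_env$raw <- raw
  }
  .fixture_env$ds
}

tiny_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- train_pipeline(tiny_dataset(), tiny_config(),
                                          k = 4L)
  }
  .fixture_env$bundle
}
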