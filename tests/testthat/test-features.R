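# Brute-force mask membership used as the independent oracle.
brute_mask_count <- function(ws, dw) {
  n <- 0L
  for (r in 0:(ws - 1)) for (c in 0:(ws - 1)) {
    if (abs(r - c) <= (dw - 1) / 2 || abs(r + c - (ws - 1)) <= (dw - 1) / 2)
      n <- n + 1L
  }
  n
}

test_that("window masks match brute-force enumeration for all sizes", {
  for (ws in c(3L, 5L, 7L, 9L)) for (dw in c(1L, 3L, 5L, 7L, 9L)) {
    wm <- window_mask(ws, dw)
    expect_equal(nrow(wm$offsets), brute_mask_count(ws, dw))
    expect_equal(sum(wm$cells), brute_mask_count(ws, dw))
    # 180-degree rotational symmetry
    expect_equal(wm$cells, wm$cells[ws:1, ws:1])
    if (dw >= ws) expect_true(all(wm$cells))
  }
  expect_equal(nrow(window_mask(3, 3)$offsets), 9L)
  expect_equal(nrow(window_mask(5, 3)$offsets), 21L)
  expect_equal(nrow(window_mask(9, 3)$offsets), 45L)
  expect_error(window_mask(4, 3), "odd")
})

test_that("candidate pairs enumerate the constrained upper triangle", {
  expect_equal(candidate_pairs(5, 3),
               cbind(i = c(1L, 1L, 2L), j = c(4L, 5L, 5L)))
  expect_equal(nrow(candidate_pairs(3, 3)), 0L)
  L <- 12
  expect_equal(nrow(candidate_pairs(L, 1)), L * (L - 1) / 2)
})

test_that("position features are the separation and four end distances", {
  L <- 10
  # terminal pair
  expect_equal(unname(position_features(1, L, L)[1, ]),
               c(L - 1, 0, L - 1, L - 1, 0))
  expect_equal(unname(position_features(3, 6, 10)[1, ]), c(3, 2, 7, 5, 4))
  expect_error(position_features(6, 3, 10))
})

test_that("map features are the per-residue MSA depth and candidate-score sd", {
  m <- matrix(0.2, 100, 100)
  cm <- contact_map(m, n_seqs = 500)
  mf <- map_features(cm)
  expect_equal(unname(mf["seq_ratio"]), 5)
  expect_equal(unname(mf["map_sd"]), 0)

  # hand-computed sd on a small map
  m2 <- matrix(0, 5, 5)
  m2[1, 4] <- 0.4; m2[1, 5] <- 0.8; m2[2, 5] <- 0.6
  cm2 <- contact_map(m2 + t(m2))
  expect_equal(unname(map_features(cm2, 3)["map_sd"]), sd(c(0.4, 0.8, 0.6)))
  expect_equal(unname(map_features(cm2, 3)["seq_ratio"]), 0)
})

test_that("feature rows have the documented lengths and sentinels", {
  cfg <- br_config()
  # stage 1 with 3 maps (raw, h, phi), ws = 5, dw = 3
  expect_equal(feature_row_length(3, 5, 3), 100L)
  expect_equal(feature_row_length(14, 3, 3, with_global = FALSE), 144L)
  expect_equal(feature_row_length(5, 3, 3, with_global = FALSE), 63L)

  L <- 20
  set.seed(1)
  maps <- list(raw = matrix(runif(L * L), L),
               h = matrix(runif(L * L), L),
               phi = matrix(runif(L * L), L))
  ss <- ss_profile(matrix(1 / 3, L, 3))
  mask <- window_mask(5, 3)
  x <- extract_pair_features(maps, ss, c(2, 0.1), mask,
                             cbind(c(5L, 1L), c(12L, L)))
  expect_equal(ncol(x), 100L)
  expect_true(all(is.finite(x)))

  # interior pair: window values match direct indexing
  off <- mask$offsets
  expect_equal(unname(x[1, seq_len(nrow(off))]),
               maps$raw[cbind(5 + off[, 1], 12 + off[, 2])])
  # boundary pair (1, L): cells above row 1 / right of column L are sentinel
  oob <- 1 + off[, 1] < 1 | L + off[, 2] > L
  expect_true(all(x[2, seq_len(nrow(off))][oob] == -1))
  expect_true(all(x[2, seq_len(nrow(off))][!oob] != -1))

  # global block: position then map features, in schema order
  expect_equal(unname(x[1, 94:100]), c(7, 4, 15, 11, 8, 2, 0.1))

  # determinism: identical inputs give bit-identical rows
  y <- extract_pair_features(maps, ss, c(2, 0.1), mask,
                             cbind(c(5L, 1L), c(12L, L)))
  expect_identical(x, y)
})

test_that("ss windows are zero-padded outside the chain", {
  L <- 10
  probs <- matrix(0, L, 3); probs[, 2] <- 1
  ss <- ss_profile(probs)
  maps <- list(raw = matrix(0, L, L))
  x <- extract_pair_features(maps, ss, NULL, window_mask(3, 3),
                             cbind(1L, 10L))
  ss_block <- x[1, 10:27]
  # window at residue 1: offset -1 out of range -> zeros; offsets 0, +1 are E
  expect_equal(unname(ss_block[1:9]), c(0, 0, 0, 0, 1, 0, 0, 1, 0))
  # window at residue 10: offset +1 out of range
  expect_equal(unname(ss_block[10:18]), c(0, 1, 0, 0, 1, 0, 0, 0, 0))
})
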