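test_that("topologies obey the pairing rules and packing constraints", {
  for (seed in c(1, 2, 3)) {
    topo <- generate_topology(80, 5, seed = seed)
    st <- topo$strands
    # strands 3-8 long, separated by >= 2 coil residues, inside the chain
    expect_true(all(st[, 2] - st[, 1] + 1 >= 3))
    expect_true(all(st[, 2] - st[, 1] + 1 <= 8))
    expect_true(all(diff(as.vector(t(st)))[c(FALSE, TRUE)] >= 3))
    expect_true(st[1, 1] >= 1 && st[nrow(st), 2] <= 80)

    # contacts follow the diagonal / anti-diagonal register of each pairing
    expected <- NULL
    for (r in seq_len(nrow(topo$pairings))) {
      A <- st[topo$pairings$a[r], ]; B <- st[topo$pairings$b[r], ]
      off <- topo$pairings$offset[r]
      kk <- 0:(A[2] - A[1])
      j <- if (topo$pairings$orientation[r] == "antiparallel")
        B[2] - kk - off else B[1] + kk + off
      ok <- j >= B[1] & j <= B[2]
      expected <- rbind(expected, cbind(A[1] + kk, j)[ok, , drop = FALSE])
    }
    expected <- unique(cbind(pmin(expected[, 1], expected[, 2]),
                             pmax(expected[, 1], expected[, 2])))
    expected <- expected[order(expected[, 1], expected[, 2]), ]
    expect_equal(unname(topo$truth$contacts), unname(expected))

    # every strand pairs with 1-2 partners (chain topology)
    deg <- table(factor(c(topo$pairings$a, topo$pairings$b),
                        levels = seq_len(nrow(st))))
    expect_true(all(deg >= 1 & deg <= 2))

    # ss string marks exactly the strand residues as E
    ss <- strsplit(topo$ss_truth, "")[[1]]
    e_idx <- which(ss == "E")
    expect_equal(e_idx, unlist(lapply(seq_len(nrow(st)),
                                      function(s) st[s, 1]:st[s, 2])))
  }
  expect_identical(generate_topology(80, 5, seed = 9),
                   generate_topology(80, 5, seed = 9))
})

test_that("an antiparallel full-register pairing yields the anti-diagonal run", {
  # locate a seed giving an antiparallel zero-offset pairing, then check the
  # enumerated contacts form (a1 + k, b2 - k)
  found <- FALSE
  for (seed in 1:30) {
    topo <- generate_topology(60, 3, seed = seed)
    rows <- which(topo$pairings$orientation == "antiparallel" &
                    topo$pairings$offset == 0)
    if (!length(rows)) next
    r <- rows[1]
    A <- topo$strands[topo$pairings$a[r], ]
    B <- topo$strands[topo$pairings$b[r], ]
    n <- min(A[2] - A[1], B[2] - B[1]) + 1
    kk <- 0:(n - 1)
    expected <- cbind(pmin(A[1] + kk, B[2] - kk), pmax(A[1] + kk, B[2] - kk))
    keys <- paste(topo$truth$contacts[, 1], topo$truth$contacts[, 2])
    expect_true(all(paste(expected[, 1], expected[, 2]) %in% keys))
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("synthetic maps are symmetric with signal concentrated on truth", {
  topo <- generate_topology(60, 4, seed = 5)
  # noiseless limit: every truth cell >= signal, far cells exactly 0
  cm0 <- generate_contact_map(topo$truth, 60, signal = 1, noise_scale = 0,
                              n_decoys = 0, seed = 5)
  expect_true(all(cm0$scores[topo$truth$contacts] >= 1))
  far <- matrix(0, 60, 60)
  for (r in seq_len(nrow(topo$truth$contacts))) {
    ij <- topo$truth$contacts[r, ]
    rr <- max(1, ij[1] - 6):min(60, ij[1] + 6)
    cc <- max(1, ij[2] - 6):min(60, ij[2] + 6)
    far[rr, cc] <- 1; far[cc, rr] <- 1
  }
  expect_true(all(cm0$scores[far == 0] == 0))

  cm <- generate_contact_map(topo$truth, 60, seed = 5)
  expect_identical(cm$scores, t(cm$scores))
  expect_true(all(cm$scores >= 0))
  truth_mean <- mean(cm$scores[topo$truth$contacts])
  bg_mean <- mean(cm$scores[far == 0])
  expect_gt(truth_mean, bg_mean)
})

test_that("ss corruption hits the requested argmax accuracy", {
  ss_truth <- paste(rep(c("H", "E", "C"), length.out = 10000), collapse = "")
  prof <- corrupt_ss_profile(ss_truth, q = 0.8, sharpness = 6, seed = 3)
  expect_true(all(abs(rowSums(prof$probs) - 1) < 1e-9))
  truth_state <- match(strsplit(ss_truth, "")[[1]], c("H", "E", "C"))
  acc <- mean(max.col(prof$probs) == truth_state)
  expect_gte(acc, 0.78)
  expect_lte(acc, 0.82)

  # q = 1 with huge sharpness recovers the one-hot truth argmax everywhere
  exact <- corrupt_ss_profile("HECCEH", q = 1, sharpness = 1e6, seed = 1)
  expect_equal(max.col(exact$probs), match(strsplit("HECCEH", "")[[1]],
                                           c("H", "E", "C")))
})

test_that("datasets are reproducible, distinct, and in the sparse regime", {
  ds <- generate_dataset(6, c(50, 70), seed = 77)
  expect_length(ds, 6)
  hashes <- vapply(ds, function(p) paste(dim(p$map$scores)[1],
                                         sum(p$map$scores)), character(1))
  expect_equal(anyDuplicated(hashes), 0L)
  ratio <- attr(ds, "pos_neg_ratio")
  expect_gt(1 / ratio, 50)      # strongly imbalanced, like real beta maps
  expect_lt(1 / ratio, 5000)
  ds2 <- generate_dataset(6, c(50, 70), seed = 77)
  expect_identical(ds[[3]]$map$scores, ds2[[3]]$map$scores)
  for (p in ds) {
    expect_true(all(abs(rowSums(p$ss_profile$probs) - 1) < 1e-9))
    expect_true(all(p$truth$contacts[, 2] - p$truth$contacts[, 1] >= 3))
  }
})

test_that("dataset files round-trip through the plain-text writers", {
  ds <- generate_dataset(2, c(40, 50), seed = 19)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  mf <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(mf), 2L)
  back <- read_contact_map(mf$map[1], n_seqs = mf$n_seqs[1])
  expect_lt(max(abs(back$scores - ds[[1]]$map$scores)), 1e-6)
  ssb <- read_ss_profile(mf$ss[1], "predicted_ss")
  expect_lt(max(abs(ssb$probs - ds[[1]]$ss_profile$probs)), 2e-6)
  lab <- read_labels(mf$labels[1])
  expect_equal(lab$contacts, ds[[1]]$truth$contacts)
  dssp <- readLines(mf$dssp[1])
  expect_equal(dssp, ds[[1]]$ss_truth)
})
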