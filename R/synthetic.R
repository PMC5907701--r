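# Seeded synthetic proteins: beta-strand topologies with ground-truth
# beta-beta contacts, noisy contact maps in which contact runs form genuine
# Gaussian ridges (diagonal for parallel pairings, anti-diagonal for
# antiparallel), and imperfect 3-state secondary-structure profiles. Every
# module of the pipeline is testable against these without downloads.

with_seed <- function(seed, expr) {
  rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs))
  set.seed(seed)
  expr
}

# sample() misbehaves on length-1 vectors; always sample from the set given
sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate a beta-strand topology with ground-truth contacts
#'
#' Places `n_strands` non-overlapping strands of length 3-8 separated by at
#' least 2 coil residues, then connects them in a chain so every strand
#' pairs with 1-2 partners. An antiparallel pairing of strands
#' `A = (a1..a2)` and `B = (b1..b2)` yields contacts `(a1 + k, b2 - k)` over
#' the overlapping register; a parallel pairing yields `(a1 + k, b1 + k)`
#' (both shifted by the sampled register offset). Deterministic per seed.
#'
#' @param L protein length, >= 30.
#' @param n_strands number of strands, in `[2, L / 6]`.
#' @param seed integer seed.
#' @return list with `ss_truth` (3-state string), `strands` (interval
#'   matrix), `pairings` (data.frame: strand indices, orientation, offset)
#'   and `truth` (a [label_set()]).
#' @export
generate_topology <- function(L, n_strands, seed = 1L) {
  stopifnot(L >= 30L, n_strands >= 2L, n_strands <= L / 6)
  with_seed(derive_seed(seed, "topology"), {
    strands <- NULL
    for (attempt in 1:50) {
      lens <- sample(3:8, n_strands, replace = TRUE)
      need <- sum(lens) + 2L * (n_strands - 1L)
      if (need > L) next
      slack <- L - need
      extra <- if (slack > 0)
        tabulate(sample(n_strands + 1L, slack, replace = TRUE),
                 n_strands + 1L)
      else rep(0L, n_strands + 1L)
      starts <- integer(n_strands)
      pos <- 1L + extra[1L]
      for (s in seq_len(n_strands)) {
        starts[s] <- pos
        pos <- pos + lens[s] + 2L + extra[s + 1L]
      }
      strands <- cbind(start = starts, end = starts + lens - 1L)
      break
    }
    if (is.null(strands))
      stop("could not place ", n_strands, " strands in length ", L)
    ord <- sample(n_strands)
    pairings <- data.frame(a = ord[-n_strands], b = ord[-1L],
                           orientation = sample(c("parallel", "antiparallel"),
                                                n_strands - 1L,
                                                replace = TRUE),
                           offset = sample(c(-1L, 0L, 0L, 0L, 1L),
                                           n_strands - 1L, replace = TRUE))
    contacts <- NULL
    for (r in seq_len(nrow(pairings))) {
      A <- strands[pairings$a[r], ]; B <- strands[pairings$b[r], ]
      off <- pairings$offset[r]
      kk <- 0:(A[2] - A[1])
      if (pairings$orientation[r] == "antiparallel") {
        i <- A[1] + kk; j <- B[2] - kk - off
      } else {
        i <- A[1] + kk; j <- B[1] + kk + off
      }
      ok <- j >= B[1] & j <= B[2]
      contacts <- rbind(contacts, cbind(i[ok], j[ok]))
    }
    ss <- rep("C", L)
    for (s in seq_len(n_strands)) ss[strands[s, 1]:strands[s, 2]] <- "E"
    # decorate long coil stretches with occasional helices
    runs <- rle(ss == "C")
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (r in which(runs$values & runs$lengths >= 7L)) {
      if (stats::runif(1) < 0.5) {
        hl <- sample1(4:(runs$lengths[r] - 3L))
        h0 <- starts[r] + sample.int(runs$lengths[r] - hl - 1L, 1L)
        ss[h0:(h0 + hl - 1L)] <- "H"
      }
    }
    list(ss_truth = paste(ss, collapse = ""),
         strands = strands,
         pairings = pairings,
         truth = label_set(contacts, strands, L = L))
  })
}

#' Generate a noisy synthetic contact map
#'
#' Background is the absolute value of centered Gaussian noise of scale
#' `noise_scale`; every true contact adds a symmetric Gaussian bump of
#' amplitude `signal` and std `bump_std` (~1 cell), so runs of consecutive
#' contacts form genuine ridges whose ground-truth width is `bump_std`.
#' `n_decoys` short diagonal/anti-diagonal decoy segments of the same
#' brightness are added off the truth set, so learning "any bright cell is a
#' contact" is not sufficient.
#'
#' @param truth a [label_set()] of true contacts.
#' @param L protein length.
#' @param signal bump amplitude (map units).
#' @param noise_scale std of the background noise before rectification.
#' @param n_decoys number of decoy segments.
#' @param seed integer seed.
#' @param bump_std std of the contact bumps, grid units.
#' @param min_sep decoys are placed with `j - i >= min_sep`.
#' @return a [contact_map()] (entries >= 0, exactly symmetric).
#' @export
generate_contact_map <- function(truth, L, signal = 1, noise_scale = 0.35,
                                 n_decoys = max(4L, round(L / 12)),
                                 seed = 1L, bump_std = 1, min_sep = 3L) {
  stopifnot(signal > 0, noise_scale >= 0)
  with_seed(derive_seed(seed, "map"), {
    bg <- matrix(0, L, L)
    ut <- upper.tri(bg, diag = TRUE)
    bg[ut] <- abs(stats::rnorm(sum(ut), 0, noise_scale))
    bg <- bg + t(bg) - diag(diag(bg))
    truth_cells <- truth$contacts
    decoys <- NULL
    if (n_decoys > 0) {
      tk <- pair_key(truth_cells)
      for (dcount in seq_len(n_decoys)) {
        for (attempt in 1:25) {
          len <- sample1(3:6)
          anti <- stats::runif(1) < 0.5
          i0 <- sample.int(L - len + 1L, 1L)
          jlo <- i0 + min_sep + if (anti) 2L * len - 2L else 0L
          jhi <- L - if (anti) 0L else len - 1L
          if (jlo > jhi) next
          j0 <- sample1(jlo:jhi)
          kk <- 0:(len - 1L)
          cand <- cbind(i0 + kk, if (anti) j0 - kk else j0 + kk)
          if (any(cand[, 2] > L) || any(cand[, 2] - cand[, 1] < min_sep))
            next
          if (any(paste(cand[, 1], cand[, 2]) %in% tk)) next
          decoys <- rbind(decoys, cand)
          break
        }
      }
    }
    bumps <- matrix(0, L, L)
    rad <- ceiling(3 * bump_std) + 1L
    add_bump <- function(i, j) {
      rr <- max(1L, i - rad):min(L, i + rad)
      cc <- max(1L, j - rad):min(L, j + rad)
      bumps[rr, cc] <<- bumps[rr, cc] + signal *
        exp(-(outer((rr - i)^2, (cc - j)^2, `+`)) / (2 * bump_std^2))
    }
    cells <- rbind(truth_cells, decoys)
    if (!is.null(cells) && nrow(cells)) {
      for (r in seq_len(nrow(cells))) {
        add_bump(cells[r, 1], cells[r, 2])
        add_bump(cells[r, 2], cells[r, 1])
      }
    }
    contact_map(pmax(bg + bumps, 0))
  })
}

#' Corrupt a native secondary-structure assignment into a soft profile
#'
#' Per residue, with probability `q` the true state receives the largest
#' probability mass, otherwise one of the two wrong states does; masses are
#' drawn with Dirichlet-like concentration `sharpness` on the selected
#' state. `q = 1` with large `sharpness` recovers the one-hot truth.
#'
#' @param ss_truth 3-state string or one-hot [ss_profile()].
#' @param q probability that the argmax state is the true one, in `(0, 1]`.
#' @param sharpness concentration of mass on the argmax state (> 0).
#' @param seed integer seed.
#' @return an [ss_profile()] with rows summing to 1.
#' @export
corrupt_ss_profile <- function(ss_truth, q = 0.8, sharpness = 6,
                               seed = 1L) {
  stopifnot(q > 0, q <= 1, sharpness > 0)
  if (is.character(ss_truth)) ss_truth <- ss_from_string(ss_truth)
  true_state <- max.col(ss_truth$probs)
  L <- length(true_state)
  with_seed(derive_seed(seed, "ss"), {
    correct <- stats::runif(L) < q
    chosen <- true_state
    wrong <- !correct
    if (any(wrong)) {
      pick <- function(s) sample(setdiff(1:3, s), 1L)
      chosen[wrong] <- vapply(true_state[wrong], pick, integer(1))
    }
    w <- matrix(stats::rgamma(3L * L, shape = 1), L, 3)
    w[cbind(seq_len(L), chosen)] <- w[cbind(seq_len(L), chosen)] + sharpness
    p <- w / rowSums(w)
    # guarantee the selected state carries the max mass
    mx <- max.col(p)
    swap <- mx != chosen
    if (any(swap)) {
      ii <- which(swap)
      tmp <- p[cbind(ii, chosen[ii])]
      p[cbind(ii, chosen[ii])] <- p[cbind(ii, mx[ii])]
      p[cbind(ii, mx[ii])] <- tmp
    }
    ss_profile(p)
  })
}

#' Generate one synthetic protein
#'
#' @param L protein length.
#' @param seed integer seed.
#' @param n_strands number of strands (default: sampled in `[3, min(7,
#'   L/12)]`).
#' @param signal,noise_scale,n_decoys,bump_std map parameters, see
#'   [generate_contact_map()].
#' @param q,sharpness secondary-structure corruption, see
#'   [corrupt_ss_profile()].
#' @param min_sep candidate-pair separation.
#' @param id protein identifier.
#' @return object of class `"synthetic_protein"`.
#' @export
generate_protein <- function(L, seed = 1L, n_strands = NULL, signal = 1,
                             noise_scale = 0.35,
                             n_decoys = max(4L, round(L / 12)),
                             bump_std = 1, q = 0.8, sharpness = 6,
                             min_sep = 3L, id = seed) {
  n_strands <- n_strands %||%
    with_seed(derive_seed(seed, "nstrands"),
              sample(3:max(3L, min(7L, L %/% 12L)), 1L))
  topo <- generate_topology(L, n_strands, seed)
  map <- generate_contact_map(topo$truth, L, signal = signal,
                              noise_scale = noise_scale,
                              n_decoys = n_decoys, seed = seed,
                              bump_std = bump_std, min_sep = min_sep)
  map$n_seqs <- with_seed(derive_seed(seed, "nseq"),
                          as.integer(round(10^stats::runif(1, 2, 3.7))))
  ssp <- corrupt_ss_profile(topo$ss_truth, q = q, sharpness = sharpness,
                            seed = seed)
  structure(list(id = id, length = L, ss_truth = topo$ss_truth,
                 strands = topo$strands, pairings = topo$pairings,
                 truth = topo$truth, map = map, ss_profile = ssp,
                 n_seqs = map$n_seqs),
            class = "synthetic_protein")
}

#' Generate a synthetic dataset
#'
#' `n` independent proteins with lengths uniform in `L_range`; per-protein
#' seeds are derived from the master seed, so the whole set is reproducible
#' and no two proteins share a map.
#'
#' @param n number of proteins.
#' @param L_range length-2 integer range of protein lengths.
#' @param seed master seed.
#' @param ... forwarded to [generate_protein()].
#' @return list of `"synthetic_protein"`; attribute `"pos_neg_ratio"` logs
#'   the positive:negative candidate-pair imbalance of the set.
#' @export
generate_dataset <- function(n, L_range = c(60L, 120L), seed = 1L, ...) {
  lens <- with_seed(derive_seed(seed, "lengths"),
                    sample(L_range[1]:L_range[2], n, replace = TRUE))
  out <- lapply(seq_len(n), function(k)
    generate_protein(lens[k], seed = derive_seed(seed, "protein", k),
                     id = k, ...))
  npos <- sum(vapply(out, function(p) nrow(p$truth$contacts), numeric(1)))
  ncand <- sum(vapply(out, function(p)
    nrow(candidate_pairs(p$length, 3L)), numeric(1)))
  attr(out, "pos_neg_ratio") <- npos / (ncand - npos)
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Per protein: the contact map (matrix dialect), the soft secondary
#' structure profile, the native 3-state string, and the label file; plus a
#' `manifest.tsv` tying them together for the `train` CLI subcommand.
#'
#' @param dataset from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(p) {
    base <- file.path(dir, sprintf("prot%03d", p$id))
    write_prediction(p$map$scores, paste0(base, ".map"))
    writeLines(sprintf("%d %.6f %.6f %.6f", seq_len(p$length),
                       p$ss_profile$probs[, 1], p$ss_profile$probs[, 2],
                       p$ss_profile$probs[, 3]), paste0(base, ".ss"))
    writeLines(p$ss_truth, paste0(base, ".dssp"))
    write_labels(p$truth, paste0(base, ".labels"))
    data.frame(id = p$id, L = p$length, n_seqs = p$n_seqs,
               map = paste0(base, ".map"), ss = paste0(base, ".ss"),
               dssp = paste0(base, ".dssp"),
               labels = paste0(base, ".labels"))
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
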