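# Feature assembly for candidate residue pairs: masked 2D windows over the
# raw map and ridge fields, 1D secondary-structure windows around both
# residues, position features and map-level features.

#' Build a square/cross window mask
#'
#' The mask is a `ws x ws` boolean stencil. With diagonal width `dw`, cell
#' `(r, c)` (center at the middle) is selected iff it lies within
#' `(dw - 1)/2` of the main diagonal or of the anti-diagonal of the window;
#' `dw >= ws` selects the full square. Beta-beta contact runs propagate along
#' these two diagonals, which is why the cross shape retains the signal while
#' dropping background cells.
#'
#' @param ws odd window size, >= 1.
#' @param dw odd diagonal width, >= 1.
#' @return object of class `"window_mask"`: list with `ws`, `dw`, logical
#'   `cells` (ws x ws) and integer offset matrix `offsets` (|mask| x 2,
#'   row/col offsets from the center in row-major scan order).
#' @export
window_mask <- function(ws, dw) {
  ws <- as.integer(ws); dw <- as.integer(dw)
  if (ws < 1L || dw < 1L || ws %% 2L == 0L || dw %% 2L == 0L)
    stop("ws and dw must be odd positive integers")
  r0 <- (ws - 1L) %/% 2L
  cells <- matrix(FALSE, ws, ws)
  for (r in 0:(ws - 1L)) for (c in 0:(ws - 1L)) {
    cells[r + 1L, c + 1L] <- abs(r - c) <= (dw - 1L) %/% 2L ||
      abs(r + c - (ws - 1L)) <= (dw - 1L) %/% 2L
  }
  off <- which(t(cells), arr.ind = TRUE)   # row-major scan order
  offsets <- cbind(dr = off[, 2L] - 1L - r0, dc = off[, 1L] - 1L - r0)
  structure(list(ws = ws, dw = dw, cells = cells, offsets = offsets),
            class = "window_mask")
}

#' @export
print.window_mask <- function(x, ...) {
  cat("window_mask: ws =", x$ws, "dw =", x$dw, "|",
      nrow(x$offsets), "selected cells\n")
  invisible(x)
}

#' Enumerate candidate residue pairs
#'
#' All pairs `i < j` with `j - i >= min_sep`, in lexicographic order.
#'
#' @param L protein length, >= 2.
#' @param min_sep minimum sequence separation, >= 1.
#' @return integer matrix with columns `i`, `j` (possibly 0 rows).
#' @export
candidate_pairs <- function(L, min_sep = 3L) {
  stopifnot(L >= 2L, min_sep >= 1L)
  i <- rep.int(seq_len(L), L)
  j <- rep(seq_len(L), each = L)
  keep <- j - i >= min_sep
  out <- cbind(i = i[keep], j = j[keep])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Position features of a residue pair
#'
#' Five features: the index difference and the four distances of the two
#' residues to the protein ends (counted as residues before/after, so the
#' N-terminal residue has distance 0 to the N terminus).
#'
#' @param i,j residue indices (1-based, `i < j`).
#' @param L protein length.
#' @return numeric 5-vector `(j - i, i - 1, L - i, j - 1, L - j)`.
#' @export
position_features <- function(i, j, L) {
  stopifnot(all(i >= 1L), all(i < j), all(j <= L))
  cbind(sep = j - i, i_n = i - 1L, i_c = L - i, j_n = j - 1L, j_c = L - j)
}

#' Map-level features
#'
#' Two global descriptors of input-map quality: the MSA depth per residue
#' (`n_seqs / L`, 0 if the depth is unknown) and the standard deviation of
#' the candidate-pair scores (strict upper triangle, `j - i >= min_sep`).
#'
#' @param map a [contact_map()].
#' @param min_sep minimum separation defining the candidate universe.
#' @return numeric 2-vector `(seq_ratio, map_sd)`.
#' @export
map_features <- function(map, min_sep = 3L) {
  m <- score_matrix(map)
  L <- nrow(m)
  n_seqs <- if (inherits(map, "contact_map")) map$n_seqs else NULL
  vals <- m[candidate_pairs(L, min_sep)]
  sdv <- if (length(vals) > 1L) stats::sd(vals) else 0
  c(seq_ratio = if (is.null(n_seqs)) 0 else n_seqs / L,
    map_sd = sdv)
}

# Gather one 2D map at (i + dr, j + dc) for all pairs x all mask offsets;
# out-of-map cells get the sentinel -1 (distinguishing the boundary from a
# genuine zero score).
gather_window <- function(m, pairs, offsets, sentinel = -1) {
  L <- nrow(m)
  n <- nrow(pairs)
  out <- matrix(sentinel, n, nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    r <- pairs[, 1] + offsets[o, 1]
    c <- pairs[, 2] + offsets[o, 2]
    ok <- r >= 1L & r <= L & c >= 1L & c <= L
    out[ok, o] <- m[cbind(r[ok], c[ok])]
  }
  out
}

# 1D secondary-structure window of length ws centered at each index in `ctr`;
# out-of-range residues contribute (0, 0, 0).
gather_ss_window <- function(probs, ctr, ws) {
  L <- nrow(probs)
  half <- (ws - 1L) %/% 2L
  out <- matrix(0, length(ctr), ws * 3L)
  col <- 0L
  for (t in seq(-half, half)) {
    r <- ctr + t
    ok <- r >= 1L & r <= L
    for (s in 1:3) {
      col <- col + 1L
      out[ok, col] <- probs[r[ok], s]
    }
  }
  out
}

#' Extract feature rows for residue pairs
#'
#' Concatenates, in fixed schema order: for each 2D map the values at
#' `(i + dr, j + dc)` over the mask cells (out-of-map cells carry the
#' sentinel -1); the 3-state secondary-structure probabilities over a
#' length-`ws` window centered at `i` then at `j` (out-of-range residues
#' contribute zeros); then, if requested, the 5 position features and the 2
#' map-level features.
#'
#' @param maps2d named list of L x L matrices (order defines the schema).
#' @param ss an [ss_profile()].
#' @param mapfeat numeric 2-vector from [map_features()], or `NULL` to omit
#'   position and map features (later-stage schema).
#' @param mask a [window_mask()].
#' @param pairs integer matrix of pairs (columns `i`, `j`), `i < j`.
#' @return numeric matrix, one row per pair, with schema column names.
#' @export
extract_pair_features <- function(maps2d, ss, mapfeat, mask, pairs) {
  stopifnot(inherits(mask, "window_mask"))
  pairs <- rbind(pairs)
  L <- nrow(maps2d[[1]])
  for (m in maps2d)
    if (!identical(dim(m), c(L, L))) stop("2D maps have mismatched sizes")
  if (ss$length != L) stop("ss profile length differs from map size")
  if (is.null(names(maps2d)))
    names(maps2d) <- paste0("map", seq_along(maps2d))
  blocks <- list()
  for (nm in names(maps2d)) {
    b <- gather_window(maps2d[[nm]], pairs, mask$offsets)
    colnames(b) <- sprintf("%s(%d,%d)", nm, mask$offsets[, 1],
                           mask$offsets[, 2])
    blocks[[length(blocks) + 1L]] <- b
  }
  for (side in c("i", "j")) {
    ctr <- pairs[, if (side == "i") 1L else 2L]
    b <- gather_ss_window(ss$probs, ctr, mask$ws)
    half <- (mask$ws - 1L) %/% 2L
    colnames(b) <- as.vector(t(outer(seq(-half, half), c("H", "E", "C"),
                                     function(t, s) sprintf("ss_%s[%+d]%s",
                                                            side, t, s))))
    blocks[[length(blocks) + 1L]] <- b
  }
  if (!is.null(mapfeat)) {
    pos <- position_features(pairs[, 1], pairs[, 2], L)
    mf <- matrix(rep(mapfeat, each = nrow(pairs)), nrow(pairs), 2)
    colnames(mf) <- c("seq_ratio", "map_sd")
    blocks <- c(blocks, list(pos, mf))
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Expected feature-row length
#'
#' Pure function of the schema: `n_maps * |mask| + 2 * ws * 3`, plus 7
#' (5 position + 2 map features) when those are included.
#'
#' @param n_maps number of 2D maps.
#' @param ws,dw mask parameters.
#' @param with_global include position and map features?
#' @return integer.
#' @export
feature_row_length <- function(n_maps, ws, dw, with_global = TRUE) {
  n_maps * nrow(window_mask(ws, dw)$offsets) + 2L * ws * 3L +
    if (with_global) 7L else 0L
}
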