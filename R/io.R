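# Readers and writers for the plain-text formats the pipeline touches:
# CCMpred-style L x L score matrices, "i j score" pair lists, 3-state
# secondary-structure profiles/strings, beta-beta label files and
# CASP-RR-like restraint lists. Files are 1-based, as are internal indices.

#' Contact map constructor
#'
#' @param scores square numeric matrix of pair scores (symmetrized by
#'   averaging with its transpose).
#' @param n_seqs optional number of sequences in the MSA the map was
#'   predicted from.
#' @return object of class `"contact_map"`: list with `scores`, `length`,
#'   `n_seqs`.
#' @export
contact_map <- function(scores, n_seqs = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores) || nrow(scores) < 2L)
    stop("contact map must be square with L >= 2")
  if (!all(is.finite(scores)))
    stop("contact map contains non-finite values")
  scores <- (scores + t(scores)) / 2
  dimnames(scores) <- NULL
  if (!is.null(n_seqs)) {
    stopifnot(length(n_seqs) == 1L, n_seqs >= 0)
    n_seqs <- as.integer(n_seqs)
  }
  structure(list(scores = scores, length = nrow(scores), n_seqs = n_seqs),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map: L =", x$length,
      if (!is.null(x$n_seqs)) paste0("(N = ", x$n_seqs, ")"), "\n")
  cat("  score range [", signif(min(x$scores), 4), ", ",
      signif(max(x$scores), 4), "]\n", sep = "")
  invisible(x)
}

#' Read a predicted residue contact map
#'
#' Supports the CCMpred dialect (a plain whitespace-separated L x L real
#' matrix) and a pair-list dialect with lines `i j score` (1-based indices;
#' unlisted cells default to 0). Maps are symmetrized by averaging with the
#' transpose on load.
#'
#' @param path file path.
#' @param dialect `"matrix"` or `"pairlist"`.
#' @param length_hint protein length L, required for the pairlist dialect
#'   unless it can be taken from the largest index.
#' @param n_seqs optional MSA depth to attach.
#' @param rescale if `TRUE`, min-max rescale scores to `[0, 1]` after loading.
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path, dialect = c("matrix", "pairlist"),
                             length_hint = NULL, n_seqs = NULL,
                             rescale = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty contact map file: ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  if (dialect == "matrix") {
    L <- length(lines)
    widths <- lengths(toks)
    if (any(widths != L))
      stop("ragged matrix: expected ", L, " columns, found rows with ",
           paste(unique(widths[widths != L]), collapse = "/"))
    vals <- suppressWarnings(as.numeric(unlist(toks)))
    if (anyNA(vals) || !all(is.finite(vals)))
      stop("non-finite or unparsable values in contact map")
    m <- matrix(vals, nrow = L, byrow = TRUE)
  } else {
    recs <- lapply(toks, function(tk) {
      if (length(tk) != 3L) stop("pairlist lines must be 'i j score'")
      suppressWarnings(as.numeric(tk))
    })
    recs <- do.call(rbind, recs)
    if (anyNA(recs) || !all(is.finite(recs)))
      stop("non-finite or unparsable values in pair list")
    L <- if (!is.null(length_hint)) as.integer(length_hint)
         else as.integer(max(recs[, 1:2]))
    if (any(recs[, 1:2] < 1) || any(recs[, 1:2] > L))
      stop("pairlist index out of range 1..", L)
    m <- matrix(0, L, L)
    m[recs[, 1:2, drop = FALSE]] <- recs[, 3]
    m[recs[, 2:1, drop = FALSE]] <- recs[, 3]
  }
  if (rescale) {
    rng <- range(m)
    if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  }
  contact_map(m, n_seqs = n_seqs)
}

#' Secondary-structure profile constructor
#'
#' @param probs L x 3 matrix of per-residue probabilities, columns (H, E, C).
#' @return object of class `"ss_profile"`.
#' @export
ss_profile <- function(probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L) stop("ss profile must have 3 columns (H, E, C)")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("ss probabilities must lie in [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-3))
    stop("ss probability rows must sum to 1 (max deviation ",
         signif(max(abs(rs - 1)), 3), ")")
  probs <- probs / rs   # remove sub-tolerance drift
  dimnames(probs) <- list(NULL, c("H", "E", "C"))
  structure(list(probs = probs, length = nrow(probs)), class = "ss_profile")
}

# 8-state DSSP -> 3-state: beta-bridge and extended strand are both beta (E);
# all helix types collapse to H; everything else is coil.
DSSP3 <- c(B = "E", E = "E", G = "H", H = "H", I = "H",
           T = "C", S = "C", C = "C", "-" = "C", "." = "C", " " = "C")

#' Build a one-hot secondary-structure profile from a state string
#'
#' Accepts a 3-state string over `{H, E, C}` or a raw 8-state DSSP string
#' (mapped as B,E to E; G,H,I to H; all else to C).
#'
#' @param s character scalar.
#' @return an [ss_profile()] with one-hot rows.
#' @export
ss_from_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  st <- strsplit(toupper(s), "")[[1]]
  unknown <- setdiff(st, names(DSSP3))
  if (length(unknown))
    stop("unknown secondary-structure state letter(s): ",
         paste(unique(unknown), collapse = ""))
  st3 <- unname(DSSP3[st])
  probs <- matrix(0, length(st3), 3)
  probs[cbind(seq_along(st3), match(st3, c("H", "E", "C")))] <- 1
  ss_profile(probs)
}

#' Read per-residue secondary-structure information
#'
#' In `predicted_ss` mode the file has one line per residue,
#' `index pH pE pC`; in `dssp_ss` mode it holds a single 3- or 8-state
#' string, which is one-hot encoded.
#'
#' @param path file path.
#' @param mode `"predicted_ss"` or `"dssp_ss"`.
#' @return an [ss_profile()].
#' @export
read_ss_profile <- function(path, mode = c("predicted_ss", "dssp_ss")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (mode == "dssp_ss") {
    if (length(lines) != 1L) stop("dssp mode expects a single state string")
    return(ss_from_string(trimws(lines)))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(toks) != 4L))
    stop("predicted mode expects lines 'index pH pE pC'")
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) stop("unparsable values in ss profile")
  m <- matrix(vals, ncol = 4, byrow = TRUE)
  ss_profile(m[order(m[, 1]), 2:4, drop = FALSE])
}

#' Beta-beta contact label set
#'
#' @param contacts 2-column matrix/data.frame of contacting residue pairs
#'   (1-based; stored with i < j, duplicates removed).
#' @param strands 2-column matrix of inclusive `(start, end)` strand
#'   intervals, or `NULL`.
#' @param L protein length (for range checks), optional.
#' @return object of class `"label_set"`.
#' @export
label_set <- function(contacts, strands = NULL, L = NULL) {
  contacts <- as.matrix(contacts)
  if (length(contacts) == 0L) contacts <- matrix(integer(), 0, 2)
  if (ncol(contacts) != 2L) stop("contacts must have two columns")
  storage.mode(contacts) <- "integer"
  contacts <- cbind(pmin(contacts[, 1], contacts[, 2]),
                    pmax(contacts[, 1], contacts[, 2]))
  contacts <- unique(contacts[order(contacts[, 1], contacts[, 2]), ,
                              drop = FALSE])
  if (nrow(contacts) && any(contacts[, 1] == contacts[, 2]))
    stop("self-contacts are not allowed")
  if (!is.null(L) && nrow(contacts) &&
      (any(contacts < 1L) || any(contacts > L)))
    stop("contact index out of range 1..", L)
  if (!is.null(strands)) {
    strands <- as.matrix(strands)
    storage.mode(strands) <- "integer"
    if (nrow(strands)) {
      strands <- strands[order(strands[, 1]), , drop = FALSE]
      if (any(strands[, 2] < strands[, 1]))
        stop("strand intervals must have start <= end")
      if (nrow(strands) > 1L &&
          any(strands[-1, 1] <= strands[-nrow(strands), 2]))
        stop("strand intervals overlap")
    }
  } else strands <- matrix(integer(), 0, 2)
  dimnames(contacts) <- list(NULL, c("i", "j"))
  dimnames(strands) <- list(NULL, c("start", "end"))
  structure(list(contacts = contacts, strands = strands, L = L),
            class = "label_set")
}

#' Read a beta-beta contact label file
#'
#' Lines are either `i j` (a contacting residue pair, 1-based) or
#' `strand start end` (a beta-strand segment).
#'
#' @param path file path.
#' @param L optional protein length for validation.
#' @return a [label_set()].
#' @export
read_labels <- function(path, L = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  is_strand <- vapply(toks, function(tk) tk[1] == "strand", logical(1))
  contacts <- do.call(rbind, lapply(toks[!is_strand], function(tk)
    as.integer(tk[1:2])))
  strands <- do.call(rbind, lapply(toks[is_strand], function(tk)
    as.integer(tk[2:3])))
  label_set(contacts %||% matrix(integer(), 0, 2), strands, L = L)
}

#' Write a label set
#' @param labels a [label_set()].
#' @param path output file path.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(labels$contacts))
    writeLines(paste(labels$contacts[, 1], labels$contacts[, 2]), con)
  if (nrow(labels$strands))
    writeLines(paste("strand", labels$strands[, 1], labels$strands[, 2]), con)
  invisible(path)
}

#' Write a prediction (or any symmetric score matrix) to disk
#'
#' `"matrix"` writes an L x L matrix at 6-decimal precision that round-trips
#' through [read_contact_map()]; `"ranked_pairs"` writes `i j score` lines
#' (1-based, `i < j`) in descending score order with deterministic `(i, j)`
#' tie-breaking.
#'
#' @param pred a `prediction_map`, `contact_map`, or numeric matrix.
#' @param path output file path.
#' @param format `"matrix"` or `"ranked_pairs"`.
#' @param min_sep minimum separation for listed pairs (ranked_pairs only).
#' @export
write_prediction <- function(pred, path, format = c("matrix", "ranked_pairs"),
                             min_sep = 1L) {
  format <- match.arg(format)
  m <- score_matrix(pred)
  if (!all(is.finite(m))) stop("prediction contains non-finite values")
  if (max(abs(m - t(m))) > 1e-12) stop("prediction must be symmetric")
  if (format == "matrix") {
    txt <- apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
    writeLines(txt, path)
  } else {
    L <- nrow(m)
    pr <- candidate_pairs(L, min_sep)
    sc <- m[pr]
    ord <- order(-sc, pr[, 1], pr[, 2])
    writeLines(sprintf("%d %d %.6f", pr[ord, 1], pr[ord, 2], sc[ord]), path)
  }
  invisible(path)
}

# Accept a bare matrix, contact_map or prediction_map wherever scores are
# needed.
score_matrix <- function(x) {
  if (is.matrix(x)) x
  else if (inherits(x, "contact_map")) x$scores
  else if (inherits(x, "prediction_map")) x$scores
  else stop("cannot extract a score matrix from class ",
            paste(class(x), collapse = "/"))
}

RESTRAINT_BOUNDS <- list(strict = c(3.5, 6.0),
                         loose = c(3.5, 10.0),
                         control = c(3.5, 8.0))

#' Export distance restraints for contact-assisted folding
#'
#' In `refined` mode, every pair scoring at or above `cutoff` on the refined
#' map becomes a strict 3.5-6 A restraint on the C-beta atoms; the list is
#' then enriched up to `L` records with the top-ranked raw-map pairs that are
#' non-redundant, i.e. fall outside a `(2k+1) x (2k+1)` square window around
#' every strict pair, as loose 3.5-10 A restraints. In `control` mode the top
#' `L` raw pairs are exported with a uniform 3.5-8 A restraint.
#'
#' @param final refined prediction (matrix / `prediction_map`); may be `NULL`
#'   in control mode.
#' @param raw the raw input [contact_map()] (or matrix).
#' @param cutoff score threshold in (0,1) for strict pairs.
#' @param mode `"refined"` or `"control"`.
#' @param config a [br_config()]; supplies `min_sep` and the redundancy
#'   half-width `k`.
#' @return data.frame with columns `i`, `j`, `lower`, `upper`, `score`,
#'   `tier`, at most `L` rows, sorted by tier then descending score.
#' @export
export_restraints <- function(final, raw, cutoff = 0.5,
                              mode = c("refined", "control"),
                              config = br_config()) {
  mode <- match.arg(mode)
  rawm <- score_matrix(raw)
  L <- nrow(rawm)
  min_sep <- config$min_sep
  k <- config$redundancy_k
  pr <- candidate_pairs(L, min_sep)
  raw_sc <- rawm[pr]
  if (mode == "control") {
    ord <- order(-raw_sc, pr[, 1], pr[, 2])
    take <- ord[seq_len(min(L, length(ord)))]
    out <- data.frame(i = pr[take, 1], j = pr[take, 2],
                      lower = 3.5, upper = 8.0, score = raw_sc[take],
                      tier = "control")
    return(out)
  }
  finm <- score_matrix(final)
  if (nrow(finm) != L) stop("refined and raw maps must have the same L")
  stopifnot(cutoff > 0, cutoff < 1)
  fin_sc <- finm[pr]
  strict_idx <- which(fin_sc >= cutoff)
  strict_idx <- strict_idx[order(-fin_sc[strict_idx], pr[strict_idx, 1],
                                 pr[strict_idx, 2])]
  if (length(strict_idx) > L) {
    warning("more strict pairs than L; keeping the top-", L, " by score")
    strict_idx <- strict_idx[seq_len(L)]
  }
  strict <- pr[strict_idx, , drop = FALSE]
  n_loose <- L - length(strict_idx)
  loose <- matrix(integer(), 0, 2); loose_sc <- numeric()
  if (n_loose > 0) {
    cand <- setdiff(order(-raw_sc, pr[, 1], pr[, 2]), strict_idx)
    keep <- logical(length(cand))
    if (nrow(strict)) {
      for (ii in seq_along(cand)) {
        p <- pr[cand[ii], ]
        keep[ii] <- all(pmax(abs(strict[, 1] - p[1]),
                             abs(strict[, 2] - p[2])) > k)
      }
    } else keep[] <- TRUE
    cand <- cand[keep]
    cand <- cand[seq_len(min(n_loose, length(cand)))]
    loose <- pr[cand, , drop = FALSE]
    loose_sc <- raw_sc[cand]
  }
  out <- rbind(
    if (nrow(strict)) data.frame(i = strict[, 1], j = strict[, 2],
                                 lower = 3.5, upper = 6.0,
                                 score = fin_sc[strict_idx], tier = "strict"),
    if (nrow(loose)) data.frame(i = loose[, 1], j = loose[, 2],
                                lower = 3.5, upper = 10.0,
                                score = loose_sc, tier = "loose"))
  out %||% data.frame(i = integer(), j = integer(), lower = numeric(),
                      upper = numeric(), score = numeric(),
                      tier = character())
}

#' Write restraints as CASP-RR-like text
#'
#' One line per record: `i j lower upper score` (1-based residue indices,
#' bounds in Angstrom), consumable by CONFOLD-style folding pipelines.
#'
#' @param restraints data.frame from [export_restraints()].
#' @param path output file path.
#' @export
write_restraints <- function(restraints, path) {
  writeLines(sprintf("%d %d %.1f %.1f %.6f",
                     restraints$i, restraints$j, restraints$lower,
                     restraints$upper, restraints$score), path)
  invisible(path)
}
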