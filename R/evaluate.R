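# Residue-level and strand-level Precision / Recall / F1, PR curves, and
# strand-pairing derivation from a native secondary-structure assignment.

#' F1 score (harmonic mean of precision and recall)
#'
#' `F1 = 2 P R / (P + R)`, defined as 0 when both are 0.
#'
#' @param precision,recall reals in `[0, 1]`.
#' @return real in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

eval_result <- function(tp, fp, fn, level) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 f1 = f1_score(precision, recall),
                 undefined = (tp + fp == 0) || (tp + fn == 0),
                 level = level),
            class = "br_eval")
}

#' @export
print.br_eval <- function(x, ...) {
  cat(sprintf("%s-level: TP=%d FP=%d FN=%d | P=%.2f%% R=%.2f%% F1=%.2f%%\n",
              x$level, x$tp, x$fp, x$fn, 100 * x$precision, 100 * x$recall,
              100 * x$f1))
  invisible(x)
}

#' Binarize a prediction map
#'
#' @param pred a `prediction_map` (or symmetric matrix).
#' @param cutoff score threshold in `[0, 1]`.
#' @param min_sep minimum separation of reported pairs.
#' @return integer matrix of pairs `i < j` with `scores >= cutoff`.
#' @export
binarize_prediction <- function(pred, cutoff, min_sep = 1L) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  m <- score_matrix(pred)
  pr <- candidate_pairs(nrow(m), min_sep)
  pr[m[pr] >= cutoff, , drop = FALSE]
}

pair_key <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(character())
  i <- pmin(pairs[, 1], pairs[, 2]); j <- pmax(pairs[, 1], pairs[, 2])
  unique(paste(i, j))
}

#' Residue-level evaluation
#'
#' @param predicted pair matrix (columns `i`, `j`) of predicted contacts.
#' @param truth a [label_set()] (its `contacts` are the native pairs).
#' @return a `"br_eval"` with TP/FP/FN, precision, recall, F1.
#' @export
residue_eval <- function(predicted, truth) {
  p <- pair_key(predicted)
  t <- pair_key(truth$contacts)
  eval_result(length(intersect(p, t)), length(setdiff(p, t)),
              length(setdiff(t, p)), "residue")
}

#' Strand intervals from a native secondary-structure assignment
#'
#' Maximal runs of state E. Requires an exact (one-hot / string) assignment;
#' predicted probability profiles are refused, since strand boundaries are
#' only defined with native secondary structure.
#'
#' @param assignment a 3-state string or a one-hot [ss_profile()].
#' @return integer matrix of `(start, end)` intervals (1-based, inclusive).
#' @export
strands_from_ss <- function(assignment) {
  if (is.character(assignment)) assignment <- ss_from_string(assignment)
  stopifnot(inherits(assignment, "ss_profile"))
  if (!all(assignment$probs %in% c(0, 1)))
    stop("strand derivation needs a native (one-hot) assignment; ",
         "use DSSP mode, not predicted probabilities")
  is_e <- assignment$probs[, "E"] == 1
  r <- rle(is_e)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- cbind(start = starts[r$values], end = ends[r$values])
  dimnames(out) <- list(NULL, c("start", "end"))
  out[order(out[, 1]), , drop = FALSE]
}

strand_of <- function(idx, strands) {
  if (nrow(strands) == 0L) return(rep(NA_integer_, length(idx)))
  s <- rep(NA_integer_, length(idx))
  for (k in seq_len(nrow(strands))) {
    in_k <- idx >= strands[k, 1] & idx <= strands[k, 2]
    s[in_k] <- k
  }
  s
}

strand_pair_key <- function(pairs, strands) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(character())
  a <- strand_of(pairs[, 1], strands)
  b <- strand_of(pairs[, 2], strands)
  ok <- !is.na(a) & !is.na(b) & a != b   # both on strands, different strands
  unique(paste(pmin(a[ok], b[ok]), pmax(a[ok], b[ok])))
}

#' Strand-level evaluation
#'
#' Two strands are considered interacting if at least one residue pair
#' between them is predicted (respectively, native) as contacting. Pairs
#' within a single strand, or touching residues on no strand, contribute
#' nothing.
#'
#' @param predicted pair matrix of predicted residue contacts.
#' @param truth a [label_set()].
#' @param strands strand intervals (e.g. from [strands_from_ss()]); defaults
#'   to the truth's strand segments.
#' @return a `"br_eval"` at strand level.
#' @export
strand_eval <- function(predicted, truth, strands = NULL) {
  strands <- strands %||% truth$strands
  p <- strand_pair_key(predicted, strands)
  t <- strand_pair_key(truth$contacts, strands)
  eval_result(length(intersect(p, t)), length(setdiff(p, t)),
              length(setdiff(t, p)), "strand")
}

#' Precision-Recall curve over a cutoff grid
#'
#' @param pred a `prediction_map` (or symmetric matrix).
#' @param truth a [label_set()].
#' @param grid ascending cutoffs. Cutoffs above the maximal score yield the
#'   conventional `(0, 0)` point.
#' @param min_sep minimum separation of candidate pairs.
#' @return data.frame with columns `cutoff`, `precision`, `recall`, `f1`.
#' @export
pr_curve <- function(pred, truth, grid = seq(0, 1, by = 0.01),
                     min_sep = 3L) {
  stopifnot(!is.unsorted(grid))
  m <- score_matrix(pred)
  pr <- candidate_pairs(nrow(m), min_sep)
  sc <- m[pr]
  tkey <- pair_key(truth$contacts)
  npos <- length(tkey)
  keys <- paste(pr[, 1], pr[, 2])
  is_t <- keys %in% tkey
  rows <- lapply(grid, function(ct) {
    sel <- sc >= ct
    tp <- sum(sel & is_t)
    fp <- sum(sel) - tp
    e <- eval_result(tp, fp, npos - tp, "residue")
    data.frame(cutoff = ct, precision = e$precision, recall = e$recall,
               f1 = e$f1)
  })
  do.call(rbind, rows)
}
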