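#' Run configuration
#'
#' Collects every tunable parameter of the pipeline. Defaults are the
#' settings the framework is optimized at: stage-1 window sizes 3/5/7/9,
#' cross-shaped masks of diagonal width 3, 1:40 positive/negative
#' under-sampling, 500-tree forests and a minimum sequence separation of 3.
#'
#' @param window_sizes odd integers; side lengths of the stage-1 feature
#'   windows (one forest per size).
#' @param diag_width odd integer; width of the diagonal/anti-diagonal bands of
#'   the cross-shaped window mask (`dw >= ws` degenerates to the full square).
#' @param pos_neg_ratio integer; negatives drawn per positive during
#'   protein-wise under-sampling.
#' @param n_trees integer; trees per random forest.
#' @param sigma_grid strictly increasing positive reals; smoothing scales
#'   (grid units) for scale-space ridge detection. Default: 12 log-spaced
#'   values in `[0.5, 4]`, bracketing the 1-3 cell widths of strand ridges.
#' @param min_sep integer; minimum `j - i` for a candidate residue pair.
#' @param seed master integer seed for all stochastic steps.
#' @param cutoff score threshold in (0,1) used when binarizing a final
#'   prediction (overridden by a trained bundle's suggested cutoff).
#' @param mode `"predicted_ss"` (3-state probabilities) or `"dssp_ss"`
#'   (one-hot native assignment).
#' @param ridge_tol relative tolerance on the directional derivative in the
#'   discrete ridge-point condition.
#' @param redundancy_k half-width of the square redundancy window used when
#'   enriching restraint lists (a `(2k+1) x (2k+1)` exclusion zone).
#' @return an object of class `"br_config"` (a named list).
#' @export
#' @examples
#' cfg <- br_config(n_trees = 60)
#' cfg$window_sizes
br_config <- function(window_sizes = c(3L, 5L, 7L, 9L),
                      diag_width = 3L,
                      pos_neg_ratio = 40L,
                      n_trees = 500L,
                      sigma_grid = exp(seq(log(0.5), log(4), length.out = 12)),
                      min_sep = 3L,
                      seed = 1L,
                      cutoff = 0.5,
                      mode = c("predicted_ss", "dssp_ss"),
                      ridge_tol = 0.1,
                      redundancy_k = 2L) {
  mode <- match.arg(mode)
  window_sizes <- as.integer(window_sizes)
  stopifnot(all(window_sizes %% 2L == 1L), all(window_sizes >= 3L),
            diag_width %% 2L == 1L, diag_width >= 1L,
            pos_neg_ratio >= 1L, n_trees >= 1L,
            length(sigma_grid) >= 1L, all(sigma_grid > 0),
            all(diff(sigma_grid) > 0),
            min_sep >= 1L, cutoff > 0, cutoff < 1, ridge_tol >= 0,
            redundancy_k >= 0L)
  structure(list(window_sizes = window_sizes,
                 diag_width = as.integer(diag_width),
                 pos_neg_ratio = as.integer(pos_neg_ratio),
                 n_trees = as.integer(n_trees),
                 sigma_grid = as.numeric(sigma_grid),
                 min_sep = as.integer(min_sep),
                 seed = as.integer(seed),
                 cutoff = cutoff,
                 mode = mode,
                 ridge_tol = ridge_tol,
                 redundancy_k = as.integer(redundancy_k)),
            class = "br_config")
}

#' @export
print.br_config <- function(x, ...) {
  cat("betaridge run configuration\n")
  cat("  window sizes :", paste(x$window_sizes, collapse = ", "), "\n")
  cat("  diag width   :", x$diag_width, "\n")
  cat("  pos/neg      : 1:", x$pos_neg_ratio, "\n", sep = "")
  cat("  trees        :", x$n_trees, "\n")
  cat("  sigma grid   :", length(x$sigma_grid), "scales in [",
      signif(min(x$sigma_grid), 3), ",", signif(max(x$sigma_grid), 3), "]\n")
  cat("  min sep      :", x$min_sep, "\n")
  cat("  mode         :", x$mode, "\n")
  invisible(x)
}
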