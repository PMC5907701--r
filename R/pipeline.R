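# Three-stage stacked random-forest framework.
#
# Stage 1: four probability forests (window sizes 3/5/7/9) over raw-map +
# ridge 2D windows, secondary-structure windows, position and map features.
# Stage 2: one forest over the four stage-1 score maps and their row/column
# rank maps, plus ridge h/phi and secondary structure, in a full 3x3 window.
# Stage 3: same protocol applied to the stage-2 map. Later stages train on
# out-of-fold predictions of the earlier stage to prevent leakage.

#' Prediction map with rank features
#'
#' Wraps a symmetric score matrix in `[0, 1]` with its descending row/column
#' rank maps (rank 1 = top score, ties broken by index, normalized by `L` so
#' ranks are length-invariant across proteins). Cells closer than `min_sep`
#' to the diagonal are forced to 0.
#'
#' @param scores L x L numeric matrix (upper triangle is mirrored if the
#'   input is not symmetric).
#' @param min_sep minimum sequence separation of scored pairs.
#' @return object of class `"prediction_map"`: list with `scores`,
#'   `row_rank`, `col_rank`, `length`.
#' @export
prediction_map <- function(scores, min_sep = 3L) {
  m <- as.matrix(scores)
  L <- nrow(m)
  stopifnot(ncol(m) == L)
  m <- (m + t(m)) / 2
  near <- abs(row(m) - col(m)) < min_sep
  m[near] <- 0
  rr <- matrix(0, L, L)
  for (i in seq_len(L)) {
    ord <- order(-m[i, ])
    rr[i, ord] <- seq_len(L) / L
  }
  structure(list(scores = m, row_rank = rr, col_rank = t(rr), length = L),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat("prediction_map: L =", x$length, "| score range [",
      signif(min(x$scores), 3), ",", signif(max(x$scores), 3), "]\n")
  invisible(x)
}

#' Protein-wise under-sampling of training pairs
#'
#' Keeps every positive pair and draws `ratio` negatives per positive
#' uniformly without replacement (capped at the available negatives) from a
#' stream derived from `(seed, protein_id)`. A protein with no positives
#' still contributes `ratio` negatives so it is not silently dropped.
#'
#' @param pairs candidate pair matrix (columns `i`, `j`).
#' @param is_pos logical vector, one entry per pair.
#' @param ratio negatives per positive.
#' @param seed master seed.
#' @param protein_id protein label used to derive the stream.
#' @return integer vector of selected row indices into `pairs` (sorted).
#' @export
undersample_pairs <- function(pairs, is_pos, ratio = 40L, seed = 1L,
                              protein_id = 1L) {
  stopifnot(ratio >= 1L, nrow(pairs) == length(is_pos))
  pos <- which(is_pos)
  neg <- which(!is_pos)
  n_draw <- min(max(length(pos), 1L) * ratio, length(neg))
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(derive_seed(seed, "undersample", protein_id))
  sort(c(pos, neg[sample.int(length(neg), n_draw)]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

# ---- per-protein cached inputs --------------------------------------------

#' Prepare a protein for the pipeline
#'
#' Computes and caches everything feature extraction needs: ridge fields of
#' the contact map, candidate pairs, per-pair labels and map-level features.
#'
#' @param map a [contact_map()].
#' @param ss an [ss_profile()] of the same length.
#' @param labels a [label_set()] (may have no contacts for pure prediction).
#' @param config a [br_config()].
#' @param id protein identifier (used for seed derivation).
#' @return object of class `"br_protein"`.
#' @export
prepare_protein <- function(map, ss, labels = NULL, config = br_config(),
                            id = 1L) {
  stopifnot(inherits(map, "contact_map"), inherits(ss, "ss_profile"))
  L <- map$length
  if (ss$length != L) stop("map and ss profile lengths differ")
  rf <- ridge_fields(map, config)
  pairs <- candidate_pairs(L, config$min_sep)
  y <- rep(FALSE, nrow(pairs))
  if (!is.null(labels) && nrow(labels$contacts)) {
    key <- paste(pairs[, 1], pairs[, 2])
    y <- key %in% paste(labels$contacts[, 1], labels$contacts[, 2])
  }
  structure(list(id = id, map = map, ss = ss, labels = labels,
                 ridge = rf, pairs = pairs, y = y,
                 mapfeat = map_features(map, config$min_sep)),
            class = "br_protein")
}

stage1_maps <- function(prot) {
  list(raw = prot$map$scores, h = prot$ridge$h, phi = prot$ridge$phi)
}

stage1_rows <- function(prot, ws, config, subset = NULL) {
  mask <- window_mask(ws, config$diag_width)
  pairs <- if (is.null(subset)) prot$pairs else prot$pairs[subset, ,
                                                           drop = FALSE]
  extract_pair_features(stage1_maps(prot), prot$ss, prot$mapfeat, mask, pairs)
}

#' Assemble later-stage feature rows
#'
#' Stage 2 consumes the four stage-1 prediction maps (score + row/column
#' ranks each), ridge height and direction, and secondary structure in a
#' full 3x3 window (`4 * 3 + 2 = 14` maps, 144 features). Stage 3 applies
#' the same protocol to the single stage-2 map (5 maps, 63 features).
#' Position and map-level features are dropped by the later stages' feature
#' selection.
#'
#' @param prev_maps named list of `prediction_map`s from the previous stage
#'   (names `ws3`, `ws5`, `ws7`, `ws9` for stage 2; a single `s2` for
#'   stage 3).
#' @param ridge a `"ridge_fields"`.
#' @param ss an [ss_profile()].
#' @param pairs pair matrix (columns `i`, `j`).
#' @return numeric feature matrix, one row per pair.
#' @export
assemble_stage_features <- function(prev_maps, ridge, ss, pairs) {
  if (is.null(names(prev_maps)) || any(!nzchar(names(prev_maps))))
    stop("previous-stage maps must be named")
  maps2d <- list()
  for (nm in names(prev_maps)) {
    pm <- prev_maps[[nm]]
    stopifnot(inherits(pm, "prediction_map"))
    maps2d[[paste0(nm, "_score")]] <- pm$scores
    maps2d[[paste0(nm, "_rrank")]] <- pm$row_rank
    maps2d[[paste0(nm, "_crank")]] <- pm$col_rank
  }
  maps2d$h <- ridge$h
  maps2d$phi <- ridge$phi
  extract_pair_features(maps2d, ss, NULL, window_mask(3L, 3L), pairs)
}

#' @rdname assemble_stage_features
#' @param stage1_preds named list of exactly four stage-1 `prediction_map`s
#'   keyed `ws3`, `ws5`, `ws7`, `ws9`.
#' @export
assemble_stage2_features <- function(stage1_preds, ridge, ss, pairs) {
  want <- paste0("ws", c(3L, 5L, 7L, 9L))
  if (!identical(names(stage1_preds), want))
    stop("stage-2 features require the four stage-1 maps named ",
         paste(want, collapse = ", "))
  assemble_stage_features(stage1_preds, ridge, ss, pairs)
}

# ---- forest training -------------------------------------------------------

fit_forest <- function(x, y, config, stream) {
  if (length(unique(y)) < 2L)
    stop("single-class training set: cannot fit a forest")
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))   # ranger-safe names
  df$.y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 probability = TRUE, num.trees = config$n_trees,
                 seed = derive_seed(config$seed, stream),
                 num.threads = 1L, verbose = FALSE)
}

forest_scores <- function(model, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  p <- stats::predict(model, data = df, num.threads = 1L,
                      verbose = FALSE)$predictions
  unname(p[, "pos"])
}

#' Train one stage-1 forest
#'
#' @param dataset list of `"br_protein"` objects with labels.
#' @param ws window size of this model.
#' @param config a [br_config()].
#' @param protein_subset optional indices of training proteins.
#' @param stream seed-stream label.
#' @return list of class `"br_stage_model"` with the fitted forest, `ws` and
#'   the schema (feature names).
#' @export
train_stage1 <- function(dataset, ws, config = br_config(),
                         protein_subset = NULL, stream = "stage1") {
  idx <- protein_subset %||% seq_along(dataset)
  xs <- list(); ys <- list()
  for (p in idx) {
    prot <- dataset[[p]]
    sel <- undersample_pairs(prot$pairs, prot$y, config$pos_neg_ratio,
                             config$seed, prot$id)
    xs[[length(xs) + 1L]] <- stage1_rows(prot, ws, config, sel)
    ys[[length(ys) + 1L]] <- prot$y[sel]
  }
  x <- do.call(rbind, xs); y <- unlist(ys)
  model <- fit_forest(x, y, config, paste0(stream, "_ws", ws))
  structure(list(model = model, ws = ws, stage = 1L,
                 schema = colnames(x)), class = "br_stage_model")
}

#' Predict a stage's score map for one protein
#'
#' Scores every candidate pair, mirrors to the lower triangle, zeroes
#' non-candidates and recomputes rank maps.
#'
#' @param stage_model a `"br_stage_model"`.
#' @param features feature matrix for the protein's candidate pairs (schema
#'   must match the model's).
#' @param pairs the candidate pair matrix the rows correspond to.
#' @param L protein length.
#' @param min_sep minimum separation.
#' @return a [prediction_map()].
#' @export
predict_stage <- function(stage_model, features, pairs, L, min_sep = 3L) {
  if (!identical(colnames(features), stage_model$schema))
    stop("feature schema does not match the model manifest")
  sc <- forest_scores(stage_model$model, features)
  m <- matrix(0, L, L)
  m[pairs] <- sc
  m[pairs[, 2:1, drop = FALSE]] <- sc
  prediction_map(m, min_sep)
}

predict_stage1_maps <- function(models, prot, config, oof = FALSE,
                                fold = NA_integer_) {
  out <- list()
  for (mod in models) {
    fx <- stage1_rows(prot, mod$ws, config)
    pm <- predict_stage(mod, fx, prot$pairs, prot$map$length, config$min_sep)
    attr(pm, "oof") <- oof
    attr(pm, "fold") <- fold
    out[[paste0("ws", mod$ws)]] <- pm
  }
  out[paste0("ws", sort(vapply(models, `[[`, integer(1), "ws")))]
}

# Train a stage-2 or stage-3 forest from previous-stage maps. When
# `require_oof` (training), every previous-stage map must carry the
# out-of-fold provenance tag; training on in-fold predictions would leak the
# labels into later stages and is refused.
train_later_stage <- function(dataset, prev_maps, config, stage,
                              protein_subset = NULL, stream = NULL,
                              require_oof = TRUE) {
  idx <- protein_subset %||% seq_along(dataset)
  xs <- list(); ys <- list()
  for (p in idx) {
    prot <- dataset[[p]]
    maps <- prev_maps[[p]]
    if (require_oof &&
        !all(vapply(maps, function(m) isTRUE(attr(m, "oof")), logical(1))))
      stop("refusing to train stage ", stage,
           " on in-fold previous-stage predictions (leakage)")
    sel <- undersample_pairs(prot$pairs, prot$y, config$pos_neg_ratio,
                             config$seed, prot$id)
    xs[[length(xs) + 1L]] <- assemble_stage_features(
      maps, prot$ridge, prot$ss, prot$pairs[sel, , drop = FALSE])
    ys[[length(ys) + 1L]] <- prot$y[sel]
  }
  x <- do.call(rbind, xs); y <- unlist(ys)
  model <- fit_forest(x, y, config, stream %||% paste0("stage", stage))
  structure(list(model = model, ws = 3L, stage = stage,
                 schema = colnames(x)), class = "br_stage_model")
}

#' @export
#' @rdname train_pipeline
train_stage2 <- function(dataset, stage1_oof_maps, config = br_config(),
                         protein_subset = NULL, stream = "stage2") {
  train_later_stage(dataset, stage1_oof_maps, config, 2L, protein_subset,
                    stream)
}

#' @export
#' @rdname train_pipeline
train_stage3 <- function(dataset, stage2_oof_maps, config = br_config(),
                         protein_subset = NULL, stream = "stage3") {
  train_later_stage(dataset, stage2_oof_maps, config, 3L, protein_subset,
                    stream)
}

# ---- cross-validation ------------------------------------------------------

assign_folds <- function(n, k, seed) {
  if (k > n) stop("more folds than proteins")
  rs <- .Random.seed_save(); on.exit(.Random.seed_restore(rs))
  set.seed(derive_seed(seed, "folds"))
  sample(rep_len(seq_len(k), n))
}

pooled_scores <- function(dataset, maps, field = "scores") {
  sc <- list(); y <- list()
  for (p in seq_along(dataset)) {
    prot <- dataset[[p]]
    m <- maps[[p]]
    sc[[p]] <- m$scores[prot$pairs]
    y[[p]] <- prot$y
  }
  list(score = unlist(sc), y = unlist(y))
}

#' Best F1 over a cutoff grid
#'
#' @param score numeric scores.
#' @param y logical labels.
#' @param grid ascending cutoffs (default 0.01..0.99 step 0.01); ties go to
#'   the smaller cutoff.
#' @return list with `cutoff` and `f1`.
#' @export
best_f1_cutoff <- function(score, y, grid = seq(0.01, 0.99, by = 0.01)) {
  npos <- sum(y)
  f1s <- vapply(grid, function(ct) {
    pred <- score >= ct
    tp <- sum(pred & y)
    f1_counts(tp, sum(pred) - tp, npos - tp)
  }, numeric(1))
  best <- which.max(f1s)
  list(cutoff = grid[best], f1 = f1s[best])
}

f1_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1_score(p, r)
}

#' Protein-wise cross-validation with stage chaining
#'
#' Partitions proteins into `k` folds (sizes differing by at most one),
#' trains the full 3-stage chain on each training split, and predicts each
#' protein only with models that never saw it. Later stages are trained on
#' the out-of-fold predictions of the earlier stage. The suggested cutoff is
#' the grid value maximizing the pooled out-of-fold residue-level F1 of the
#' final stage.
#'
#' @param dataset list of `"br_protein"` objects.
#' @param config a [br_config()].
#' @param k number of folds.
#' @return list with `folds`, per-protein out-of-fold maps per stage
#'   (`oof_stage1`, `oof_stage2`, `oof_stage3`), `suggested_cutoff` and a
#'   `summary` of pooled per-stage F1 at each stage's own best cutoff.
#' @export
cross_validate <- function(dataset, config = br_config(), k = 5L) {
  n <- length(dataset)
  folds <- assign_folds(n, k, config$seed)
  oof1 <- vector("list", n); oof2 <- vector("list", n)
  oof3 <- vector("list", n)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    s1 <- lapply(config$window_sizes, function(ws)
      train_stage1(dataset, ws, config, tr,
                   stream = paste0("cv", f, "_stage1")))
    for (p in te)
      oof1[[p]] <- predict_stage1_maps(s1, dataset[[p]], config,
                                       oof = TRUE, fold = f)
  }
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    s2 <- train_stage2(dataset, oof1, config, tr,
                       stream = paste0("cv", f, "_stage2"))
    for (p in te) {
      fx <- assemble_stage_features(oof1[[p]], dataset[[p]]$ridge,
                                    dataset[[p]]$ss, dataset[[p]]$pairs)
      pm <- predict_stage(s2, fx, dataset[[p]]$pairs,
                          dataset[[p]]$map$length, config$min_sep)
      attr(pm, "oof") <- TRUE; attr(pm, "fold") <- f
      oof2[[p]] <- list(s2 = pm)
    }
  }
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    s3 <- train_stage3(dataset, oof2, config, tr,
                       stream = paste0("cv", f, "_stage3"))
    for (p in te) {
      fx <- assemble_stage_features(oof2[[p]], dataset[[p]]$ridge,
                                    dataset[[p]]$ss, dataset[[p]]$pairs)
      pm <- predict_stage(s3, fx, dataset[[p]]$pairs,
                          dataset[[p]]$map$length, config$min_sep)
      attr(pm, "oof") <- TRUE; attr(pm, "fold") <- f
      oof3[[p]] <- list(s3 = pm)
    }
  }
  # pooled per-stage F1 at each stage's own best cutoff
  stage1_f1 <- vapply(paste0("ws", config$window_sizes), function(nm) {
    ps <- pooled_scores(dataset, lapply(oof1, `[[`, nm))
    best_f1_cutoff(ps$score, ps$y)$f1
  }, numeric(1))
  ps2 <- pooled_scores(dataset, lapply(oof2, `[[`, "s2"))
  ps3 <- pooled_scores(dataset, lapply(oof3, `[[`, "s3"))
  b2 <- best_f1_cutoff(ps2$score, ps2$y)
  b3 <- best_f1_cutoff(ps3$score, ps3$y)
  list(folds = folds, oof_stage1 = oof1, oof_stage2 = oof2,
       oof_stage3 = oof3, suggested_cutoff = b3$cutoff,
       summary = list(stage1_f1 = stage1_f1, stage2_f1 = b2$f1,
                      stage3_f1 = b3$f1))
}

# ---- full pipeline ---------------------------------------------------------

#' Train the full 3-stage pipeline
#'
#' Runs protein-wise cross-validation (for stage chaining and suggested
#' cutoff selection), then refits every stage on the whole training set:
#' stage 1 on all proteins, stages 2-3 on the out-of-fold predictions of the
#' preceding stage.
#'
#' @param dataset list of `"br_protein"` objects (see [prepare_protein()]).
#' @param config a [br_config()].
#' @param k cross-validation folds.
#' @return object of class `"br_bundle"`: stage models, schema manifests,
#'   `suggested_cutoff`, cross-validation `cv_summary`, the config snapshot
#'   and the ridge width calibration constant.
#' @export
#' @rdname train_pipeline
train_pipeline <- function(dataset, config = br_config(), k = 5L) {
  stopifnot(length(dataset) >= k)
  cv <- cross_validate(dataset, config, k)
  stage1 <- lapply(config$window_sizes, function(ws)
    train_stage1(dataset, ws, config, stream = "full_stage1"))
  names(stage1) <- paste0("ws", config$window_sizes)
  stage2 <- train_stage2(dataset, cv$oof_stage1, config,
                         stream = "full_stage2")
  stage3 <- train_stage3(dataset, cv$oof_stage2, config,
                         stream = "full_stage3")
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 schemas = list(
                   stage1 = lapply(stage1, `[[`, "schema"),
                   stage2 = stage2$schema, stage3 = stage3$schema),
                 suggested_cutoff = cv$suggested_cutoff,
                 cv_summary = cv$summary,
                 config = config,
                 width_calibration = WIDTH_CALIBRATION),
            class = "br_bundle")
}

#' @export
print.br_bundle <- function(x, ...) {
  cat("betaridge model bundle\n")
  cat("  stage-1 windows :", paste(names(x$stage1), collapse = ", "), "\n")
  cat("  suggested cutoff:", x$suggested_cutoff, "\n")
  cat("  CV F1 (stages)  :",
      paste(signif(c(max(x$cv_summary$stage1_f1), x$cv_summary$stage2_f1,
                     x$cv_summary$stage3_f1), 4), collapse = " -> "), "\n")
  invisible(x)
}

#' Predict beta-beta contacts for one protein
#'
#' Runs the trained bundle end to end: stage-1 maps from the four window
#' models, stage-2 refinement, stage-3 final map.
#'
#' @param bundle a `"br_bundle"` from [train_pipeline()].
#' @param map a [contact_map()].
#' @param ss an [ss_profile()].
#' @return the final-stage [prediction_map()]; earlier stages are attached
#'   as attribute `"stages"`.
#' @export
predict_pipeline <- function(bundle, map, ss) {
  config <- bundle$config
  prot <- prepare_protein(map, ss, labels = NULL, config = config)
  s1 <- predict_stage1_maps(bundle$stage1, prot, config)
  fx2 <- assemble_stage_features(s1, prot$ridge, prot$ss, prot$pairs)
  s2 <- predict_stage(bundle$stage2, fx2, prot$pairs, prot$map$length,
                      config$min_sep)
  fx3 <- assemble_stage_features(list(s2 = s2), prot$ridge, prot$ss,
                                 prot$pairs)
  s3 <- predict_stage(bundle$stage3, fx3, prot$pairs, prot$map$length,
                      config$min_sep)
  attr(s3, "stages") <- list(stage1 = s1, stage2 = s2)
  s3
}

#' Save / load a model bundle
#'
#' Bundles round-trip through `saveRDS`/`readRDS` with identical
#' predictions.
#'
#' @param bundle a `"br_bundle"`.
#' @param path file path.
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "br_bundle")) stop("not a betaridge model bundle")
  b
}
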