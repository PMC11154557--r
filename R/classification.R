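# Per-measure binary classification of fused feature vectors:
# stratified 2:1 train/test split, train-fitted scaling and PCA (95 %
# retained variance), RBF-kernel SVM with randomized hyperparameter search
# under 3-fold cross-validation, scored and reported as micro-averaged F1.

#' Model configuration
#'
#' @param pca_variance Fraction of variance the retained principal
#'   components must reach (default 0.95).
#' @param n_iter Randomized-search draws (default 50).
#' @param folds Cross-validation folds (default 3).
#' @param cost_range Log-uniform search range for the SVM cost C.
#' @param gamma_range Log-uniform search range for the RBF kernel width.
#' @param train_fraction Training share of the 2:1 train/test split.
#' @param split One of `"stratified"` (random over vectors, default) or
#'   `"by_subject"` (leave-subjects-out grouping).
#' @return List of class `model_config`.
#' @export
model_config <- function(pca_variance = 0.95, n_iter = 50, folds = 3,
                         cost_range = c(1e-2, 1e3),
                         gamma_range = c(1e-4, 1e1),
                         train_fraction = 2 / 3,
                         split = c("stratified", "by_subject")) {
  stopifnot(pca_variance > 0, pca_variance <= 1, folds >= 2, n_iter >= 1)
  structure(list(pca_variance = pca_variance, n_iter = n_iter,
                 folds = folds, cost_range = cost_range,
                 gamma_range = gamma_range,
                 train_fraction = train_fraction,
                 split = match.arg(split)),
            class = "model_config")
}

#' Label anchor windows against the annotation track
#'
#' A vector is positive (1) iff its anchor window's half-open extent
#' \[t_start, t_end) overlaps any annotated interval of the measure's label
#' by more than zero seconds. Context windows never affect the label.
#'
#' @param anchors Data.frame with `t_start`, `t_end` columns (one row per
#'   vector), e.g. the `anchors` element of [assemble_vectors()].
#' @param annotations Annotation data.frame (see [annotation_track()]).
#' @param measure Sensing measure / annotation label to match.
#' @return Integer vector of 0/1 labels.
#' @export
label_vectors <- function(anchors, annotations, measure) {
  iv <- annotations[annotations$label == measure, , drop = FALSE]
  if (!nrow(iv) || !nrow(anchors)) return(rep(0L, nrow(anchors)))
  vapply(seq_len(nrow(anchors)), function(i) {
    t0 <- anchors$t_start[i]; t1 <- anchors$t_end[i]
    as.integer(any(t0 < iv$t_end & iv$t_start < t1))
  }, integer(1))
}

#' Micro-averaged F1 score
#'
#' F1 computed from globally pooled per-class true-positive, false-positive
#' and false-negative counts. For single-label problems every
#' misclassification is one false positive and one false negative in the
#' pooled counts, so the micro-averaged F1 equals accuracy; it is still
#' reported under its own name because it is the metric the evaluation grid
#' is scored with.
#'
#' @param truth,pred Vectors of class labels (coerced to character).
#' @return Micro-averaged F1 in \[0, 1\].
#' @export
micro_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- union(truth, pred)
  tp <- sum(vapply(classes, function(cl)
    sum(truth == cl & pred == cl), numeric(1)))
  fp <- sum(vapply(classes, function(cl)
    sum(truth != cl & pred == cl), numeric(1)))
  fn <- sum(vapply(classes, function(cl)
    sum(truth == cl & pred != cl), numeric(1)))
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

stratified_indices <- function(y, fraction) {
  idx <- unlist(lapply(unique(y), function(cl) {
    pool <- which(y == cl)
    take <- round(length(pool) * fraction)
    take <- min(max(take, 1L), length(pool))
    sample(pool, take)
  }))
  sort(idx)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    pool <- sample(which(y == cl))
    fold[pool] <- rep_len(seq_len(k), length(pool))
  }
  fold
}

#' Split, scale and project a labelled dataset
#'
#' Splits vectors 2:1 into train/test before any statistic is fitted, then
#' standardizes features with train-only means/SDs (zero-SD columns map to
#' zero) and fits PCA on the scaled training block, keeping the smallest
#' number of components whose cumulative variance reaches the configured
#' fraction. The test block is transformed with the train-fitted statistics
#' only.
#'
#' @param X Feature matrix (vectors x features).
#' @param y Binary label vector.
#' @param config A [model_config()].
#' @param seed Integer seed for the split.
#' @param groups Optional subject ids (used when `config$split` is
#'   `"by_subject"`).
#' @return List with `train`/`test` (each `X`, `y`), the fitted `scaler`
#'   and `pca`, and `n_components`.
#' @export
split_scale_project <- function(X, y, config = model_config(), seed = 1,
                                groups = NULL) {
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 30) stop("need >= 30 vectors to fit", call. = FALSE)
  set.seed(as.integer(seed))
  if (config$split == "by_subject" && !is.null(groups)) {
    gs <- unique(groups)
    n_tr <- max(1L, round(length(gs) * config$train_fraction))
    tr_groups <- sample(gs, n_tr)
    tr_idx <- which(groups %in% tr_groups)
  } else {
    tr_idx <- stratified_indices(y, config$train_fraction)
  }
  te_idx <- setdiff(seq_len(nrow(X)), tr_idx)
  if (length(unique(y[tr_idx])) < 2) {
    stop("training split contains a single class; stratification failed",
         call. = FALSE)
  }
  transformed <- fit_scale_pca(X[tr_idx, , drop = FALSE], config)
  Xtr <- transformed$scores
  Xte <- apply_scale_pca(transformed, X[te_idx, , drop = FALSE])
  list(train = list(X = Xtr, y = y[tr_idx]),
       test = list(X = Xte, y = y[te_idx]),
       scaler = transformed$scaler, pca = transformed$pca,
       n_components = transformed$k,
       train_index = tr_idx, test_index = te_idx)
}

fit_scale_pca <- function(Xtr, config) {
  mu <- colMeans(Xtr)
  sd_ <- apply(Xtr, 2, stats::sd)
  sd_safe <- ifelse(is.finite(sd_) & sd_ > 0, sd_, 1)
  Z <- sweep(sweep(Xtr, 2, mu), 2, sd_safe, "/")
  Z[, sd_safe == 1 & sd_ == 0] <- 0
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  v <- pca$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= config$pca_variance)[1]
  list(scaler = list(mean = mu, sd = sd_safe, zero = sd_ == 0),
       pca = pca, k = k,
       scores = pca$x[, seq_len(k), drop = FALSE])
}

apply_scale_pca <- function(fit, Xnew) {
  Z <- sweep(sweep(Xnew, 2, fit$scaler$mean), 2, fit$scaler$sd, "/")
  Z[, fit$scaler$zero] <- 0
  (Z %*% fit$pca$rotation)[, seq_len(fit$k), drop = FALSE]
}

#' Train an RBF SVM with randomized hyperparameter search
#'
#' Draws `n_iter` (cost, gamma) pairs log-uniformly from the configured
#' ranges, scores each by mean micro-F1 over stratified k-fold
#' cross-validation of the training block, picks the best pair (ties to the
#' earlier draw), and refits on the full training block.
#'
#' @param train List with `X` (projected features) and `y` (binary labels).
#' @param config A [model_config()].
#' @param seed Integer seed: the same seed reproduces the same draws, folds
#'   and chosen hyperparameters.
#' @return List with the fitted `model`, `cost`, `gamma`, `cv_f1` (best mean
#'   CV score), and the full `search` table.
#' @export
train_svm <- function(train, config = model_config(), seed = 1) {
  y <- factor(train$y)
  if (nlevels(y) < 2) stop("training data has a single class", call. = FALSE)
  set.seed(as.integer(seed))
  lrunif <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  cand <- data.frame(cost = lrunif(config$n_iter, config$cost_range),
                     gamma = lrunif(config$n_iter, config$gamma_range))
  fold <- stratified_folds(as.integer(y), config$folds)
  if (any(vapply(seq_len(config$folds), function(f)
    length(unique(y[fold == f])) < 2, logical(1)))) {
    stop(paste("a cross-validation fold lost a class; regenerate data or",
               "lower the fold count"), call. = FALSE)
  }
  cand$cv_f1 <- vapply(seq_len(config$n_iter), function(i) {
    mean(vapply(seq_len(config$folds), function(f) {
      tr <- fold != f
      m <- e1071::svm(train$X[tr, , drop = FALSE], y[tr],
                      type = "C-classification", kernel = "radial",
                      cost = cand$cost[i], gamma = cand$gamma[i],
                      scale = FALSE)
      micro_f1(y[!tr], stats::predict(m, train$X[!tr, , drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cand$cv_f1)
  model <- e1071::svm(train$X, y, type = "C-classification",
                      kernel = "radial", cost = cand$cost[best],
                      gamma = cand$gamma[best], scale = FALSE)
  list(model = model, cost = cand$cost[best], gamma = cand$gamma[best],
       cv_f1 = cand$cv_f1[best], search = cand)
}

#' Evaluate a fitted model on the test block
#'
#' @param fit Output of [train_svm()].
#' @param test List with `X` and `y`.
#' @return One-row data.frame: `micro_f1`, confusion counts `tp`, `fp`,
#'   `fn`, `tn` (w.r.t. the positive class "1"), `n_test`, and the chosen
#'   hyperparameters.
#' @export
evaluate_model <- function(fit, test) {
  if (!length(test$y)) stop("empty test set", call. = FALSE)
  pred <- stats::predict(fit$model, test$X)
  truth <- factor(test$y, levels = levels(fit$model$fitted))
  data.frame(micro_f1 = micro_f1(truth, pred),
             tp = sum(truth == "1" & pred == "1"),
             fp = sum(truth != "1" & pred == "1"),
             fn = sum(truth == "1" & pred != "1"),
             tn = sum(truth != "1" & pred != "1"),
             n_test = length(pred),
             cost = fit$cost, gamma = fit$gamma, cv_f1 = fit$cv_f1)
}

#' Run one classification cell
#'
#' Assembles vectors for each session, labels them, pools them across
#' sessions, then splits, projects, trains and evaluates.
#'
#' @param feats List of [session_features()] objects (one per session).
#' @param measure Sensing measure.
#' @param sensors Sensor combination string.
#' @param past_s,future_s Context seconds.
#' @param config A [model_config()].
#' @param seed Integer seed covering split, search, and folds.
#' @return One-row data.frame describing the cell and its scores, including
#'   the trivial majority-class baseline `baseline_f1`.
#' @export
run_cell <- function(feats, measure, sensors, past_s, future_s,
                     config = model_config(), seed = 1) {
  pooled_X <- list(); pooled_y <- list(); pooled_g <- list()
  for (sf in feats) {
    vs <- assemble_vectors(sf, measure, sensors, past_s, future_s)
    if (!nrow(vs$X)) next
    pooled_X[[length(pooled_X) + 1L]] <- vs$X
    pooled_y[[length(pooled_y) + 1L]] <-
      label_vectors(vs$anchors, sf$annotations, measure)
    pooled_g[[length(pooled_g) + 1L]] <- rep(sf$subject_id, nrow(vs$X))
  }
  X <- do.call(rbind, pooled_X)
  y <- unlist(pooled_y)
  groups <- unlist(pooled_g)
  sp <- split_scale_project(X, y, config, seed = seed, groups = groups)
  fit <- train_svm(sp$train, config, seed = seed + 1L)
  res <- evaluate_model(fit, sp$test)
  maj <- names(which.max(table(sp$train$y)))
  res$baseline_f1 <- micro_f1(sp$test$y, rep(maj, length(sp$test$y)))
  res$prevalence <- mean(y == 1)
  cbind(data.frame(measure = measure, sensors = sensors,
                   past_s = past_s, future_s = future_s,
                   n_vectors = nrow(X), n_components = sp$n_components,
                   seed = seed, registry = feats[[1]]$registry_id,
                   stringsAsFactors = FALSE),
        res)
}

#' Sweep the sensor-combination by context-size evaluation grid
#'
#' Runs [run_cell()] for every requested measure, sensor combination and
#' context configuration (by default the full 3 x 4 x 11 = 132-cell grid)
#' and reports the per-measure peak micro-F1 with its arg-max cell.
#'
#' @param feats List of [session_features()] objects.
#' @param measures Sensing measures to sweep.
#' @param combos Optional named list mapping measure -> combinations;
#'   defaults to all four per measure.
#' @param configs Data.frame of `past_s`, `future_s` rows; defaults to the
#'   eleven configurations.
#' @param config A [model_config()].
#' @param seed Base seed; each cell derives a distinct deterministic seed.
#' @return Data.frame of one row per cell (class `eval_grid`), with the
#'   per-measure peaks available through [summarize_grid()].
#' @export
run_grid <- function(feats, measures = names(MEASURE_ANCHOR),
                     combos = NULL, configs = context_configurations(),
                     config = model_config(), seed = 1) {
  rows <- list()
  cell_id <- 0L
  for (ms in measures) {
    cbs <- if (is.null(combos)) sensor_combinations(ms) else combos[[ms]]
    for (cb in cbs) {
      for (j in seq_len(nrow(configs))) {
        cell_id <- cell_id + 1L
        rows[[cell_id]] <- run_cell(feats, ms, cb,
                                    configs$past_s[j], configs$future_s[j],
                                    config,
                                    seed = seed * 1000L + cell_id)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_grid", "data.frame")
  out
}

#' Per-measure peak scores of an evaluation grid
#'
#' @param grid Output of [run_grid()].
#' @return Data.frame with one row per measure: the peak micro-F1 and the
#'   sensor combination and context configuration achieving it.
#' @export
summarize_grid <- function(grid) {
  do.call(rbind, lapply(split(grid, grid$measure), function(g) {
    b <- g[which.max(g$micro_f1), ]
    data.frame(measure = b$measure, peak_micro_f1 = b$micro_f1,
               sensors = b$sensors, past_s = b$past_s,
               future_s = b$future_s, stringsAsFactors = FALSE)
  }))
}
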