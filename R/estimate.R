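# Estimation of per-node non-commuting counts from the all-purpose count and
# locational features, evaluated by k-fold cross-validated Pearson
# correlation of pooled out-of-fold predictions against the observed counts.

FEATURE_COLS <- c("Num_cycling", "Dis_to_Greenspace", "Dis_to_Waterbody",
                  "Dis_to_Citycentre", "Num_nearest_busstops")
MODEL_KINDS <- c("OLS", "MLP", "SVM", "RF")

.min_dist <- function(px, py, layer, name) {
  if (nrow(layer) == 0L) abort(sprintf("environment layer '%s' is empty", name))
  vapply(seq_along(px), function(i) {
    sqrt(min((layer$x - px[i])^2 + (layer$y - py[i])^2))
  }, numeric(1))
}

#' Build locational features for each node
#'
#' Features: the all-purpose count (`Num_cycling`), Euclidean distances to
#' the nearest greenspace point, nearest waterbody point and the city
#' centre, and the number of bus stops within 100 m (boundary-inclusive:
#' distance <= 100).
#'
#' @param nodes Node tibble with `id`, `x`, `y`, `count_total`.
#' @param env_layers EnvLayers list (see [make_env_layers()]).
#' @param busstop_radius Radius for the bus-stop count, meters (default 100).
#' @return Tibble: `id` plus the five feature columns.
#' @export
build_features <- function(nodes, env_layers, busstop_radius = 100) {
  stopifnot(all(c("id", "x", "y", "count_total") %in% names(nodes)))
  bs <- env_layers$busstop
  if (nrow(bs) == 0L) abort("environment layer 'busstop' is empty")
  cc <- env_layers$city_centre
  n_bus <- vapply(seq_len(nrow(nodes)), function(i) {
    sum((bs$x - nodes$x[i])^2 + (bs$y - nodes$y[i])^2 <= busstop_radius^2)
  }, numeric(1))
  tibble(
    id = as.character(nodes$id),
    Num_cycling = as.numeric(nodes$count_total),
    Dis_to_Greenspace = .min_dist(nodes$x, nodes$y, env_layers$greenspace, "greenspace"),
    Dis_to_Waterbody = .min_dist(nodes$x, nodes$y, env_layers$waterbody, "waterbody"),
    Dis_to_Citycentre = sqrt((nodes$x - cc[1])^2 + (nodes$y - cc[2])^2),
    Num_nearest_busstops = as.integer(n_bus)
  )
}

#' Screen features for linear association with the target
#'
#' Pairwise Pearson correlation of each feature with the target; features
#' with |r| < 0.1 are flagged as not significantly linearly correlated (the
#' screening that motivates the use of nonlinear models alongside OLS).
#'
#' @param features Tibble of numeric feature columns (an `id` column is
#'   ignored).
#' @param target Numeric response vector.
#' @param threshold Flagging threshold on |r| (default 0.1).
#' @return Tibble `(feature, r, linearly_correlated)`; `r` is NA for
#'   zero-variance columns.
#' @export
screen_correlations <- function(features, target, threshold = 0.1) {
  feats <- features[, setdiff(names(features), "id"), drop = FALSE]
  if (nrow(feats) < 3L) abort("need at least 3 rows to screen correlations")
  rs <- vapply(feats, function(col) {
    if (stats::sd(col) == 0 || stats::sd(target) == 0) return(NA_real_)
    stats::cor(col, target)
  }, numeric(1))
  rs <- stats::setNames(unname(rs), names(rs))
  tibble(feature = names(rs), r = unname(rs),
         linearly_correlated = unname(!is.na(rs) & abs(rs) >= threshold))
}

#' Shuffled k-fold assignment
#'
#' @param n_rows Number of rows.
#' @param k Number of folds (2 <= k <= n_rows).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`, sizes differing by at
#'   most 1; deterministic given the seed.
#' @export
kfold_split <- function(n_rows, k = 10L, seed = 0L) {
  if (k < 2L) abort("k must be at least 2")
  if (k > n_rows) abort("k cannot exceed the number of rows")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n_rows))
}

#' Fit one regression model and predict
#'
#' Model kinds: `OLS` — least-squares linear regression with intercept;
#' `MLP` — single-hidden-layer feed-forward network (64 units, standardized
#' inputs and response); `SVM` — radial-basis-function support-vector
#' regression (standardized inputs, cost 1); `RF` — random forest (500
#' trees). Stochastic models are seeded. A constant training response is
#' handled degenerately: every model predicts that constant.
#'
#' @param model_kind One of `"OLS"`, `"MLP"`, `"SVM"`, `"RF"`.
#' @param train_features,test_features Numeric feature tibbles (no `id`).
#' @param train_target Numeric response.
#' @param seed Integer seed for stochastic fits.
#' @return Numeric predictions for `test_features`, all finite.
#' @export
fit_and_predict <- function(model_kind, train_features, train_target,
                            test_features, seed = 0L) {
  if (!model_kind %in% MODEL_KINDS) {
    abort(sprintf("unknown model_kind '%s' (use %s)", model_kind,
                  paste(MODEL_KINDS, collapse = "/")))
  }
  train_features <- as.data.frame(train_features[, setdiff(names(train_features), "id"),
                                                 drop = FALSE])
  test_features <- as.data.frame(test_features[, names(train_features), drop = FALSE])
  if (nrow(train_features) < ncol(train_features) + 1L) {
    abort("degenerate training set: fewer rows than features + 1")
  }
  if (stats::sd(train_target) == 0) {
    return(rep(train_target[1], nrow(test_features)))
  }
  preds <- switch(model_kind,
    OLS = {
      df <- cbind(.y = train_target, train_features)
      fit <- stats::lm(.y ~ ., data = df)
      unname(stats::predict(fit, newdata = test_features))
    },
    MLP = {
      mu <- vapply(train_features, mean, numeric(1))
      sg <- vapply(train_features, stats::sd, numeric(1))
      sg[sg == 0] <- 1
      xs <- scale(train_features, mu, sg)
      xt <- scale(test_features, mu, sg)
      ym <- mean(train_target); ys <- stats::sd(train_target)
      set.seed(seed)
      fit <- nnet::nnet(xs, (train_target - ym) / ys, size = 64, linout = TRUE,
                        maxit = 500, decay = 1e-4, trace = FALSE, MaxNWts = 2000)
      as.numeric(stats::predict(fit, xt)) * ys + ym
    },
    SVM = {
      set.seed(seed)
      fit <- e1071::svm(x = train_features, y = train_target,
                        kernel = "radial", cost = 1, scale = TRUE)
      unname(stats::predict(fit, test_features))
    },
    RF = {
      df <- cbind(.y = train_target, train_features)
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = 500,
                            seed = seed, num.threads = 1)
      stats::predict(fit, test_features, num.threads = 1)$predictions
    }
  )
  if (any(!is.finite(preds))) abort("model produced non-finite predictions")
  preds
}

#' Cross-validated estimation of non-commuting counts
#'
#' Runs shuffled k-fold cross-validation for one model kind, pools the
#' out-of-fold predictions (each row predicted exactly once) and reports the
#' Pearson correlation of pooled predictions against the observed target,
#' plus the per-fold mean correlation for transparency.
#'
#' @param features Feature tibble (see [build_features()]; an `id` column is
#'   carried through to the predictions).
#' @param target Numeric response (observed non-commuting counts).
#' @param model_kind One of `"OLS"`, `"MLP"`, `"SVM"`, `"RF"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling both the fold split and the
#'   stochastic fits.
#' @return A `purpose_cv` object: `$result` (one-row tibble with `model`,
#'   `pearson_r`, `mean_fold_r`, `k`, `seed`), `$predictions` (tibble
#'   `id`, `actual`, `predicted`, `fold`, `model`).
#' @export
cross_validated_correlation <- function(features, target, model_kind,
                                        k = 10L, seed = 0L) {
  ids <- if ("id" %in% names(features)) as.character(features$id) else
    as.character(seq_len(nrow(features)))
  feats <- features[, setdiff(names(features), "id"), drop = FALSE]
  n <- nrow(feats)
  folds <- kfold_split(n, k, seed)
  predicted <- numeric(n)
  fold_r <- numeric(k)
  for (f in seq_len(k)) {
    te <- folds == f
    predicted[te] <- fit_and_predict(model_kind, feats[!te, , drop = FALSE],
                                     target[!te], feats[te, , drop = FALSE],
                                     seed = split_seed(seed, 200L + f))
    fold_r[f] <- if (stats::sd(predicted[te]) > 0 && stats::sd(target[te]) > 0) {
      stats::cor(predicted[te], target[te])
    } else NA_real_
  }
  r <- stats::cor(predicted, target)
  structure(list(
    result = tibble(model = model_kind, pearson_r = r,
                    mean_fold_r = mean(fold_r, na.rm = TRUE),
                    k = as.integer(k), seed = as.integer(seed)),
    predictions = tibble(id = ids, actual = target, predicted = predicted,
                         fold = folds, model = model_kind)
  ), class = "purpose_cv")
}

#' Compare several estimation models by cross-validated correlation
#'
#' @param features,target,k,seed As in [cross_validated_correlation()].
#' @param models Character vector of model kinds (default all four).
#' @return A `purpose_cv` object pooling all models: `$result` has one row
#'   per model.
#' @export
estimate_purpose <- function(features, target, models = MODEL_KINDS,
                             k = 10L, seed = 0L) {
  fits <- lapply(models, function(m)
    cross_validated_correlation(features, target, m, k = k, seed = seed))
  structure(list(
    result = bind_rows(lapply(fits, function(f) f$result)),
    predictions = bind_rows(lapply(fits, function(f) f$predictions))
  ), class = "purpose_cv")
}

#' @export
print.purpose_cv <- function(x, ...) {
  cat("<purpose_cv> pooled out-of-fold Pearson correlations\n")
  print(as.data.frame(x$result), row.names = FALSE)
  invisible(x)
}

#' Per-model tidy view of a cross-validation result
#'
#' @param x A `purpose_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per model.
#' @method tidy purpose_cv
#' @export
tidy.purpose_cv <- function(x, ...) x$result

#' One-row summary of a cross-validation result
#'
#' @param x A `purpose_cv` object.
#' @param ... Unused.
#' @return One-row tibble: best model, best r, k, number of rows.
#' @method glance purpose_cv
#' @export
glance.purpose_cv <- function(x, ...) {
  best <- x$result[which.max(x$result$pearson_r), ]
  tibble(best_model = best$model, best_r = best$pearson_r,
         k = best$k, n = sum(x$predictions$model == best$model))
}
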