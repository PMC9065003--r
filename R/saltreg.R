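# Salt-concentration regression protocols: comparator models (ridge linear,
# regression tree), train/test split, evaluation metrics, k-fold CV,
# leave-one-concentration-out and minimum-residual week inference.

#' Stratified train/test split
#'
#' Splits indices into train and test, stratified by the target levels so
#' every concentration appears in both sets. Deterministic given `seed`.
#'
#' @param y Target vector (stratified by its unique values).
#' @param test_fraction Test share, in (0, 1), default 0.2.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
split_train_test <- function(y, test_fraction = 0.2, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop_ramansalt("parameter", "test_fraction must be in (0, 1)")
  }
  set.seed(as.integer(seed))
  test <- integer(0)
  for (lv in unique(y)) {
    idx <- which(y == lv)
    k <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, k))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Fit a salt-concentration regression model by tag
#'
#' Dispatches to the exact GP ([fit_gpr()]) for `gpr-*` tags, ridge linear
#' regression (`glmnet`, alpha = 0, lambda by internal CV with
#' deterministic folds) for `"ridge"`, and a CART regression tree
#' (`rpart`) for `"tree"`. All returned objects share the `salt_model`
#' predict contract.
#'
#' @param X Feature matrix (rows = preprocessed spectra).
#' @param y Concentrations, mM.
#' @param model One of `"gpr-rq"`, `"gpr-se"`, `"gpr-matern52"`,
#'   `"gpr-exp"`, `"ridge"`, `"tree"`.
#' @param seed Integer seed (restart jitter / CV folds).
#' @param ... Passed through to the underlying fitter.
#' @return A fitted model of class `salt_model` with a `model_tag`
#'   attribute.
#' @export
fit_salt_model <- function(X, y, model = "gpr-rq", seed = 1L, ...) {
  X <- as.matrix(X)
  fit <- if (grepl("^gpr-", model)) {
    fit_gpr(X, y, kernel = sub("^gpr-", "", model), seed = seed, ...)
  } else if (model == "ridge") {
    fit_ridge(X, y, seed = seed, ...)
  } else if (model == "tree") {
    fit_tree(X, y, ...)
  } else {
    stop_ramansalt("parameter", "unknown model tag '", model, "'")
  }
  attr(fit, "model_tag") <- model
  fit
}

fit_ridge <- function(X, y, seed = 1L, nfolds = 5L, ...) {
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  cv <- glmnet::cv.glmnet(X, y, alpha = 0, foldid = foldid,
                          standardize = TRUE)
  structure(list(fit = cv, lambda = cv$lambda.min),
            class = c("ridge_model", "salt_model"))
}

#' @export
predict.ridge_model <- function(object, X_new, ...) {
  as.numeric(stats::predict(object$fit, newx = as.matrix(X_new),
                            s = "lambda.min"))
}

fit_tree <- function(X, y, maxdepth = 8L, cp = 1e-4, ...) {
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_len(ncol(df)))
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                      control = rpart::rpart.control(maxdepth = maxdepth,
                                                     cp = cp, xval = 0))
  structure(list(fit = fit, p = ncol(X)), class = c("tree_model", "salt_model"))
}

#' @export
predict.tree_model <- function(object, X_new, ...) {
  df <- as.data.frame(as.matrix(X_new))
  names(df) <- paste0("v", seq_len(ncol(df)))
  as.numeric(stats::predict(object$fit, newdata = df))
}

#' Fit the comparator model set
#'
#' Ridge linear regression and a CART regression tree under the common
#' `salt_model` contract, for side-by-side evaluation against the GP.
#'
#' @inheritParams fit_salt_model
#' @return Named list of fitted `salt_model`s (`ridge`, `tree`).
#' @export
fit_baselines <- function(X, y, seed = 1L, ...) {
  list(ridge = fit_salt_model(X, y, "ridge", seed = seed, ...),
       tree = fit_salt_model(X, y, "tree", seed = seed, ...))
}

#' Evaluate a model on a test set
#'
#' RMSE (`sqrt(mean((y - yhat)^2))`, mM), R^2
#' (`1 - SS_res/SS_tot`), per-sample residuals `y - yhat`, and the median
#' prediction for each true concentration level. When the test targets
#' have zero variance R^2 is undefined and reported `NA` with a warning.
#'
#' @param model A fitted `salt_model`.
#' @param X_test,y_test Test features and true concentrations (mM).
#' @param model_tag,week Optional identifiers carried into the report.
#' @return An `eval_report`: list with `rmse`, `r2`, `residuals`,
#'   `per_concentration_medians`, `predictions`, `model_tag`, `week`, `n`.
#' @export
evaluate <- function(model, X_test, y_test, model_tag = NULL, week = NA) {
  if (!length(y_test)) stop_ramansalt("input", "empty test set")
  yhat <- predict(model, X_test)
  resid <- y_test - yhat
  rmse <- sqrt(mean(resid^2))
  sst <- sum((y_test - mean(y_test))^2)
  r2 <- if (sst == 0) {
    warning("zero-variance test targets: R^2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(resid^2) / sst
  med <- tapply(yhat, y_test, stats::median)
  structure(list(rmse = rmse, r2 = r2, residuals = resid,
                 per_concentration_medians =
                   stats::setNames(as.numeric(med), names(med)),
                 predictions = yhat,
                 model_tag = model_tag %||% attr(model, "model_tag"),
                 week = week, n = length(y_test)),
            class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report%s%s: n=%d, RMSE=%.3f mM, R2=%s>\n",
              if (is.null(x$model_tag)) "" else paste0(" ", x$model_tag),
              if (is.na(x$week)) "" else paste0(" week ", x$week),
              x$n, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' k-fold cross-validation
#'
#' Deterministic fold assignment from `seed`; fits the model tag on each
#' training complement and evaluates on the held-out fold.
#'
#' @inheritParams fit_salt_model
#' @param folds Number of folds, >= 2 (default 5; `folds = n` gives
#'   leave-one-out).
#' @return List with `fold_reports` (per-fold `eval_report`s, folds with
#'   zero test variance carry `r2 = NA`), `fold_assignment`, and `summary`
#'   (mean and sd of fold RMSE and R^2).
#' @export
cross_validate <- function(X, y, model = "gpr-rq", folds = 5L, seed = 1L,
                           ...) {
  X <- as.matrix(X)
  n <- length(y)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n) {
    stop_ramansalt("parameter", "need 2 <= folds <= n")
  }
  set.seed(as.integer(seed))
  assignment <- sample(rep_len(seq_len(folds), n))
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(assignment == f)
    tr <- which(assignment != f)
    fit <- fit_salt_model(X[tr, , drop = FALSE], y[tr], model,
                          seed = seed, ...)
    reports[[f]] <- suppressWarnings(
      evaluate(fit, X[te, , drop = FALSE], y[te], model_tag = model))
  }
  rmses <- vapply(reports, `[[`, numeric(1), "rmse")
  r2s <- vapply(reports, `[[`, numeric(1), "r2")
  list(fold_reports = reports, fold_assignment = assignment,
       summary = list(rmse_mean = mean(rmses), rmse_sd = stats::sd(rmses),
                      r2_mean = mean(r2s, na.rm = TRUE),
                      r2_sd = stats::sd(r2s, na.rm = TRUE)))
}

#' Leave-one-concentration-out evaluation
#'
#' Trains on every concentration group except `left_out`, predicts the
#' withheld group, and reports `median(yhat) - left_out` (mM) — the bias
#' incurred when the model must interpolate to an unseen stress level.
#'
#' @inheritParams fit_salt_model
#' @param left_out Concentration (mM) to withhold; must be present in `y`
#'   with at least two other levels remaining.
#' @return List with `report` (an `eval_report` on the withheld group,
#'   `r2` is `NA` there since the true values are constant) and
#'   `median_deviation` (mM).
#' @export
leave_one_concentration_out <- function(X, y, left_out, model = "gpr-rq",
                                        seed = 1L, ...) {
  X <- as.matrix(X)
  if (!left_out %in% y) {
    stop_ramansalt("input", "left_out = ", left_out, " mM not present in y")
  }
  if (length(unique(y[y != left_out])) < 2L) {
    stop_ramansalt("input", "need >= 2 remaining concentration levels")
  }
  tr <- which(y != left_out)
  te <- which(y == left_out)
  fit <- fit_salt_model(X[tr, , drop = FALSE], y[tr], model, seed = seed, ...)
  rep <- suppressWarnings(
    evaluate(fit, X[te, , drop = FALSE], y[te], model_tag = model))
  list(report = rep,
       median_deviation = stats::median(rep$predictions) - left_out,
       model = fit)
}

#' Infer sample week by minimum concentration residual
#'
#' Given per-week trained models and spectra of known true concentration
#' but unknown week, scores each week model by
#' `|median(predictions) - true_concentration|` and returns the arg-min
#' week; ties break toward the earlier week.
#'
#' @param models Named list of fitted `salt_model`s; names are weeks.
#' @param X_unknown Spectra to score.
#' @param true_concentration Known concentration, mM.
#' @return List with `week` (numeric) and `table` (data.frame: week,
#'   median_prediction, abs_residual).
#' @export
predict_week <- function(models, X_unknown, true_concentration) {
  if (!length(models)) stop_ramansalt("input", "empty model map")
  weeks <- as.numeric(names(models))
  if (anyNA(weeks)) stop_ramansalt("input", "model names must be weeks")
  med <- vapply(models, function(m) {
    stats::median(predict(m, X_unknown))
  }, numeric(1))
  tab <- data.frame(week = weeks, median_prediction = as.numeric(med),
                    abs_residual = abs(as.numeric(med) - true_concentration))
  tab <- tab[order(tab$week), , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab$week[which.min(tab$abs_residual)]  # which.min: first = earliest
  list(week = best, table = tab)
}
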