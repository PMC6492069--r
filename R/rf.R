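# R-side interface to the compiled forest.

#' Random-forest classifier
#'
#' Bagged CART trees with Gini impurity splits and per-node feature
#' subsampling (`mtry`, default `floor(sqrt(p))`). Probability predictions
#' average the leaf class distributions across trees; feature importances
#' are the classic mean-decrease-in-impurity sums, normalized to 1.
#' Training is deterministic given `seed`.
#'
#' @param x Numeric matrix or data.frame of predictors (no missing values).
#' @param y Factor (or coercible) of class labels.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param min_node Minimum samples per leaf (default 1: trees grown to
#'   purity, the usual classification setting).
#' @param max_depth Depth cap, 0 = unlimited.
#' @param seed Integer seed for the forest's internal RNG.
#' @return Object of class `cm_rf` with elements `forest`, `levels`,
#'   `importance` (named, sums to 1 when any split occurred), `feature_names`.
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' y <- factor(x[, 1] + rnorm(100, sd = 0.3) > 0)
#' fit <- cm_rf(x, y, ntree = 50, seed = 1)
#' head(predict(fit, x))
#' @export
cm_rf <- function(x, y, ntree = 500, mtry = NULL, min_node = 1,
                  max_depth = 0, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("predictors contain missing values; filter complete rows first")
  y <- factor(y)
  if (length(y) != nrow(x)) stop("x and y lengths differ")
  lev <- levels(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  forest <- .rf_fit_cpp(x, as.integer(y) - 1L, length(lev), as.integer(ntree),
                        as.integer(mtry), as.integer(min_node),
                        as.integer(max_depth), as.integer(seed))
  imp <- as.numeric(forest$importance)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  names(imp) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  structure(list(forest = forest, levels = lev, importance = imp,
                 feature_names = names(imp), ntree = ntree, mtry = mtry,
                 seed = seed),
            class = "cm_rf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a `cm_rf` forest
#'
#' @param object A fitted [cm_rf()].
#' @param newdata Matrix or data.frame with the training columns.
#' @param type `"prob"` for the class-probability matrix, `"class"` for the
#'   argmax label (ties to the first level).
#' @param ... Unused.
#' @return Probability matrix (rows sum to 1) or factor of predictions.
#' @export
predict.cm_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(newdata) <- "double"
  if (anyNA(newdata)) stop("newdata contains missing values")
  pr <- .rf_predict_cpp(object$forest, newdata)
  colnames(pr) <- object$levels
  if (type == "prob") return(pr)
  factor(object$levels[max.col(pr, ties.method = "first")], levels = object$levels)
}

#' @export
print.cm_rf <- function(x, ...) {
  cat(sprintf("<cm_rf> %d trees, mtry %d, %d features, classes: %s\n",
              x$ntree, x$mtry, length(x$feature_names),
              paste(x$levels, collapse = "/")))
  invisible(x)
}
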