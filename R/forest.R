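#' Curvature-test p-value for one predictor against a response
#'
#' The split-predictor selection rule used by the age forest: the predictor
#' is binned into at most four quartile cells (a categorical predictor uses
#' its levels), the response into at most four quartile cells, and the
#' Pearson chi-square test of independence is applied to the resulting
#' contingency table with `df = (r-1)(c-1)` after dropping empty rows and
#' columns. Pairs with a missing predictor value are removed first. A
#' constant predictor returns `p = 1` by convention so it is never
#' preferred.
#'
#' @param x predictor values (numeric, or integer level codes when
#'   `categorical = TRUE`).
#' @param y response values.
#' @param categorical treat `x` as categorical level codes.
#' @return p-value in `[0, 1]`.
#' @export
curvature_test_p <- function(x, y, categorical = FALSE) {
  stopifnot(length(x) == length(y))
  .cb_curvature_p(as.numeric(x), as.numeric(y), isTRUE(categorical))
}

#' Fit a bagged regression-forest age model
#'
#' Trains an ensemble of regression trees on chronological age with percent
#' methylation at the panel CpGs plus sex as predictors. Each tree is grown
#' on a with-replacement bootstrap of the training samples; at every node
#' the split predictor is the one minimising the curvature-test p-value
#' (ties to the lowest feature index), the cut point maximises the reduction
#' in sum of squared errors, nodes are split down to a minimum leaf size of
#' one, and surrogate split rules are fitted at every internal node so
#' samples with missing values can still be routed. Sex is the first feature
#' and is handled as a categorical predictor.
#'
#' @param cohort a [methylation_cohort()] providing the training samples, or
#'   a numeric feature matrix (then supply `age` and `categorical`).
#' @param cpgs CpG names to use as features (default: all CpGs in the
#'   cohort).
#' @param n_trees number of trees (default 1000).
#' @param min_leaf minimum samples per leaf (default 1).
#' @param predictor_selection `"curvature"` (default) or `"mse_exhaustive"`
#'   (classic greedy CART selection, kept as a reference alternative).
#' @param surrogate fit surrogate split rules at every internal node
#'   (default `TRUE`).
#' @param oob compute out-of-bag predictions at fit time (default `TRUE`).
#' @param seed integer seed; the fitted forest is a pure function of the
#'   data, parameters and seed.
#' @param age,categorical only for the matrix interface: the response vector
#'   and a logical vector flagging categorical columns.
#' @return An object of class `age_forest` with elements `trees`, `inbag`
#'   (n x n_trees bootstrap count matrix), `features`, `categorical`,
#'   `train_age`, `oob_pred`, `params`.
#' @examples
#' panel <- default_panel()
#' ref <- generate_cohort(panel, cohort_spec(60), seed = 1)
#' fit <- age_forest(ref, cpgs = panel$name[panel$clock], n_trees = 25,
#'                   seed = 1)
#' print(fit)
#' @export
age_forest <- function(cohort, cpgs = NULL, n_trees = 1000, min_leaf = 1,
                       predictor_selection = c("curvature", "mse_exhaustive"),
                       surrogate = TRUE, oob = TRUE, seed = NULL,
                       age = NULL, categorical = NULL) {
  predictor_selection <- match.arg(predictor_selection)
  stopifnot(n_trees >= 1, min_leaf >= 1)
  if (inherits(cohort, "methylation_cohort")) {
    if (is.null(cpgs)) cpgs <- cpg_names(cohort)
    missing_cpgs <- setdiff(cpgs, cpg_names(cohort))
    if (length(missing_cpgs) > 0)
      stop("CpGs not in cohort: ", paste(missing_cpgs, collapse = ", "))
    X <- forest_features(cohort, cpgs)
    y <- cohort$age
    categorical <- c(TRUE, rep(FALSE, length(cpgs)))
  } else {
    X <- as.matrix(cohort)
    y <- as.numeric(age)
    if (is.null(categorical)) categorical <- rep(FALSE, ncol(X))
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  boot <- with_seed(seed,
    matrix(sample.int(n, n * n_trees, replace = TRUE), n, n_trees))
  trees <- .cb_fit_forest(X, y, categorical, boot, as.integer(min_leaf),
                          isTRUE(surrogate),
                          predictor_selection == "curvature")
  inbag <- apply(boot, 2, tabulate, nbins = n)
  fit <- structure(list(trees = trees, inbag = inbag,
                        features = colnames(X), categorical = categorical,
                        train_age = y, oob_pred = NULL,
                        params = list(n_trees = n_trees, min_leaf = min_leaf,
                                      predictor_selection = predictor_selection,
                                      surrogate = surrogate, seed = seed)),
                   class = "age_forest")
  if (oob) {
    tp <- .cb_predict_trees(trees, X)
    out_mask <- inbag == 0
    num <- rowSums(tp * out_mask)
    den <- rowSums(out_mask)
    fit$oob_pred <- ifelse(den > 0, num / den, NA_real_)
  }
  fit
}

# assemble the [sex, CpG...] feature matrix; sex coded F=0, M=1
forest_features <- function(cohort, cpgs) {
  X <- cbind(sex = as.numeric(cohort$sex == "M"),
             cohort$betas[, cpgs, drop = FALSE])
  colnames(X) <- c("sex", cpgs)
  X
}

#' Predict ages from a fitted forest
#'
#' The forest prediction is the arithmetic mean of the tree predictions, so
#' it always lies within the range of the training ages. Missing feature
#' values are routed through surrogate rules, falling back to the larger
#' child.
#'
#' @param object an [age_forest()].
#' @param newdata a [methylation_cohort()] or a feature matrix with the same
#'   columns the forest was trained on.
#' @param ... unused.
#' @return Numeric vector of predicted ages.
#' @export
predict.age_forest <- function(object, newdata, ...) {
  if (inherits(newdata, "methylation_cohort")) {
    cpgs <- setdiff(object$features, "sex")
    missing_cpgs <- setdiff(cpgs, cpg_names(newdata))
    if (length(missing_cpgs) > 0)
      stop("CpGs not in cohort: ", paste(missing_cpgs, collapse = ", "))
    X <- forest_features(newdata, cpgs)
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object$features))
      stop("newdata must have the same feature layout as the training data")
  }
  rowMeans(.cb_predict_trees(object$trees, X))
}

#' @export
print.age_forest <- function(x, ...) {
  cat(sprintf("age_forest: %d trees, %d features (%s selection)\n",
              x$params$n_trees, length(x$features),
              x$params$predictor_selection))
  cat(sprintf("  trained on %d samples, ages %.2f-%.2f y\n",
              length(x$train_age), min(x$train_age), max(x$train_age)))
  if (!is.null(x$oob_pred)) {
    ok <- !is.na(x$oob_pred)
    cat(sprintf("  out-of-bag MAE: %.3f y\n",
                mean(abs(x$oob_pred[ok] - x$train_age[ok]))))
  }
  invisible(x)
}

#' @export
summary.age_forest <- function(object, ...) {
  out <- list(n_trees = object$params$n_trees,
              n_features = length(object$features),
              n_train = length(object$train_age),
              oob_mae = NA_real_, oob_gap = NA_real_)
  if (!is.null(object$oob_pred)) {
    ok <- !is.na(object$oob_pred)
    out$oob_mae <- mean(abs(object$oob_pred[ok] - object$train_age[ok]))
    out$oob_gap <- mean(object$oob_pred[ok] - object$train_age[ok])
  }
  class(out) <- "summary.age_forest"
  out
}

#' @export
print.summary.age_forest <- function(x, ...) {
  cat(sprintf("age forest: %d trees, %d features, %d training samples\n",
              x$n_trees, x$n_features, x$n_train))
  if (!is.na(x$oob_mae))
    cat(sprintf("  out-of-bag MAE %.3f y, mean age gap %+.3f y\n",
                x$oob_mae, x$oob_gap))
  invisible(x)
}

#' @export
residuals.age_forest <- function(object, ...) {
  if (is.null(object$oob_pred))
    stop("forest was fitted with oob = FALSE; no out-of-bag residuals")
  object$oob_pred - object$train_age
}

#' @export
plot.age_forest <- function(x, ...) {
  if (is.null(x$oob_pred))
    stop("forest was fitted with oob = FALSE; nothing to plot")
  graphics::plot(x$train_age, x$oob_pred,
                 xlab = "chronological age [y]",
                 ylab = "out-of-bag predicted age [y]", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
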