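# Uniform wrappers over the six downstream classifiers. The wrappers
# delegate to established fitting libraries (glmnet, e1071, ranger, xgboost)
# and guarantee a common contract: binary labels, a fixed sorted class
# order, an n x 2 probability matrix on the simplex, and class predictions
# that are always the argmax of the probabilities.

.MODEL_NAMES <- c("LR", "SVM", "RF", "ETC", "GBM", "KNN")

# Tuned defaults; the tuning ranges they were selected from are documented
# in the vignette.
.MODEL_DEFAULTS <- list(
  RF  = list(n_estimators = 200L, max_depth = 200L),
  ETC = list(n_estimators = 200L, max_depth = 200L),
  GBM = list(n_estimators = 200L, max_depth = 200L, learning_rate = 0.8),
  KNN = list(n_neighbors = 5L, weights = "uniform"),
  SVM = list(kernel = "linear", C = 2.0),
  LR  = list(solver = "liblinear", C = 2.0)
)

#' Classifier configuration
#'
#' Builds a configuration for one of the six supported classifiers with its
#' tuned default hyperparameters; any default can be overridden by name.
#'
#' @param name one of `"LR"`, `"SVM"`, `"RF"`, `"ETC"`, `"GBM"`, `"KNN"`.
#' @param ... hyperparameter overrides (e.g. `C = 1.0`, `n_neighbors = 3`).
#' @param seed integer seed controlling every stochastic element of the fit.
#' @return an object of class `model_config`.
#' @examples
#' model_config("SVM")           # kernel = linear, C = 2
#' model_config("KNN", n_neighbors = 3)
#' @export
model_config <- function(name, ..., seed = 0L) {
  if (length(name) != 1L || !name %in% .MODEL_NAMES) {
    abort(paste0("unknown model name: '", paste(name, collapse = ","),
                 "' (supported: ", paste(.MODEL_NAMES, collapse = ", "), ")"))
  }
  hyper <- .MODEL_DEFAULTS[[name]]
  override <- list(...)
  bad <- setdiff(names(override), names(hyper))
  if (length(bad) > 0L) {
    abort(paste0("unknown hyperparameter(s) for ", name, ": ",
                 paste(bad, collapse = ", ")))
  }
  hyper[names(override)] <- override
  .validate_hyper(name, hyper)
  structure(list(name = name, hyperparameters = hyper, seed = as.integer(seed)),
            class = "model_config")
}

.validate_hyper <- function(name, h) {
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid ", name, " hyperparameter: ", msg))
  if (name %in% c("RF", "ETC", "GBM")) {
    chk(h$n_estimators >= 1, "n_estimators must be >= 1")
    chk(h$max_depth >= 1, "max_depth must be >= 1")
  }
  if (name == "GBM") chk(h$learning_rate > 0, "learning_rate must be > 0")
  if (name == "KNN") {
    chk(h$n_neighbors >= 1, "n_neighbors must be >= 1")
    chk(h$weights %in% c("uniform", "distance"), "weights must be uniform or distance")
  }
  if (name %in% c("SVM", "LR")) chk(h$C > 0, "C must be > 0")
  if (name == "SVM") {
    chk(h$kernel %in% c("linear", "poly", "sigmoid", "radial"),
        "kernel must be one of linear, poly, sigmoid, radial")
  }
  if (name == "LR") {
    chk(h$solver %in% c("liblinear", "saga", "sag"),
        "solver must be one of liblinear, saga, sag")
  }
  invisible(TRUE)
}

#' @export
print.model_config <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1L)),
              sep = "=", collapse = ", ")
  cat("<model_config> ", x$name, " (", hp, "; seed=", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Sigmoid function
#'
#' `sig(t) = 1 / (1 + exp(-t))`, the link used by logistic regression and by
#' the Platt-style calibration of the SVM decision values.
#'
#' @param t numeric vector.
#' @return values in (0, 1); `sigmoid(0) == 0.5`.
#' @export
sigmoid <- function(t) 1 / (1 + exp(-t))

#' Shannon entropy of a discrete distribution
#'
#' `-sum(p * log(p))` (natural log), the split criterion used by the
#' entropy-based tree models. Zero terms contribute zero.
#'
#' @param p probability vector summing to 1.
#' @return non-negative entropy; `log(2)` for a uniform two-class split, 0
#'   for a pure node.
#' @export
class_entropy <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Pairwise Euclidean distances
#'
#' `sqrt(sum((x_i - y_i)^2))` between every row of `a` and every row of `b`;
#' the metric used by the KNN wrapper.
#'
#' @param a,b numeric matrices with the same number of columns.
#' @return an `nrow(a)` x `nrow(b)` distance matrix.
#' @export
euclidean_distances <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.binary_labels <- function(labels) {
  y <- factor(labels)
  if (nlevels(y) > 2L) abort("labels must take at most two distinct values")
  y
}

#' Fit a configured classifier
#'
#' Fits the classifier named by `config` on a feature matrix and binary
#' labels. The class order of every downstream probability matrix is the
#' sorted order of the observed label values. A single-class training set
#' yields a constant predictor for that class.
#'
#' @param X a `feature_matrix`, numeric matrix or data frame of numeric
#'   columns (documents x features).
#' @param labels binary label vector aligned with rows.
#' @param config a [model_config()].
#' @return an object of class `fitted_model`.
#' @export
fit_model <- function(X, labels, config) {
  stopifnot(inherits(config, "model_config"))
  y <- .binary_labels(labels)
  Xd <- .as_dense(X)
  stopifnot(nrow(Xd) == length(y))
  elapsed <- system.time({
    fit <- if (nlevels(droplevels(y)) < 2L) {
      list(kind = "constant", class = as.character(droplevels(y)[1L]))
    } else {
      switch(config$name,
        LR = .fit_lr(Xd, y, config),
        SVM = .fit_svm(Xd, y, config),
        RF = .fit_forest(Xd, y, config, extratrees = FALSE),
        ETC = .fit_forest(Xd, y, config, extratrees = TRUE),
        GBM = .fit_gbm(Xd, y, config),
        KNN = list(kind = "knn", x = Xd, y = y)
      )
    }
  })["elapsed"]
  structure(
    list(config = config, fit = fit, class_order = levels(y),
         n_features = ncol(Xd), feature_names = colnames(Xd),
         fit_time = unname(elapsed)),
    class = "fitted_model"
  )
}

.fit_lr <- function(X, y, config) {
  # liblinear-style L2-regularized logistic regression: cost C maps to
  # glmnet's ridge penalty lambda = 1 / (n * C)
  C <- config$hyperparameters$C
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 1 / (nrow(X) * C), standardize = FALSE)
  list(kind = "lr", model = fit)
}

.fit_svm <- function(X, y, config) {
  h <- config$hyperparameters
  kernel <- c(linear = "linear", poly = "polynomial",
              sigmoid = "sigmoid", radial = "radial")[[h$kernel]]
  set.seed(config$seed)
  fit <- e1071::svm(X, y, kernel = kernel, cost = h$C, scale = FALSE)
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1L]
  # Platt-style sigmoid calibration of the decision values, fitted here so
  # that probabilities are fully seed-deterministic
  platt_df <- data.frame(dv = dv, pos = as.integer(y == levels(y)[2L]))
  platt <- suppressWarnings(glm(pos ~ dv, data = platt_df, family = binomial()))
  list(kind = "svm", model = fit, platt = platt)
}

.fit_forest <- function(X, y, config, extratrees) {
  h <- config$hyperparameters
  args <- list(
    x = X, y = y, num.trees = h$n_estimators, max.depth = h$max_depth,
    probability = TRUE, seed = config$seed, num.threads = 1L
  )
  if (extratrees) {
    args$splitrule <- "extratrees"
    args$replace <- FALSE
    args$sample.fraction <- 1
  }
  list(kind = "forest", model = do.call(ranger::ranger, args))
}

.fit_gbm <- function(X, y, config) {
  h <- config$hyperparameters
  set.seed(config$seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  params <- list(objective = "binary:logistic", max_depth = h$max_depth,
                 eta = h$learning_rate, nthread = 1L, seed = config$seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = h$n_estimators, verbose = 0)
  list(kind = "gbm", model = fit)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model> ", x$config$name, " on ", x$n_features,
      " features; classes: ", paste(x$class_order, collapse = " < "), "\n",
      sep = "")
  invisible(x)
}

#' Class probabilities from a fitted model
#'
#' @param object a [fit_model()] result.
#' @param X feature matrix of new documents (same width as at fit time).
#' @return an `n x 2` matrix of probabilities, columns named by the sorted
#'   class order; every row sums to 1.
#' @export
predict_proba <- function(object, X) {
  stopifnot(inherits(object, "fitted_model"))
  Xd <- .as_dense(X)
  if (ncol(Xd) != object$n_features) {
    abort(paste0("feature dimension mismatch: model was fitted on ",
                 object$n_features, " features, got ", ncol(Xd)))
  }
  cls <- object$class_order
  n <- nrow(Xd)
  if (length(cls) == 1L) {  # constant single-class predictor
    return(matrix(1, n, 1L, dimnames = list(rownames(Xd), cls)))
  }
  if (n == 0L) {
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, cls)))
  }
  f <- object$fit
  p2 <- switch(f$kind,
    constant = rep(as.numeric(f$class == cls[2L]), n),
    lr = as.numeric(predict(f$model, Xd, type = "response")),
    svm = {
      dv <- attr(predict(f$model, Xd, decision.values = TRUE),
                 "decision.values")[, 1L]
      as.numeric(predict(f$platt, data.frame(dv = dv), type = "response"))
    },
    forest = {
      pr <- predict(f$model, data = Xd, num.threads = 1L)$predictions
      as.numeric(pr[, cls[2L]])
    },
    gbm = as.numeric(predict(f$model, xgboost::xgb.DMatrix(Xd))),
    knn = .knn_proba(object, Xd)
  )
  out <- cbind(1 - p2, p2)
  dimnames(out) <- list(rownames(Xd), cls)
  out
}

.knn_proba <- function(object, Xd) {
  f <- object$fit
  h <- object$config$hyperparameters
  k <- min(h$n_neighbors, nrow(f$x))
  d <- euclidean_distances(Xd, f$x)
  pos <- f$y == object$class_order[2L]
  vapply(seq_len(nrow(Xd)), function(i) {
    nn <- order(d[i, ])[seq_len(k)]  # distance ties broken by training index
    if (h$weights == "uniform") {
      mean(pos[nn])
    } else {
      di <- d[i, nn]
      if (any(di == 0)) return(mean(pos[nn[di == 0]]))
      w <- 1 / di
      sum(w * pos[nn]) / sum(w)
    }
  }, numeric(1L))
}

#' Predict classes or probabilities
#'
#' Class predictions are always the argmax of [predict_proba()] (first class
#' wins exact ties), so the two are consistent by construction.
#'
#' @param object a `fitted_model`.
#' @param X feature matrix of new documents.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return a character vector of labels, or the probability matrix.
#' @export
predict.fitted_model <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  pr <- predict_proba(object, X)
  if (type == "prob") return(pr)
  if (ncol(pr) == 1L) return(rep(object$class_order, nrow(pr)))
  object$class_order[ifelse(pr[, 2L] > pr[, 1L], 2L, 1L)]
}

#' @method glance fitted_model
#' @export
glance.fitted_model <- function(x, ...) {
  tibble(
    model = x$config$name,
    n_features = x$n_features,
    classes = paste(x$class_order, collapse = "/"),
    seed = x$config$seed,
    fit_time = x$fit_time
  )
}

#' @method tidy model_config
#' @export
tidy.model_config <- function(x, ...) {
  tibble(
    model = x$name,
    hyperparameter = names(x$hyperparameters),
    value = vapply(x$hyperparameters, format, character(1L))
  )
}

#' Grid search over hyperparameters
#'
#' Evaluates every combination in `grid` by stratified cross-validated
#' accuracy and returns the best configuration; exact ties go to the
#' earlier combination in enumeration order (first grid values listed
#' first).
#'
#' @param name model name (see [model_config()]).
#' @param grid named list of hyperparameter value vectors; must be non-empty.
#' @param X feature matrix.
#' @param labels binary labels.
#' @param n_folds folds for cross-validation.
#' @param seed seed for the fold partition and the fits.
#' @return the winning [model_config()], with the CV accuracies of all
#'   combinations attached as attribute `"cv_results"`.
#' @export
grid_search <- function(name, grid, X, labels, n_folds = 5L, seed = 0L) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    abort("grid must be a non-empty named list of value vectors")
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    cfg <- do.call(model_config,
                   c(list(name = name, seed = seed), as.list(combos[i, , drop = FALSE])))
    cross_validate(X, labels, cfg, n_folds = n_folds, seed = seed)$mean
  }, numeric(1L))
  best <- which.max(scores)  # which.max takes the first maximum: tie-break
  out <- do.call(model_config,
                 c(list(name = name, seed = seed), as.list(combos[best, , drop = FALSE])))
  attr(out, "cv_results") <- dplyr::bind_cols(
    as_tibble(combos), tibble(cv_accuracy = scores)
  )
  out
}
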