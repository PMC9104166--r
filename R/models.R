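#' Supported classification algorithms
#'
#' The nine classifiers compared by the evaluation harness: four support
#' vector machines (linear, polynomial, radial-basis and sigmoid kernels),
#' k-nearest neighbours (uniform or inverse-distance weights), logistic
#' regression (ridge-penalised), a decision tree, a random forest and a
#' multilayer perceptron.
#'
#' @format Character vector of length 9, in canonical comparison order.
#' @export
iaq_algorithms <- c("svm_linear", "svm_poly", "svm_rbf", "svm_sigmoid",
                    "knn", "logistic", "decision_tree", "random_forest",
                    "mlp")

#' Create a model specification
#'
#' A model spec pairs an algorithm name with a set of hyperparameters. The
#' regularization factor `C` follows the inverse-regularization convention
#' throughout (larger C = weaker penalty), matching the SVM cost parameter;
#' for logistic regression the ridge penalty is `lambda = 1/(n C)`, and for
#' the MLP `C` is the L2 weight penalty itself (there, *smaller* is weaker,
#' as in common neural-network practice).
#'
#' @param algorithm One of [iaq_algorithms].
#' @param ... Hyperparameters. Recognised names: `C`; `c0`, `c1` (kernel
#'   coefficient and polynomial degree); `k`, `weight` ("uniform" or
#'   "distance"); `D` (max tree depth), `n_s` (min samples to split), `n_r`
#'   (min samples at a leaf), `impurity` ("gini" or "entropy"), `n_f`
#'   (number of trees); `total_neurons`, `ratio` (hidden-layer ratio string
#'   such as "1:8:1"), `activation`, `solver`, `learning_rate`, `max_iter`.
#' @return An object of class `iaq_model_spec`.
#' @examples
#' model_spec("svm_poly", C = 1000, c1 = 3, c0 = 1)
#' @export
model_spec <- function(algorithm, ...) {
  algorithm <- match.arg(algorithm, iaq_algorithms)
  structure(list(algorithm = algorithm, hyperparameters = list(...)),
            class = "iaq_model_spec")
}

#' @export
print.iaq_model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              purrr::map_chr(x$hyperparameters, format), sep = "=",
              collapse = ", ")
  cat("<iaq_model_spec> ", x$algorithm,
      if (nzchar(hp)) paste0(" (", hp, ")"), "\n", sep = "")
  invisible(x)
}

hp <- function(spec, name, default) spec$hyperparameters[[name]] %||% default

parse_ratio <- function(ratio) {
  if (is.character(ratio)) as.integer(strsplit(ratio, ":")[[1]])
  else as.integer(ratio)
}

#' Fit a classifier to normalised features
#'
#' Uniform fit/predict/score adapter over the nine supported algorithms.
#' Features are expected to be min-max scaled to [0,1] on the training data
#' (see [minmax_scale()]); labels must be a two-level factor. Fitting is
#' deterministic given the spec and `seed` (the seed drives random-forest
#' bootstraps and MLP weight initialisation).
#'
#' @param spec An [model_spec()].
#' @param features Data frame or matrix of numeric features.
#' @param labels Two-level factor (first level = satisfactory by package
#'   convention).
#' @param seed Integer seed for stochastic backends.
#' @return An object of class `iaq_model` supporting
#'   [predict()][predict.iaq_model] and [model_accuracy()].
#' @examples
#' d <- generate_offices(n_offices = 120, seed = 3)
#' sc <- minmax_scale(d[iaq_surrogates])
#' m <- fit_classifier(model_spec("decision_tree", D = 5), sc$train, d$label)
#' model_accuracy(m, sc$train, d$label)
#' @export
fit_classifier <- function(spec, features, labels, seed = 1L) {
  stopifnot(inherits(spec, "iaq_model_spec"))
  x <- as.matrix(features)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) {
    stop("degenerate training labels: only one class present", call. = FALSE)
  }
  if (nlevels(labels) != 2L) {
    stop("binary classification only", call. = FALSE)
  }
  lv <- levels(labels)
  alg <- spec$algorithm
  fit <- switch(alg,
    svm_linear = ,
    svm_rbf = ,
    svm_poly = ,
    svm_sigmoid = {
      kernel <- c(svm_linear = "linear", svm_rbf = "radial",
                  svm_poly = "polynomial", svm_sigmoid = "sigmoid")[[alg]]
      e1071::svm(x, labels, kernel = kernel,
                 cost = hp(spec, "C", 1),
                 degree = hp(spec, "c1", 3),
                 coef0 = hp(spec, "c0", 0),
                 scale = FALSE)
    },
    knn = list(x = x, y = labels,
               k = hp(spec, "k", 5),
               weight = hp(spec, "weight", "uniform")),
    logistic = {
      n <- nrow(x)
      glmnet::glmnet(x, labels, family = "binomial", alpha = 0,
                     lambda = 1 / (n * hp(spec, "C", 1)))
    },
    decision_tree = {
      df <- data.frame(x, .label = labels)
      split <- if (identical(hp(spec, "impurity", "gini"), "entropy"))
        "information" else "gini"
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = split),
                   control = rpart::rpart.control(
                     maxdepth = hp(spec, "D", 8),
                     minsplit = hp(spec, "n_s", 3),
                     minbucket = hp(spec, "n_r", 2),
                     cp = 0, xval = 0))
    },
    random_forest = {
      df <- data.frame(x, .label = labels)
      ranger::ranger(.label ~ ., data = df,
                     num.trees = hp(spec, "n_f", 60),
                     max.depth = hp(spec, "D", 0),
                     min.node.size = hp(spec, "n_r", 1),
                     seed = seed, num.threads = 1)
    },
    mlp = {
      hidden <- allocate_neurons(hp(spec, "total_neurons", 100),
                                 parse_ratio(hp(spec, "ratio", "1")))
      mlp_fit(x, as.integer(labels) - 1L, hidden,
              activation = hp(spec, "activation", "relu"),
              solver = hp(spec, "solver", "lbfgs"),
              learning_rate = hp(spec, "learning_rate", "constant"),
              alpha = hp(spec, "C", 1e-4),
              max_iter = hp(spec, "max_iter", 200),
              seed = seed)
    })
  structure(list(spec = spec, fit = fit, levels = lv,
                 features = colnames(features) %||% colnames(x),
                 seed = seed),
            class = "iaq_model")
}

#' @export
print.iaq_model <- function(x, ...) {
  cat("<iaq_model> ", x$spec$algorithm, ", features: ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

knn_predict <- function(fit, x) {
  x <- as.matrix(x)
  tr <- fit$x
  # squared Euclidean distances, vectorised
  d2 <- outer(rowSums(x^2), rowSums(tr^2), `+`) - 2 * x %*% t(tr)
  d2 <- pmax(d2, 0)
  k <- min(fit$k, nrow(tr))
  lv <- levels(fit$y)
  yi <- as.integer(fit$y)
  pred <- apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    w <- if (identical(fit$weight, "distance") ||
             identical(fit$weight, "1/d")) {
      d <- sqrt(row[nn])
      if (any(d == 0)) as.numeric(d == 0) else 1 / d
    } else rep(1, k)
    votes <- c(sum(w[yi[nn] == 1L]), sum(w[yi[nn] == 2L]))
    # tie goes to the second level: the conservative screening outcome
    if (votes[1] > votes[2]) 1L else 2L
  })
  factor(lv[pred], levels = lv)
}

#' Predict class labels from a fitted classifier
#'
#' @param object An `iaq_model`.
#' @param newdata Feature table scaled with the same scaler as the training
#'   features.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.iaq_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  lv <- object$levels
  alg <- object$spec$algorithm
  out <- switch(alg,
    svm_linear = , svm_rbf = , svm_poly = , svm_sigmoid =
      factor(as.character(predict(object$fit, x)), levels = lv),
    knn = knn_predict(object$fit, x),
    logistic = {
      p <- predict(object$fit, newx = x, type = "response")[, 1]
      factor(lv[(p > 0.5) + 1L], levels = lv)
    },
    decision_tree = {
      p <- predict(object$fit, data.frame(x), type = "class")
      factor(as.character(p), levels = lv)
    },
    random_forest = {
      # ties in the trees' vote are broken randomly: seed the predict too
      p <- predict(object$fit, data = data.frame(x),
                   num.threads = 1, seed = object$seed)$predictions
      factor(as.character(p), levels = lv)
    },
    mlp = {
      p <- mlp_predict_prob(object$fit, x)
      factor(lv[(p > 0.5) + 1L], levels = lv)
    })
  out
}

#' Fraction of correct predictions
#'
#' @param model An `iaq_model`.
#' @param features Scaled feature table.
#' @param labels True labels.
#' @return Accuracy in [0, 1].
#' @export
model_accuracy <- function(model, features, labels) {
  mean(as.character(predict(model, features)) == as.character(labels))
}

#' @exportS3Method generics::tidy
tidy.iaq_model <- function(x, ...) {
  hps <- x$spec$hyperparameters
  if (length(hps) == 0L) {
    return(tibble::tibble(algorithm = x$spec$algorithm,
                          hyperparameter = character(),
                          value = character()))
  }
  tibble::tibble(algorithm = x$spec$algorithm,
                 hyperparameter = names(hps),
                 value = purrr::map_chr(hps, function(v) paste(v, collapse = ":")))
}
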