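# Supervised benign-vs-malignant pixel classification: SVMs (linear, RBF,
# sigmoid kernels), random forest, and a small feed-forward neural network.
# Every model exposes a malignant score in [0, 1]: SVM decision values are
# passed through a logistic (Platt-style) calibration fitted on the
# training data, the forest reports its vote fraction, and the network its
# softmax output.

.classifiers <- c("svm_linear", "svm_rbf", "svm_sigmoid", "rf", "ann")

#' Classifier hyperparameter set
#'
#' Only the fields relevant to `classifier` are read at training time.
#' `gamma` and `slope` default to `1 / n_features` (resolved when the
#' feature count is known, i.e. at training).
#'
#' @param classifier One of `"svm_linear"`, `"svm_rbf"`, `"svm_sigmoid"`,
#'   `"rf"`, `"ann"`.
#' @param C SVM cost (> 0).
#' @param gamma RBF kernel width (> 0); `NULL` means `1 / n_features`.
#' @param slope,intercept Sigmoid kernel slope and intercept constant;
#'   `slope = NULL` means `1 / n_features`.
#' @param n_trees Number of random-forest trees.
#' @param neurons Integer vector of the four hidden-layer widths of the
#'   neural network.
#' @return A list of class `hyperparameter_set`.
#' @export
hyperparameter_set <- function(classifier, C = 1, gamma = NULL,
                               slope = NULL, intercept = 0,
                               n_trees = 500L, neurons = c(1L, 1L, 1L, 1L)) {
  classifier <- match.arg(classifier, .classifiers)
  if (C <= 0) stop_contract("C must be positive")
  if (!is.null(gamma) && gamma <= 0) stop_contract("gamma must be positive")
  if (length(neurons) != 4L || any(neurons < 1L))
    stop_contract("neurons must be 4 positive integers")
  structure(list(classifier = classifier, C = C, gamma = gamma,
                 slope = slope, intercept = intercept,
                 n_trees = as.integer(n_trees),
                 neurons = as.integer(round(neurons))),
            class = "hyperparameter_set")
}

#' @export
print.hyperparameter_set <- function(x, ...) {
  cat("<hyperparameter_set>", x$classifier, "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

lesion_xy <- function(set) {
  idx <- set$class %in% .lesion_classes
  list(x = set$spectra[idx, , drop = FALSE],
       y = factor(set$class[idx], levels = .lesion_classes))
}

#' Train a benign-vs-malignant pixel classifier
#'
#' @param train A [labeled_spectra()] containing both lesion classes (any
#'   `skin` rows are ignored).
#' @param hp A [hyperparameter_set()].
#' @param seed Integer seed; training is reproducible given (data, hp,
#'   seed).
#' @return An object of class `hsderm_model`.
#' @export
train_classifier <- function(train, hp, seed = 1L) {
  stopifnot(inherits(train, "labeled_spectra"),
            inherits(hp, "hyperparameter_set"))
  d <- lesion_xy(train)
  if (length(unique(d$y)) < 2L)
    stop_contract("training set must contain both lesion classes")
  x <- d$x; y <- d$y
  nf <- ncol(x)
  gamma <- if (is.null(hp$gamma)) 1 / nf else hp$gamma
  slope <- if (is.null(hp$slope)) 1 / nf else hp$slope
  fit <- with_seed(seed, switch(hp$classifier,
    svm_linear = ,
    svm_rbf = {
      kernel <- if (hp$classifier == "svm_linear") "linear" else "radial"
      m <- e1071::svm(x, y, kernel = kernel, cost = hp$C, gamma = gamma,
                      scale = FALSE)
      dec <- attr(stats::predict(m, x, decision.values = TRUE),
                  "decision.values")[, 1L]
      # Platt-style logistic calibration of the decision values
      cal <- suppressWarnings(
        stats::glm((y == "malignant") ~ dec, family = stats::binomial()))
      list(svm = m, platt = stats::coef(cal))
    },
    svm_sigmoid = {
      # sigmoid kernel tanh(slope * <u, v> + intercept); the slope may be
      # negative, which kernlab's tanhdot permits
      m <- kernlab::ksvm(x, y, kernel = kernlab::tanhdot(
        scale = slope, offset = hp$intercept), C = hp$C, scaled = FALSE)
      dec <- as.numeric(kernlab::predict(m, x, type = "decision")[, 1L])
      cal <- suppressWarnings(
        stats::glm((y == "malignant") ~ dec, family = stats::binomial()))
      list(svm = m, platt = stats::coef(cal))
    },
    rf = randomForest::randomForest(x, y, ntree = hp$n_trees),
    ann = mlp_train(x, y, hidden = hp$neurons, epochs = 200L)
  ))
  structure(list(classifier = hp$classifier, hp = hp, fit = fit,
                 n_features = nf, classes = .lesion_classes,
                 seed = as.integer(seed)),
            class = "hsderm_model")
}

#' @export
print.hsderm_model <- function(x, ...) {
  cat(sprintf("<hsderm_model> %s, %d features, classes %s\n", x$classifier,
              x$n_features, paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict lesion class and malignant score for pixel spectra
#'
#' @param object A trained `hsderm_model`.
#' @param spectra Numeric matrix of spectra (columns must match the
#'   training feature count).
#' @param ... Unused.
#' @return A data.frame with columns `label` (`"benign"`/`"malignant"`) and
#'   `score` (malignant probability in [0, 1]); `label` is `"malignant"`
#'   when `score > 0.5`.
#' @export
predict.hsderm_model <- function(object, spectra, ...) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) == 0L)
    return(data.frame(label = character(0), score = numeric(0)))
  if (ncol(spectra) != object$n_features)
    stop_contract("expected ", object$n_features, " features, got ",
                  ncol(spectra))
  score <- switch(object$classifier,
    svm_linear = ,
    svm_rbf = {
      dec <- attr(stats::predict(object$fit$svm, spectra,
                                 decision.values = TRUE),
                  "decision.values")[, 1L]
      b <- object$fit$platt
      as.vector(stats::plogis(b[1L] + b[2L] * dec))
    },
    svm_sigmoid = {
      dec <- as.numeric(kernlab::predict(object$fit$svm, spectra,
                                         type = "decision")[, 1L])
      b <- object$fit$platt
      as.vector(stats::plogis(b[1L] + b[2L] * dec))
    },
    rf = stats::predict(object$fit, spectra, type = "prob")[, "malignant"],
    ann = mlp_predict(object$fit, spectra)
  )
  score <- pmin(1, pmax(0, as.numeric(score)))
  data.frame(label = ifelse(score > 0.5, "malignant", "benign"),
             score = score, stringsAsFactors = FALSE)
}
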