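#' Train the N/O glycosylation-type classifier
#'
#' Binary (two-class multinomial) logistic regression of glycosylation
#' type on the 9 normalized oxonium intensity ratios, fit by maximum
#' likelihood. The O-linked class is modeled as the positive class. When
#' the classes are perfectly (or quasi-) separated — common on clean
#' training sets, where the MLE diverges — the fit falls back to a
#' lightly ridge-penalized IRLS (L2 strength `ridge`, intercept
#' unpenalized) with a warning.
#'
#' @param features data.frame or matrix containing the 9 ratio columns
#'   `r138` ... `r366` (extra columns such as `scan_id`/`i204` are
#'   ignored), one row per spectrum.
#' @param labels vector of class labels, `"N"` or `"O"`.
#' @param seed integer recorded in the model metadata (the fit itself is
#'   deterministic given the input order).
#' @param ridge L2 penalty used only on separation/non-convergence.
#' @return object of class `glyco_logit`: weights (named length-9),
#'   intercept, `feature_order`, `positive_class = "O"`, coefficient
#'   covariance and training metadata.
#' @export
train_classifier <- function(features, labels, seed = NULL, ridge = 1e-4) {
  x <- .feature_matrix(features)
  labels <- as.character(labels)
  .assert(length(labels) == nrow(x), "features and labels differ in length")
  .assert(all(labels %in% c("N", "O")), "labels must be \"N\" or \"O\"")
  .assert(all(is.finite(x)), "features must be finite")
  counts <- table(factor(labels, levels = c("N", "O")))
  if (any(counts < 2L)) {
    stop("need at least 2 examples of each class (N and O)", call. = FALSE)
  }
  y <- as.numeric(labels == "O")
  xd <- cbind(`(Intercept)` = 1, x)

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(xd, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 500L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated || !fit$converged) {
    warning("separation or non-convergence detected; refitting with ridge ",
            "penalty lambda = ", format(ridge))
    beta <- .ridge_logit(xd, y, lambda = ridge)
    penalized <- TRUE
  } else {
    beta <- fit$coefficients
    penalized <- FALSE
  }
  structure(
    list(
      weights = beta[-1L],
      intercept = unname(beta[1L]),
      feature_order = .FEATURE_NAMES,
      positive_class = "O",
      penalized = penalized,
      ridge = if (penalized) ridge else 0,
      vcov = .logit_vcov(xd, beta, if (penalized) ridge else 0),
      training_meta = list(
        n_n = unname(counts[["N"]]), n_o = unname(counts[["O"]]),
        seed = seed
      )
    ),
    class = "glyco_logit"
  )
}

# pull the 9 ratio columns in canonical order, as a numeric matrix
.feature_matrix <- function(features) {
  if (inherits(features, "oxonium_features")) {
    features <- as.data.frame(as.list(features$ratios))
  }
  if (is.numeric(features) && is.null(dim(features))) {
    features <- as.data.frame(as.list(features))
  }
  features <- as.data.frame(features)
  missing <- setdiff(.FEATURE_NAMES, names(features))
  if (length(missing) > 0) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(features[, .FEATURE_NAMES, drop = FALSE])
}

# ridge-penalized logistic IRLS; lambda is not applied to the intercept
.ridge_logit <- function(xd, y, lambda, max_iter = 500L, tol = 1e-8) {
  p <- ncol(xd)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(xd, y - mu)) - 2 * lambda * c(0, beta[-1L])
    info <- crossprod(xd, xd * w) + 2 * pen
    step <- solve(info, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(xd))
}

.logit_vcov <- function(xd, beta, lambda = 0) {
  mu <- stats::plogis(drop(xd %*% beta))
  w <- mu * (1 - mu)
  info <- crossprod(xd, xd * w)
  if (lambda > 0) info <- info + 2 * diag(c(0, rep(lambda, ncol(xd) - 1L)))
  out <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(out)) dimnames(out) <- list(colnames(xd), colnames(xd))
  out
}

#' @export
print.glyco_logit <- function(x, ...) {
  cat(sprintf(
    "<glyco_logit> 9-feature N/O logistic model (trained on %d N / %d O%s)\n",
    x$training_meta$n_n, x$training_meta$n_o,
    if (x$penalized) ", ridge-stabilized" else ""
  ))
  invisible(x)
}

#' Predict glycosylation type from oxonium features
#'
#' Applies a fitted model: a spectrum is called O-linked when the modeled
#' probability of the O class is at least 0.5 (ties go to O), N-linked
#' otherwise. Alongside the call, the probability of the assigned class
#' (`max(p, 1 - p)`) is reported.
#'
#' @param object a `glyco_logit` model.
#' @param features an `oxonium_features` object, a named numeric vector,
#'   or a data.frame with the ratio columns (one row per spectrum).
#' @param ... unused.
#' @return data.frame with columns `call` (`"N"`/`"O"`), `probability`
#'   (of the assigned class) and `p_o` (probability of O).
#' @export
predict.glyco_logit <- function(object, features, ...) {
  x <- .feature_matrix(features)
  x <- x[, object$feature_order, drop = FALSE]
  p_o <- stats::plogis(drop(x %*% object$weights) + object$intercept)
  call <- ifelse(p_o >= 0.5, "O", "N")
  data.frame(call = call, probability = pmax(p_o, 1 - p_o), p_o = p_o,
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Splits each class evenly across `k_folds` folds (reproducibly from
#' `seed`), trains on k-1 folds and pools the out-of-fold predictions
#' into an overall accuracy plus per-class true rates. Per-feature Wald
#' p-values come from the full-data fit.
#'
#' @param features,labels as in [train_classifier()].
#' @param k_folds number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return object of class `classifier_report`: `overall_accuracy`,
#'   `true_n_rate`, `true_o_rate`, `confusion` (2x2 table),
#'   `per_feature_p_values`, `k_folds`, `seed`, `scheme`.
#' @export
cross_validate <- function(features, labels, k_folds = 10L, seed = 1L) {
  .assert(k_folds >= 2L, "k_folds must be >= 2")
  x <- .feature_matrix(features)
  labels <- as.character(labels)
  n <- nrow(x)
  .assert(length(labels) == n, "features and labels differ in length")
  if (min(table(labels)) < k_folds) {
    stop("each class needs at least k_folds members for stratified folds",
         call. = FALSE)
  }
  fold <- integer(n)
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  pred <- character(n)
  for (k in seq_len(k_folds)) {
    test <- fold == k
    model <- suppressWarnings(
      train_classifier(x[!test, , drop = FALSE], labels[!test], seed = seed)
    )
    pred[test] <- predict(model, x[test, , drop = FALSE])$call
  }
  confusion <- table(truth = factor(labels, c("N", "O")),
                     call = factor(pred, c("N", "O")))
  full <- suppressWarnings(train_classifier(x, labels, seed = seed))
  structure(
    list(
      overall_accuracy = sum(diag(confusion)) / n,
      true_n_rate = confusion["N", "N"] / sum(confusion["N", ]),
      true_o_rate = confusion["O", "O"] / sum(confusion["O", ]),
      confusion = confusion,
      per_feature_p_values = feature_significance(full, x, labels),
      k_folds = k_folds,
      seed = seed,
      scheme = "stratified k-fold, pooled out-of-fold predictions"
    ),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    paste0("<classifier_report> %d-fold CV: overall accuracy %.1f%%, ",
           "true N rate %.1f%%, true O rate %.1f%%\n"),
    x$k_folds, 100 * x$overall_accuracy, 100 * x$true_n_rate,
    100 * x$true_o_rate
  ))
  invisible(x)
}

#' Wald significance of each oxonium feature
#'
#' Per-coefficient Wald tests (z = beta / SE, SE from the inverse
#' observed information at the fitted coefficients) of the model applied
#' to its training data.
#'
#' @param model a `glyco_logit` model.
#' @param features,labels the training data the model was fit on.
#' @return named numeric vector of p-values, one per ratio feature
#'   (`NA` with a warning when the information matrix is singular).
#' @export
feature_significance <- function(model, features, labels) {
  x <- .feature_matrix(features)
  xd <- cbind(`(Intercept)` = 1, x[, model$feature_order, drop = FALSE])
  beta <- c(model$intercept, model$weights)
  v <- .logit_vcov(xd, beta, model$ridge)
  if (is.null(v)) {
    warning("singular information matrix; p-values unavailable")
    return(stats::setNames(rep(NA_real_, length(model$feature_order)),
                           model$feature_order))
  }
  se <- sqrt(diag(v))[-1L]
  z <- model$weights / se
  stats::setNames(2 * stats::pnorm(-abs(z)), model$feature_order)
}

#' Save / load a fitted classifier as JSON
#'
#' The JSON schema stores the feature order, weights (full precision),
#' intercept and training metadata; loading validates the schema and
#' reproduces predictions exactly.
#'
#' @param model a `glyco_logit` model.
#' @param path JSON file path.
#' @return `save_model()` returns `path` invisibly; `load_model()`
#'   returns the restored `glyco_logit`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    schema_version = 1L,
    feature_order = model$feature_order,
    weights = as.list(model$weights),
    intercept = model$intercept,
    positive_class = model$positive_class,
    penalized = model$penalized,
    ridge = model$ridge,
    training_meta = model$training_meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot parse model file: ", conditionMessage(e),
                             call. = FALSE)
                      })
  required <- c("schema_version", "feature_order", "weights", "intercept")
  if (!all(required %in% names(payload))) {
    stop("model file missing field(s): ",
         paste(setdiff(required, names(payload)), collapse = ", "),
         call. = FALSE)
  }
  weights <- unlist(payload$weights)
  if (!setequal(names(weights), .FEATURE_NAMES)) {
    stop("model file weights do not cover the 9 oxonium features",
         call. = FALSE)
  }
  feature_order <- unlist(payload$feature_order)
  model <- structure(
    list(
      weights = weights[feature_order],
      intercept = payload$intercept,
      feature_order = feature_order,
      positive_class = payload$positive_class %||% "O",
      penalized = isTRUE(payload$penalized),
      ridge = payload$ridge %||% 0,
      vcov = NULL,
      training_meta = payload$training_meta
    ),
    class = "glyco_logit"
  )
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
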