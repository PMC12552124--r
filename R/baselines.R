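# Biophysical logistic-regression baselines: loop length, solvent exposure
# (residue count within 10 A of the loop) and their combination.

#' Fit a biophysical baseline classifier
#'
#' Maximum-likelihood logistic regression (via `stats::glm`, IRLS) of the
#' flexible/rigid label on loop length, solvent exposure, or both. On
#' perfectly separable data a tiny ridge penalty (`epsilon = 1e-6`) is
#' applied to keep the coefficients finite, and the returned object carries
#' `separable = TRUE`.
#'
#' @param features data.frame (or matrix) with columns `length` and/or
#'   `exposure`.
#' @param labels Binary 0/1 labels.
#' @param kind `"length"`, `"exposure"` or `"length+exposure"`.
#' @return Object of class `flex_baseline` with `kind`, `coefficients`
#'   (intercept first) and `separable`.
#' @export
fit_logistic <- function(features, labels,
                         kind = c("length", "exposure", "length+exposure")) {
  kind <- match.arg(kind)
  labels <- as.numeric(labels)
  check_two_classes(labels)
  cols <- strsplit(kind, "+", fixed = TRUE)[[1]]
  features <- as.data.frame(features)
  miss <- setdiff(cols, names(features))
  if (length(miss) > 0L) stop("features missing column(s): ",
                              paste(miss, collapse = ", "))
  dat <- features[, cols, drop = FALSE]
  dat$.y <- labels
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  # perfect separation drives every fitted probability to its label
  separable <- !fit$converged ||
    all(abs(stats::fitted(fit) - labels) < 1e-4)
  if (separable) {
    # ridge-stabilised IRLS: penalised logistic fit with epsilon = 1e-6
    X <- cbind(1, as.matrix(dat[, cols, drop = FALSE]))
    beta <- ridge_logistic(X, labels, lambda = 1e-6)
    coefs <- stats::setNames(as.numeric(beta), c("(Intercept)", cols))
    warning("perfectly separable data: coefficients capped by regularisation")
  } else {
    coefs <- stats::coef(fit)
  }
  structure(list(kind = kind, coefficients = coefs, separable = separable),
            class = "flex_baseline")
}

ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 200L,
                           tol = 1e-8) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    g <- crossprod(X, y - p) - lambda * beta
    Hm <- crossprod(X * W, X) + diag(lambda, ncol(X))
    step <- solve(Hm, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' @export
print.flex_baseline <- function(x, ...) {
  cat("Logistic baseline (", x$kind, ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.flex_baseline <- function(object, ...) object$coefficients

#' Predict from a biophysical baseline
#'
#' @param object A `flex_baseline`.
#' @param newdata data.frame with the feature column(s) used by the model.
#' @param type `"score"` (probability) or `"class"`.
#' @param threshold Classification threshold.
#' @param ... Unused.
#' @return Numeric scores or integer classes.
#' @export
predict.flex_baseline <- function(object, newdata,
                                  type = c("score", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  cols <- names(object$coefficients)[-1]
  X <- cbind(1, as.matrix(as.data.frame(newdata)[, cols, drop = FALSE]))
  p <- stats::plogis(as.numeric(X %*% object$coefficients))
  if (type == "score") p else as.integer(p >= threshold)
}
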