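#' Regularized linear discriminant analysis
#'
#' Two-class Gaussian discriminant with a single covariance matrix
#' shared by both classes (the equal-covariance assumption of LDA),
#' regularized by shrinkage toward a scaled identity:
#' `Sigma_reg = (1 - lambda) * Sigma_pooled + lambda * vbar * I`,
#' where `vbar` is the mean pooled variance. Shrinkage keeps the
#' covariance well conditioned when features are many or collinear and
#' limits over-fitting. Features are z-scored with training-set
#' statistics stored in the model, so validation data never leak into
#' the standardization.
#'
#' @param x Numeric feature matrix (rows = boluses/segments).
#' @param y Binary labels (0 = unimpaired, 1 = impaired); at least two
#'   examples of each class.
#' @param lambda Shrinkage coefficient in \[0, 1\], or `NULL` for
#'   analytic selection via [select_shrinkage()].
#' @param priors Class priors: `"frequency"` (training frequencies),
#'   `"equal"`, or a numeric vector `c(p0, p1)` summing to 1.
#' @param standardize Z-score columns with training statistics.
#' @return An object of class `sws_rlda`.
#' @export
fit_rlda <- function(x, y, lambda = NULL, priors = "frequency",
                     standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop_data("labels must be binary 0/1 without missing values")
  }
  if (!all(is.finite(x))) stop_data("features must be finite")
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 < 2L || n1 < 2L) {
    stop_data("need at least two training examples per class")
  }
  if (!is.null(lambda) && (lambda < 0 || lambda > 1)) {
    stop_config("shrinkage lambda must lie in [0, 1]")
  }
  center <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scale_ <- if (standardize) {
    s <- apply(x, 2, stats::sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  mu0 <- colMeans(xs[y == 0L, , drop = FALSE])
  mu1 <- colMeans(xs[y == 1L, , drop = FALSE])
  xc <- xs
  xc[y == 0L, ] <- sweep(xs[y == 0L, , drop = FALSE], 2, mu0)
  xc[y == 1L, ] <- sweep(xs[y == 1L, , drop = FALSE], 2, mu1)
  n <- nrow(xs)
  sigma <- crossprod(xc) / (n - 2)
  if (is.null(lambda)) lambda <- lw_shrinkage(xc)
  vbar <- mean(diag(sigma))
  sigma_reg <- (1 - lambda) * sigma + diag(lambda * vbar, ncol(xs))

  pr <- if (is.numeric(priors)) {
    if (length(priors) != 2 || abs(sum(priors) - 1) > 1e-8) {
      stop_config("numeric priors must be length 2 and sum to 1")
    }
    priors
  } else if (identical(priors, "equal")) {
    c(0.5, 0.5)
  } else {
    c(n0, n1) / n
  }

  ch <- tryCatch(chol(sigma_reg), error = function(e) NULL)
  if (is.null(ch)) {
    stop_data("regularized covariance is not positive definite")
  }
  structure(list(means = rbind(unimpaired = mu0, impaired = mu1),
                 sigma_reg = sigma_reg, chol = ch, lambda = lambda,
                 priors = stats::setNames(pr, c("unimpaired", "impaired")),
                 center = center, scale = scale_,
                 feature_names = colnames(x), n = c(n0 = n0, n1 = n1)),
            class = "sws_rlda")
}

# Ledoit-Wolf analytic shrinkage toward the scaled identity, computed
# on within-class centered rows
lw_shrinkage <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  m <- mean(diag(s))
  d2 <- sum((s - diag(m, p))^2) / p
  if (d2 <= .Machine$double.eps) return(1)
  b2bar <- 0
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    b2bar <- b2bar + sum((tcrossprod(xi) - s)^2)
  }
  b2bar <- b2bar / (n^2 * p)
  lam <- min(b2bar, d2) / d2
  min(max(lam, 0), 1)
}

#' Analytic shrinkage selection
#'
#' Ledoit-Wolf-type estimator of the optimal blend between the pooled
#' sample covariance and its scaled-identity target, computed from the
#' variance of the sample covariance entries on within-class centered
#' data. Approaches 0 when observations vastly outnumber features and
#' stays bounded away from 0 when `p > n`, guaranteeing invertibility.
#' Fully deterministic given the data.
#'
#' @inheritParams fit_rlda
#' @return Shrinkage coefficient in \[0, 1\].
#' @export
select_shrinkage <- function(x, y) {
  x <- as.matrix(x); y <- as.integer(y)
  for (cls in c(0L, 1L)) {
    idx <- y == cls
    x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                      colMeans(x[idx, , drop = FALSE]))
  }
  lw_shrinkage(x)
}

#' Posterior probability of impairment
#'
#' Gaussian class posteriors under the shared regularized covariance:
#' monotone in the linear discriminant score and normalized so the two
#' class probabilities sum to one.
#'
#' @param model An `sws_rlda` fit.
#' @param x Feature matrix with the training feature dimension.
#' @return Numeric vector of `P(impaired)` in (0, 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "sws_rlda"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(model$means)) {
    stop_data(sprintf("feature dimension %d does not match model (%d)",
                      ncol(x), ncol(model$means)))
  }
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  inv <- chol2inv(model$chol)
  w <- inv %*% t(model$means)          # p x 2
  const <- -0.5 * colSums(t(model$means) * w) + log(model$priors)
  scores <- xs %*% w + matrix(const, nrow(xs), 2, byrow = TRUE)
  1 / (1 + exp(scores[, 1] - scores[, 2]))
}

#' @export
predict.sws_rlda <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
print.sws_rlda <- function(x, ...) {
  cat(sprintf(paste0("<sws_rlda> %d features, lambda = %.4f, priors = ",
                     "%.3f/%.3f, n = %d/%d\n"),
              ncol(x$means), x$lambda, x$priors[1], x$priors[2],
              x$n["n1"], x$n["n0"]))
  invisible(x)
}

#' Serialize / restore a fitted discriminant
#'
#' Writes the model (means, regularized covariance, shrinkage, priors,
#' standardization and feature names) to a JSON container.
#'
#' @param model An `sws_rlda`.
#' @param path File path.
#' @return `write_rlda` returns `path` invisibly; `read_rlda` the
#'   restored model.
#' @export
write_rlda <- function(model, path) {
  stopifnot(inherits(model, "sws_rlda"))
  obj <- list(means = unclass(model$means), sigma_reg = model$sigma_reg,
              lambda = model$lambda, priors = as.numeric(model$priors),
              center = model$center, scale = model$scale,
              feature_names = model$feature_names,
              n = as.integer(model$n))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rlda
#' @export
read_rlda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nrow_) {
    if (is.matrix(m)) m else matrix(unlist(m), nrow = nrow_, byrow = TRUE)
  }
  sigma <- as_mat(obj$sigma_reg, length(obj$center))
  means <- as_mat(obj$means, 2)
  dimnames(means) <- list(c("unimpaired", "impaired"), NULL)
  dimnames(sigma) <- NULL
  structure(list(means = means, sigma_reg = sigma, chol = chol(sigma),
                 lambda = obj$lambda,
                 priors = stats::setNames(obj$priors,
                                          c("unimpaired", "impaired")),
                 center = obj$center, scale = obj$scale,
                 feature_names = obj$feature_names,
                 n = stats::setNames(obj$n, c("n0", "n1"))),
            class = "sws_rlda")
}
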