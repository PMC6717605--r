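# brute-force Gaussian posterior with explicit densities and the
# model's shared covariance: the independent oracle for predict_proba
oracle_posterior <- function(model, x) {
  xs <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  Sinv <- solve(model$sigma_reg)
  dens <- function(r, mu) {
    exp(-0.5 * drop(t(r - mu) %*% Sinv %*% (r - mu)))
  }
  apply(xs, 1, function(r) {
    d0 <- dens(r, model$means[1, ]) * model$priors[1]
    d1 <- dens(r, model$means[2, ]) * model$priors[2]
    unname(d1 / (d0 + d1))
  })
}

gaussian_clouds <- function(n = 200, p = 6, shift = 5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * p), ncol = p),
             matrix(rnorm(n / 2 * p, mean = shift), ncol = p))
  colnames(x) <- paste0("f", 1:p)
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

test_that("well-separated clouds give near-perfect training AUC", {
  d <- gaussian_clouds(shift = 5)
  m <- fit_rlda(d$x, d$y)
  expect_gte(roc_auc(predict_proba(m, d$x), d$y), 0.99)
})

test_that("permuted labels give chance-level training AUC", {
  d <- gaussian_clouds(shift = 5)
  set.seed(2)
  yperm <- sample(d$y)
  m <- fit_rlda(d$x, yperm)
  auc <- roc_auc(predict_proba(m, d$x), yperm)
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("posteriors equal the brute-force Gaussian oracle", {
  set.seed(3)
  for (rep in 1:5) {
    p <- sample(2:8, 1)
    d <- gaussian_clouds(n = 60, p = p, shift = runif(1, 0, 3), seed = rep)
    lam <- runif(1)
    m <- fit_rlda(d$x, d$y, lambda = lam)
    xnew <- matrix(rnorm(20 * p, sd = 2), ncol = p)
    expect_lt(max(abs(predict_proba(m, xnew) - oracle_posterior(m, xnew))),
              1e-8)
  }
})

test_that("lambda = 1 reduces to the scaled-identity discriminant", {
  d <- gaussian_clouds(n = 100, p = 4, shift = 2, seed = 4)
  m <- fit_rlda(d$x, d$y, lambda = 1)
  # independent diagonal-covariance implementation
  xs <- sweep(sweep(d$x, 2, m$center), 2, m$scale, "/")
  vbar <- mean(diag(crossprod(
    rbind(sweep(xs[d$y == 0L, ], 2, colMeans(xs[d$y == 0L, ])),
          sweep(xs[d$y == 1L, ], 2, colMeans(xs[d$y == 1L, ])))) /
      (nrow(xs) - 2)))
  diag_post <- function(r) {
    d0 <- exp(-0.5 * sum((r - m$means[1, ])^2) / vbar) * m$priors[1]
    d1 <- exp(-0.5 * sum((r - m$means[2, ])^2) / vbar) * m$priors[2]
    d1 / (d0 + d1)
  }
  want <- apply(xs, 1, diag_post)
  expect_equal(unname(predict_proba(m, d$x)), unname(want),
               tolerance = 1e-10)
})

test_that("symmetry and extremes of the posterior", {
  d <- gaussian_clouds(n = 200, p = 3, shift = 3, seed = 5)
  m <- fit_rlda(d$x, d$y, priors = "equal")
  mid <- (m$means[1, ] + m$means[2, ]) / 2 * m$scale + m$center
  expect_equal(unname(predict_proba(m, matrix(mid, 1))), 0.5,
               tolerance = 1e-10)
  far <- (m$means[2, ] * 5) * m$scale + m$center
  expect_gt(predict_proba(m, matrix(far, 1)), 0.99)
  # probabilities of the two classes sum to one by construction:
  # P(unimpaired) = 1 - P(impaired); check the logistic form is in (0,1)
  pr <- predict_proba(m, matrix(rnorm(300), ncol = 3))
  expect_true(all(pr > 0 & pr < 1))
})

test_that("posterior is monotone in the discriminant score", {
  d <- gaussian_clouds(n = 100, p = 4, shift = 2, seed = 6)
  m <- fit_rlda(d$x, d$y)
  Sinv <- chol2inv(m$chol)
  w <- drop(Sinv %*% (m$means[2, ] - m$means[1, ]))
  xs <- sweep(sweep(d$x, 2, m$center), 2, m$scale, "/")
  score <- drop(xs %*% w)
  p <- predict_proba(m, d$x)
  expect_true(all(diff(p[order(score)]) >= -1e-12))
})

test_that("fit is invariant to a consistent feature permutation", {
  d <- gaussian_clouds(n = 80, p = 5, shift = 1.5, seed = 7)
  m1 <- fit_rlda(d$x, d$y, lambda = 0.3)
  perm <- c(3, 1, 5, 2, 4)
  m2 <- fit_rlda(d$x[, perm], d$y, lambda = 0.3)
  xnew <- matrix(rnorm(50), ncol = 5)
  expect_equal(predict_proba(m1, xnew), predict_proba(m2, xnew[, perm]),
               tolerance = 1e-12)
})

test_that("analytic shrinkage behaves across data regimes", {
  set.seed(8)
  # n >> p with a markedly non-spherical covariance: lambda near 0
  x <- matrix(rnorm(5000 * 10), ncol = 10) %*% diag(sqrt(1:10))
  y <- rep(c(0L, 1L), 2500)
  expect_lt(select_shrinkage(x, y), 0.05)
  # p > n: lambda bounded away from 0 and covariance invertible
  x2 <- matrix(rnorm(30 * 50), ncol = 50)
  y2 <- rep(c(0L, 1L), 15)
  lam <- select_shrinkage(x2, y2)
  expect_gt(lam, 0.1)
  m <- fit_rlda(x2, y2)
  expect_true(all(is.finite(chol2inv(m$chol))))
  # constant feature column: still invertible after regularization
  x3 <- cbind(gaussian_clouds(n = 40, p = 3, seed = 9)$x, const = 1)
  m3 <- fit_rlda(x3, rep(c(0L, 1L), each = 20))
  expect_true(all(is.finite(predict_proba(m3, x3))))
})

test_that("fit and predict reject invalid inputs", {
  d <- gaussian_clouds(n = 40, p = 3, seed = 10)
  expect_error(fit_rlda(d$x, rep(0L, 40)), class = "sws_data_error")
  expect_error(fit_rlda(d$x, d$y, lambda = 2), class = "sws_config_error")
  m <- fit_rlda(d$x, d$y)
  expect_error(predict_proba(m, matrix(0, 2, 5)), class = "sws_data_error")
})

test_that("model serialization round-trips predictions exactly", {
  d <- gaussian_clouds(n = 60, p = 4, shift = 2, seed = 11)
  m <- fit_rlda(d$x, d$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_rlda(m, path)
  m2 <- read_rlda(path)
  expect_equal(predict_proba(m2, d$x), predict_proba(m, d$x),
               tolerance = 1e-12)
  expect_equal(m2$lambda, m$lambda)
})
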