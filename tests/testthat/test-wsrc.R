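# Weighted sparse representation classifier: model building, Gaussian
# weights, the constrained L1 solver and the residual decision rule.

test_that("model building normalizes columns and validates inputs", {
  withr::with_seed(61, X <- matrix(rnorm(4 * 6), 4, 6))
  m <- wsrc_fit(X, c(1, 1, 0, 0))
  expect_equal(ncol(m$dictionary), 4L)
  expect_equal(colSums(m$dictionary^2), rep(1, 4), tolerance = 1e-12)
  expect_equal(m$classes, c(0, 1))
  expect_gt(m$sigma, 0)

  Xz <- X; Xz[2, ] <- 0
  expect_error(wsrc_fit(Xz, c(1, 1, 0, 0)), "zero-norm")
  expect_error(wsrc_fit(X, rep(1, 4)), "single class")
  expect_error(wsrc_fit(X[1, , drop = FALSE], 1), "2 training samples")
})

test_that("Gaussian weights follow the kernel in both orientations", {
  D <- diag(3)  # three orthonormal atoms
  m <- wsrc_fit(t(D), c(0, 1, 1), sigma = 1, invert_weights = FALSE)
  w <- gaussian_weights(m$dictionary[, 1], m)
  expect_equal(w[1], 1)                       # coincident atom
  # distance between two orthonormal atoms is sqrt(2) = sigma*sqrt(2),
  # squared-norm reading gives exactly exp(-1)
  expect_equal(w[2], exp(-1))
  expect_true(all(w > 0 & w <= 1))

  m_inv <- wsrc_fit(t(D), c(0, 1, 1), sigma = 1, invert_weights = TRUE)
  w_inv <- gaussian_weights(m_inv$dictionary[, 1], m_inv)
  expect_equal(w_inv, 1 / pmax(w, 1e-8))

  m_uns <- wsrc_fit(t(D), c(0, 1, 1), sigma = 1, kernel = "unsquared",
                    invert_weights = FALSE)
  w_uns <- gaussian_weights(m_uns$dictionary[, 1], m_uns)
  expect_equal(w_uns[2], exp(-sqrt(2) / 2))

  # sigma -> infinity: all weights approach 1 (unweighted SRC)
  m_big <- wsrc_fit(t(D), c(0, 1, 1), sigma = 1e9, invert_weights = FALSE)
  expect_equal(gaussian_weights(m_big$dictionary[, 1], m_big), rep(1, 3),
               tolerance = 1e-12)

  expect_error(wsrc_fit(t(D), c(0, 1, 1), sigma = -1), "positive")
})

test_that("solver handles exact atoms, zero targets and stays feasible", {
  withr::with_seed(62, X <- matrix(rnorm(6 * 8), 6, 8))
  m <- wsrc_fit(X, c(1, 1, 1, 0, 0, 0), epsilon = 1e-3)

  s0 <- solve_weighted_l1(rep(0, 8), m)
  expect_equal(s0$beta, numeric(6))
  expect_equal(s0$objective, 0)
  expect_true(s0$converged)

  y <- m$dictionary[, 3]
  s1 <- solve_weighted_l1(y, m, weights = rep(1, 6))
  expect_lte(s1$residual, 1e-3 * (1 + 1e-9))
  # optimum of min ||b||_1 s.t. ||x_k - X b|| <= eps is ~ (1 - eps) e_k
  expect_equal(s1$objective, 1 - 1e-3, tolerance = 1e-4)
  expect_equal(which.max(abs(s1$beta)), 3L)
})

test_that("solver objective matches the independent glmnet oracle", {
  skip_if_not_installed("glmnet")
  withr::with_seed(63, {
    for (i in 1:25) {
      inst <- planted_wl1_instance()
      mine <- solve_weighted_l1(inst$y, inst$model, weights = inst$weights,
                                control = list(maxit = 50000,
                                               abstol = 1e-10,
                                               reltol = 1e-10))
      orc <- wl1_glmnet_oracle(inst$model$dictionary, inst$y,
                               inst$weights, inst$eps)
      skip_if(is.null(orc), "oracle path did not reach the residual ball")
      expect_equal(mine$objective, orc$objective, tolerance = 1e-6)
      expect_lte(mine$residual, inst$eps * (1 + 1e-9))
    }
  })
})

test_that("classification picks the minimum-residual class with tie-breaks", {
  # two far-separated clusters in 2D
  withr::with_seed(64, {
    X <- rbind(matrix(rnorm(10, mean = 5, sd = 0.2), 5, 2),
               matrix(rnorm(10, mean = -5, sd = 0.2), 5, 2))
  })
  lab <- rep(c(0, 1), each = 5)
  m <- wsrc_fit(X, lab, epsilon = 1e-3)
  inside2 <- c(-5.1, -4.9) / sqrt(sum(c(-5.1, -4.9)^2))
  r <- wsrc_classify(inside2, m)
  expect_equal(r$label, 1)
  # brute-force check of the class residuals from the same code
  b <- r$code$beta
  for (cl in c(0, 1)) {
    bc <- b; bc[lab != cl] <- 0
    expect_equal(unname(r$residuals[as.character(cl)]),
                 sqrt(sum((inside2 - m$dictionary %*% bc)^2)),
                 tolerance = 1e-10)
  }

  # exact atom is assigned its column's class
  r2 <- wsrc_classify(m$dictionary[, 2], m)
  expect_equal(r2$label, 0)
  expect_lte(unname(r2$residuals["0"]), 1e-3 * (1 + 1e-6))

  # symmetric configuration: the two class residuals coincide
  Xs <- rbind(c(1, 0), c(1, 0.1), c(0, 1), c(0.1, 1))
  ms <- wsrc_fit(Xs, c(0, 0, 1, 1), sigma = 1, epsilon = 1e-6)
  y45 <- c(1, 1) / sqrt(2)
  rs <- wsrc_classify(y45, ms)
  expect_equal(unname(rs$residuals["0"]), unname(rs$residuals["1"]),
               tolerance = 1e-6)
  # exact tie (zero target, all residuals identically 0): lowest class wins
  rz <- wsrc_classify(c(0, 0), ms)
  expect_equal(unname(rz$residuals), c(0, 0))
  expect_equal(rz$label, 0)
})

test_that("full-support residual never beats a class restriction", {
  withr::with_seed(65, {
    for (i in 1:10) {
      inst <- planted_wl1_instance(m = 5, n = 9)
      r <- wsrc_classify(inst$y, inst$model,
                         control = list(maxit = 20000, abstol = 1e-9,
                                        reltol = 1e-9))
      full_res <- sqrt(sum((inst$y / sqrt(sum(inst$y^2)) -
                              inst$model$dictionary %*% r$code$beta)^2))
      expect_lte(full_res, min(r$residuals) + 1e-6)
    }
  })
})

test_that("sigma -> infinity reproduces unweighted SRC decisions", {
  withr::with_seed(66, {
    for (i in 1:8) {
      inst <- planted_wl1_instance(m = 4, n = 8)
      m_inf <- wsrc_fit(t(inst$model$dictionary) * 3, inst$model$labels,
                        sigma = 1e9, epsilon = inst$model$epsilon)
      lab_inf <- wsrc_classify(inst$y, m_inf)$label
      # unweighted SRC: solve with unit weights on the same model
      sol <- solve_weighted_l1(inst$y, m_inf, weights = rep(1, 8))
      res <- vapply(m_inf$classes, function(cl) {
        b <- sol$beta; b[m_inf$labels != cl] <- 0
        sqrt(sum((inst$y - m_inf$dictionary %*% b)^2))
      }, numeric(1))
      expect_equal(lab_inf, m_inf$classes[which.min(res)])
    }
  })
})

test_that("WSRC models survive JSON serialization", {
  withr::with_seed(67, X <- matrix(rnorm(6 * 5), 6, 5))
  m <- wsrc_fit(X, c(1, 1, 1, 0, 0, 0))
  f <- tempfile(fileext = ".json")
  wsrc_save(m, f)
  m2 <- wsrc_load(f)
  y <- rnorm(5); y <- y / sqrt(sum(y^2))
  r1 <- wsrc_classify(y, m)
  r2 <- wsrc_classify(y, m2)
  expect_equal(r1$label, r2$label)
  expect_equal(r1$residuals, r2$residuals, tolerance = 1e-8)
})
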