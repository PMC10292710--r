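test_that("the forward pass follows the Tanh-hidden / Sigmoid-output form", {
  arch <- ann_architecture(2, 2)
  w <- ann_init(arch, seed = 1)
  w$W1[] <- 0; w$b1[] <- 0; w$W2[] <- 0; w$b2 <- 0
  expect_equal(ann_forward(w, c(0.3, 0.7)), 0.5)

  # zero hidden nodes: the constant model Sigmoid(b2)
  w0 <- ann_init(ann_architecture(3, 0), seed = 1)
  w0$b2 <- 0.4
  expect_equal(ann_forward(w0, matrix(runif(9), 3, 3)),
               rep(1 / (1 + exp(-0.4)), 3))

  # hand-computed forward pass on a small random network
  set.seed(13)
  w <- ann_init(arch, seed = 13)
  x <- c(0.2, 0.9)
  a1 <- tanh(w$W1[1, 1] * x[1] + w$W1[1, 2] * x[2] + w$b1[1])
  a2 <- tanh(w$W1[2, 1] * x[1] + w$W1[2, 2] * x[2] + w$b1[2])
  z <- w$W2[1, 1] * a1 + w$W2[1, 2] * a2 + w$b2
  expect_equal(ann_forward(w, x), 1 / (1 + exp(-z)), tolerance = 1e-12)

  expect_error(ann_forward(w, c(1, 2, 3)), "width")
})

test_that("analytic gradients match central differences", {
  set.seed(21)
  for (case in 1:4) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    arch <- ann_architecture(n, m)
    w <- ann_init(arch, seed = 20 + case)
    I <- 12
    X <- matrix(runif(I * n), I, n)
    y <- runif(I)
    lambda <- c(0, 0.01, 0.1, 0)[case]
    cg <- ann_cost_grad(w, X, y, lambda)
    analytic <- c(cg$gW1, cg$gb1, cg$gW2, cg$gb2)
    v0 <- weights_to_vec(w)
    h <- 1e-6
    numeric_g <- vapply(seq_along(v0), function(j) {
      vp <- v0; vp[j] <- vp[j] + h
      vm <- v0; vm[j] <- vm[j] - h
      (ann_cost_grad(vec_to_weights(vp, w), X, y, lambda)$J_reg -
         ann_cost_grad(vec_to_weights(vm, w), X, y, lambda)$J_reg) / (2 * h)
    }, numeric(1))
    expect_equal(analytic, numeric_g, tolerance = 1e-5)
  }
})

test_that("training recovers a teacher network and shrinks under heavy L2", {
  arch <- ann_architecture(2, 2)
  teacher <- ann_init(arch, seed = 42)
  set.seed(5)
  X <- matrix(runif(200), 100, 2)
  y <- ann_forward(teacher, X)
  student <- train_ann(X, y, arch, lambda = 0, max_iterations = 20000,
                       seed = 1)
  expect_lt(student$J, 1e-4)

  # dominant penalty drives the weights to zero and the output to Sig(b2)
  heavy <- train_ann(X, y, arch, lambda = 100, max_iterations = 3000,
                     seed = 1)
  expect_lt(sum(heavy$W1^2) + sum(heavy$W2^2), 1e-4)
  expect_equal(ann_forward(heavy, X),
               rep(1 / (1 + exp(-heavy$b2)), nrow(X)), tolerance = 1e-3)

  # identical seeds give identical trained weights
  s2 <- train_ann(X, y, arch, lambda = 0, max_iterations = 500, seed = 7)
  s3 <- train_ann(X, y, arch, lambda = 0, max_iterations = 500, seed = 7)
  expect_identical(weights_to_vec(s2), weights_to_vec(s3))
})

test_that("the prediction-risk estimate obeys its algebra", {
  expect_equal(prediction_risk(1, 12, 40), 1.6)
  expect_identical(ann_architecture(3, 3)$Q, 12L)
  # P >= J with equality iff Q = 0
  expect_identical(prediction_risk(0.7, 0, 33), 0.7)
  set.seed(6)
  for (i in 1:10) {
    J <- runif(1); Q <- sample(1:50, 1); I <- sample(10:100, 1)
    expect_gt(prediction_risk(J, Q, I), J)
  }
  # strictly increasing in Q
  risks <- vapply(1:10, function(Q) prediction_risk(0.5, Q, 30), numeric(1))
  expect_true(all(diff(risks) > 0))
  expect_error(prediction_risk(1, 1, 0), "I")
})

test_that("normalisation maps to [0,1], inverts exactly, and clips", {
  nm <- normalize_residuals(c(-2, 0, 2))
  expect_equal(nm$values, c(0, 0.5, 1))
  x <- rnorm(20)
  nm2 <- normalize_residuals(x)
  expect_equal(denormalize_residuals(nm2$values, nm2$spec), x,
               tolerance = 1e-12)
  expect_warning(out <- normalize_residuals(-3, nm$spec), "clipped")
  expect_identical(out$values, 0)
  expect_error(normalize_residuals(rep(1, 5)), "constant_residuals")
})

test_that("the lag matrix maps recent residuals to the next target", {
  e <- 1:10 / 10
  lm_ <- build_lag_matrix(e, 3)
  expect_identical(lm_$I, 7L)
  expect_identical(dim(lm_$X), c(7L, 3L))
  # first row: lags t-1, t-2, t-3 of target e[4]
  expect_equal(lm_$X[1, ], c(0.3, 0.2, 0.1))
  expect_equal(lm_$y[1], 0.4)
  expect_equal(lm_$y, e[4:10])
  expect_error(build_lag_matrix(e, 10), "more residuals")
})
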