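## Single-hidden-layer feedforward network used to model the nonlinear
## structure of ARIMA residuals: Tanh hidden layer, Sigmoid output layer,
## full-batch gradient descent on L2-regularised mean squared error.
## Written from scratch because the architecture-selection procedure needs
## exact control over the cost, the weight count Q, and the gradients.

#' ANN architecture
#'
#' @param n_inputs number of input nodes (lagged residuals), `>= 1` unless
#'   `m_hidden = 0`.
#' @param m_hidden number of hidden nodes, `>= 0`; `m_hidden = 0` is the
#'   degenerate constant model `Sigmoid(b2)` with weight count `Q = 0`.
#' @return object of class `ann_architecture` with the weight count
#'   `Q = n * m + m`.
#' @export
ann_architecture <- function(n_inputs, m_hidden) {
  n_inputs <- as.integer(n_inputs); m_hidden <- as.integer(m_hidden)
  stopifnot(n_inputs >= 0, m_hidden >= 0)
  structure(list(n_inputs = n_inputs, m_hidden = m_hidden,
                 Q = n_inputs * m_hidden + m_hidden),
            class = "ann_architecture")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Seeded uniform weight initialisation
#'
#' @param arch an [ann_architecture].
#' @param seed integer seed; weights are uniform on `[-0.5, 0.5]`.
#' @return list of weights `W1` (m x n), `b1` (m), `W2` (1 x m), `b2`
#'   (scalar) with the architecture attached.
#' @export
ann_init <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "ann_architecture"))
  set.seed(seed)
  n <- arch$n_inputs; m <- arch$m_hidden
  list(W1 = matrix(stats::runif(m * n, -0.5, 0.5), m, n),
       b1 = stats::runif(m, -0.5, 0.5),
       W2 = matrix(stats::runif(m, -0.5, 0.5), 1, m),
       b2 = stats::runif(1, -0.5, 0.5),
       arch = arch)
}

#' Forward pass of the residual network
#'
#' Hidden activation `a = Tanh(W1 x + b1)`, output
#' `Sigmoid(W2 a + b2) in (0, 1)`.  With zero hidden nodes the output is the
#' constant `Sigmoid(b2)`.
#'
#' @param weights weight list from [ann_init] or [train_ann].
#' @param X input matrix (one row per data point, `n_inputs` columns), or a
#'   single input vector.
#' @return numeric vector of outputs in (0, 1).
#' @export
ann_forward <- function(weights, X) {
  arch <- weights$arch
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != arch$n_inputs && arch$m_hidden > 0) {
    stop("ann_forward: input width does not match n_inputs")
  }
  if (arch$m_hidden == 0) {
    return(rep(.sigmoid(weights$b2), nrow(X)))
  }
  A <- tanh(sweep(X %*% t(weights$W1), 2, weights$b1, `+`))
  as.numeric(.sigmoid(A %*% t(weights$W2) + weights$b2))
}

#' Cost and analytic gradient of the regularised MSE
#'
#' `J = mean((y - out)^2)`;
#' `J_reg = J + lambda/2 * (||W1||^2 + ||W2||^2)` (biases unpenalised).
#' Gradients are exact backpropagation; they are checked against central
#' differences in the test suite.
#'
#' @param weights weight list.
#' @param X input matrix (I x n).
#' @param y targets in `[0, 1]` (length I).
#' @param lambda L2 coefficient, `>= 0`.
#' @return list with `J`, `J_reg`, and gradients `gW1`, `gb1`, `gW2`, `gb2`.
#' @export
ann_cost_grad <- function(weights, X, y, lambda = 0) {
  arch <- weights$arch
  I <- length(y)
  if (arch$m_hidden == 0) {
    o <- .sigmoid(weights$b2)
    r <- y - o
    J <- mean(r^2)
    gb2 <- sum(-2 / I * r * o * (1 - o))
    return(list(J = J, J_reg = J,
                gW1 = weights$W1, gb1 = weights$b1 * 0,
                gW2 = weights$W2, gb2 = gb2))
  }
  Z1 <- sweep(X %*% t(weights$W1), 2, weights$b1, `+`)
  A <- tanh(Z1)
  o <- as.numeric(.sigmoid(A %*% t(weights$W2) + weights$b2))
  r <- y - o
  J <- mean(r^2)
  J_reg <- J + lambda / 2 * (sum(weights$W1^2) + sum(weights$W2^2))
  d2 <- -2 / I * r * o * (1 - o)                  # I
  gW2 <- matrix(d2, 1, I) %*% A + lambda * weights$W2
  gb2 <- sum(d2)
  D1 <- (d2 %*% weights$W2) * (1 - A^2)           # I x m
  gW1 <- t(D1) %*% X + lambda * weights$W1
  gb1 <- colSums(D1)
  list(J = J, J_reg = J_reg, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train the residual network by full-batch gradient descent
#'
#' Backpropagation with an adaptive step size: the step is halved when a
#' proposed update increases the regularised cost and grown slightly after
#' successful steps.  Initialisation is seeded, so training is fully
#' deterministic.  Training stops when the cost change drops below `tol` or
#' after `max_iterations` updates; a non-finite cost aborts with
#' diagnostics.
#'
#' @param X input matrix (I x n, inputs in `[0, 1]`).
#' @param y targets in `[0, 1]`.
#' @param arch an [ann_architecture].
#' @param lambda L2 coefficient (default 0.01).
#' @param max_iterations maximum gradient steps (default 5000).
#' @param learning_rate initial step size.
#' @param tol convergence tolerance on the cost change (default 1e-9).
#' @param seed seed for the weight initialisation.
#' @return weight list with `J`, `J_reg`, `iterations`, `converged`.
#' @export
train_ann <- function(X, y, arch, lambda = 0.01, max_iterations = 5000L,
                      learning_rate = 0.2, tol = 1e-9, seed = 1L) {
  stopifnot(inherits(arch, "ann_architecture"), length(y) >= 1)
  if (is.null(dim(X))) X <- matrix(X, ncol = max(arch$n_inputs, 1))
  w <- ann_init(arch, seed)
  lr <- learning_rate
  cg <- ann_cost_grad(w, X, y, lambda)
  if (!is.finite(cg$J_reg)) stop("train_ann: non-finite initial cost")
  it <- 0L; converged <- FALSE
  while (it < max_iterations) {
    it <- it + 1L
    stepped <- FALSE
    for (half in 1:30) {
      w2 <- w
      w2$W1 <- w$W1 - lr * cg$gW1
      w2$b1 <- w$b1 - lr * cg$gb1
      w2$W2 <- w$W2 - lr * cg$gW2
      w2$b2 <- w$b2 - lr * cg$gb2
      cg2 <- ann_cost_grad(w2, X, y, lambda)
      if (!is.finite(cg2$J_reg)) {
        stop(sprintf("train_ann: cost diverged at iteration %d (lr = %g)",
                     it, lr))
      }
      if (cg2$J_reg <= cg$J_reg) { stepped <- TRUE; break }
      lr <- lr / 2
    }
    if (!stepped) { converged <- TRUE; break }
    delta <- cg$J_reg - cg2$J_reg
    w <- w2; cg <- cg2
    lr <- min(lr * 1.05, 1)
    if (delta < tol) { converged <- TRUE; break }
  }
  w$J <- cg$J; w$J_reg <- cg$J_reg
  w$iterations <- it; w$converged <- converged
  w
}

#' Algebraic prediction-risk estimate
#'
#' `P_hat = J * (1 + 2 * Q / I)`: the training MSE inflated by the ratio of
#' weight count to training points, an estimate of out-of-sample MSE when
#' the model is trained on all available data.
#'
#' @param J training mean squared error.
#' @param Q number of network weights (`n * m + m`).
#' @param I number of training points, `> 0`.
#' @return estimated prediction risk; always `>= J`, with equality iff
#'   `Q = 0`.
#' @export
prediction_risk <- function(J, Q, I) {
  if (I <= 0) stop("prediction_risk: I must be > 0")
  J * (1 + 2 * Q / I)
}
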