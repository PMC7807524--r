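#' SVR hyperparameters
#'
#' Settings of the epsilon-insensitive support vector regressor used for
#' both the surface-signal predictor and the external/internal correlator:
#' RBF kernel width `gamma = 0.1` and penalty `C = 1000`. The tube
#' half-width epsilon is a free choice (the regressor is always fitted on
#' standardized data, so epsilon is in standard-deviation units).
#'
#' @param gamma RBF kernel width (> 0).
#' @param cost regularization constant C (> 0).
#' @param epsilon tube half-width (>= 0).
#' @param kernel `"rbf"` (default) or `"linear"`; the linear kernel exists
#'   mainly so small analytic test instances can be solved in closed view.
#' @return an object of class `svr_config`.
#' @export
svr_config <- function(gamma = 0.1, cost = 1000, epsilon = 0.1,
                       kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  if (gamma <= 0 || cost <= 0 || epsilon < 0) {
    stop_arg("need gamma > 0, cost > 0, epsilon >= 0")
  }
  structure(list(gamma = gamma, cost = cost, epsilon = epsilon,
                 kernel = kernel),
            class = "svr_config")
}

#' Radial basis function kernel
#'
#' `k(u, v) = exp(-gamma * ||u - v||^2)`, in (0, 1] with `k(x, x) = 1`.
#'
#' @param u,v numeric vectors of equal length.
#' @param gamma kernel width.
#' @return similarity scalar.
#' @export
rbf_kernel <- function(u, v, gamma = 0.1) {
  if (length(u) != length(v)) stop_arg("kernel inputs differ in dimension")
  exp(-gamma * sum((u - v)^2))
}

# cross-kernel matrix K[i, j] = k(U[i, ], V[j, ])
kernel_matrix <- function(U, V, config) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (config$kernel == "linear") return(U %*% t(V))
  sq <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * U %*% t(V)
  exp(-config$gamma * pmax(sq, 0))
}

#' Fit an epsilon-insensitive support vector regressor
#'
#' Solves the standard eps-SVR problem (squared-norm regularizer plus
#' C-weighted epsilon-insensitive loss). Fitting is delegated to the libsvm
#' SMO solver; the returned model stores the support vectors, the dual
#' coefficient differences and the offset, and predictions are computed
#' directly from that expansion by [predict_svr()]. [fit_svr_qp()] provides
#' an independent dense quadratic-programming solution of the same dual for
#' verification.
#'
#' @param X matrix of input windows (rows = examples).
#' @param y numeric targets.
#' @param config an [svr_config()].
#' @param tolerance SMO termination tolerance.
#' @return an object of class `svr_model`: list with `support` (matrix of
#'   support vectors), `beta` (dual coefficient differences, one per support
#'   vector, bounded by C in magnitude), `b` (offset), `config`, and
#'   `fitted` (decision values at the training points).
#' @export
fit_svr <- function(X, y, config = svr_config(), tolerance = 0.001) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop_arg("empty training set")
  if (length(y) != nrow(X)) stop_arg("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop_arg("non-finite data")
  fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                    kernel = if (config$kernel == "rbf") "radial" else
                      "linear",
                    gamma = config$gamma, cost = config$cost,
                    epsilon = config$epsilon, scale = FALSE,
                    tolerance = tolerance, fitted = FALSE)
  support <- as.matrix(fit$SV)
  beta <- as.numeric(fit$coefs)
  model <- structure(list(support = support, beta = beta, b = -fit$rho,
                          config = config),
                     class = "svr_model")
  model$fitted <- predict_svr(model, X)
  model
}

#' Predict with a fitted SVR model
#'
#' Evaluates the support-vector expansion
#' `f(x) = sum_i beta_i k(x_i, x) + b` with the model's kernel.
#'
#' @param model an `svr_model` from [fit_svr()] or [fit_svr_qp()].
#' @param X matrix of query windows (rows = examples), or a single vector.
#' @return numeric vector of predictions.
#' @export
predict_svr <- function(model, X) {
  stopifnot(inherits(model, "svr_model"))
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (length(model$beta) == 0L) return(rep(model$b, nrow(X)))
  if (ncol(X) != ncol(model$support)) {
    stop_arg("query dimension ", ncol(X), " does not match support vectors (",
             ncol(model$support), ")")
  }
  drop(kernel_matrix(X, model$support, model$config) %*% model$beta) +
    model$b
}

#' Exact dense-QP solution of the eps-SVR dual
#'
#' Solves the dual quadratic program over `(alpha_hat, alpha)` with box
#' constraints `[0, C]` and the balance constraint
#' `sum(alpha_hat - alpha) = 0` by interior-point optimization
#' ([kernlab::ipop()]) on the dense kernel matrix. Exact but O(m^3); meant
#' as ground truth on small instances, not for production fitting. The
#' offset is recovered from the Karush-Kuhn-Tucker conditions as the
#' midpoint of the interval of offsets minimizing the epsilon-insensitive
#' loss given the dual expansion (a single point whenever a free support
#' vector exists).
#'
#' @inheritParams fit_svr
#' @param sigf,maxiter interior-point precision controls passed to
#'   [kernlab::ipop()].
#' @return an `svr_model` (same structure as [fit_svr()]).
#' @export
fit_svr_qp <- function(X, y, config = svr_config(), sigf = 9, maxiter = 100) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m == 0L) stop_arg("empty training set")
  K <- kernel_matrix(X, X, config)
  # minimize 0.5 x'H x + c'x over x = (alpha_hat, alpha)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * m)
  cc <- c(config$epsilon - y, config$epsilon + y)
  A <- matrix(c(rep(1, m), rep(-1, m)), nrow = 1)
  res <- kernlab::ipop(c = cc, H = H, A = A, b = 0,
                       l = rep(0, 2 * m), u = rep(config$cost, 2 * m),
                       r = 0, sigf = sigf, maxiter = maxiter)
  x <- kernlab::primal(res)
  beta <- x[seq_len(m)] - x[m + seq_len(m)]
  g <- drop(K %*% beta)
  b <- svr_offset(y - g, config$epsilon)
  structure(list(support = X, beta = beta, b = b, config = config,
                 fitted = g + b),
            class = "svr_model")
}

# Offset minimizing sum(max(0, |r - b| - eps)): convex piecewise linear in
# b with breakpoints r +- eps; midpoint of the minimizing interval.
svr_offset <- function(r, eps) {
  cand <- sort(unique(c(r - eps, r + eps)))
  loss <- vapply(cand, function(b) sum(pmax(abs(r - b) - eps, 0)), 0)
  keep <- cand[loss <= min(loss) + 1e-12 * (1 + min(loss))]
  (min(keep) + max(keep)) / 2
}

#' Dual objective value of an SVR model
#'
#' Evaluates the (maximized) dual objective
#' `-(1/2) beta' K beta + y' beta - eps * sum(|beta|)` for a fitted model on
#' its own training inputs/targets, used to compare independent solvers.
#'
#' @param model an `svr_model`.
#' @param X,y the training data the model was fitted on.
#' @return dual objective scalar.
#' @export
svr_dual_objective <- function(model, X, y) {
  X <- as.matrix(X)
  Kb <- drop(kernel_matrix(X, model$support, model$config) %*% model$beta)
  # beta on the full training set (zero off-support)
  match_rows <- function(A, B) {
    # indices in A of the rows of B (exact match)
    key <- function(M) apply(M, 1, paste, collapse = "\r")
    match(key(B), key(A))
  }
  beta_full <- rep(0, nrow(X))
  beta_full[match_rows(X, model$support)] <- model$beta
  -0.5 * sum(beta_full * Kb) + sum(y * beta_full) -
    model$config$epsilon * sum(abs(beta_full))
}
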