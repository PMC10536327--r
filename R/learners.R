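#' Fit a gradient-boosted tree classifier
#'
#' Deterministic second-order boosting with logistic loss (no subsampling).
#' Two named presets mirror the common boosted-tree library defaults used
#' for feature selection: `gbdt_a` (300 trees, depth 4, learning rate 0.1)
#' and `gbdt_b` (400 trees, depth 3, learning rate 0.05).
#'
#' @param x numeric matrix, samples in rows, features in columns
#' @param y 0/1 numeric vector (1 = recoverer)
#' @param n_trees,max_depth,learning_rate,lambda,min_child_weight boosting
#'   hyperparameters (`lambda` is the L2 leaf penalty)
#' @return object of class `gbdt` with elements `model` (trees),
#'   `importance` (named total split gain per feature)
#' @export
gbdt_fit <- function(x, y, n_trees = 300, max_depth = 4, learning_rate = 0.1,
                     lambda = 1, min_child_weight = 1e-3) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  fit <- fit_gbdt_cpp(x, y, as.integer(n_trees), as.integer(max_depth),
                      learning_rate, lambda, min_child_weight)
  imp <- setNames(fit$importance, colnames(x))
  structure(list(model = fit, importance = imp,
                 features = colnames(x)), class = "gbdt")
}

#' @param object a `gbdt` fit
#' @param newdata numeric matrix with the training columns
#' @param type `"response"` (probability) or `"link"` (log-odds margin)
#' @param ... unused
#' @rdname gbdt_fit
#' @export
predict.gbdt <- function(object, newdata,
                         type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  m <- predict_gbdt_cpp(object$model, newdata)
  if (type == "link") m else 1 / (1 + exp(-m))
}

#' Named boosting presets
#' @param learner `"gbdt_a"` or `"gbdt_b"`
#' @return list of hyperparameters for [gbdt_fit()]
#' @export
gbdt_params <- function(learner = c("gbdt_a", "gbdt_b")) {
  learner <- match.arg(learner)
  if (learner == "gbdt_a")
    list(n_trees = 300, max_depth = 4, learning_rate = 0.1, lambda = 1)
  else
    list(n_trees = 400, max_depth = 3, learning_rate = 0.05, lambda = 1)
}

# Ridge-penalized logistic regression via IRLS (internal). Used as the fast
# learner in combination search and as the fallback under perfect
# separation. lambda is not applied to the intercept.
ridge_logistic <- function(x, y, lambda = 1e-2, max_iter = 100, tol = 1e-10) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(x)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(x * w, x) + pen
    new_beta <- drop(solve(xtwx, crossprod(x * w, z)))
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  structure(list(coefficients = setNames(beta, colnames(x))),
            class = "ridge_logistic")
}

predict_ridge_logistic <- function(fit, x) {
  eta <- drop(cbind(1, as.matrix(x)) %*% fit$coefficients)
  1 / (1 + exp(-eta))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC; ties in scores contribute 1/2.
#'
#' @param scores numeric predictions
#' @param labels 0/1 vector (or logical) with 1 the positive class
#' @return AUC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment (internal): deterministic given the RNG state.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# Vectorized one-sided Wilcoxon rank-sum p-values (internal).
# X: samples x taxa; grp1 logical marking the "greater" group. Exact
# distribution when there are no ties and m + n < 50, otherwise normal
# approximation with tie correction and continuity correction (matching
# stats::wilcox.test).
rank_sum_p <- function(X, grp1, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  X <- as.matrix(X)
  m <- sum(grp1); n <- sum(!grp1)
  if (m == 0 || n == 0) stop("both groups must be non-empty")
  R <- apply(X, 2, rank)
  W <- colSums(R[grp1, , drop = FALSE]) - m * (m + 1) / 2  # U statistic
  has_ties <- apply(X, 2, function(col) anyDuplicated(col) > 0)
  p <- numeric(ncol(X))
  exact_ok <- !has_ties & (m + n < 50)
  if (any(exact_ok)) {
    w <- W[exact_ok]
    if (alternative == "greater") {
      p[exact_ok] <- stats::pwilcox(w - 1, m, n, lower.tail = FALSE)
    } else {
      p_hi <- stats::pwilcox(w - 1, m, n, lower.tail = FALSE)
      p_lo <- stats::pwilcox(w, m, n)
      p[exact_ok] <- pmin(1, 2 * pmin(p_hi, p_lo))
    }
  }
  if (any(!exact_ok)) {
    idx <- which(!exact_ok)
    mu <- m * n / 2
    for (j in idx) {
      nties <- table(X[, j])
      sigma2 <- m * n / 12 *
        ((m + n + 1) - sum(nties^3 - nties) / ((m + n) * (m + n - 1)))
      z <- W[j] - mu
      corr <- if (alternative == "greater") 0.5 else sign(z) * 0.5
      z <- (z - corr) / sqrt(sigma2)
      p[j] <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
              else 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5)
    }
  }
  setNames(p, colnames(X))
}
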