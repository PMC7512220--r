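## Ridge-penalized logistic regression via IRLS. A fixed small ridge is
## applied always (not only under separation) so per-fold models are
## comparable; the intercept is unpenalized. Features are expected to be
## standardized by the caller.
.ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100L,
                            tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), nrow = p)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X1, w * X1) + pen
    beta <- drop(solve(A, crossprod(X1, w * z)))
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                    (1 - y) * log(pmax(1 - mu, 1e-12))) +
      lambda * sum(beta[-1L]^2)
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  beta
}

.ridge_predict <- function(beta, X) {
  stats::plogis(drop(cbind(1, X) %*% beta))
}

## standardize columns by training mean/sd (sd 0 -> 1)
.std_fit <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(m = m, s = s)
}
.std_apply <- function(X, st) sweep(sweep(X, 2L, st$m, `-`), 2L, st$s, `/`)

## Precompute per-fold PC score geometry. PCA is unsupervised, so the fold
## scores do not depend on the group labels; a permutation test can reuse
## this cache and only refit the regression.
.loocv_precompute <- function(values, k_components, pca_policy,
                              transform = "sqrt", scaling = "pareto") {
  n <- ncol(values)
  ids <- colnames(values)
  folds <- vector("list", n)
  if (pca_policy == "global") {
    pm <- protein_matrix(values, stage = "averaged")
    model <- suppressWarnings(
      sqrt_pareto_pca(pm, n_components = k_components,
                      transform = transform, scaling = scaling))
    sc <- model$scores
    for (i in seq_len(n)) {
      st <- .std_fit(sc[-i, , drop = FALSE])
      folds[[i]] <- list(
        Xtrain = .std_apply(sc[-i, , drop = FALSE], st),
        xheld = .std_apply(sc[i, , drop = FALSE], st))
    }
  } else {
    for (i in seq_len(n)) {
      pm <- protein_matrix(values[, -i, drop = FALSE], stage = "averaged")
      model <- suppressWarnings(
        sqrt_pareto_pca(pm, n_components = k_components,
                        transform = transform, scaling = scaling))
      held <- predict(model, values[, i, drop = FALSE])
      st <- .std_fit(model$scores)
      folds[[i]] <- list(Xtrain = .std_apply(model$scores, st),
                         xheld = .std_apply(held, st))
    }
  }
  list(folds = folds, ids = ids, n = n)
}

## run LOOCV over a cached geometry for a given 0/1 label vector
.loocv_from_cache <- function(cache, y, lambda = 1e-3) {
  probs <- numeric(cache$n)
  for (i in seq_len(cache$n)) {
    beta <- .ridge_logistic(cache$folds[[i]]$Xtrain, y[-i], lambda = lambda)
    probs[i] <- .ridge_predict(beta, cache$folds[[i]]$xheld)
  }
  pred <- as.integer(probs > 0.5)
  list(probs = probs, pred = pred, error_count = sum(pred != y))
}

#' Principal-component logistic regression with leave-one-out cross-validation
#'
#' Diagnostic classifier on the replicate-averaged protein matrix: samples
#' are represented by their first \code{k_components} principal component
#' scores (square-root/Pareto PCA) and classified case versus control by a
#' logistic regression with a fixed small ridge penalty (\code{lambda},
#' default 1e-3, applied always so that per-fold models remain comparable
#' and perfect separation in a fold cannot break the fit; PC scores are
#' standardized within each training fold so the penalty scale is
#' comparable). Performance is summarized by leave-one-out cross-validation:
#' each sample's probability of being a case is predicted by a model that
#' never saw it.
#'
#' With \code{pca_policy = "refit_per_fold"} (default) the PCA itself is
#' refitted on each fold's training samples and the held-out sample is
#' projected with the training center/scale/loadings, avoiding any
#' information leakage. With \code{"global"} the PCA is fitted once on all
#' samples and only the regression is refitted per fold.
#'
#' @param matrix a [protein_matrix()] with stage \code{"averaged"}.
#' @param samples sample metadata (\code{sample_id}, \code{group}); at
#'   least 3 samples per group.
#' @param k_components number of principal components (default 3).
#' @param pca_policy \code{"refit_per_fold"} or \code{"global"}.
#' @param lambda fixed ridge penalty of the logistic fit.
#' @return object of class \code{classifier_result}: list with
#'   \code{k_components}, \code{pca_policy}, \code{per_sample} (data.frame:
#'   sample_id, held_out_probability, predicted_label, true_label),
#'   \code{error_count}, \code{lambda}.
#' @export
pc_logistic_loocv <- function(matrix, samples, k_components = 3L,
                              pca_policy = c("refit_per_fold", "global"),
                              lambda = 1e-3) {
  .assert_stage(matrix, "averaged")
  pca_policy <- match.arg(pca_policy)
  values <- matrix$values
  grp <- samples$group[match(colnames(values), samples$sample_id)]
  if (anyNA(grp)) stop("sample metadata missing for some matrix columns")
  if (sum(grp == "case") < 3L || sum(grp == "control") < 3L)
    stop("need at least 3 samples per group")
  n <- ncol(values)
  if (k_components > n - 2L)
    stop("'k_components' must be <= n_samples - 2")
  y <- as.integer(grp == "case")
  cache <- .loocv_precompute(values, k_components, pca_policy)
  fit <- .loocv_from_cache(cache, y, lambda = lambda)
  lab <- function(v) ifelse(v == 1L, "case", "control")
  structure(list(
    k_components = as.integer(k_components), pca_policy = pca_policy,
    per_sample = data.frame(
      sample_id = cache$ids, held_out_probability = fit$probs,
      predicted_label = lab(fit$pred), true_label = lab(y),
      stringsAsFactors = FALSE),
    error_count = fit$error_count, lambda = lambda),
    class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf(
    "classifier_result: %d/%d LOOCV errors (k = %d, PCA %s)\n",
    x$error_count, nrow(x$per_sample), x$k_components, x$pca_policy))
  invisible(x)
}

#' Label-permutation test of the LOOCV prediction error
#'
#' Builds the null distribution of the cross-validated error count by
#' shuffling the case/control labels over samples (preserving group sizes)
#' and re-running the complete LOOCV for each shuffle. "As extreme or more"
#' means a null error less than or equal to the observed one
#' (better-or-equal performance).
#'
#' When the number of distinct label arrangements \code{choose(n, n_cases)}
#' is at most \code{exhaustive_limit} (and \code{exhaustive} is
#' \code{"auto"} or \code{"always"}), all arrangements are enumerated and
#' the p-value is exact: the fraction of arrangements (the observed one
#' included) performing as well or better. Otherwise \code{n_permutations}
#' random shuffles are drawn and the add-one-smoothed estimate
#' \code{(1 + #\{null <= observed\}) / (n_permutations + 1)} is reported, so
#' the p-value can never be exactly zero.
#'
#' Because the PCA stage is unsupervised, the per-fold component geometry is
#' computed once and shared by all permutations; only the penalized
#' regression is refitted.
#'
#' @param matrix,samples,k_components,pca_policy,lambda as in
#'   [pc_logistic_loocv()]; must match the observed result.
#' @param observed the [pc_logistic_loocv()] result being tested.
#' @param n_permutations number of random shuffles in sampled mode.
#' @param seed integer seed for the shuffles.
#' @param exhaustive \code{"auto"} (default), \code{"always"} or
#'   \code{"never"}.
#' @param exhaustive_limit arrangement-count cutoff for automatic
#'   enumeration (default 20000).
#' @return object of class \code{permutation_result}: list with
#'   \code{observed_error}, \code{null_errors}, \code{n_permutations},
#'   \code{p_value}, \code{seed}, \code{method}.
#' @export
permutation_test <- function(matrix, samples, k_components = 3L,
                             observed, n_permutations = 2000L, seed = 1L,
                             pca_policy = c("refit_per_fold", "global"),
                             lambda = 1e-3,
                             exhaustive = c("auto", "always", "never"),
                             exhaustive_limit = 20000L) {
  .assert_stage(matrix, "averaged")
  pca_policy <- match.arg(pca_policy)
  exhaustive <- match.arg(exhaustive)
  if (!inherits(observed, "classifier_result"))
    stop("'observed' must be a classifier_result")
  if (n_permutations < 1L)
    stop("'n_permutations' must be >= 1")
  values <- matrix$values
  grp <- samples$group[match(colnames(values), samples$sample_id)]
  if (anyNA(grp)) stop("sample metadata missing for some matrix columns")
  y <- as.integer(grp == "case")
  n <- length(y)
  cache <- .loocv_precompute(values, k_components, pca_policy)

  n_arrange <- choose(n, sum(y))
  use_exhaustive <- exhaustive == "always" ||
    (exhaustive == "auto" && n_arrange <= exhaustive_limit)

  if (use_exhaustive) {
    combs <- utils::combn(n, sum(y))
    null_errors <- apply(combs, 2L, function(idx) {
      yp <- integer(n); yp[idx] <- 1L
      .loocv_from_cache(cache, yp, lambda = lambda)$error_count
    })
    p <- mean(null_errors <= observed$error_count)
    method <- "exhaustive"
    n_perm <- length(null_errors)
  } else {
    null_errors <- .with_seed(seed, vapply(seq_len(n_permutations),
      function(b) {
        yp <- sample(y)
        .loocv_from_cache(cache, yp, lambda = lambda)$error_count
      }, numeric(1L)))
    p <- (1 + sum(null_errors <= observed$error_count)) /
      (n_permutations + 1)
    method <- "sampled"
    n_perm <- as.integer(n_permutations)
  }
  structure(list(observed_error = observed$error_count,
                 null_errors = as.numeric(null_errors),
                 n_permutations = n_perm, p_value = p,
                 seed = as.integer(seed), method = method),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed error %d, p = %.4g (%s, %d permutations)\n",
    x$observed_error, x$p_value, x$method, x$n_permutations))
  invisible(x)
}
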