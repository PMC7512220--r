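#' Square-root / Pareto-scaled principal component analysis
#'
#' PCA of a replicate-averaged protein matrix as used for unsupervised
#' cohort stratification in MS studies: intensities are square-root
#' transformed element-wise, each protein is mean-centered and divided by
#' the square root of its standard deviation (Pareto scaling, the usual
#' compromise between no scaling and unit variance), and the resulting
#' sample x protein matrix is decomposed by SVD. Samples are rows; percent
#' variance is of the total transformed-scaled variance.
#'
#' The decomposition runs on the sample-space crossproduct (samples are few,
#' proteins many). Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive. Proteins with
#' zero variance after the transform carry no information for the
#' decomposition and are dropped with a warning (they stay in the input
#' matrix).
#'
#' @param matrix a [protein_matrix()] with stage \code{"averaged"}.
#' @param n_components number of components to retain; at most
#'   \code{min(n_samples - 1, n_proteins)}.
#' @param transform \code{"sqrt"} (default) or \code{"none"}.
#' @param scaling \code{"pareto"} (default) or \code{"none"}; both steps are
#'   independently switchable.
#' @return an object of class \code{pca_model}: list with \code{center},
#'   \code{scale}, \code{loadings} (protein x component), \code{scores}
#'   (sample x component), \code{explained_pct}, \code{sdev},
#'   \code{kept_proteins}, \code{dropped_proteins}, \code{transform},
#'   \code{scaling}.
#' @export
sqrt_pareto_pca <- function(matrix, n_components = NULL,
                            transform = c("sqrt", "none"),
                            scaling = c("pareto", "none")) {
  .assert_stage(matrix, "averaged")
  transform <- match.arg(transform)
  scaling <- match.arg(scaling)
  X <- t(matrix$values)                      # samples x proteins
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 samples")
  if (transform == "sqrt") X <- sqrt(X)

  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0L) {
    warning(sprintf(
      "%d zero-variance protein(s) dropped from PCA (kept in matrix)",
      length(dropped)), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0L) stop("degenerate matrix: all proteins constant")
  kept <- colnames(X)

  center <- colMeans(X)
  scale_vec <- if (scaling == "pareto") sqrt(sds)
               else rep(1, length(sds))
  names(scale_vec) <- kept
  Xs <- sweep(sweep(X, 2L, center, `-`), 2L, scale_vec, `/`)

  max_k <- min(n - 1L, ncol(Xs))
  if (is.null(n_components)) n_components <- max_k
  if (n_components < 1L || n_components > max_k)
    stop(sprintf("'n_components' must lie in [1, %d]", max_k))

  ## eigendecomposition in sample space: Xs Xs' = U D^2 U'
  K <- tcrossprod(Xs)
  eig <- eigen(K, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  d <- sqrt(ev)
  total_var <- sum(ev)
  k <- n_components
  pos <- d[seq_len(k)] > max(d) * 1e-12
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  scores <- U %*% diag(d[seq_len(k)], nrow = k)
  loadings <- matrix(0, nrow = ncol(Xs), ncol = k)
  if (any(pos))
    loadings[, pos] <- crossprod(Xs, U[, pos, drop = FALSE]) %*%
      diag(1 / d[seq_len(k)][pos], nrow = sum(pos))

  ## deterministic sign: largest-|loading| per component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (length(i) > 0L && loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(kept, paste0("PC", seq_len(k)))
  structure(list(
    center = center, scale = scale_vec, loadings = loadings,
    scores = scores,
    explained_pct = if (total_var > 0) 100 * ev[seq_len(k)] / total_var
                    else rep(0, k),
    sdev = d[seq_len(k)] / sqrt(n - 1L),
    kept_proteins = kept, dropped_proteins = dropped,
    transform = transform, scaling = scaling), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model (%s/%s): %d components over %d proteins x %d samples\n",
              x$transform, x$scaling, ncol(x$scores), nrow(x$loadings),
              nrow(x$scores)))
  cat("  explained %:", paste(sprintf("%.1f", x$explained_pct),
                              collapse = " "), "\n")
  invisible(x)
}

#' Project new samples onto a fitted PCA model
#'
#' Applies the training transform, centering, scaling and loadings of a
#' [sqrt_pareto_pca()] model to new samples (used e.g. to place a held-out
#' sample into the training component space during cross-validation).
#'
#' @param object a \code{pca_model}.
#' @param newdata a [protein_matrix()] (stage \code{"averaged"}), a numeric
#'   matrix with proteins as rows, or a named numeric vector (one sample).
#' @param ... unused.
#' @return sample x component score matrix.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  if (inherits(newdata, "protein_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "new"))
  miss <- setdiff(object$kept_proteins, rownames(newdata))
  if (length(miss) > 0L)
    stop("newdata lacks protein(s) used by the model: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  X <- t(newdata[object$kept_proteins, , drop = FALSE])
  if (object$transform == "sqrt") X <- sqrt(X)
  Xs <- sweep(sweep(X, 2L, object$center, `-`), 2L, object$scale, `/`)
  Xs %*% object$loadings
}

## mean silhouette width for a 2-cluster partition of score coordinates
.mean_silhouette <- function(x, cluster) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- mean(d[i, cluster != cluster[i]])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the case subgroup separating from controls
#'
#' Partitions the samples into two clusters on the chosen principal
#' component scores with a deterministic 2-means rule: centers are
#' initialized at the two samples with extreme scores on the last listed
#' component (PC2 by default, where the case subgroup separates) and run to
#' convergence. The cluster containing the majority of controls is the
#' control-like cluster; cases falling in it are reported as excluded
#' (signal-free, co-clustering with controls), the rest as the core case
#' subgroup.
#'
#' When the two clusters are poorly separated (mean silhouette width below
#' \code{stability_threshold}) the assignment is flagged unstable and the
#' excluded set should not be interpreted. The default threshold 0.5
#' follows the usual silhouette reading in which values above 0.5 indicate
#' a reasonable cluster structure and values below it weak or artificial
#' structure.
#'
#' @param model a fitted \code{pca_model} on these samples.
#' @param samples sample metadata (\code{sample_id}, \code{group}).
#' @param components integer indices of the score components to cluster on.
#' @param stability_threshold minimum mean silhouette width for a stable
#'   call (default 0.5).
#' @return object of class \code{subgroup_assignment}: list with
#'   \code{core_case_ids}, \code{excluded_case_ids}, \code{cluster},
#'   \code{stable}, \code{silhouette}, \code{method_record}.
#' @export
select_subgroup <- function(model, samples, components = c(1L, 2L),
                            stability_threshold = 0.5) {
  if (!inherits(model, "pca_model")) stop("'model' must be a pca_model")
  if (any(components > ncol(model$scores)))
    stop("'components' exceed the fitted number of components")
  sc <- model$scores[, components, drop = FALSE]
  ids <- rownames(sc)
  if (!all(ids %in% samples$sample_id))
    stop("model fitted on samples absent from metadata")
  grp <- samples$group[match(ids, samples$sample_id)]

  split_axis <- sc[, ncol(sc)]
  i_lo <- which.min(split_axis); i_hi <- which.max(split_axis)
  init <- sc[c(i_lo, i_hi), , drop = FALSE]
  if (all(init[1L, ] == init[2L, ]))
    stop("degenerate clustering: all samples identical on chosen components")
  km <- stats::kmeans(sc, centers = init)
  cl <- km$cluster

  n_ctrl <- c(sum(grp == "control" & cl == 1L),
              sum(grp == "control" & cl == 2L))
  if (n_ctrl[1L] != n_ctrl[2L]) {
    control_like <- which.max(n_ctrl)
  } else {
    ## tie: cluster whose centroid is nearer the overall control centroid
    ctr <- colMeans(sc[grp == "control", , drop = FALSE])
    dd <- rowSums((km$centers - matrix(ctr, 2L, ncol(sc),
                                       byrow = TRUE))^2)
    control_like <- which.min(dd)
  }
  case_ids <- ids[grp == "case"]
  excluded <- ids[grp == "case" & cl == control_like]
  core <- setdiff(case_ids, excluded)
  sil <- .mean_silhouette(sc, cl)
  structure(list(
    core_case_ids = core, excluded_case_ids = excluded,
    cluster = stats::setNames(cl, ids),
    stable = sil >= stability_threshold, silhouette = sil,
    method_record = sprintf(
      "2-means on components [%s], centers initialized at extreme PC%d scores; control-like = cluster holding the control majority; silhouette %.3f (threshold %.2f)",
      paste(components, collapse = ","), components[length(components)],
      sil, stability_threshold)), class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat("subgroup_assignment:", length(x$core_case_ids), "core case(s),",
      length(x$excluded_case_ids), "excluded case(s)",
      if (x$stable) "(stable)" else "(UNSTABLE)", "\n")
  if (length(x$excluded_case_ids) > 0L)
    cat("  excluded:", paste(x$excluded_case_ids, collapse = ", "), "\n")
  invisible(x)
}
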