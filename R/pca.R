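# Component analysis of the feature matrix: correlation-matrix PCA,
# varimax rotation of the retained loadings, elbow-based selection.

.fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Varimax criterion of a loadings matrix
#'
#' Sum over components of the variance of the squared loadings:
#' `sum_j [ mean(L[,j]^4) - mean(L[,j]^2)^2 ]`. This is the quantity the
#' (unnormalized) varimax rotation maximizes.
#'
#' @param L features x components matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(L) {
  L <- as.matrix(L)
  sum(colMeans(L^4) - colMeans(L^2)^2)
}

#' Varimax rotation of component loadings
#'
#' Orthogonally rotates a loadings matrix to maximize the variance of the
#' squared loadings within each component (simple structure). Uses the
#' standard SVD-based iteration; Kaiser row normalization is off by
#' default. After convergence, columns are re-sorted by decreasing sum of
#' squared loadings and signed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param loadings features x k matrix, k >= 2 (k = 1 is returned as-is:
#'   rotation is undefined).
#' @param tol convergence tolerance on the relative criterion improvement.
#' @param max_iter iteration cap; non-convergence sets the `converged`
#'   attribute to `FALSE` (with a warning) rather than failing.
#' @param normalize apply Kaiser row normalization before rotating.
#' @return The rotated matrix, with attributes `rotation` (the orthogonal
#'   matrix R such that `rotated = loadings %*% R` up to column
#'   permutation/sign), `criterion` and `converged`.
#' @export
varimax_rotate <- function(loadings, tol = 1e-8, max_iter = 1000L,
                           normalize = FALSE) {
  L0 <- as.matrix(loadings)
  p <- nrow(L0); k <- ncol(L0)
  if (k < 1L) stop("loadings must have at least one column")
  if (k == 1L) {
    out <- .fix_signs(L0)
    attr(out, "rotation") <- diag(1)
    attr(out, "criterion") <- varimax_criterion(out)
    attr(out, "converged") <- TRUE
    return(out)
  }
  sc <- rep(1, p)
  if (normalize) {
    sc <- sqrt(rowSums(L0^2))
    sc[sc == 0] <- 1
  }
  L <- L0 / sc
  R <- diag(k)
  d_old <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    z <- (L0 / sc) %*% R
    B <- crossprod(L0 / sc, z^3 - z %*% diag(colMeans(z^2), k))
    s <- La.svd(B)
    R <- s$u %*% s$vt
    d <- sum(s$d)
    if (d < d_old * (1 + tol)) { converged <- TRUE; break }
    d_old <- d
  }
  if (!converged) warning("varimax rotation did not converge in ",
                          max_iter, " iterations")
  z <- ((L0 / sc) %*% R) * sc
  ord <- order(-colSums(z^2))
  z <- .fix_signs(z[, ord, drop = FALSE])
  colnames(z) <- paste0("RC", seq_len(k))
  rownames(z) <- rownames(L0)
  attr(z, "rotation") <- R[, ord, drop = FALSE]
  attr(z, "criterion") <- varimax_criterion(z)
  attr(z, "converged") <- converged
  z
}

#' Elbow rule for the number of components
#'
#' Selects k as the scree-curve point with the largest perpendicular
#' distance to the straight line joining the first and last points of the
#' explained-variance-ratio curve. The choice is advisory; callers may
#' override it. A flat (linear) scree is degenerate for this rule; the
#' result then carries attribute `degenerate = TRUE` and k = 1.
#'
#' @param explained_variance_ratio non-increasing ratios, length >= 3.
#' @return Integer k.
#' @export
select_k_elbow <- function(explained_variance_ratio) {
  r <- as.numeric(explained_variance_ratio)
  n <- length(r)
  stopifnot(n >= 3L)
  x <- seq_len(n)
  # distance from (x_i, r_i) to line through (1, r_1) and (n, r_n)
  dx <- n - 1; dy <- r[n] - r[1]
  d <- abs(dy * x - dx * r + dx * r[1] - dy) / sqrt(dx^2 + dy^2)
  if (max(d) < 1e-10) {
    return(structure(1L, degenerate = TRUE))
  }
  as.integer(which.max(d))
}

#' Principal component analysis of a feature matrix
#'
#' Standardizes every column to zero mean and unit variance (equivalently,
#' eigendecomposition of the correlation matrix -- the features carry
#' heterogeneous units), orders components by decreasing eigenvalue, fixes
#' a deterministic sign convention (largest-magnitude loading of each
#' component positive), and varimax-rotates the k retained components.
#'
#' @param X recordings x features numeric matrix or data.frame; no missing
#'   cells (drop invalid rows beforehand).
#' @param k number of components to retain and rotate; `NULL` (default)
#'   applies [select_k_elbow()].
#' @param rotate varimax-rotate the retained loadings (default `TRUE`).
#' @param normalize,tol,max_iter passed to [varimax_rotate()].
#' @return An object of class `tap_pca` with `loadings` (all components),
#'   `eigenvalues`, `explained_variance_ratio`, `k`, `rotated_loadings`,
#'   `scores`, `feature_names`, `center`, `scale`.
#' @export
tap_pca <- function(X, k = NULL, rotate = TRUE, normalize = FALSE,
                    tol = 1e-8, max_iter = 1000L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing cells; drop invalid rows first")
  if (nrow(X) < 2L || ncol(X) < 2L) stop("X must be at least 2 x 2")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  L <- .fix_signs(pc$rotation)
  scores <- scale(X, center = pc$center, scale = pc$scale) %*% L
  if (is.null(k)) k <- select_k_elbow(ratio)
  k <- max(1L, min(as.integer(k), ncol(L)))
  rotated <- if (rotate) {
    # rotate loadings scaled by sqrt(eigenvalue), the factor-analytic
    # convention that makes squared loadings variance contributions
    varimax_rotate(L[, seq_len(k), drop = FALSE] %*%
                     diag(sqrt(ev[seq_len(k)]), k),
                   tol = tol, max_iter = max_iter, normalize = normalize)
  } else L[, seq_len(k), drop = FALSE]
  structure(list(loadings = L, eigenvalues = ev,
                 explained_variance_ratio = ratio, k = k,
                 rotated_loadings = rotated, scores = scores,
                 feature_names = colnames(X),
                 center = pc$center, scale = pc$scale),
            class = "tap_pca")
}

#' @export
print.tap_pca <- function(x, ...) {
  cat("<tap_pca>", length(x$feature_names), "features,",
      x$k, "retained components\n")
  cum <- cumsum(x$explained_variance_ratio)
  cat(sprintf("  variance explained by %d components: %.1f%%\n",
              x$k, 100 * cum[x$k]))
  invisible(x)
}

#' @export
summary.tap_pca <- function(object, ...) {
  data.frame(component = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             ratio = object$explained_variance_ratio,
             cumulative = cumsum(object$explained_variance_ratio))
}

#' Scree plot
#' @param x a [tap_pca()] object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.tap_pca <- function(x, ...) {
  r <- x$explained_variance_ratio
  bp <- graphics::barplot(100 * r, names.arg = seq_along(r),
                          xlab = "component",
                          ylab = "% variance explained", ...)
  graphics::lines(bp, 100 * cumsum(r), type = "b", pch = 16)
  invisible(x)
}
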