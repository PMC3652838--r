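# Discriminant validation of a species grouping, DAPC-style: the distance
# matrix is first embedded by classical principal coordinates (a raw
# n x (n-1) distance-row design is singular for Fisher discriminants), the
# canonical axes are then the generalized eigenvectors of between- vs
# within-group scatter, and held-out samples are assigned to the nearest
# group centroid in canonical space (equal priors).

#' Principal-coordinates embedding of a distance matrix
#'
#' Classical metric scaling: double-centre the squared-distance Gram
#' matrix, eigendecompose, and keep the axes with positive eigenvalues
#' (negative-eigenvalue axes, which arise when the distances are not
#' exactly Euclidean, are dropped with a notice). Pairwise Euclidean
#' distances in the full embedding approximate the input distances.
#'
#' @param m A `pairwise_dist` with no undefined pairs, or a symmetric
#'   numeric matrix with zero diagonal.
#' @param n_components Number of axes to keep (default: all positive).
#' @param impute Replace undefined distances with the maximum defined
#'   distance instead of failing.
#' @return An object of class `pcoa_coords`: list with `ids`, `coords`
#'   (n x k matrix, columns ordered by decreasing eigenvalue),
#'   `eigenvalues` (positive ones, matching columns), `n_components`.
#' @export
distances_to_coordinates <- function(m, n_components = NULL, impute = FALSE) {
  if (inherits(m, "pairwise_dist")) {
    d <- m$d; ids <- m$ids
  } else {
    d <- as.matrix(m); ids <- rownames(d)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  }
  if (anyNA(d)) {
    if (!impute)
      stop("distance matrix has undefined pairs; set impute = TRUE to ",
           "replace them with the maximum defined distance", call. = FALSE)
    d[is.na(d)] <- max(d, na.rm = TRUE)
    diag(d) <- 0
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  if (all(d == 0)) {
    k <- max(1L, min(n_components %||% 1L, 1L))
    return(structure(list(ids = ids,
                          coords = matrix(0, n, k,
                                          dimnames = list(ids, paste0("PCo", seq_len(k)))),
                          eigenvalues = rep(0, k), n_components = k),
                     class = "pcoa_coords"))
  }
  B <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- which(eg$values > tol)
  n_neg <- sum(eg$values < -tol)
  if (n_neg > 0)
    message("dropped ", n_neg, " negative-eigenvalue axes ",
            "(non-Euclidean distances)")
  if (!length(pos)) stop("no positive eigenvalues", call. = FALSE)
  k <- if (is.null(n_components)) length(pos) else min(n_components, length(pos))
  coords <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eg$values[pos[seq_len(k)]]), k)
  dimnames(coords) <- list(ids, paste0("PCo", seq_len(k)))
  structure(list(ids = ids, coords = coords,
                 eigenvalues = eg$values[pos[seq_len(k)]], n_components = k),
            class = "pcoa_coords")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pick the number of retained axes: enough to explain `var_explained` of the
# positive-eigenvalue variance, capped so the pooled within-group scatter
# stays invertible (k <= n - g - 1).
select_components <- function(eigenvalues, n, n_groups, var_explained = 0.95) {
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  k_var <- which(cum >= var_explained)[[1L]]
  max(1L, min(k_var, n - n_groups - 1L, length(eigenvalues)))
}

#' Fit a canonical discriminant analysis on ordination scores
#'
#' Finds the linear axes maximizing between-group relative to within-group
#' variance (Fisher's generalized eigenproblem) on principal-coordinate
#' scores, giving a graphical summary of a species grouping and the basis
#' for nearest-centroid classification. The number of retained input axes
#' defaults to those explaining `var_explained` of the positive-eigenvalue
#' variance, capped at `n - n_groups - 1` so the within-group scatter is
#' invertible. Singleton groups are allowed: they contribute a centroid and
#' no within-group scatter.
#'
#' @param coords A `pcoa_coords` from [distances_to_coordinates()], or a
#'   plain numeric matrix of scores (rows = samples).
#' @param groups Group label per sample (character or factor); group order
#'   is order of first appearance.
#' @param n_components Number of input axes to use (default: automatic).
#' @param var_explained Variance fraction for the automatic rule.
#' @return An object of class `cda_fit`: list with `axes` (input-space
#'   discriminant directions), `scores` (samples x canonical axes),
#'   `centroids` (groups x canonical axes), `eigenvalues`, `groups` (factor
#'   levels), `n_components`, `grand_mean`.
#' @export
fit_cda <- function(coords, groups, n_components = NULL,
                    var_explained = 0.95) {
  X <- if (inherits(coords, "pcoa_coords")) coords$coords else as.matrix(coords)
  ev <- if (inherits(coords, "pcoa_coords")) coords$eigenvalues else
    rep(1, ncol(X))
  groups <- as.character(groups)
  if (length(groups) != nrow(X))
    stop("one group label per sample required", call. = FALSE)
  g <- factor(groups, levels = unique(groups))
  n <- nrow(X); ng <- nlevels(g)
  if (ng < 2L) stop("need at least two groups", call. = FALSE)
  if (is.null(n_components))
    n_components <- select_components(ev, n, ng, var_explained)
  n_components <- min(n_components, ncol(X))
  X <- X[, seq_len(n_components), drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  M <- apply(Xc, 2L, function(col) tapply(col, g, mean))
  M <- matrix(M, nrow = ng,
              dimnames = list(levels(g), colnames(X)))
  cnt <- as.vector(table(g))
  B <- crossprod(M * sqrt(cnt))
  W <- crossprod(Xc - M[as.integer(g), , drop = FALSE])
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R))
    stop("within-group scatter is singular; reduce n_components or merge ",
         "tiny groups", call. = FALSE)
  # W^{-1} B eigenproblem via the Cholesky factor of W (symmetric form)
  S <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)), transpose = TRUE)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  n_axes <- min(ng - 1L, n_components)
  A <- backsolve(R, eg$vectors[, seq_len(n_axes), drop = FALSE])
  colnames(A) <- paste0("CAN", seq_len(n_axes))
  scores <- Xc %*% A
  rownames(scores) <- rownames(X)
  centroids <- M %*% A
  structure(
    list(axes = A, scores = scores, centroids = centroids,
         eigenvalues = eg$values[seq_len(n_axes)], groups = levels(g),
         n_components = n_components, grand_mean = mu),
    class = "cda_fit")
}

#' @export
print.cda_fit <- function(x, ...) {
  cat("Canonical discriminant analysis: ", length(x$groups), " groups, ",
      nrow(x$scores), " samples, ", x$n_components,
      " ordination axes -> ", ncol(x$scores), " canonical axes\n", sep = "")
  cat("  leading eigenvalues: ",
      paste(sprintf("%.3g", utils::head(x$eigenvalues, 4L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.cda_fit <- function(x, xlab = "Canonical axis 1",
                         ylab = "Canonical axis 2", ...) {
  s <- x$scores
  if (ncol(s) < 2L) s <- cbind(s, 0)
  grp <- classify_cda(x, NULL)  # group of each training sample
  graphics::plot(s[, 1L], s[, 2L], col = as.integer(factor(grp, x$groups)),
                 pch = 16, xlab = xlab, ylab = ylab, ...)
  graphics::points(x$centroids[, 1L],
                   if (ncol(x$centroids) >= 2L) x$centroids[, 2L] else
                     rep(0, nrow(x$centroids)), pch = 3, cex = 1.4)
  invisible(x)
}

# Nearest-centroid assignment in canonical space (equal priors); ties break
# to the earlier group in input order. newdata = NULL classifies the
# training scores.
classify_cda <- function(fit, newdata = NULL) {
  S <- if (is.null(newdata)) fit$scores else newdata
  d2 <- outer(rowSums(S^2), rowSums(fit$centroids^2), `+`) -
    2 * S %*% t(fit$centroids)
  fit$groups[apply(d2, 1L, which.min)]
}

#' Predict group membership for new samples
#'
#' @param object A `cda_fit`.
#' @param newdata Matrix of ordination scores on the same axes the model
#'   was fitted on (at least `object$n_components` columns).
#' @param ... Unused.
#' @return Character vector of assigned group labels (nearest centroid in
#'   canonical space, equal priors).
#' @export
predict.cda_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  X <- newdata[, seq_len(object$n_components), drop = FALSE]
  S <- sweep(X, 2L, object$grand_mean) %*% object$axes
  classify_cda(object, S)
}

#' Leave-one-out cross-validated classification
#'
#' For each sample, the discriminant analysis is refitted on the remaining
#' n - 1 samples and the held-out sample is assigned to the nearest group
#' centroid in canonical space. Singleton groups can only be misclassified
#' (their only member leaves no trace in the training set).
#'
#' @inheritParams fit_cda
#' @return An object of class `loocv_report`: list with `confusion`
#'   (true groups x predicted groups count matrix), `per_group_correct_pct`,
#'   `overall_correct_pct`, `n`, `failed_folds`.
#' @export
loocv_classify <- function(coords, groups, n_components = NULL,
                           var_explained = 0.95) {
  X <- if (inherits(coords, "pcoa_coords")) coords$coords else as.matrix(coords)
  ev <- if (inherits(coords, "pcoa_coords")) coords$eigenvalues else
    rep(1, ncol(X))
  groups <- as.character(groups)
  lev <- unique(groups)
  n <- nrow(X)
  predicted <- rep(NA_character_, n)
  failed <- integer(0L)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fit <- tryCatch(
      fit_cda(structure(list(coords = X[tr, , drop = FALSE],
                             eigenvalues = ev,
                             ids = rownames(X)[tr],
                             n_components = ncol(X)),
                        class = "pcoa_coords"),
              groups[tr], n_components = n_components,
              var_explained = var_explained),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- c(failed, i); next }
    predicted[[i]] <- predict(fit, X[i, , drop = FALSE])
  }
  used <- !is.na(predicted)
  confusion <- table(true = factor(groups[used], lev),
                     predicted = factor(predicted[used], lev))
  per_group <- 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  structure(
    list(confusion = unclass(confusion),
         per_group_correct_pct = per_group,
         overall_correct_pct = overall, n = sum(used),
         failed_folds = failed),
    class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat("Leave-one-out cross-validation: ", x$n, " samples, ",
      nrow(x$confusion), " groups\n", sep = "")
  cat(sprintf("  overall correct: %.1f%%\n", x$overall_correct_pct))
  if (length(x$failed_folds))
    cat("  failed folds: ", length(x$failed_folds), "\n", sep = "")
  wrong <- which(x$confusion > 0 & row(x$confusion) != col(x$confusion),
                 arr.ind = TRUE)
  if (nrow(wrong))
    for (k in seq_len(nrow(wrong)))
      cat("  ", rownames(x$confusion)[wrong[k, 1L]], " -> ",
          colnames(x$confusion)[wrong[k, 2L]], ": ",
          x$confusion[wrong[k, , drop = FALSE]], "\n", sep = "")
  invisible(x)
}

#' Write a LOOCV confusion matrix as TSV (groups x groups + totals)
#' @param report A `loocv_report`.
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_loocv_report <- function(report, path) {
  cm <- report$confusion
  df <- data.frame(group = rownames(cm), as.data.frame.matrix(cm),
                   total = rowSums(cm),
                   pct_correct = sprintf("%.1f", report$per_group_correct_pct),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
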