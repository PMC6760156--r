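complete_case_features <- function(table) {
  feats <- feature_columns(table)
  X <- as.matrix(table[feats])
  keep_rows <- stats::complete.cases(X)
  X <- X[keep_rows, , drop = FALSE]
  const <- apply(X, 2L, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning(sprintf("dropping %d constant feature column(s): %s",
                    sum(const), paste(colnames(X)[const], collapse = ", ")),
            call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  list(X = X, subject_id = table$subject_id[keep_rows],
       excluded = table$subject_id[!keep_rows], dropped = feats[const])
}

# orient each column of a rotation/score pair so the largest-|loading|
# feature loads positively (reproducible sign convention)
orient_axes <- function(loadings, scores) {
  for (k in seq_len(ncol(loadings))) {
    f <- which.max(abs(loadings[, k]))
    if (loadings[f, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Correlation-matrix PCA of a feature table with joint retention rule
#'
#' Feature columns are centred and scaled (so the decomposition is of the
#' correlation matrix); subjects with any missing feature are excluded
#' (complete-case, as for the discriminant analysis); constant columns are
#' dropped with a warning.  Components are retained if their eigenvalue
#' exceeds 1 (Kaiser rule), truncated at the smallest leading set whose
#' cumulative variance share exceeds 80%.
#'
#' @param table Feature table from [compute_feature_table()].
#' @param var_share Cumulative variance threshold (default 0.80).
#' @return A `tooth_pca` object: `eigenvalues`, `loadings`
#'   (feature x component), `scores` (subject x component, rownames =
#'   subject ids), `retained` (integer indices), `cum_share`,
#'   `excluded_subjects`, `dropped_columns`.
#' @export
pca_fit <- function(table, var_share = 0.80) {
  cc <- complete_case_features(table)
  if (ncol(cc$X) < 2L) stop("need at least 2 non-constant feature columns", call. = FALSE)
  pr <- stats::prcomp(cc$X, center = TRUE, scale. = TRUE)
  eig <- pr$sdev^2
  cum <- cumsum(eig) / sum(eig)
  k_eig <- sum(eig > 1)
  k_cum <- which(cum > var_share)[1]
  k <- max(1L, min(k_eig, k_cum))
  o <- orient_axes(pr$rotation, pr$x)
  rownames(o$scores) <- cc$subject_id
  structure(list(eigenvalues = eig, loadings = o$loadings, scores = o$scores,
                 retained = seq_len(k), cum_share = cum,
                 excluded_subjects = cc$excluded, dropped_columns = cc$dropped),
            class = "tooth_pca")
}

#' Per-component group contrasts against the neurotypical reference
#'
#' For each retained principal component, fits an ordinary linear model of
#' the component score on diagnosis with TD as reference, giving one
#' beta/p-value per contrast (ADHD, ASD, COMORBID vs TD).
#'
#' @param pca A `tooth_pca` from [pca_fit()].
#' @param subjects Subject table (must contain all four diagnosis classes
#'   among the scored subjects).
#' @return A data frame: `component`, `contrast`, `beta`, `se`, `p`.
#' @export
component_group_tests <- function(pca, subjects) {
  dx <- subjects$diagnosis[match(rownames(pca$scores), subjects$subject_id)]
  dx <- factor(dx, levels = c("TD", "ADHD", "ASD", "COMORBID"))
  if (any(table(dx) == 0)) {
    stop("inestimable contrast: a diagnosis class is absent", call. = FALSE)
  }
  out <- list()
  for (k in pca$retained) {
    fit <- stats::lm(pca$scores[, k] ~ dx)
    cf <- summary(fit)$coefficients
    for (lvl in c("ADHD", "ASD", "COMORBID")) {
      rn <- paste0("dx", lvl)
      out[[length(out) + 1L]] <- data.frame(
        component = k, contrast = lvl,
        beta = cf[rn, "Estimate"], se = cf[rn, "Std. Error"],
        p = cf[rn, "Pr(>|t|)"], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fisher linear discriminant analysis of the feature table
#'
#' Complete-case 4-class LDA: subjects missing any feature are excluded;
#' the pooled within-class covariance is shrunk toward its diagonal with a
#' fixed small coefficient (the feature count is comparable to the subject
#' count in cohorts of this kind, so the raw pooled covariance can be
#' singular), and the discriminant directions are the leading generalized
#' eigenvectors of the between-class scatter in the within-class metric,
#' with class priors proportional to observed class sizes.  Scores are
#' scaled to unit within-class variance and are uncorrelated in the
#' within-class metric; each axis is oriented so its largest-|correlation|
#' feature loads positively.
#'
#' @param table Feature table from [compute_feature_table()].
#' @param subjects Subject table with `diagnosis`.
#' @param lambda Diagonal shrinkage coefficient for the within-class
#'   covariance (default 1e-4).
#' @param n_axes Number of discriminant axes; default `classes - 1` (3).
#' @return A `tooth_lda` object: `scores` (subject x axis, rownames =
#'   subject ids), `class_means` (class x axis), `axes` (feature x axis
#'   discriminant directions), `eigenvalues` (between/within variance
#'   ratios), `classes`, `excluded_subjects`, `features`.
#' @export
lda_fit <- function(table, subjects, lambda = 1e-4, n_axes = NULL) {
  cc <- complete_case_features(table)
  dx <- subjects$diagnosis[match(cc$subject_id, subjects$subject_id)]
  classes <- intersect(c("TD", "ADHD", "ASD", "COMORBID"), unique(dx))
  classes <- c(classes, setdiff(unique(dx), classes))
  counts <- table(factor(dx, levels = classes))
  if (any(counts < 2L)) {
    stop(sprintf("class '%s' retains fewer than 2 subjects after complete-case exclusion",
                 names(counts)[which(counts < 2L)[1]]), call. = FALSE)
  }
  X <- cc$X
  n <- nrow(X); g <- length(classes)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  W <- matrix(0, ncol(X), ncol(X))
  M <- matrix(0, g, ncol(X), dimnames = list(classes, colnames(X)))
  for (cl in classes) {
    Xi <- Xc[dx == cl, , drop = FALSE]
    M[cl, ] <- colMeans(Xi)
    Xi <- sweep(Xi, 2L, M[cl, ])
    W <- W + crossprod(Xi)
  }
  W <- W / (n - g)
  B <- crossprod(M * sqrt(as.numeric(counts))) / n  # priors = class proportions
  Ws <- (1 - lambda) * W + lambda * diag(diag(W))
  U <- chol(Ws)
  # symmetric whitened between-class scatter: U^-T B U^-1
  K <- backsolve(U, t(backsolve(U, t(B), transpose = TRUE)), transpose = TRUE)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  n_axes <- n_axes %||% (g - 1L)
  A <- backsolve(U, e$vectors[, seq_len(n_axes), drop = FALSE])
  rownames(A) <- colnames(X)
  scores <- Xc %*% A
  # orient each axis so its largest-|correlation| feature loads positively
  L0 <- stats::cor(X, scores)
  for (k in seq_len(n_axes)) {
    f <- which.max(abs(L0[, k]))
    if (L0[f, k] < 0) {
      scores[, k] <- -scores[, k]
      A[, k] <- -A[, k]
    }
  }
  colnames(scores) <- colnames(A) <- paste0("LD", seq_len(n_axes))
  rownames(scores) <- cc$subject_id
  cm <- apply(scores, 2L, function(s) tapply(s, factor(dx, levels = classes), mean))
  structure(list(scores = scores, class_means = cm, axes = A,
                 eigenvalues = e$values[seq_len(n_axes)], classes = classes,
                 class_of = stats::setNames(dx, cc$subject_id),
                 excluded_subjects = cc$excluded, features = colnames(X)),
            class = "tooth_lda")
}

#' Standardized LDA loadings: feature-axis correlations
#'
#' The loading of feature `f` on axis `k` is the Pearson correlation between
#' the raw feature column (over the complete cases used in the fit) and the
#' subjects' scores on that axis — a scale-free measure of variable
#' importance bounded in \[-1, 1\].
#'
#' @param fit A `tooth_lda` from [lda_fit()].
#' @param table The feature table the fit was computed from.
#' @return A feature x axis matrix of correlations; features with zero
#'   variance among complete cases get `NA` rows (with a warning).
#' @export
lda_loadings <- function(fit, table) {
  rows <- match(rownames(fit$scores), table$subject_id)
  feats <- feature_columns(table)
  X <- as.matrix(table[rows, feats, drop = FALSE])
  L <- matrix(NA_real_, length(feats), ncol(fit$scores),
              dimnames = list(feats, colnames(fit$scores)))
  sds <- apply(X, 2L, stats::sd)
  ok <- is.finite(sds) & sds > 0
  if (any(!ok)) {
    warning(sprintf("zero-variance feature(s) among complete cases: %s",
                    paste(feats[!ok], collapse = ", ")), call. = FALSE)
  }
  L[ok, ] <- stats::cor(X[, ok, drop = FALSE], fit$scores)
  L
}

#' Classify scored subjects by nearest class mean in discriminant space
#'
#' Reclassification of the training subjects (no cross-validation is
#' implied): each subject is assigned the class whose mean is nearest in the
#' discriminant score space.
#'
#' @param fit A `tooth_lda`.
#' @return Named character vector of assigned classes.
#' @export
lda_classify <- function(fit) {
  d2 <- sapply(seq_len(nrow(fit$class_means)), function(i) {
    rowSums(sweep(fit$scores, 2L, fit$class_means[i, ])^2)
  })
  stats::setNames(rownames(fit$class_means)[max.col(-d2)], rownames(fit$scores))
}
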