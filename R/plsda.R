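#' Construct a spectral dataset
#'
#' A labelled matrix of preprocessed spectra sharing one wavenumber axis:
#' the unit of PLS-DA model fitting and cross-validation.
#'
#' @param matrix Numeric matrix, `n_samples x n_features`.
#' @param labels Character vector of class names, one per row.
#' @param axis Shared wavenumber axis, one value per column.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(matrix, labels, axis) {
  matrix <- as.matrix(matrix)
  labels <- as.character(labels)
  if (nrow(matrix) != length(labels)) {
    stop("one label per spectrum required", call. = FALSE)
  }
  if (ncol(matrix) != length(axis)) {
    stop("axis length must equal the number of features", call. = FALSE)
  }
  structure(list(matrix = matrix, labels = labels, axis = as.numeric(axis)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d wavenumbers; classes: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s (%d)", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

# NIPALS PLS2 on centered X against centered one-hot Y.
# Returns weights W, loadings P, Y-loadings Q (n_classes x a), scores T.
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); k <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, k, ncomp); Tm <- matrix(0, n, ncomp)
  for (h in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      wn <- sqrt(sum(w^2))
      if (wn < tol) break
      w <- w / wn
      t <- drop(X %*% w)
      q <- drop(crossprod(Y, t)) / sum(t^2)
      u <- drop(Y %*% q) / sum(q^2)
      if (sum((t - t_old)^2) < tol * sum(t^2)) break
      t_old <- t
    }
    pvec <- drop(crossprod(X, t)) / sum(t^2)
    X <- X - tcrossprod(t, pvec)
    Y <- Y - tcrossprod(t, q)
    W[, h] <- w; P[, h] <- pvec; Q[, h] <- q; Tm[, h] <- t
  }
  list(W = W, P = P, Q = Q, T = Tm)
}

#' Fit a PLS-DA classification model
#'
#' One-hot encodes the class labels and fits a PLS2 regression of the
#' indicator matrix on the mean-centered spectra via NIPALS: successive
#' orthogonal latent variables maximizing covariance between spectra and
#' class indicators. Features are mean-centered, not variance-scaled, by
#' default (spectra are already normalized); set `scale = TRUE` for
#' autoscaling.
#'
#' @param data A [spectral_dataset()] with >= 2 classes and >= 2 samples
#'   per class.
#' @param n_components Number of latent variables (default 2, the pair
#'   conventionally plotted as LV1/LV2).
#' @param scale Autoscale features to unit variance before fitting.
#' @param positive_class Class treated as the "positive"/lesion class for
#'   thresholded margin work; defaults to the first class name.
#' @param threshold Decision threshold in `[0, 1]` applied to the positive
#'   class response (default 0.5); adjustable post hoc via
#'   `model$threshold`.
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(data, n_components = 2L, scale = FALSE,
                      positive_class = NULL, threshold = 0.5) {
  stopifnot(inherits(data, "spectral_dataset"))
  classes <- sort(unique(data$labels))
  if (length(classes) < 2L) {
    stop("PLS-DA needs at least two classes", call. = FALSE)
  }
  if (any(table(data$labels) < 2L)) {
    stop("PLS-DA needs at least two samples per class", call. = FALSE)
  }
  n <- nrow(data$matrix); p <- ncol(data$matrix)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, p)) {
    stop(sprintf("n_components must lie in [1, %d]", min(n - 1L, p)),
         call. = FALSE)
  }
  if (is.null(positive_class)) positive_class <- classes[1]
  if (!positive_class %in% classes) {
    stop("positive_class must be one of the data's classes", call. = FALSE)
  }
  Y <- outer(data$labels, classes, `==`) * 1
  colnames(Y) <- classes
  x_center <- colMeans(data$matrix)
  x_scale <- if (scale) {
    s <- apply(data$matrix, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  X <- sweep(sweep(data$matrix, 2, x_center), 2, x_scale, `/`)
  y_center <- colMeans(Y)
  fit <- nipals_pls2(X, sweep(Y, 2, y_center), n_components)
  # regression coefficients and score rotation in the original X space
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B <- R %*% t(fit$Q)
  structure(
    list(n_components = n_components, class_names = classes,
         x_weights = fit$W, x_loadings = fit$P, y_loadings = fit$Q,
         scores = fit$T, rotation = R, coefficients = B,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         axis = data$axis, positive_class = positive_class,
         threshold = threshold, scaled = scale),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "<plsda_model> %d latent variables, classes: %s (positive: %s, threshold %.2f)\n",
    x$n_components, paste(x$class_names, collapse = ", "),
    x$positive_class, x$threshold))
  invisible(x)
}

# Continuous per-class responses for a matrix of spectra on the model axis.
plsda_responses <- function(model, m) {
  X <- sweep(sweep(m, 2, model$x_center), 2, model$x_scale, `/`)
  resp <- sweep(X %*% model$coefficients, 2, model$y_center, `+`)
  colnames(resp) <- model$class_names
  resp
}

#' Predict the class of a spectrum
#'
#' Computes the model's continuous per-class responses, assigns the label
#' by argmax, and flags the acquisition as positive when the response of
#' the designated positive class meets the decision threshold. Lowering
#' the threshold can only turn negatives into positives, never the
#' reverse.
#'
#' @param object A [plsda_model()].
#' @param newdata A [raman_spectrum()] on the model's axis, or a numeric
#'   matrix with one spectrum per row.
#' @param threshold Optional threshold override (defaults to the model's).
#' @param ... Unused.
#' @return For a single spectrum, a `diagnosis` list with `label`,
#'   `scores` (named per-class responses) and `positive`; for a matrix, a
#'   data frame with one row per spectrum.
#' @export
predict.plsda_model <- function(object, newdata, threshold = NULL, ...) {
  if (is.null(threshold)) threshold <- object$threshold
  single <- inherits(newdata, "raman_spectrum")
  if (single) {
    if (length(newdata$wavenumbers) != length(object$axis) ||
        any(abs(newdata$wavenumbers - object$axis) > 1e-6)) {
      stop("spectrum axis does not match the model axis", call. = FALSE)
    }
    m <- matrix(newdata$intensities, nrow = 1)
  } else {
    m <- as.matrix(newdata)
    if (ncol(m) != length(object$axis)) {
      stop("feature count does not match the model axis", call. = FALSE)
    }
  }
  resp <- plsda_responses(object, m)
  labels <- object$class_names[max.col(resp, ties.method = "first")]
  positive <- resp[, object$positive_class] >= threshold
  if (single) {
    structure(list(label = labels[1],
                   scores = stats::setNames(resp[1, ], object$class_names),
                   positive = unname(positive[1])),
              class = "diagnosis")
  } else {
    data.frame(label = labels,
               score = unname(resp[, object$positive_class]),
               positive = unname(positive),
               stringsAsFactors = FALSE)
  }
}

#' Venetian-blinds fold assignment
#'
#' Fold of sample `i` (1-based, dataset order) is `((i - 1) %% n_splits) + 1`:
#' every `n_splits`-th sample shares a fold. A pure function of the index,
#' reproducible without seeds.
#'
#' @param n_samples,n_splits Integers.
#' @return Integer vector of fold ids in `1..n_splits`.
#' @export
venetian_folds <- function(n_samples, n_splits) {
  ((seq_len(n_samples) - 1L) %% as.integer(n_splits)) + 1L
}

#' Venetian-blinds cross-validation of a PLS-DA model
#'
#' For each fold the model is refit excluding the fold and evaluated on
#' it (argmax label); accuracies are aggregated over all samples.
#'
#' @inheritParams fit_plsda
#' @param n_splits Number of interleaved folds (default 10, automatically
#'   reduced to the smallest class size if that is smaller).
#' @return List with `overall_accuracy` (fraction), `per_class_accuracy`,
#'   `confusion` (rows = truth, columns = prediction), `predicted`,
#'   `n_splits` used.
#' @export
venetian_blinds_cv <- function(data, n_components = 2L, n_splits = 10L,
                               scale = FALSE) {
  stopifnot(inherits(data, "spectral_dataset"))
  n <- nrow(data$matrix)
  n_splits <- as.integer(n_splits)
  if (n_splits < 2L) stop("n_splits must be >= 2", call. = FALSE)
  if (n_splits > n) stop("n_splits exceeds the number of samples", call. = FALSE)
  smallest <- min(table(data$labels))
  if (n_splits > smallest) n_splits <- max(2L, as.integer(smallest))
  folds <- venetian_folds(n, n_splits)
  classes <- sort(unique(data$labels))
  predicted <- character(n)
  for (f in seq_len(n_splits)) {
    idx <- folds == f
    train <- spectral_dataset(data$matrix[!idx, , drop = FALSE],
                              data$labels[!idx], data$axis)
    model <- fit_plsda(train, n_components = n_components, scale = scale)
    resp <- plsda_responses(model, data$matrix[idx, , drop = FALSE])
    predicted[idx] <- model$class_names[max.col(resp, ties.method = "first")]
  }
  confusion <- table(truth = factor(data$labels, classes),
                     predicted = factor(predicted, classes))
  per_class <- diag(confusion) / rowSums(confusion)
  list(overall_accuracy = mean(predicted == data$labels),
       per_class_accuracy = per_class,
       confusion = confusion,
       predicted = predicted,
       n_splits = n_splits)
}

#' PCA scores of a spectral dataset
#'
#' Mean-centered principal component analysis, used to discriminate the
#' strongly fluorescent phantom class whose broad background dominates
#' total variance.
#'
#' @param data A [spectral_dataset()].
#' @param n_pcs Number of components, `<= min(n_samples - 1, n_features)`.
#' @return List with `scores` (`n_samples x n_pcs`), `explained_variance`
#'   (fractions, non-increasing, summing to <= 1) and `labels`.
#' @export
pca_scores <- function(data, n_pcs = 2L) {
  stopifnot(inherits(data, "spectral_dataset"))
  n_pcs <- as.integer(n_pcs)
  n <- nrow(data$matrix); p <- ncol(data$matrix)
  if (n_pcs < 1L || n_pcs > min(n - 1L, p)) {
    stop(sprintf("n_pcs must lie in [1, %d]", min(n - 1L, p)), call. = FALSE)
  }
  pc <- stats::prcomp(data$matrix, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       explained_variance = ev[seq_len(n_pcs)],
       labels = data$labels)
}
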