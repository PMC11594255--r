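#' Principal component analysis of a bucket table
#'
#' Columns are mean-centered (no unit-variance scaling: bucket intensities
#' share a scale, and scaling would inflate noise bins). The basis comes
#' from the singular value decomposition; the retained dimension is the
#' smallest component count whose cumulative explained variance reaches
#' `variance_threshold`, capped at `min(n_samples - 1, n_bins)`.
#'
#' @param table A `bucket_table`, or a plain numeric matrix (samples x
#'   variables).
#' @param variance_threshold Cumulative explained-variance fraction in
#'   (0, 1] (default 0.95).
#' @return List with `column_means`, `pca_basis` (columns = orthonormal
#'   loadings), `n_pcs`, `explained_variance` (all-component fractions),
#'   and `scores` (training projections on the retained components).
#' @export
fit_pca <- function(table, variance_threshold = 0.95) {
  x <- if (inherits(table, "bucket_table")) table$values else as.matrix(table)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 1L,
            variance_threshold > 0, variance_threshold <= 1)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  ev <- sv$d^2
  total <- sum(ev)
  if (total <= 0) stop("bucket table has zero total variance", call. = FALSE)
  frac <- ev / total
  cap <- min(nrow(x) - 1L, ncol(x))
  n_pcs <- min(which(cumsum(frac) >= variance_threshold - 1e-12)[1L], cap)
  basis <- fix_signs(sv$v[, seq_len(n_pcs), drop = FALSE])
  list(column_means = mu,
       pca_basis = basis,
       n_pcs = n_pcs,
       explained_variance = frac,
       scores = xc %*% basis)
}

# Deterministic sign convention: largest-magnitude coefficient positive.
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Canonical discriminant analysis with MANOVA dimension selection
#'
#' Solves the generalized eigenproblem of between-class versus within-class
#' scatter on PC scores. Directions are normalized to unit within-class
#' variance (a' Sw a = 1 with Sw the pooled within-class covariance), so
#' Euclidean distance in canonical space is the Mahalanobis distance of the
#' within-class metric. The retained dimension is chosen by sequential
#' MANOVA tests on residual Wilks' lambda using the Bartlett chi-square
#' approximation: dimension k is retained while the test of "no separation
#' beyond the first k directions" rejects at `alpha`.
#'
#' @param scores Numeric matrix, samples x PCs.
#' @param labels Class labels (character or factor), one per row.
#' @param alpha Significance level for the sequential tests (default 0.05).
#' @return List with `canonical_basis` (PC-space direction columns),
#'   `n_canonical` (0 if even the first test fails to reject, with a
#'   warning), `class_centers` (classes x dims, all directions),
#'   `manova_pvalues`, `eigenvalues`, and `class_labels`.
#' @export
fit_canonical <- function(scores, labels, alpha = 0.05) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels), ncol(scores) >= 1L)
  classes <- sort(unique(labels))
  g <- length(classes)
  if (g < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every class needs >= 2 samples (got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")",
         call. = FALSE)
  }
  n <- nrow(scores); p <- ncol(scores)
  grand <- colMeans(scores)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  centers_raw <- matrix(NA_real_, g, p, dimnames = list(classes, NULL))
  for (ci in seq_along(classes)) {
    xi <- scores[labels == classes[ci], , drop = FALSE]
    mu <- colMeans(xi)
    centers_raw[ci, ] <- mu
    xc <- sweep(xi, 2L, mu)
    W <- W + crossprod(xc)
    B <- B + nrow(xi) * tcrossprod(mu - grand)
  }
  eW <- eigen(W, symmetric = TRUE)
  ev <- eW$values
  if (ev[1L] <= 0 || ev[1L] / max(ev[p], 0) > 1e10 || ev[p] <= 0) {
    warning("within-class scatter ill-conditioned; ridge-regularizing",
            call. = FALSE)
    W <- W + 1e-6 * (sum(diag(W)) / p) * diag(p)
    eW <- eigen(W, symmetric = TRUE)
    ev <- eW$values
  }
  Wih <- eW$vectors %*% (t(eW$vectors) / sqrt(ev))  # W^{-1/2}
  eB <- eigen(Wih %*% B %*% Wih, symmetric = TRUE)
  s <- min(p, g - 1L)
  lambda <- pmax(eB$values[seq_len(s)], 0)          # eigenvalues of W^{-1} B
  # directions scaled so a' (W/(n-g)) a = 1
  A <- fix_signs(Wih %*% eB$vectors[, seq_len(s), drop = FALSE] * sqrt(n - g))

  # sequential Bartlett tests on residual Wilks' lambda
  pvals <- numeric(s)
  for (k in seq_len(s) - 1L) {
    chi <- (n - 1 - (p + g) / 2) * sum(log1p(lambda[(k + 1L):s]))
    df <- (p - k) * (g - 1L - k)
    pvals[k + 1L] <- stats::pchisq(chi, df, lower.tail = FALSE)
  }
  n_canonical <- 0L
  for (k in seq_len(s)) {
    if (pvals[k] < alpha) n_canonical <- k else break
  }
  if (n_canonical == 0L) {
    warning("no significant canonical dimension at alpha = ", alpha,
            call. = FALSE)
  }
  centers <- sweep(centers_raw, 2L, grand) %*% A
  list(canonical_basis = A, n_canonical = n_canonical,
       class_centers = centers, manova_pvalues = pvals,
       eigenvalues = lambda, class_labels = classes)
}

#' Fit the full fingerprint model (PCA + canonical analysis)
#'
#' @param table A `bucket_table` or numeric matrix (samples x bins).
#' @param labels Class labels aligned to rows.
#' @param variance_threshold PCA retention threshold (see [fit_pca()]).
#' @param alpha MANOVA significance level (see [fit_canonical()]).
#' @param rule Classification rule: `"nearest_center"` (distance to class
#'   center in canonical space, the default) or `"knn"` (majority vote of
#'   the `k` nearest training projections).
#' @param k Neighbor count for the knn rule (default 5).
#' @param min_dim Minimum canonical dimension used for classification even
#'   when the MANOVA selects none (default 1; a discriminant rule needs at
#'   least one axis).
#' @return A `fingerprint_model`.
#' @export
fit_fingerprint <- function(table, labels, variance_threshold = 0.95,
                            alpha = 0.05, rule = c("nearest_center", "knn"),
                            k = 5L, min_dim = 1L) {
  rule <- match.arg(rule)
  x <- if (inherits(table, "bucket_table")) table$values else as.matrix(table)
  labels <- as.character(labels)
  pca <- fit_pca(x, variance_threshold)
  ca <- fit_canonical(pca$scores, labels, alpha)
  dim_use <- max(ca$n_canonical, min(min_dim, ncol(ca$canonical_basis)))
  proj <- pca$scores %*% ca$canonical_basis[, seq_len(dim_use), drop = FALSE]
  structure(
    list(column_means = pca$column_means,
         pca_basis = pca$pca_basis, n_pcs = pca$n_pcs,
         explained_variance = pca$explained_variance,
         canonical_basis = ca$canonical_basis,
         n_canonical = ca$n_canonical, dim_use = dim_use,
         manova_pvalues = ca$manova_pvalues,
         class_centers = ca$class_centers[, seq_len(dim_use), drop = FALSE],
         class_labels = ca$class_labels,
         rule = rule, k = as.integer(k),
         training_projections = proj, training_labels = labels),
    class = "fingerprint_model"
  )
}

#' @export
print.fingerprint_model <- function(x, ...) {
  cat(sprintf(paste0("<fingerprint_model> %d classes (%s); %d PCs; ",
                     "%d significant canonical dim(s), %d used; rule = %s\n"),
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              x$n_pcs, x$n_canonical, x$dim_use, x$rule))
  invisible(x)
}

project_samples <- function(x, model) {
  if (inherits(x, "bucket_table")) {
    x <- x$values
  } else if (!is.matrix(x)) {
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != length(model$column_means)) {
    stop("sample dimensionality (", ncol(x), ") does not match model (",
         length(model$column_means), ")", call. = FALSE)
  }
  sweep(x, 2L, model$column_means) %*% model$pca_basis %*%
    model$canonical_basis[, seq_len(model$dim_use), drop = FALSE]
}

#' Classify samples with a fitted fingerprint model
#'
#' New samples are centered with the training means, projected through the
#' PCA then canonical bases, and assigned by the model's rule. Ties (equal
#' distances or split votes) are broken by class-label lexicographic order
#' and flagged.
#'
#' @param x A bin vector, a samples x bins matrix, or a `bucket_table`.
#' @param model A `fingerprint_model`.
#' @return Data frame with `label`, `tie`, one distance (nearest_center) or
#'   vote-share (knn) column per class, and the canonical coordinates.
#' @export
classify_samples <- function(x, model) {
  stopifnot(inherits(model, "fingerprint_model"))
  proj <- project_samples(x, model)
  classes <- model$class_labels
  if (model$rule == "nearest_center") {
    d <- vapply(seq_along(classes), function(ci) {
      sqrt(rowSums(sweep(proj, 2L, model$class_centers[ci, ])^2))
    }, numeric(nrow(proj)))
    d <- matrix(d, nrow = nrow(proj),
                dimnames = list(NULL, paste0("dist_", classes)))
    best <- apply(d, 1L, which.min)          # which.min = first (lexicographic) on ties
    tie <- apply(d, 1L, function(r) sum(r <= min(r) + 1e-12) > 1L)
    score <- d
  } else {
    k <- min(model$k, nrow(model$training_projections))
    share <- matrix(0, nrow(proj), length(classes),
                    dimnames = list(NULL, paste0("vote_", classes)))
    for (i in seq_len(nrow(proj))) {
      dd <- sqrt(colSums((t(model$training_projections) - proj[i, ])^2))
      nb <- model$training_labels[order(dd)[seq_len(k)]]
      tab <- table(factor(nb, levels = classes))
      share[i, ] <- as.numeric(tab) / k
    }
    best <- apply(share, 1L, which.max)
    tie <- apply(share, 1L, function(r) sum(r >= max(r) - 1e-12) > 1L)
    score <- share
  }
  out <- data.frame(label = classes[best], tie = tie, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(score), as.data.frame(proj) |>
          stats::setNames(paste0("can", seq_len(ncol(proj)))))
}

#' Monte-Carlo cross-validation of the fingerprint classifier
#'
#' Per iteration: a stratified random split holds out `test_fraction` of
#' each class, the whole model (centering, PCA, canonical analysis) is
#' refit on the training portion only, held-out samples are classified, and
#' truth x assignment counts are pooled over iterations. Splits that leave
#' a class with fewer than 2 training samples are redrawn (and counted).
#'
#' @param table A `bucket_table` or numeric matrix.
#' @param labels Class labels aligned to rows.
#' @param n_iterations Number of random splits (default 500).
#' @param test_fraction Held-out fraction per class in (0, 1) (default 0.2).
#' @param variance_threshold,alpha,rule,k,min_dim Passed to
#'   [fit_fingerprint()].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A `confusion_matrix` object (see [confusion_matrix()]) with
#'   attributes `n_redraws` and `iteration_records` (per-iteration correct
#'   counts).
#' @export
mccv <- function(table, labels, n_iterations = 500L, test_fraction = 0.2,
                 variance_threshold = 0.95, alpha = 0.05,
                 rule = c("nearest_center", "knn"), k = 5L, min_dim = 1L,
                 seed = 1L) {
  rule <- match.arg(rule)
  x <- if (inherits(table, "bucket_table")) table$values else as.matrix(table)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), test_fraction > 0, test_fraction < 1)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs >= 2 samples", call. = FALSE)
  if (all(counts <= 2L)) {
    stop("no class can spare a held-out sample (all classes have <= 2)",
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(truth = classes, assigned = classes))
  redraws <- 0L
  records <- data.frame(iteration = seq_len(n_iterations), n_test = NA_integer_,
                        n_correct = NA_integer_)
  idx_by_class <- split(seq_along(labels), labels)
  for (it in seq_len(n_iterations)) {
    repeat {
      test_idx <- unlist(lapply(idx_by_class, function(ix) {
        n_test <- max(1L, round(length(ix) * test_fraction))
        n_test <- min(n_test, length(ix) - 2L)  # keep >= 2 in training
        if (n_test < 1L) integer(0) else sample(ix, n_test)
      }), use.names = FALSE)
      train_lab <- labels[-test_idx]
      if (all(table(factor(train_lab, levels = classes)) >= 2L) &&
          length(test_idx) >= 1L) break
      redraws <- redraws + 1L
    }
    fit <- suppressWarnings(fit_fingerprint(
      x[-test_idx, , drop = FALSE], labels[-test_idx],
      variance_threshold = variance_threshold, alpha = alpha,
      rule = rule, k = k, min_dim = min_dim))
    pred <- classify_samples(x[test_idx, , drop = FALSE], fit)$label
    truth <- labels[test_idx]
    for (j in seq_along(test_idx)) {
      cm[truth[j], pred[j]] <- cm[truth[j], pred[j]] + 1L
    }
    records$n_test[it] <- length(test_idx)
    records$n_correct[it] <- sum(pred == truth)
  }
  out <- confusion_matrix(cm)
  attr(out, "n_redraws") <- redraws
  attr(out, "iteration_records") <- records
  out
}

#' Construct a confusion matrix with row-normalized proportions
#'
#' Rows are truth, columns are assignment; `proportions` rows sum to 1 and
#' the diagonal is the probability of true classification per class.
#'
#' @param counts Square integer matrix with identical row/column names.
#' @return A `confusion_matrix` list with `class_labels`, `counts`,
#'   `proportions`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(rownames(counts))) {
    rownames(counts) <- colnames(counts) <- paste0("class", seq_len(nrow(counts)))
  }
  stopifnot(identical(rownames(counts), colnames(counts)))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(
    list(class_labels = rownames(counts), counts = counts, proportions = props),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> truth (rows) x assigned (columns), proportions:\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Pooled sensitivity and specificity from a confusion matrix
#'
#' The positive classes are pooled: sensitivity is the fraction of
#' positive-class samples assigned to any positive class; specificity is
#' the fraction of negative-class samples assigned to any negative class.
#'
#' @param cm A `confusion_matrix`.
#' @param positive_classes Non-empty proper subset of the class labels.
#' @return Named numeric `c(sensitivity, specificity)`; `NaN` with a
#'   warning when a pooled margin is empty.
#' @export
sensitivity_specificity <- function(cm, positive_classes) {
  stopifnot(inherits(cm, "confusion_matrix"))
  classes <- cm$class_labels
  if (length(positive_classes) == 0L || !all(positive_classes %in% classes) ||
      length(positive_classes) >= length(classes)) {
    stop("positive_classes must be a non-empty proper subset of the labels",
         call. = FALSE)
  }
  pos <- classes %in% positive_classes
  tp <- sum(cm$counts[pos, pos, drop = FALSE])
  fn <- sum(cm$counts[pos, !pos, drop = FALSE])
  tn <- sum(cm$counts[!pos, !pos, drop = FALSE])
  fp <- sum(cm$counts[!pos, pos, drop = FALSE])
  if (tp + fn == 0 || tn + fp == 0) {
    warning("empty pooled class margin; metric undefined", call. = FALSE)
  }
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}
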