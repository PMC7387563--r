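#' Normalize a cohort table to each subject's control measurement
#'
#' Implements the temperature-matched-control design: every feature value
#' is divided by the same feature's value in the measurement designated as
#' the subject's control (column `control_ref` naming a row `id`).  Control
#' rows are retained with ratio 1.  Features whose control value is
#' numerically zero are set to `NA` for that subject and flagged.
#'
#' @param tab cohort `data.frame` with columns `id`, `control_ref`, and the
#'   feature columns.
#' @param features character vector of feature column names.
#' @param tol controls are treated as zero below this magnitude.
#' @return the normalized table; flagged (subject, feature) pairs are
#'   attached as attribute `"flagged"`.
#' @export
normalize_to_control <- function(tab, features, tol = 1e-12) {
  stopifnot(all(c("id", "control_ref") %in% names(tab)),
            all(features %in% names(tab)))
  if (anyNA(match(tab$control_ref, tab$id)))
    stop("every row must designate an existing control measurement")
  ctrl <- tab[match(tab$control_ref, tab$id), features, drop = FALSE]
  flagged <- character(0)
  out <- tab
  for (f in features) {
    cv <- ctrl[[f]]
    zero <- abs(cv) < tol
    out[[f]] <- ifelse(zero, NA_real_, tab[[f]] / cv)
    if (any(zero))
      flagged <- c(flagged, paste0(tab$id[zero], ":", f))
  }
  attr(out, "flagged") <- flagged
  out
}

#' Rank features by association with the class label
#'
#' For each feature: Spearman correlation against the binary label and a
#' two-sample t-test (Welch by default, optionally paired) at alpha = 0.05.
#' Features are ordered by decreasing |rho|; constant features have
#' undefined rho, rank last and are flagged.
#'
#' @param tab cohort `data.frame` with a `label` column
#'   (healthy/tumor).
#' @param features feature column names.
#' @param alpha significance level.
#' @param paired use a paired t-test (rows must be ordered consistently
#'   within each class).
#' @return `data.frame` with columns `feature`, `rho`, `p_value`,
#'   `significant`, `flagged`, ordered by |rho| descending.
#' @export
rank_features <- function(tab, features, alpha = 0.05, paired = FALSE) {
  lab <- as.integer(tab$label == "tumor")
  if (length(unique(lab)) < 2) stop("both classes must be present")
  if (min(table(lab)) < 3) stop("need n >= 3 per class")
  rows <- lapply(features, function(f) {
    x <- tab[[f]]
    keep <- is.finite(x)
    const <- sd(x[keep]) == 0 || sum(keep) < 3
    rho <- if (const) NA_real_ else
      suppressWarnings(cor(x[keep], lab[keep], method = "spearman"))
    p <- if (const) NA_real_ else
      t.test(x[keep & lab == 1], x[keep & lab == 0], paired = paired)$p.value
    data.frame(feature = f, rho = rho, p_value = p,
               significant = isTRUE(p < alpha), flagged = const)
  })
  out <- do.call(rbind, rows)
  out[order(out$flagged, -abs(out$rho), method = "radix"), , drop = FALSE]
}

#' Feature-by-feature correlation matrix and independent-subset selection
#'
#' @param tab cohort `data.frame`.
#' @param features feature column names (>= 2).
#' @param method correlation method.
#' @param threshold pairwise |r| ceiling for [select_independent()].
#' @return correlation matrix; a maximal greedy subset of features with
#'   pairwise |r| below `threshold` is attached as attribute
#'   `"independent"`.
#' @export
correlation_matrix <- function(tab, features, method = "pearson",
                               threshold = 0.8) {
  if (length(features) < 2) stop("need at least two features")
  m <- cor(as.matrix(tab[, features, drop = FALSE]), method = method,
           use = "pairwise.complete.obs")
  attr(m, "independent") <- select_independent(m, threshold)
  m
}

#' @rdname correlation_matrix
#' @param cmat a correlation matrix.
#' @export
select_independent <- function(cmat, threshold = 0.8) {
  feats <- colnames(cmat)
  keep <- character(0)
  for (f in feats) {
    if (!length(keep) || all(abs(cmat[f, keep]) < threshold, na.rm = TRUE))
      keep <- c(keep, f)
  }
  keep
}

# stratified fold assignment: shuffles within each class (and group, when
# given) and deals round-robin, keeping class ratios within one sample
stratified_folds <- function(label, k, seed, group = NULL) {
  set.seed(seed)
  fold <- integer(length(label))
  if (is.null(group)) group <- seq_along(label)
  gl <- split(seq_along(label), group)
  g_label <- vapply(gl, function(i) label[i[1]], label[1])
  for (cl in unique(g_label)) {
    gs <- which(g_label == cl)
    gs <- gs[sample.int(length(gs))]
    f <- rep(seq_len(k), length.out = length(gs))
    for (j in seq_along(gs)) fold[gl[[gs[j]]]] <- f[j]
  }
  fold
}

# quadratic-discriminant posterior scores with a ridge fallback for
# singular class covariances
qda_scores <- function(train_x, train_lab, test_x) {
  df <- data.frame(train_x)
  df$.lab <- factor(train_lab)
  fit <- tryCatch(MASS::qda(.lab ~ ., data = df), error = function(e) NULL)
  if (!is.null(fit)) {
    post <- stats::predict(fit, data.frame(test_x))$posterior
    return(list(scores = post[, "tumor"], regularized = FALSE))
  }
  # ridge-regularized Gaussian discriminant (eps = 1e-6 * trace / d)
  x <- as.matrix(train_x); tx <- as.matrix(test_x)
  classes <- sort(unique(train_lab))
  logd <- vapply(classes, function(cl) {
    xc <- x[train_lab == cl, , drop = FALSE]
    mu <- colMeans(xc)
    S <- cov(xc)
    S <- S + diag(1e-6 * sum(diag(S)) / ncol(S) + 1e-12, ncol(S))
    ic <- solve(S)
    ctr <- sweep(tx, 2, mu)
    as.numeric(-0.5 * rowSums((ctr %*% ic) * ctr) -
                 0.5 * determinant(S)$modulus +
                 log(mean(train_lab == cl)))
  }, numeric(nrow(tx)))
  logd <- matrix(logd, nrow = nrow(tx))
  p <- exp(logd - apply(logd, 1, max))
  p <- matrix(p, nrow = nrow(tx))
  p <- p / rowSums(p)
  list(scores = p[, which(classes == "tumor")], regularized = TRUE)
}

#' Cross-validated quadratic discriminant classification with ROC/AUC
#'
#' Fits a Gaussian class-conditional model with per-class covariance (QDA)
#' under stratified k-fold cross-validation, pools the out-of-fold
#' posterior probabilities of the tumor class, and computes the ROC curve
#' and AUC.  Deterministic given `seed`.  Singular class covariances fall
#' back to a ridge-regularized discriminant and are flagged.
#'
#' @param tab cohort `data.frame` with `label` column.
#' @param features feature column names to use.
#' @param k number of folds.
#' @param seed integer seed for fold assignment.
#' @param group optional grouping vector (e.g. animal id); all measurements
#'   of a group share a fold, preventing leakage with repeated measures.
#' @return object of class `roc_result`: `auc`, `scores` (out-of-fold
#'   posterior of tumor), `label`, `fold`, `roc` (a [pROC::roc] object
#'   with thresholds/sensitivities/specificities), `seed`, `features`,
#'   `regularized`.
#' @export
qda_cv <- function(tab, features, k = 5, seed = 1L, group = NULL) {
  stopifnot(all(features %in% names(tab)))
  lab <- as.character(tab$label)
  keep <- rowSums(!is.finite(as.matrix(tab[, features, drop = FALSE]))) == 0
  tab <- tab[keep, , drop = FALSE]; lab <- lab[keep]
  if (!is.null(group)) group <- group[keep]
  if (min(table(lab)) < k)
    stop("need at least k samples per class")
  fold <- stratified_folds(lab, k, seed, group)
  scores <- rep(NA_real_, nrow(tab))
  reg <- FALSE
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    res <- qda_scores(tab[tr, features, drop = FALSE], lab[tr],
                      tab[te, features, drop = FALSE])
    scores[te] <- res$scores
    reg <- reg || res$regularized
  }
  roc <- pROC::roc(response = lab, predictor = scores,
                   levels = c("healthy", "tumor"), direction = "<",
                   quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(roc)), scores = scores,
                 label = lab, fold = fold, roc = roc, seed = seed,
                 features = features, regularized = reg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("qda_cv: AUC = %.3f (%d samples, %d folds, features: %s)%s\n",
              x$auc, length(x$scores), max(x$fold),
              paste(x$features, collapse = ", "),
              if (x$regularized) " [ridge-regularized]" else ""))
  invisible(x)
}

#' Compare single-feature classifiers against the combined classifier
#'
#' Runs [qda_cv()] for each feature alone and for the full feature set on
#' identical folds (same seed and stratification), and reports whether the
#' combined AUC is at least the best single-feature AUC.
#'
#' @inheritParams qda_cv
#' @return list with `table` (`data.frame` of feature set vs AUC),
#'   `combined_auc`, `best_single_auc`, and
#'   `combined_ge_single` flag.
#' @export
multi_vs_single_feature <- function(tab, features, k = 5, seed = 1L,
                                    group = NULL) {
  if (length(features) < 2) stop("need at least two features")
  singles <- vapply(features, function(f)
    qda_cv(tab, f, k = k, seed = seed, group = group)$auc, numeric(1))
  combined <- qda_cv(tab, features, k = k, seed = seed, group = group)$auc
  list(table = data.frame(features = c(features, "combined"),
                          auc = c(singles, combined)),
       combined_auc = combined,
       best_single_auc = max(singles),
       combined_ge_single = combined >= max(singles) - 1e-12)
}
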