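#' Stratified k-fold assignment
#'
#' Assigns every sample to exactly one test fold, stratified so that each
#' fold's class counts differ from an even split by at most one sample.
#' Classes with fewer members than \code{k} spread their samples across
#' distinct folds.  Deterministic given \code{seed}.
#'
#' @param labels class labels (factor or coercible).
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold indices in \code{1..k}, one per sample.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 42) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  set.seed(seed %% .Machine$integer.max)
  fold <- integer(n)
  cursor <- 0L  # rotate the fold cycle across classes to even out fold sizes
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
    cursor <- (cursor + length(idx)) %% k
  }
  fold
}

#' Train-fold feature normalization
#'
#' Per-feature z-scoring with mean and standard deviation estimated on the
#' training fold only; the identical transform is applied to the held-out
#' data, so no test-fold statistics leak into the model.  Zero-variance
#' features are centered but not divided.
#'
#' @param train_features,other_features numeric matrices with matching
#'   columns; \code{other_features} may be \code{NULL}.
#' @return list with \code{train}, \code{other}, and the fitted \code{center}
#'   and \code{scale} vectors.
#' @export
normalize_fit_apply <- function(train_features, other_features = NULL) {
  if (nrow(train_features) < 2)
    stop("training fold needs at least 2 samples", call. = FALSE)
  center <- colMeans(train_features)
  scale <- apply(train_features, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  tr <- sweep(sweep(train_features, 2, center), 2, scale, `/`)
  ot <- if (!is.null(other_features))
    sweep(sweep(other_features, 2, center), 2, scale, `/`)
  list(train = tr, other = ot, center = center, scale = scale)
}

#' Confusion matrix
#'
#' @param truth,pred factors over the same levels.
#' @return square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred) {
  lev <- levels(as.factor(truth))
  unclass(table(factor(truth, levels = lev), factor(pred, levels = lev)))
}

#' Support-weighted per-class accuracy
#'
#' For each class the confusion matrix is collapsed one-vs-rest and the
#' per-class accuracy \eqn{(TP + TN) / (TP + FP + TN + FN)} is computed;
#' the result is the average weighted by class support (or by the supplied
#' weights).
#'
#' @param confusion square count matrix, rows = truth, columns = predicted.
#' @param class_weights optional per-class weights summing to 1; defaults to
#'   the class support shares.
#' @return accuracy in \code{[0, 1]}.
#' @export
weighted_accuracy <- function(confusion, class_weights = NULL) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  C <- nrow(confusion)
  if (is.null(class_weights)) class_weights <- rowSums(confusion) / total
  acc <- vapply(seq_len(C), function(c) {
    tp <- confusion[c, c]
    fp <- sum(confusion[, c]) - tp
    fn <- sum(confusion[c, ]) - tp
    tn <- total - tp - fp - fn
    (tp + tn) / total
  }, numeric(1))
  sum(acc * class_weights) / sum(class_weights)
}

#' Grid-search model selection
#'
#' Evaluates every grid point by inner stratified cross-validation on the
#' training data (3 folds by default), scoring with [weighted_accuracy], and
#' returns the maximizer; ties are broken by first occurrence in the grid's
#' enumeration order.
#'
#' @param classifier_tag one of \code{"SVM"}, \code{"kNN"}, \code{"DT"},
#'   \code{"NB"}, \code{"BT"}.
#' @param grid data.frame of candidate hyperparameters (one row per point);
#'   defaults to [default_grid].
#' @param train_features numeric matrix of (already normalized) features.
#' @param train_labels factor of labels.
#' @param seed integer seed for the inner folds and stochastic classifiers.
#' @param inner_k inner fold count (default 3).
#' @return list with \code{params} (the winning row as a list), \code{score}
#'   (its mean inner-CV weighted accuracy) and \code{scores} (all points).
#' @export
grid_search <- function(classifier_tag, grid = default_grid(classifier_tag),
                        train_features, train_labels, seed = 42,
                        inner_k = 3) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty grid", call. = FALSE)
  train_labels <- droplevels(as.factor(train_labels))
  inner_k <- min(inner_k, min(table(train_labels)), nrow(train_features))
  inner_k <- max(inner_k, 2)
  fold <- stratified_kfold(train_labels, inner_k, seed)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    accs <- vapply(seq_len(inner_k), function(f) {
      tr <- fold != f; te <- fold == f
      if (!any(te) || length(unique(train_labels[tr])) < 2) return(NA_real_)
      model <- classifier_fit(classifier_tag,
                              train_features[tr, , drop = FALSE],
                              droplevels(train_labels[tr]),
                              params, seed + g)
      pred <- classifier_predict(classifier_tag, model,
                                 train_features[te, , drop = FALSE])
      cm <- confusion_matrix(factor(train_labels[te],
                                    levels = levels(train_labels)),
                             factor(pred, levels = levels(train_labels)))
      weighted_accuracy(cm)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)   # first occurrence wins ties
  list(params = as.list(grid[best, , drop = FALSE]), score = scores[best],
       scores = scores)
}

# Feature-matrix extraction for a descriptor name (+ optional spec overrides).
descriptor_features <- function(images, descriptor, spec = NULL) {
  fv1 <- function(img) {
    if (descriptor %in% .CARTESIAN_FAMILIES) {
      compute_cartesian_moments(img, spec %||% moment_spec(descriptor))
    } else if (descriptor %in% .CIRCULAR_FAMILIES) {
      magnitudes(compute_circular_moments(img, spec %||% moment_spec(descriptor)))
    } else if (descriptor == "HARri") {
      rotation_invariant_haralick(img)
    } else if (descriptor == "LBPri") {
      lbp_feature_vector(img)
    } else stop("unknown descriptor: ", descriptor, call. = FALSE)
  }
  fvs <- lapply(images, fv1)
  mat <- do.call(rbind, lapply(fvs, function(f) f$values))
  colnames(mat) <- fvs[[1]]$labels
  mat
}

#' Run the classification benchmark
#'
#' The full protocol: for each descriptor, features are extracted once; then
#' for each classifier a stratified 10-fold cross-validation is run in which
#' the training fold alone is used to fit the z-score normalization and to
#' grid-search hyperparameters (inner stratified 3-fold CV), and the held-out
#' fold is scored with the support-weighted per-class accuracy.
#'
#' @param dataset list with \code{images} (list of matrices) and
#'   \code{labels} (factor), e.g. from [generate_dataset] or [read_dataset].
#' @param descriptors character vector of descriptor names (moment family
#'   tags, \code{"HARri"}, \code{"LBPri"}), or a named list of
#'   [moment_spec] objects.
#' @param classifiers character vector of classifier tags.
#' @param k outer fold count (default 10).
#' @param seed integer governing folds, inner folds and stochastic
#'   classifiers.
#' @param grids optional named list of hyperparameter grids per classifier.
#' @return object of class \code{evaluation_result}: \code{table}
#'   (descriptor x classifier mean accuracies, plus AVG column), \code{folds}
#'   (per-fold detail with chosen hyperparameters), \code{feature_sizes}.
#' @export
run_benchmark <- function(dataset, descriptors, classifiers = c("kNN"),
                          k = 10, seed = 42, grids = NULL) {
  labels <- as.factor(dataset$labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("dataset must contain at least 2 classes", call. = FALSE)
  if (k > length(labels))
    stop("k exceeds the number of samples", call. = FALSE)
  spec_list <- if (is.list(descriptors)) descriptors else
    stats::setNames(vector("list", length(descriptors)), descriptors)
  dnames <- names(spec_list) %||% as.character(descriptors)
  fold <- stratified_kfold(labels, k, seed)
  tab <- matrix(NA_real_, length(dnames), length(classifiers),
                dimnames = list(dnames, classifiers))
  folds_detail <- list()
  feature_sizes <- integer(length(dnames)); names(feature_sizes) <- dnames
  for (d in seq_along(dnames)) {
    feats <- descriptor_features(dataset$images, dnames[d], spec_list[[d]])
    feature_sizes[d] <- ncol(feats)
    for (cl in classifiers) {
      grid <- grids[[cl]] %||% default_grid(cl)
      fold_acc <- numeric(k); fold_par <- vector("list", k)
      for (f in seq_len(k)) {
        tr <- fold != f; te <- fold == f
        nz <- normalize_fit_apply(feats[tr, , drop = FALSE],
                                  feats[te, , drop = FALSE])
        gs <- grid_search(cl, grid, nz$train, labels[tr],
                          seed = seed + 1000 * f)
        model <- classifier_fit(cl, nz$train, droplevels(labels[tr]),
                                gs$params, seed + 1000 * f)
        pred <- classifier_predict(cl, model, nz$other)
        cm <- confusion_matrix(factor(labels[te], levels = levels(labels)),
                               factor(pred, levels = levels(labels)))
        fold_acc[f] <- weighted_accuracy(cm)
        fold_par[[f]] <- gs$params
      }
      tab[d, cl] <- mean(fold_acc)
      folds_detail[[paste(dnames[d], cl, sep = ".")]] <-
        list(accuracies = fold_acc, params = fold_par)
    }
  }
  table_df <- as.data.frame(tab)
  table_df$AVG <- rowMeans(tab)
  structure(list(table = table_df, folds = folds_detail,
                 feature_sizes = feature_sizes, k = k, seed = seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result (k = %d, seed = %d)\n", x$k, x$seed))
  print(round(x$table, 4))
  invisible(x)
}

#' Category-level aggregation of benchmark results
#'
#' Summarizes per-descriptor accuracies into descriptor-category means,
#' standard deviations and ranges, mirroring the category columns and whisker
#' plots of the reference protocol (CM Cartesian, JM Jacobi, BM
#' Bessel-Fourier, HM harmonic, TF texture).
#'
#' @param result an \code{evaluation_result}, or a named numeric vector of
#'   per-descriptor accuracies.
#' @param category_map named character vector mapping descriptor name ->
#'   category; defaults to the standard taxonomy for known descriptors.
#' @return data.frame with columns \code{category}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{n}.
#' @export
aggregate_by_category <- function(result, category_map = default_category_map()) {
  vals <- if (inherits(result, "evaluation_result"))
    stats::setNames(result$table$AVG, rownames(result$table))
  else result
  if (is.null(names(vals))) stop("descriptor names required", call. = FALSE)
  missing <- setdiff(names(vals), names(category_map))
  if (length(missing))
    stop("descriptors without a category: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cats <- category_map[names(vals)]
  out <- do.call(rbind, lapply(split(vals, cats), function(v)
    data.frame(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v), n = length(v))))
  out <- cbind(category = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Standard descriptor taxonomy
#'
#' @return named character vector mapping each built-in descriptor to its
#'   category: CM (Cartesian), JM (Jacobi-polynomial circular), BM
#'   (Bessel-Fourier), HM (harmonic circular), TF (texture).
#' @export
default_category_map <- function() {
  c(LM = "CM", CHM = "CM", CH2M = "CM",
    ZM = "JM", PZM = "JM", OFMM = "JM", CHFM = "JM", PJFM = "JM",
    JFM = "JM", FrJFM = "JM",
    BFM = "BM",
    RHFM = "HM", EFM = "HM", PCET = "HM", PCT = "HM", PST = "HM",
    FrRHFM = "HM", FrPCET = "HM", FrPCT = "HM", FrPST = "HM",
    LBPri = "TF", HARri = "TF")
}
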