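# In-package classifiers backing the benchmark pipeline.  Each classifier is
# a pair fit_<tag>(x, y, params, seed) -> model, predict_<tag>(model, x) ->
# factor.  x is a numeric matrix (rows = samples), y a factor.  All are
# deterministic given the seed.

## ---- k-nearest neighbours ----------------------------------------------
fit_knn <- function(x, y, params, seed = NULL) {
  list(x = x, y = y, k = params$k %||% 5,
       distance = params$distance %||% "euclidean")
}

predict_knn <- function(model, x) {
  dists <- if (model$distance == "cityblock") {
    apply(x, 1, function(row) colSums(abs(t(model$x) - row)))
  } else {
    apply(x, 1, function(row) sqrt(colSums((t(model$x) - row)^2)))
  }
  dists <- matrix(dists, nrow = nrow(model$x))   # train x test
  k <- min(model$k, nrow(model$x))
  lev <- levels(model$y)
  pred <- apply(dists, 2, function(d) {
    nn <- order(d)[seq_len(k)]
    votes <- table(factor(model$y[nn], levels = lev))
    top <- which(votes == max(votes))
    if (length(top) > 1) {                      # tie: closest class wins
      md <- sapply(lev[top], function(cl)
        min(d[nn][model$y[nn] == cl]))
      top <- top[which.min(md)]
    }
    lev[top[1]]
  })
  factor(pred, levels = lev)
}

## ---- Gaussian naive Bayes ----------------------------------------------
fit_nb <- function(x, y, params, seed = NULL) {
  eps <- params$var_smoothing %||% 1e-9
  lev <- levels(y)
  mu <- t(sapply(lev, function(cl) colMeans(x[y == cl, , drop = FALSE])))
  v <- t(sapply(lev, function(cl)
    apply(x[y == cl, , drop = FALSE], 2, stats::var)))
  v[!is.finite(v)] <- 0
  v <- v + eps * max(apply(x, 2, stats::var), 1e-12)
  prior <- as.vector(table(y)) / length(y)
  list(levels = lev, mu = mu, var = v, log_prior = log(prior))
}

predict_nb <- function(model, x) {
  ll <- sapply(seq_along(model$levels), function(c) {
    mu <- model$mu[c, ]; v <- model$var[c, ]
    apply(x, 1, function(row)
      sum(-0.5 * log(2 * pi * v) - (row - mu)^2 / (2 * v)))
  })
  ll <- matrix(ll, nrow = nrow(x))
  ll <- sweep(ll, 2, model$log_prior, `+`)
  factor(model$levels[max.col(ll, ties.method = "first")],
         levels = model$levels)
}

## ---- CART decision tree (Gini) -----------------------------------------
gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

grow_tree <- function(x, y, depth, max_depth, min_leaf) {
  lev <- levels(y)
  counts <- table(factor(y, levels = lev))
  majority <- lev[which.max(counts)]
  if (depth >= max_depth || length(y) < 2 * min_leaf ||
      length(unique(y)) == 1)
    return(list(leaf = TRUE, class = majority))
  n <- length(y)
  best <- list(gain = 0)
  parent_imp <- gini_impurity(counts)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]; ys <- y[ord]
    cand <- which(diff(vs) > 0)
    cand <- cand[cand >= min_leaf & cand <= n - min_leaf]
    if (length(cand) == 0) next
    # cumulative class counts along the sorted order
    cum <- apply(sapply(lev, function(cl) cumsum(ys == cl)), 2, identity)
    cum <- matrix(cum, nrow = n)
    tot <- cum[n, ]
    for (i in cand) {
      left <- cum[i, ]; right <- tot - left
      imp <- (i * gini_impurity(left) + (n - i) * gini_impurity(right)) / n
      gain <- parent_imp - imp
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = j,
                     threshold = (vs[i] + vs[i + 1]) / 2)
      }
    }
  }
  if (best$gain <= 0) return(list(leaf = TRUE, class = majority))
  go_left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       class = majority,
       left = grow_tree(x[go_left, , drop = FALSE], factor(y[go_left], levels = lev),
                        depth + 1, max_depth, min_leaf),
       right = grow_tree(x[!go_left, , drop = FALSE], factor(y[!go_left], levels = lev),
                         depth + 1, max_depth, min_leaf))
}

fit_dt <- function(x, y, params, seed = NULL) {
  max_depth <- params$max_depth %||% Inf
  min_leaf <- params$min_leaf %||% 1
  list(tree = grow_tree(x, y, 0, max_depth, min_leaf), levels = levels(y))
}

predict_tree_row <- function(node, row) {
  while (!node$leaf)
    node <- if (row[node$feature] <= node$threshold) node$left else node$right
  node$class
}

predict_dt <- function(model, x) {
  factor(apply(x, 1, function(row) predict_tree_row(model$tree, row)),
         levels = model$levels)
}

## ---- bagged trees -------------------------------------------------------
fit_bt <- function(x, y, params, seed = 0) {
  n_trees <- params$n_trees %||% 100
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(x)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], factor(y[idx], levels = levels(y)),
              0, params$max_depth %||% Inf, params$min_leaf %||% 1)
  })
  list(trees = trees, levels = levels(y))
}

predict_bt <- function(model, x) {
  lev <- model$levels
  votes <- matrix(0L, nrow(x), length(lev))
  for (tr in model$trees) {
    p <- apply(x, 1, function(row) predict_tree_row(tr, row))
    votes <- votes + outer(p, lev, `==`)
  }
  factor(lev[max.col(votes, ties.method = "first")], levels = lev)
}

## ---- least-squares kernel SVM ------------------------------------------
# One-vs-rest LS-SVM: for each class, solve (K + I/C) a = y with y = +/-1 and
# classify by the largest decision value.  Linear and RBF kernels; the RBF
# width follows the "scale" heuristic gamma = g_mult / (d * var(X)).
svm_kernel <- function(x1, x2, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(x1, x2))
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), `+`) - 2 * tcrossprod(x1, x2)
  exp(-gamma * pmax(d2, 0))
}

fit_svm <- function(x, y, params, seed = NULL) {
  kernel <- params$kernel %||% "rbf"
  C <- params$C %||% 1
  g_mult <- params$gamma_mult %||% 1
  vx <- stats::var(as.vector(x)); if (!is.finite(vx) || vx == 0) vx <- 1
  gamma <- g_mult / (ncol(x) * vx)
  K <- svm_kernel(x, x, kernel, gamma)
  A <- K + diag(nrow(x)) / C
  lev <- levels(y)
  targets <- sapply(lev, function(cl) ifelse(y == cl, 1, -1))
  alpha <- solve(A, targets)
  list(x = x, alpha = alpha, kernel = kernel, gamma = gamma, levels = lev)
}

predict_svm <- function(model, x) {
  K <- svm_kernel(x, model$x, model$kernel, model$gamma)
  dec <- K %*% model$alpha
  factor(model$levels[max.col(dec, ties.method = "first")],
         levels = model$levels)
}

## ---- registry -----------------------------------------------------------
`%||%` <- function(a, b) if (is.null(a)) b else a

classifier_fit <- function(tag, x, y, params, seed = 0) {
  switch(tag,
         SVM = fit_svm(x, y, params, seed),
         kNN = fit_knn(x, y, params, seed),
         DT = fit_dt(x, y, params, seed),
         NB = fit_nb(x, y, params, seed),
         BT = fit_bt(x, y, params, seed),
         stop("unknown classifier tag: ", tag, call. = FALSE))
}

classifier_predict <- function(tag, model, x) {
  switch(tag,
         SVM = predict_svm(model, x),
         kNN = predict_knn(model, x),
         DT = predict_dt(model, x),
         NB = predict_nb(model, x),
         BT = predict_bt(model, x),
         stop("unknown classifier tag: ", tag, call. = FALSE))
}

#' Default hyperparameter grids
#'
#' Small, standard grids used by the benchmark's grid search, enumerated in
#' a fixed documented order (ties in the inner-CV score are broken by first
#' occurrence).  SVM: kernel linear/RBF, \code{C} in 0.1/1/10/100, RBF width
#' from the scale heuristic times 0.1/1/10.  kNN: \code{k} in 1/3/5/7/9,
#' euclidean or cityblock distance.  DT: max depth 3/5/10/unbounded,
#' minimum leaf 1/3/5.  NB: variance smoothing 1e-9/1e-6.  BT: 50/100/200
#' trees.
#'
#' @param tag classifier tag: \code{"SVM"}, \code{"kNN"}, \code{"DT"},
#'   \code{"NB"} or \code{"BT"}.
#' @return data.frame, one row per grid point.
#' @export
default_grid <- function(tag) {
  switch(tag,
    SVM = {
      g <- expand.grid(kernel = c("linear", "rbf"), C = c(0.1, 1, 10, 100),
                       gamma_mult = c(0.1, 1, 10),
                       stringsAsFactors = FALSE)
      g[g$kernel == "rbf" | g$gamma_mult == 1, ]   # gamma irrelevant to linear
    },
    kNN = expand.grid(k = c(1, 3, 5, 7, 9),
                      distance = c("euclidean", "cityblock"),
                      stringsAsFactors = FALSE),
    DT = expand.grid(max_depth = c(3, 5, 10, Inf), min_leaf = c(1, 3, 5)),
    NB = data.frame(var_smoothing = c(1e-9, 1e-6)),
    BT = data.frame(n_trees = c(50, 100, 200)),
    stop("unknown classifier tag: ", tag, call. = FALSE))
}
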