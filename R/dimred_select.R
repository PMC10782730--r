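#' Impute missing abundance values
#'
#' Deterministic fills for left-censored label-free data. `half_min` (the
#' default, a standard proteomics left-censoring surrogate) replaces every
#' missing cell of a peptide with half that peptide's minimum present value;
#' `zero` and `per_peptide_mean` are alternatives. Present values are never
#' altered.
#'
#' @param mat An `AbundanceMatrix`.
#' @param method One of `"half_min"`, `"zero"`, `"per_peptide_mean"`.
#' @return A complete `AbundanceMatrix`.
#' @export
impute_missing <- function(mat, method = c("half_min", "zero",
                                           "per_peptide_mean")) {
  method <- match.arg(method)
  v <- mat$values
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing))
    stop("all-missing peptide(s) cannot be imputed (filter first): ",
         paste(utils::head(rownames(v)[all_missing]), collapse = ", "))
  for (i in which(rowSums(is.na(v)) > 0)) {
    fill <- switch(method,
      half_min = min(v[i, ], na.rm = TRUE) / 2,
      zero = 0,
      per_peptide_mean = mean(v[i, ], na.rm = TRUE))
    v[i, is.na(v[i, ])] <- fill
  }
  out <- mat
  out$values <- v
  # zero imputation intentionally breaks positivity; bypass the constructor
  out
}

#' Embed samples in two dimensions
#'
#' Projects samples (columns) into 2-D for visual separation of control and
#' treated phases. `"pca"` uses `prcomp` on centred features (deterministic up
#' to sign); `"mds"` uses classical multidimensional scaling (`cmdscale`) of
#' the Euclidean sample distances.
#'
#' @param mat A complete `AbundanceMatrix` or numeric matrix (features x
#'   samples), typically restricted to the significant peptides.
#' @param labels Optional phase label per sample (stored in the result).
#' @param method `"pca"` (default) or `"mds"`.
#' @param seed Integer seed recorded in the result (both methods are
#'   deterministic; kept for interface stability).
#' @return list of class `embedding`: `method`, `coordinates` (samples x 2),
#'   `explained_variance` (PCA only), `labels`, `seed`.
#' @export
embed_samples <- function(mat, labels = NULL, method = c("pca", "mds"),
                          seed = 1L) {
  method <- match.arg(method)
  v <- if (inherits(mat, "AbundanceMatrix")) mat$values else as.matrix(mat)
  if (anyNA(v)) stop("missing values present; impute first")
  if (ncol(v) < 3L) stop("need at least 3 samples to embed")
  x <- t(v)   # samples x features
  if (method == "pca") {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    coords <- pc$x[, seq_len(k), drop = FALSE]
    if (k < 2L) coords <- cbind(coords, 0)
    ev <- (pc$sdev^2 / sum(pc$sdev^2))
    explained <- ev[1:2]
  } else {
    coords <- stats::cmdscale(stats::dist(x), k = 2L)
    explained <- NULL
  }
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- colnames(v)
  structure(list(method = toupper(method), coordinates = coords,
                 explained_variance = explained, labels = labels,
                 seed = seed),
            class = "embedding")
}

#' Mean silhouette width of a labelling in an embedding
#'
#' Simple silhouette on Euclidean distances in the 2-D embedding; used to
#' quantify phase separation.
#'
#' @param embedding An `embedding` (or a samples x 2 coordinate matrix).
#' @param labels Group label per sample.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(embedding, labels) {
  coords <- if (inherits(embedding, "embedding")) embedding$coordinates
            else as.matrix(embedding)
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# ---- consensus feature selection -------------------------------------------

rank_rfe_svm <- function(x, y, top_k) {
  # recursive feature elimination, linear SVM base ranker, one feature per
  # step down to top_k; surviving features ranked by elimination order
  features <- colnames(x)
  elimination <- character(0)
  current <- features
  while (length(current) > top_k) {
    fit <- e1071::svm(x[, current, drop = FALSE], y, kernel = "linear",
                      scale = FALSE, cost = 1)
    w <- drop(t(fit$coefs) %*% fit$SV)   # weight vector of the linear SVM
    worst <- current[which.min(abs(w))]
    elimination <- c(worst, elimination)
    current <- setdiff(current, worst)
  }
  fit <- e1071::svm(x[, current, drop = FALSE], y, kernel = "linear",
                    scale = FALSE, cost = 1)
  w <- drop(t(fit$coefs) %*% fit$SV)
  c(current[order(-abs(w))], elimination)
}

rank_random_forest <- function(x, y, n_trees = 500L) {
  fit <- randomForest::randomForest(x, y, ntree = n_trees, importance = FALSE)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  names(sort(imp, decreasing = TRUE))
}

rank_extra_trees <- function(x, y, n_trees = 500L, seed = 1L) {
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        splitrule = "extratrees", num.random.splits = 1L,
                        replace = FALSE, sample.fraction = 1,
                        importance = "impurity", seed = seed)
  names(sort(fit$variable.importance, decreasing = TRUE))
}

rank_lasso <- function(x, y, n_folds = 3L) {
  y_num <- as.numeric(y) - 1
  cv <- glmnet::cv.glmnet(x, y_num, alpha = 1, nfolds = n_folds,
                          standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  names(beta) <- colnames(x)
  beta <- beta[beta != 0]
  names(sort(abs(beta), decreasing = TRUE))
}

#' Consensus feature selection across four algorithms
#'
#' Ranks features by one wrapper method - recursive feature elimination with a
#' linear-SVM base ranker - and three embedded methods: random forest
#' classification, extra-trees classification, and lasso regression on the
#' phase label. Features are standardized (zero mean, unit variance) before
#' the lasso and RFE. A feature belongs to the consensus when it appears in
#' the top `top_k` of at least `min_agreement` algorithms. Deterministic for
#' a fixed seed.
#'
#' @param mat A complete `AbundanceMatrix` or numeric matrix (features x
#'   samples).
#' @param labels Two-class label per sample (e.g. the phase).
#' @param top_k Depth of each ranking considered (default 10).
#' @param min_agreement Minimum number of algorithms agreeing (default 2).
#' @param seed Integer seed.
#' @return list of class `consensus_selection`: `rankings` (per-algorithm
#'   full rankings), `top` (per-algorithm top-k sets), `consensus`, `top_k`,
#'   `min_agreement`, `seed`.
#' @export
consensus_feature_selection <- function(mat, labels, top_k = 10L,
                                        min_agreement = 2L, seed = 1L) {
  v <- if (inherits(mat, "AbundanceMatrix")) mat$values else as.matrix(mat)
  if (anyNA(v)) stop("missing values present; impute first")
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must contain exactly two classes")
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")
  x <- t(v)                                  # samples x features
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  xs <- scale(x, center = TRUE, scale = sds)  # for lasso + RFE
  set.seed(seed)
  rankings <- list(
    rfe = rank_rfe_svm(xs, labels, top_k),
    random_forest = rank_random_forest(x, labels),
    extra_trees = rank_extra_trees(x, labels, seed = seed),
    lasso = rank_lasso(xs, labels))
  top <- lapply(rankings, function(r) utils::head(r, top_k))
  counts <- table(unlist(top))
  consensus <- names(counts)[counts >= min_agreement]
  structure(list(rankings = rankings, top = top,
                 consensus = sort(consensus),
                 top_k = top_k, min_agreement = min_agreement, seed = seed),
            class = "consensus_selection")
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf("Consensus feature selection: %d feature(s) in top-%d of >= %d/4 algorithms\n",
              length(x$consensus), x$top_k, x$min_agreement))
  if (length(x$consensus)) cat("  ", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}
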