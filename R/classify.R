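#' Binarize a peak-amplitude map at the per-channel mean
#'
#' Per channel, the threshold is the mean over events of the recorded peak
#' amplitudes; an entry becomes 1 when it strictly exceeds its channel's
#' mean (ties map to 0). This turns the continuous peak amplitudes into
#' categorical features for classification.
#'
#' @param map events x channels matrix (e.g. [peak_amplitudes()]).
#' @return Binary events x channels matrix with attribute `thresholds`
#'   (the per-channel means).
#' @export
binarize <- function(map) {
  if (!is.matrix(map) || nrow(map) < 1L) stop("map must have >= 1 event")
  th <- colMeans(map)
  feat <- 1 * sweep(unclass(map), 2, th, ">")
  attributes(feat) <- attributes(feat)[c("dim")]
  attr(feat, "thresholds") <- th
  feat
}

#' Stratified train/test split
#'
#' Random split that keeps each class's train fraction at
#' `round(train_fraction * n_class)`, guarding against empty test classes
#' at small sample sizes.
#'
#' @param labels class label per event.
#' @param train_fraction fraction assigned to training (default 0.60).
#' @param seed random seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_stratified <- function(labels, train_fraction = 0.60, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs >= 2 events to split; offending class(es): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  train <- integer(0)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    ntr <- max(1L, min(length(idx) - 1L,
                       round(train_fraction * length(idx))))
    train <- c(train, sample(idx, ntr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

l1_dist_matrix <- function(a, b) {
  # rows of a x rows of b city-block distances
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(ncol(a)))
    out <- out + abs(outer(a[, j], b[, j], "-"))
  out
}

#' k-nearest-neighbour classification of evoked-potential sources
#'
#' City-block (L1) KNN with `k = 1` by default. Each test event takes the
#' majority label among its k nearest training events; ties are broken by
#' the smallest within-tie distance sum, then by the lowest class index
#' (alphabetical order of labels).
#'
#' @param train_x training feature matrix (events x channels).
#' @param train_y training labels.
#' @param test_x test feature matrix.
#' @param k neighbour count (default 1).
#' @param test_y optional true test labels; enables the confusion matrix
#'   and accuracy.
#' @return An object of class `knn_result`: `predicted`, and when `test_y`
#'   is given `confusion` (true x predicted), `accuracy`
#'   (= trace / total) and `per_class_loss` (1 - per-class recall).
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 1, test_y = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) stop("feature dimension mismatch")
  if (nrow(train_x) < 1L) stop("empty training set")
  if (length(train_y) != nrow(train_x))
    stop("train_y length must match train_x rows")
  if (k < 1L || k > nrow(train_x)) stop("k must lie in [1, n_train]")
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  d <- l1_dist_matrix(test_x, train_x)
  predicted <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nn <- order(d[i, ])[seq_len(k)]
    votes <- table(factor(train_y[nn], levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl)
        sum(d[i, nn[train_y[nn] == cl]]), numeric(1))
      top <- top[sums == min(sums)]
    }
    predicted[i] <- top[1L]   # lowest class index among remaining ties
  }
  out <- list(predicted = predicted, k = k, metric = "cityblock")
  if (!is.null(test_y)) {
    lev <- sort(unique(c(classes, as.character(test_y))))
    cm <- table(factor(as.character(test_y), levels = lev),
                factor(predicted, levels = lev), dnn = c("true", "predicted"))
    out$confusion <- cm
    out$accuracy <- sum(diag(cm)) / sum(cm)
    rs <- rowSums(cm)
    out$per_class_loss <- ifelse(rs > 0, 1 - diag(cm) / rs, NA_real_)
  }
  structure(out, class = "knn_result")
}

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf("<knn_result> k = %d, %s metric\n", x$k, x$metric))
  if (!is.null(x$accuracy)) {
    cat(sprintf("accuracy: %.1f%%\n", 100 * x$accuracy))
    print(x$confusion)
  }
  invisible(x)
}

#' Principal-component embedding of event features
#'
#' Centred (unscaled) PCA via the singular value decomposition; component
#' variances are non-increasing.
#'
#' @param features continuous events x channels matrix.
#' @param n_components number of components to retain.
#' @return Events x `n_components` score matrix with attributes
#'   `variance_ratio` (per retained component) and `rotation`.
#' @export
reduce_pca <- function(features, n_components) {
  features <- as.matrix(features)
  if (n_components < 1 || n_components > ncol(features))
    stop("n_components must lie in [1, n_channels]")
  p <- prcomp(features, center = TRUE, scale. = FALSE)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  attr(scores, "variance_ratio") <-
    (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)]
  attr(scores, "rotation") <- p$rotation[, seq_len(n_components),
                                         drop = FALSE]
  scores
}

#' UMAP embedding of event features (optional dependency)
#'
#' Nonlinear embedding through the `uwot` package when it is installed;
#' otherwise a clear error points to [reduce_pca()] as the linear
#' alternative.
#'
#' @param features events x channels matrix.
#' @param n_components embedding dimension (default 2).
#' @param seed random seed for reproducibility.
#' @return Events x `n_components` embedding matrix.
#' @export
reduce_umap <- function(features, n_components = 2, seed = 1L) {
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("package 'uwot' is not installed; install it for UMAP embeddings ",
         "or use reduce_pca() for a linear embedding")
  features <- as.matrix(features)
  uwot::umap(features, n_components = n_components,
             seed = as.integer(seed), batch = TRUE)
}

match_labels <- function(cluster_id, true_labels) {
  # exact optimal matching by exhaustive permutation (k! small for k <= 6)
  cl <- sort(unique(cluster_id))
  lv <- sort(unique(true_labels))
  if (length(cl) > 6L)
    stop("label matching supported for up to 6 clusters")
  cm <- table(factor(cluster_id, levels = cl),
              factor(true_labels, levels = lv))
  k <- length(cl)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  # assign each cluster a distinct label column (pad label set if needed)
  cols <- seq_len(max(k, length(lv)))
  best <- -Inf; best_map <- NULL
  for (p in perms(cols)) {
    hit <- 0
    for (i in seq_len(k)) {
      j <- p[i]
      if (j <= length(lv)) hit <- hit + cm[i, j]
    }
    if (hit > best) { best <- hit; best_map <- p }
  }
  mapped <- rep(NA_character_, length(cluster_id))
  for (i in seq_len(k)) {
    j <- best_map[i]
    if (j <= length(lv)) mapped[cluster_id == cl[i]] <- lv[j]
  }
  list(mapped = mapped, agreement = best / length(cluster_id))
}

#' Unsupervised clustering of evoked-potential features
#'
#' Partitions events into `n_clusters` groups: by default k-medoids (PAM)
#' under the city-block distance — exemplar-based, the same metric as the
#' supervised classifier — with k-means available as the alternative
#' reading. When true labels are supplied, an agreement score is computed
#' after optimal cluster-to-label matching.
#'
#' @param features events x channels matrix (binary or embedded).
#' @param n_clusters number of clusters (2 for tibial vs peroneal, 4 for
#'   the left/right MEP/SSEP sessions).
#' @param seed random seed.
#' @param method `"kmedoids"` (default) or `"kmeans"`.
#' @param true_labels optional true source labels for the agreement score.
#' @return List with `cluster` (integer assignment), `method`, and when
#'   labels were given `matched_labels` and `agreement`.
#' @export
cluster_sources <- function(features, n_clusters, seed = 1L,
                            method = c("kmedoids", "kmeans"),
                            true_labels = NULL) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (n_clusters > nrow(features))
    stop("n_clusters exceeds the event count")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  assignment <- if (method == "kmedoids") {
    cluster::pam(stats::dist(features, method = "manhattan"),
                 k = n_clusters, cluster.only = TRUE)
  } else {
    kmeans(features, centers = n_clusters, nstart = 10)$cluster
  }
  out <- list(cluster = as.integer(assignment), method = method)
  if (!is.null(true_labels)) {
    m <- match_labels(out$cluster, as.character(true_labels))
    out$matched_labels <- m$mapped
    out$agreement <- m$agreement
  }
  out
}
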