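#' Extract an edge-feature table from connectomes
#'
#' Looks up the Fisher-z weight of each selected edge in every session's
#' weighted connectome. Columns are ordered lexicographically by ROI
#' pair, so train and test tables built from the same edge list share
#' identical column order.
#'
#' @param connectomes Named list of weighted connectome matrices.
#' @param edges Data frame with columns `roi_i`, `roi_j` (label pairs),
#'   or a character vector of `"roiA|roiB"` feature names.
#' @param labels Class label per session (same order as `connectomes`);
#'   factor or character.
#' @return Data frame: one row per session, one numeric column per
#'   edge, plus a `label` column.
#' @export
extract_features <- function(connectomes, edges, labels) {
  stopifnot(length(labels) == length(connectomes))
  if (is.character(edges))
    edges <- do.call(rbind, lapply(strsplit(edges, "|", fixed = TRUE),
                                   function(p) data.frame(roi_i = p[1],
                                                          roi_j = p[2])))
  key <- paste0(pmin(edges$roi_i, edges$roi_j), "|",
                pmax(edges$roi_i, edges$roi_j))
  ord <- order(key)
  edges <- edges[ord, , drop = FALSE]
  key <- key[ord]
  roi_names <- rownames(connectomes[[1L]])
  miss <- setdiff(unique(c(edges$roi_i, edges$roi_j)), roi_names)
  if (length(miss)) stop("ROI(s) absent from connectomes: ",
                         paste(miss, collapse = ", "))
  vals <- vapply(connectomes, function(m)
    unclass(as.matrix(m))[cbind(match(edges$roi_i, rownames(m)),
                                match(edges$roi_j, colnames(m)))],
    numeric(nrow(edges)))
  vals <- if (nrow(edges) == 1L) matrix(vals, ncol = 1L) else t(vals)
  out <- as.data.frame(vals)
  names(out) <- key
  out$label <- as.character(labels)
  rownames(out) <- names(connectomes)
  out
}

#' Train an RBF support-vector classifier and validate on held-out data
#'
#' Binary verification of connectivity biomarkers: features are
#' standardized with the training cohort's mean/SD only, a radial-basis
#' support-vector machine (libsvm) is fit on the training cohort, and
#' accuracy plus the ROC curve of its decision scores are computed on
#' the held-out cohort.
#'
#' @param train,test Feature tables from [extract_features()] with
#'   identical feature columns; labels must be binary.
#' @param config List of hyperparameters: `cost` (default 1), `gamma`
#'   (default `1 / n_features` on the standardized features), `seed`.
#' @return A `classification_report` list: `accuracy`, `roc` (data frame
#'   threshold/fpr/tpr), `auc`, `confusion`, `hyperparameters`, `seed`,
#'   `scores`, `predicted`.
#' @export
train_validate <- function(train, test, config = list()) {
  stopifnot(nrow(train) > 0L, nrow(test) > 0L,
            identical(setdiff(names(train), "label"),
                      setdiff(names(test), "label")))
  feats <- setdiff(names(train), "label")
  ytr <- factor(train$label)
  if (nlevels(ytr) != 2L)
    stop("training cohort must contain exactly two classes, got ",
         nlevels(ytr))
  yte <- factor(test$label, levels = levels(ytr))
  xtr <- as.matrix(train[, feats, drop = FALSE])
  xte <- as.matrix(test[, feats, drop = FALSE])
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdev, "/")
  xte <- sweep(sweep(xte, 2L, mu), 2L, sdev, "/")
  cost <- if (is.null(config$cost)) 1 else config$cost
  gamma <- if (is.null(config$gamma)) 1 / ncol(xtr) else config$gamma
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  pred <- stats::predict(fit, xte, decision.values = TRUE)
  scores <- as.numeric(attr(pred, "decision.values"))
  # libsvm's decision value is signed toward the class named first in
  # the "A/B" column label; orient scores so larger = second factor
  # level (the "positive" class)
  pos <- levels(ytr)[2L]
  first <- strsplit(colnames(attr(pred, "decision.values"))[1L],
                    "/", fixed = TRUE)[[1L]][1L]
  if (first != pos) scores <- -scores
  roc <- roc_points(scores, yte == pos)
  structure(list(accuracy = mean(pred == yte),
                 roc = roc$points, auc = roc$auc,
                 confusion = table(predicted = pred, truth = yte),
                 hyperparameters = list(cost = cost, gamma = gamma),
                 seed = seed, scores = scores,
                 predicted = as.character(pred)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("RBF-SVM verification: accuracy %.3f, AUC %.3f (n test = %d)\n",
              x$accuracy, x$auc, length(x$scores)))
  invisible(x)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values
#' (grouping ties), producing the standard ROC step curve and its area
#' by the trapezoid rule. The AUC equals the Mann-Whitney U statistic
#' divided by n1*n2.
#'
#' @param scores Numeric decision scores, larger = more "positive".
#' @param labels Logical (or two-level) vector; `TRUE` = positive class.
#' @return List: `points` (data frame threshold, fpr, tpr, from (0,0)
#'   to (1,1)) and `auc`.
#' @export
roc_points <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels),
            any(labels), any(!labels))
  np <- sum(labels); nn <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  pts <- pts[!duplicated(pts[, c("fpr", "tpr")]), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}
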