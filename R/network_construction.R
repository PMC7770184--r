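#' Atlas ROI labels
#'
#' Returns the 116 region-of-interest labels of the AAL atlas
#' (90 cerebral regions, 18 cerebellar hemispheric lobules, 8 vermis
#' parcels) in the conventional atlas order. These are the default node
#' labels of every connectome produced by the package.
#'
#' @param n Optional number of labels to return (first `n` of the 116);
#'   useful for reduced-size simulations.
#' @return Character vector of ROI labels.
#' @export
aal116_labels <- function(n = 116L) {
  path <- system.file("extdata", "aal116_labels.txt", package = "fcstates",
                      mustWork = TRUE)
  labs <- readLines(path)
  if (n < 1L || n > length(labs))
    stop("n must be between 1 and ", length(labs))
  labs[seq_len(n)]
}

#' Construct an ROI time-series object
#'
#' One subject-session's T x R matrix of mean BOLD-like signals, one
#' column per region of interest.
#'
#' @param values Numeric T x R matrix (rows = time points).
#' @param roi_labels Character vector of R unique region labels; defaults
#'   to the matrix column names.
#' @param subject_id Subject identifier.
#' @param group Group label, one of `"NC"`, `"IBSbs"`, `"IBS1st"`.
#' @param session Session tag (`"single"`, `"baseline"` or `"post"`).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, roi_labels = colnames(values),
                           subject_id = NA_character_,
                           group = NA_character_,
                           session = NA_character_) {
  values <- as.matrix(values)
  if (is.null(roi_labels))
    roi_labels <- paste0("ROI", seq_len(ncol(values)))
  stopifnot(is.numeric(values))
  if (nrow(values) < 3L) stop("time series needs at least 3 time points")
  if (ncol(values) < 2L) stop("time series needs at least 2 ROIs")
  if (!all(is.finite(values))) stop("time series contains non-finite values")
  if (anyDuplicated(roi_labels)) stop("ROI labels must be unique")
  if (length(roi_labels) != ncol(values))
    stop("roi_labels length must match number of columns")
  colnames(values) <- roi_labels
  structure(list(values = values, roi_labels = roi_labels,
                 subject_id = subject_id, group = group, session = session),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %s [%s/%s], %d time points x %d ROIs\n",
              x$subject_id, x$group, x$session,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Functional connectivity matrix of one session
#'
#' Pairwise Pearson correlation between the mean time series of every
#' pair of ROIs. The diagonal is 1 (self-correlation) at this stage;
#' self-connections are removed later by [fisher_z()].
#'
#' A zero-variance column has no defined correlation with anything; its
#' row and column are set to 0 (and its diagonal entry to 1) with a
#' warning, so that downstream binarization stays total.
#'
#' @param ts A [roi_timeseries()] object or a plain T x R matrix.
#' @return Symmetric R x R correlation matrix with ROI labels as
#'   dimnames.
#' @export
compute_fc <- function(ts) {
  x <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  if (nrow(x) < 3L) stop("need at least 3 time points")
  sds <- apply(x, 2L, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(flat)) {
    warning(sum(flat), " zero-variance ROI column(s); their correlations set to 0")
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(colnames(x), colnames(x))
  r
}

#' Fisher z transform of a correlation matrix
#'
#' Applies arctanh to every off-diagonal entry to variance-stabilize the
#' correlations, and removes self-connections by forcing the diagonal to
#' zero. An off-diagonal correlation of exactly +/-1 has infinite z and
#' is rejected.
#'
#' @param r_matrix Symmetric correlation matrix with `|r| <= 1`.
#' @return A `weighted_connectome`: the R x R matrix of z weights with a
#'   zero diagonal, carrying its ROI labels as dimnames.
#' @export
fisher_z <- function(r_matrix) {
  r <- as.matrix(r_matrix)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (any(abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  off <- abs(r) >= 1 - .Machine$double.eps
  diag(off) <- FALSE
  if (any(off))
    stop("off-diagonal |r| = 1 would map to infinite z; offending pairs: ",
         paste(which(off, arr.ind = TRUE)[1, ], collapse = ","))
  z <- atanh(pmin(pmax(r, -1), 1))
  diag(z) <- 0
  structure(z, class = c("weighted_connectome", class(z)))
}

#' Binarize a weighted connectome on the positive-weight rule
#'
#' An edge exists iff its weight is strictly greater than zero; negative
#' and exactly-zero weights (including the removed self-connections) map
#' to 0. The sign of a Fisher z weight equals the sign of the underlying
#' correlation, so the rule is identical on r and on z.
#'
#' @param w A `weighted_connectome` (or any symmetric numeric matrix of
#'   edge weights with a zero diagonal).
#' @return A `binary_connectome`: 0/1 adjacency matrix, zero diagonal.
#' @export
binarize_positive <- function(w) {
  w <- unclass(as.matrix(w))
  a <- (w > 0) * 1L
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  structure(a, class = c("binary_connectome", class(a)))
}

#' Group frequency connection matrix
#'
#' Counts, for every unordered ROI pair, how many subjects in a group
#' possess the binarized edge: if m subjects have the edge, its
#' frequency is m.
#'
#' @param nets List of `binary_connectome` adjacency matrices sharing
#'   dimensions and ROI labels.
#' @return A `frequency_matrix`: integer R x R matrix of counts with an
#'   `n_subjects` attribute.
#' @export
frequency_matrix <- function(nets) {
  if (length(nets) == 0L) stop("need at least one network")
  dims <- vapply(nets, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("all networks must share dimensions")
  labs <- dimnames(nets[[1L]])
  counts <- Reduce(`+`, lapply(nets, function(a) unclass(as.matrix(a))))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- labs
  structure(counts, n_subjects = length(nets),
            class = c("frequency_matrix", class(counts)))
}

#' Count never-connected ROI pairs
#'
#' Number of unordered off-diagonal pairs whose frequency count is zero,
#' i.e. edges absent in every subject of the group. A ROI subset (e.g.
#' the cerebellar parcels) restricts the count to pairs within the
#' subset.
#'
#' @param f A [frequency_matrix()].
#' @param roi_subset Optional character vector of ROI labels, or integer
#'   indices, restricting the pair scan.
#' @return Integer count of unconnected pairs.
#' @export
count_unconnected_edges <- function(f, roi_subset = NULL) {
  m <- unclass(as.matrix(f))
  if (!is.null(roi_subset)) {
    idx <- if (is.character(roi_subset)) match(roi_subset, rownames(m))
           else as.integer(roi_subset)
    if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(m)))
      stop("roi_subset contains unknown ROIs")
    m <- m[idx, idx, drop = FALSE]
  }
  sum(m[upper.tri(m)] == 0)
}

#' Write / read a connectome matrix as TSV
#'
#' Plain-text interchange: an R x R matrix with the ROI labels as header
#' row and no row names.
#'
#' @param m Matrix to write.
#' @param path File path.
#' @return `write_connectome_tsv` returns `path` invisibly;
#'   `read_connectome_tsv` returns the labelled matrix.
#' @export
write_connectome_tsv <- function(m, path) {
  m <- unclass(as.matrix(m))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_connectome_tsv
#' @export
read_connectome_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  m
}
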