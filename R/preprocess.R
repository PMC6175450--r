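# Trace normalization and the variance-explained ratio used both for
# hierarchical pre-clustering and SOM node-count selection.

#' Z-normalize expression traces
#'
#' Rescales each gene's trace to mean 0 and unit variance across
#' timepoints; the per-timepoint uncertainty is rescaled by the same
#' factor. Population (1/n) variance is the default convention.
#'
#' @param x genes x timepoints FPKM matrix (or the list returned by
#'   \code{\link{expression_matrix}}).
#' @param sd matching uncertainty matrix (optional when \code{x} is a
#'   matrix).
#' @param variance "population" (1/n, default) or "sample" (1/(n-1)).
#' @return list with \code{x}, \code{sd} (normalized matrices restricted
#'   to non-constant traces) and \code{excluded} (gene ids of constant
#'   traces, which cannot be normalized and are dropped with a warning).
#' @export
znormalize <- function(x, sd = NULL, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  days <- NULL
  if (is.list(x) && !is.data.frame(x)) {
    sd <- x$sd
    days <- x$days
    x <- x$x
  }
  x <- as.matrix(x)
  mu <- rowMeans(x)
  vfun <- if (variance == "population") pop_var else var
  v <- apply(x, 1L, vfun)
  constant <- v <= 0
  if (any(constant)) {
    warning(sum(constant), " constant trace(s) excluded: ",
            paste(head(rownames(x)[constant], 5L), collapse = ", "))
  }
  keep <- which(!constant)
  scale <- sqrt(v[keep])
  xn <- (x[keep, , drop = FALSE] - mu[keep]) / scale
  sn <- if (is.null(sd)) NULL else as.matrix(sd)[keep, , drop = FALSE] / scale
  list(x = xn, sd = sn, days = days,
       excluded = rownames(x)[constant] %||% character(0))
}

#' Between-cluster over total sum of squares
#'
#' The variance-explained ratio sum_c N_c ||xbar_c - xbar||^2 /
#' sum_g ||x_g - xbar||^2, with traces compared in the full time
#' dimension. Equals 0 for a single cluster and 1 for singletons.
#'
#' @param assignment integer/character cluster label per row of \code{x}.
#' @param x genes x timepoints matrix.
#' @return ratio in \[0, 1\].
#' @export
variance_explained_ratio <- function(assignment, x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("undefined ratio: no genes")
  if (length(assignment) != nrow(x)) {
    stop("assignment must cover every row of x")
  }
  xbar <- colMeans(x)
  tss <- sum(sweep(x, 2L, xbar)^2)
  if (tss == 0) return(0)
  labs <- unique(assignment)
  bss <- 0
  for (l in labs) {
    sel <- assignment == l
    cm <- colMeans(x[sel, , drop = FALSE])
    bss <- bss + sum(sel) * sum((cm - xbar)^2)
  }
  bss / tss
}

#' Hierarchical pre-clustering of expression traces
#'
#' Complete-linkage hierarchical clustering on Euclidean distances between
#' normalized traces, cut at the smallest number of clusters H whose
#' variance-explained ratio reaches \code{target_ratio}. The per-cluster
#' mean traces feed the co-expression module detector.
#'
#' @param x normalized genes x timepoints matrix (>= 2 rows).
#' @param target_ratio required between/total sum-of-squares ratio in
#'   (0, 1].
#' @return list of class \code{precluster} with \code{assignment} (named
#'   integer vector), \code{centers} (cluster x timepoint mean matrix),
#'   \code{sizes}, \code{H} and \code{ratio}.
#' @export
hierarchical_precluster <- function(x, target_ratio = 0.98) {
  if (!is.numeric(target_ratio) || target_ratio <= 0 || target_ratio > 1) {
    stop("configuration error: target_ratio must lie in (0, 1]")
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 genes to pre-cluster")
  hc <- hclust(dist(x), method = "complete")
  H <- NA_integer_
  ratio <- NA_real_
  for (h in seq_len(nrow(x))) {
    cut <- cutree(hc, k = h)
    r <- variance_explained_ratio(cut, x)
    if (r >= target_ratio) {
      H <- h
      ratio <- r
      assignment <- cut
      break
    }
  }
  centers <- t(vapply(seq_len(H), function(cl) {
    colMeans(x[assignment == cl, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(centers) <- sprintf("cluster%04d", seq_len(H))
  structure(list(assignment = assignment, centers = centers,
                 sizes = as.integer(table(assignment)), H = H, ratio = ratio),
            class = "precluster")
}

#' @export
print.precluster <- function(x, ...) {
  cat("Hierarchical pre-clustering\n")
  cat(sprintf("  %d genes in %d clusters (variance-explained ratio %.4f)\n",
              length(x$assignment), x$H, x$ratio))
  invisible(x)
}
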