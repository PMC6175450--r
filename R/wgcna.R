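# Self-contained co-expression module detection: soft-thresholded
# adjacency, topological overlap, average-linkage tree cut and eigengene
# merging, plus the homologue same-module statistics.

#' Soft-thresholded co-expression adjacency
#'
#' a_ij = |cor(x_i, x_j)|^beta (unsigned, default) or
#' ((1 + cor)/2)^beta (signed); the diagonal is set to 1 by convention.
#' Zero-variance profiles are excluded with a warning.
#'
#' @param profiles nodes x timepoints matrix.
#' @param beta soft-threshold power (default 30).
#' @param signed use the signed transform.
#' @return symmetric adjacency matrix in \[0, 1\].
#' @export
soft_adjacency <- function(profiles, beta = 30, signed = FALSE) {
  x <- as.matrix(profiles)
  if (nrow(x) < 2L) stop("need at least 2 profiles")
  v <- apply(x, 1L, pop_var)
  if (any(v <= 0)) {
    warning(sum(v <= 0), " zero-variance profile(s) excluded")
    x <- x[v > 0, , drop = FALSE]
  }
  r <- cor(t(x))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' connectivity k_i = sum_{u != i} a_iu and TOM_ii = 1.
#'
#' @param adjacency symmetric adjacency matrix in \[0, 1\] with unit
#'   diagonal.
#' @return symmetric TOM similarity matrix in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# First principal component of the member profiles, oriented so that its
# mean correlation with the members is positive.
module_eigengene <- function(profiles) {
  if (nrow(profiles) == 1L) return(profiles[1L, ])
  pc <- prcomp(t(profiles), center = TRUE, scale. = FALSE)
  e <- pc$x[, 1L]
  if (mean(cor(e, t(profiles))) < 0) e <- -e
  unname(e)
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' 1 - TOM with a static cut at \code{cut_height}; clusters smaller than
#' \code{min_size} are left unassigned. Module eigengenes (first principal
#' component of member profiles) are then compared and modules whose
#' eigengene correlation is at least 1 - \code{merge_height} are merged
#' iteratively until no pair qualifies.
#'
#' @param profiles nodes x timepoints matrix (pre-cluster mean traces).
#' @param beta soft-threshold power.
#' @param signed signed adjacency flag.
#' @param min_size minimum module size before merging (default 30).
#' @param cut_height static tree-cut dissimilarity (default 0.99).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. merge at eigengene correlation >= 0.75);
#'   0 disables merging.
#' @return list of class \code{module_set} with \code{labels} (0 =
#'   unassigned), \code{eigengenes}, \code{n_modules}, \code{tom}.
#' @export
detect_modules <- function(profiles, beta = 30, signed = FALSE,
                           min_size = 30, cut_height = 0.99,
                           merge_height = 0.25) {
  x <- as.matrix(profiles)
  if (is.null(rownames(x))) rownames(x) <- sprintf("node%04d", seq_len(nrow(x)))
  adj <- soft_adjacency(x, beta = beta, signed = signed)
  tom <- topological_overlap(adj)
  hc <- hclust(stats::as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(nrow(x))
  names(labels) <- rownames(x)
  for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  if (all(labels == 0L)) {
    warning("all nodes unassigned: no cluster reached min_size")
    return(structure(list(labels = labels, eigengenes = NULL,
                          n_modules = 0L, tom = tom),
                     class = "module_set"))
  }
  # iterative eigengene merging to a fixed point; module count never grows
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    eig <- t(vapply(mods, function(m) {
      module_eigengene(x[labels == m, , drop = FALSE])
    }, numeric(ncol(x))))
    if (length(mods) < 2L || merge_height <= 0) break
    ec <- cor(t(eig))
    diag(ec) <- -Inf
    best <- which(ec == max(ec), arr.ind = TRUE)[1L, ]
    if (ec[best[1L], best[2L]] < 1 - merge_height) break
    from <- mods[max(best)]
    to <- mods[min(best)]
    labels[labels == from] <- to
  }
  mods <- sort(unique(labels[labels > 0L]))
  relab <- labels
  for (i in seq_along(mods)) relab[labels == mods[i]] <- i
  mods2 <- seq_along(mods)
  eig <- t(vapply(mods2, function(m) {
    module_eigengene(x[relab == m, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(eig) <- sprintf("module%02d", mods2)
  structure(list(labels = relab, eigengenes = eig,
                 n_modules = length(mods2), tom = tom),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("Co-expression module set\n")
  cat(sprintf("  %d nodes, %d modules, %d unassigned\n",
              length(x$labels), x$n_modules, sum(x$labels == 0L)))
  if (x$n_modules > 0L) {
    print(table(module = x$labels[x$labels > 0L]))
  }
  invisible(x)
}

#' Same-module fraction of homologue families
#'
#' Genes inherit the module of their pre-cluster; for each reference-gene
#' family the number of expressed copies and of distinct modules they
#' occupy is reported. A family is consistent with tight co-regulation
#' when all copies fall in one module. Genes without a module (unassigned
#' pre-cluster) count as their own singleton module.
#'
#' @param families data frame (gene_id, reference_gene_id) of expressed
#'   genes.
#' @param gene_cluster named vector mapping gene_id to pre-cluster label.
#' @param module_set a \code{\link{detect_modules}} result (or a named
#'   vector mapping cluster label to module).
#' @return list with \code{families} (per-family table) and
#'   \code{fraction_same_module} over families with >= 2 copies.
#' @export
same_module_fraction <- function(families, gene_cluster, module_set) {
  assert_cols(families, c("gene_id", "reference_gene_id"))
  mod_of_cluster <- if (inherits(module_set, "module_set")) {
    module_set$labels
  } else {
    module_set
  }
  cl <- gene_cluster[families$gene_id]
  mod <- mod_of_cluster[as.character(cl)]
  # unassigned or missing -> unique singleton pseudo-modules (negative ids)
  missing <- is.na(mod) | mod == 0L
  mod <- as.integer(mod)
  mod[missing] <- -seq_len(sum(missing))
  fam <- split(mod, families$reference_gene_id)
  tab <- data.frame(
    reference_gene_id = names(fam),
    n_expressed_copies = vapply(fam, length, 0L),
    n_distinct_modules = vapply(fam, function(m) length(unique(m)), 0L),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  multi <- tab$n_expressed_copies >= 2L
  frac <- if (any(multi)) mean(tab$n_distinct_modules[multi] == 1L) else NaN
  list(families = tab, fraction_same_module = frac)
}
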