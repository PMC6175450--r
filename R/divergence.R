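# The ensemble-SOM divergence method: erf-soft-thresholded clustering
# coefficients, clique regulatory modules and the five-way classification
# of homologue families.

#' Clustering coefficient from ensemble co-mapping statistics
#'
#' 0.5 * (1 + erf((mu - theta) / (sigma * sqrt(2)))): the probability mass
#' of a Gaussian with the pair's across-map mean and SD that lies above
#' the threshold. At sigma = 0 the limit is a step: 1 when mu > theta,
#' 0 when mu < theta, 0.5 at equality.
#'
#' @param mu mean co-mapping probability across maps.
#' @param sigma SD of the co-mapping probability across maps (>= 0).
#' @param theta threshold (see \code{\link{derive_threshold}}).
#' @return coefficient in \[0, 1\]; vectorized.
#' @export
clustering_coefficient <- function(mu, sigma, theta) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  n <- max(length(mu), length(sigma), length(theta))
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  theta <- rep_len(theta, n)
  out <- numeric(n)
  pos <- sigma > 0
  out[pos] <- 0.5 * (1 + erf((mu[pos] - theta[pos]) /
                               (sigma[pos] * sqrt(2))))
  out[!pos] <- (mu[!pos] > theta[!pos]) + 0.5 * (mu[!pos] == theta[!pos])
  out
}

# Deterministic Bron-Kerbosch maximal-clique enumeration with pivoting.
# `adj` is a logical adjacency matrix (no self loops assumed relevant).
bron_kerbosch <- function(adj) {
  diag(adj) <- FALSE
  res <- list()
  expand <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      res[[length(res) + 1L]] <<- R
      return(invisible(NULL))
    }
    pool <- c(P, X)
    u <- pool[which.max(vapply(pool, function(v) sum(adj[v, P]), 0L))]
    for (v in P[!adj[u, P]]) {
      nb <- which(adj[v, ])
      expand(c(R, v), P[P %in% nb], X[X %in% nb])
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  expand(integer(0), seq_len(nrow(adj)), integer(0))
  res
}

#' Binarize clustering coefficients and enumerate regulatory modules
#'
#' Coefficients above 0.5 become edges; genes whose self-coefficient does
#' not exceed 0.5 (genes that do not robustly map to the SOM) are removed
#' first. Regulatory modules are the maximal cliques of the remaining
#' binary graph; a gene may belong to several modules. Enumeration is
#' deterministic; modules are reported sorted by decreasing size then by
#' member ids, members sorted.
#'
#' @param coefficients symmetric matrix of pairwise clustering
#'   coefficients with gene ids as dimnames.
#' @param self_coefficients named vector of self clustering coefficients.
#' @return list with \code{modules} (list of character vectors) and
#'   \code{removed} (non-robust gene ids).
#' @export
binarize_and_modularize <- function(coefficients, self_coefficients) {
  m <- as.matrix(coefficients)
  if (max(abs(m - t(m)), 0) > 1e-8) stop("coefficient matrix must be symmetric")
  genes <- rownames(m) %||% names(self_coefficients)
  robust <- genes[self_coefficients[genes] > 0.5]
  removed <- setdiff(genes, robust)
  if (length(robust) == 0L) {
    return(list(modules = list(), removed = removed))
  }
  adj <- m[robust, robust, drop = FALSE] > 0.5
  cliques <- bron_kerbosch(adj)
  modules <- lapply(cliques, function(ix) sort(robust[ix]))
  o <- order(-vapply(modules, length, 0L),
             vapply(modules, function(m) paste(m, collapse = "|"), ""))
  list(modules = modules[o], removed = removed)
}

#' Classify a family's pattern of regulatory module assignment
#'
#' Five patterns of module assignment within a homologue family:
#' \emph{redundant} (a single module holds every robust gene),
#' \emph{unique} (every module is a singleton, one per gene),
#' \emph{distinct} (two or more mutually disjoint modules, at least one
#' with two or more genes), \emph{gradated} (two or more modules, each
#' sharing at least one gene with another), and \emph{mixed} (at least
#' one overlapping pair of modules together with at least one module
#' disjoint from all others). Families with fewer than two robust genes
#' are unclassifiable.
#'
#' @param modules list of modules (character vectors) as returned by
#'   \code{\link{binarize_and_modularize}}.
#' @param robust_genes the robust gene ids the modules cover.
#' @return one of "redundant", "distinct", "gradated", "unique", "mixed",
#'   "unclassifiable".
#' @export
classify_pattern <- function(modules, robust_genes) {
  if (length(robust_genes) < 2L) return("unclassifiable")
  nm <- length(modules)
  if (nm == 0L) return("unclassifiable")
  if (nm == 1L) return("redundant")
  sizes <- vapply(modules, length, 0L)
  overlaps <- vapply(seq_len(nm), function(i) {
    any(vapply(seq_len(nm)[-i], function(j) {
      length(intersect(modules[[i]], modules[[j]])) > 0L
    }, FALSE))
  }, FALSE)
  if (!any(overlaps)) {
    if (all(sizes == 1L) && nm == length(robust_genes)) return("unique")
    return("distinct")
  }
  if (all(overlaps)) return("gradated")
  "mixed"
}

#' Cohort tables for a set of pattern calls
#'
#' Builds the per-tissue pattern percentage table and, when homologue
#' pairs are supplied, the per-pair same-module flags (both members
#' robust and sharing at least one regulatory module) with the resulting
#' integer percentage.
#'
#' @param calls data frame with columns reference_gene_id and pattern
#'   (from \code{\link{som_divergence}}; unclassifiable rows are excluded
#'   from the percentage table).
#' @param modules named list (by gene id is not needed; by family) of
#'   module lists, as stored on a \code{som_divergence} fit. Only needed
#'   for pair calls.
#' @param pairs optional data frame (a_genome_gene_id, c_genome_gene_id).
#' @return list with \code{pattern_counts} (pattern, n, percent),
#'   \code{pair_calls}, \code{percent_same_module}.
#' @export
family_divergence_summary <- function(calls, modules = NULL, pairs = NULL) {
  assert_cols(calls, c("reference_gene_id", "pattern"))
  cls <- calls$pattern[calls$pattern != "unclassifiable"]
  lev <- c("distinct", "gradated", "unique", "redundant", "mixed")
  n <- vapply(lev, function(p) sum(cls == p), 0L)
  pattern_counts <- data.frame(
    pattern = lev, n = n,
    percent = if (length(cls) > 0) percent_round(n, length(cls))
              else rep(NA_integer_, length(lev)))
  pair_calls <- NULL
  percent_same <- NA_integer_
  if (!is.null(pairs)) {
    assert_cols(pairs, c("a_genome_gene_id", "c_genome_gene_id"))
    all_modules <- unlist(modules, recursive = FALSE)
    same <- vapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs$a_genome_gene_id[i]
      b <- pairs$c_genome_gene_id[i]
      any(vapply(all_modules,
                 function(m) all(c(a, b) %in% m), FALSE))
    }, FALSE)
    pair_calls <- cbind(pairs, same_module = same)
    if (nrow(pairs) > 0) {
      percent_same <- percent_round(sum(same), nrow(pairs))
    }
  }
  list(pattern_counts = pattern_counts, pair_calls = pair_calls,
       percent_same_module = percent_same)
}

#' Cross-tissue intersection of same-module pairs
#'
#' @param pair_calls_1,pair_calls_2 \code{pair_calls} tables from
#'   \code{\link{family_divergence_summary}} for two tissues.
#' @return number of pairs flagged same-module in both tissues.
#' @export
same_module_intersection <- function(pair_calls_1, pair_calls_2) {
  key <- function(pc) {
    paste(pc$a_genome_gene_id, pc$c_genome_gene_id)[pc$same_module]
  }
  length(intersect(key(pair_calls_1), key(pair_calls_2)))
}

#' Fit the ensemble-SOM regulatory divergence model
#'
#' The core analysis: expressed genes are z-normalized, a SOM grid is
#' sized from the data (aspect ratio of the first two principal-component
#' eigenvalues; node count reaching the variance-explained target), an
#' ensemble of M maps is trained, and each gene's trace is resampled B
#' times per map under its per-timepoint uncertainty. Pairwise co-mapping
#' probabilities within each homologue family are averaged across maps,
#' soft-thresholded into clustering coefficients at the threshold theta
#' derived from the self-consistency distribution, binarized at 0.5, and
#' the resulting clique regulatory modules classify every family into one
#' of the five divergence patterns.
#'
#' @param expression long expression data frame (gene_id, tissue, day,
#'   fpkm, fpkm_sd).
#' @param families data frame (gene_id, reference_gene_id) defining the
#'   homologue families of interest. Other expressed genes still inform
#'   map training and the threshold.
#' @param tissue tissue analysed.
#' @param threshold expressed-gene FPKM threshold (inclusive, default 2).
#' @param M ensemble size (default 100).
#' @param B resampling draws per gene per map (default 500).
#' @param target_ratio variance-explained target for grid sizing.
#' @param dims optional explicit grid dimensions (skips the search).
#' @param theta optional explicit threshold (skips the derivation).
#' @param noise_scale interpret the uncertainty column as an "sd"
#'   (default) or a "variance".
#' @param seed master seed for the ensemble.
#' @param max_nodes cap for the grid search.
#' @return an object of class \code{som_divergence}; see
#'   \code{\link{print.som_divergence}}, \code{summary}, \code{coef} and
#'   \code{plot} methods.
#' @export
som_divergence <- function(expression, families, tissue = "apex",
                           threshold = 2.0, M = 100L, B = 500L,
                           target_ratio = 0.85, dims = NULL, theta = NULL,
                           noise_scale = "sd", seed = 1L, max_nodes = NULL) {
  assert_cols(families, c("gene_id", "reference_gene_id"))
  flags <- filter_expressed(expression, threshold, tissue)
  expressed <- names(flags)[flags]
  if (length(expressed) < 3L) stop("fewer than 3 expressed genes")
  em <- expression_matrix(
    expression[expression$gene_id %in% expressed, , drop = FALSE], tissue)
  xn <- znormalize(em)
  x <- em$x[rownames(xn$x), , drop = FALSE]
  s <- em$sd[rownames(xn$x), , drop = FALSE]
  if (is.null(dims)) {
    grid <- choose_grid(xn$x, target_ratio = target_ratio,
                        seed = derive_seed(seed, 999L), max_nodes = max_nodes)
    dims <- grid$dims
  } else {
    grid <- list(dims = as.integer(dims), S = prod(dims), ratio = NA_real_)
  }
  fam <- families[families$gene_id %in% rownames(x), , drop = FALSE]
  fam_split <- split(fam$gene_id, fam$reference_gene_id)
  pair_list <- lapply(fam_split, function(g) {
    if (length(g) < 2L) return(NULL)
    t(utils::combn(sort(g), 2L))
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) stop("no family has 2 or more expressed copies")
  ens <- ensemble_probabilities(x, s, dims = dims, pairs = pairs, M = M,
                                B = B, base_seed = seed,
                                noise_scale = noise_scale)
  if (is.null(theta)) theta <- derive_threshold(ens$self_per_map)
  pair_tab <- ens$pairs
  pair_tab$coefficient <- clustering_coefficient(pair_tab$mu,
                                                 pair_tab$sigma, theta)
  self_tab <- ens$self
  self_tab$coefficient <- clustering_coefficient(self_tab$mu,
                                                 self_tab$sigma, theta)
  self_coef <- setNames(self_tab$coefficient, self_tab$gene)
  per_family <- lapply(names(fam_split), function(ref) {
    g <- sort(fam_split[[ref]])
    cm <- matrix(1, length(g), length(g), dimnames = list(g, g))
    if (length(g) >= 2L) {
      sel <- pair_tab$gene1 %in% g & pair_tab$gene2 %in% g
      pt <- pair_tab[sel, , drop = FALSE]
      cm[cbind(pt$gene1, pt$gene2)] <- pt$coefficient
      cm[cbind(pt$gene2, pt$gene1)] <- pt$coefficient
    }
    diag(cm) <- self_coef[g]
    bm <- binarize_and_modularize(cm, self_coef[g])
    robust <- setdiff(g, bm$removed)
    list(reference_gene_id = ref, coefficients = cm, modules = bm$modules,
         removed = bm$removed,
         pattern = classify_pattern(bm$modules, robust))
  })
  names(per_family) <- names(fam_split)
  calls <- data.frame(
    reference_gene_id = names(per_family),
    n_expressed = vapply(per_family, function(f) ncol(f$coefficients), 0L),
    n_robust = vapply(per_family,
                      function(f) ncol(f$coefficients) - length(f$removed),
                      0L),
    n_modules = vapply(per_family, function(f) length(f$modules), 0L),
    pattern = vapply(per_family, `[[`, "", "pattern"),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(calls = calls, families = per_family, pairs = pair_tab,
                 self = self_tab, theta = theta, dims = dims,
                 grid = grid, M = M, B = B, tissue = tissue,
                 expressed_genes = rownames(x),
                 excluded = xn$excluded, seed = seed),
            class = "som_divergence")
}

#' @describeIn som_divergence compact overview of the fit.
#' @param x,object a \code{som_divergence} fit.
#' @param ... unused.
#' @export
print.som_divergence <- function(x, ...) {
  cat("Ensemble-SOM regulatory divergence fit\n")
  cat(sprintf("  tissue: %s; %d expressed genes; grid %d x %d; M = %d maps; B = %d draws\n",
              x$tissue, length(x$expressed_genes), x$dims[1L], x$dims[2L],
              x$M, x$B))
  cat(sprintf("  threshold theta = %.4f\n", x$theta))
  cat(sprintf("  %d families classified:\n", nrow(x$calls)))
  print(table(pattern = x$calls$pattern))
  invisible(x)
}

#' @describeIn som_divergence cohort summary with pattern percentages.
#' @param pairs optional homologue pairs for same-module percentages.
#' @export
summary.som_divergence <- function(object, pairs = NULL, ...) {
  out <- family_divergence_summary(
    object$calls, modules = lapply(object$families, `[[`, "modules"),
    pairs = pairs)
  out$theta <- object$theta
  out$n_families <- nrow(object$calls)
  class(out) <- "summary.som_divergence"
  out
}

#' @export
print.summary.som_divergence <- function(x, ...) {
  cat(sprintf("Divergence patterns over %d families (theta = %.4f):\n",
              x$n_families, x$theta))
  print(x$pattern_counts, row.names = FALSE)
  if (!is.null(x$pair_calls)) {
    cat(sprintf("Homologue pairs in a shared module: %d / %d (%d%%)\n",
                sum(x$pair_calls$same_module), nrow(x$pair_calls),
                x$percent_same_module))
  }
  invisible(x)
}

#' @describeIn som_divergence pairwise clustering coefficients; with
#'   \code{family} set, the family's coefficient matrix.
#' @param family a reference gene id.
#' @export
coef.som_divergence <- function(object, family = NULL, ...) {
  if (is.null(family)) return(object$pairs)
  f <- object$families[[family]]
  if (is.null(f)) stop("unknown family: ", family)
  f$coefficients
}

#' @describeIn som_divergence clustering-coefficient heatmap of one
#'   family, robust genes only annotated.
#' @export
plot.som_divergence <- function(x, family, ...) {
  cm <- coef.som_divergence(x, family)
  n <- nrow(cm)
  graphics::image(seq_len(n), seq_len(n), t(cm[n:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = sprintf("%s (%s)", family,
                                 x$families[[family]]$pattern), ...)
  graphics::axis(1L, at = seq_len(n), labels = colnames(cm), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2L, at = seq_len(n), labels = rev(rownames(cm)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
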