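# Self-organizing map machinery: grid sizing by principal-component
# aspect, seeded Kohonen training, and the resampling loop that turns
# per-timepoint uncertainty into node-mapping counts.

#' Train a self-organizing map on normalized traces
#'
#' Online Kohonen training on a rectangular grid with a Gaussian
#' neighbourhood. The neighbourhood radius decays linearly from half the
#' larger grid dimension to 1 and the learning rate from 0.05 to 0.01;
#' the number of iterations defaults to 100 per gene. The codebook is
#' initialized from randomly sampled data rows. Deterministic given the
#' seed.
#'
#' @param x normalized genes x timepoints matrix.
#' @param dims integer (rows, cols) of the grid.
#' @param seed integer seed.
#' @param n_iter training iterations.
#' @param alpha learning-rate schedule (start, end).
#' @param radius neighbourhood radius schedule (start, end); default
#'   c(max(dims)/2, 1).
#' @return object of class \code{som_grid} with \code{codebook} (S x T),
#'   \code{dims}, and the quantization-error trace \code{qe}.
#' @export
train_som <- function(x, dims, seed = NULL, n_iter = 100L * nrow(x),
                      alpha = c(0.05, 0.01), radius = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty data")
  dims <- as.integer(dims)
  stopifnot(length(dims) == 2L, all(dims >= 1L))
  S <- prod(dims)
  if (is.null(radius)) radius <- c(max(dims) / 2, 1)
  with_seed(seed, {
    init <- x[sample.int(nrow(x), S, replace = nrow(x) < S), , drop = FALSE]
    w <- cpp_som_train(x, init, dims[1L], dims[2L], as.integer(n_iter),
                       alpha[1L], alpha[2L], radius[1L], radius[2L])
    structure(list(codebook = w[, , drop = FALSE], dims = dims, S = S,
                   qe = attr(w, "qe"), seed = seed),
              class = "som_grid")
  })
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("SOM grid %d x %d (%d nodes), trace length %d\n",
              x$dims[1L], x$dims[2L], x$S, ncol(x$codebook)))
  invisible(x)
}

#' Assign traces to their nearest codebook node
#'
#' @param som a \code{som_grid}.
#' @param x traces (matrix or single vector).
#' @return integer node indices (1-based).
#' @export
assign_nodes <- function(som, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  cpp_assign_bmu(as.matrix(x), som$codebook)
}

# Factor pair (rows, cols) of S whose aspect best matches `aspect` >= 1.
grid_dims_for <- function(S, aspect) {
  divs <- which(S %% seq_len(S) == 0L)
  cand <- cbind(rows = S / divs, cols = divs)
  cand <- cand[cand[, 1L] >= cand[, 2L], , drop = FALSE]
  err <- abs(log(cand[, 1L] / cand[, 2L]) - log(max(aspect, 1)))
  as.integer(cand[which.min(err), ])
}

#' Choose the SOM grid size from the data
#'
#' The grid aspect ratio follows the ratio of the first two principal
#' component eigenvalues of the data; the node count S is the smallest
#' value whose trained-map variance-explained ratio (node assignments as
#' clusters) reaches \code{target_ratio}. The search doubles S until the
#' target is met, then binary-refines downward to the smallest adequate S.
#'
#' @param x normalized genes x timepoints matrix (>= 3 genes).
#' @param target_ratio required variance-explained ratio (default 0.85).
#' @param seed seed used for the trial trainings.
#' @param max_nodes search cap (default number of genes).
#' @param n_iter_per_gene training iterations per gene for trial maps.
#' @return list with \code{dims}, \code{S}, \code{ratio}, \code{aspect}.
#' @export
choose_grid <- function(x, target_ratio = 0.85, seed = 1L, max_nodes = NULL,
                        n_iter_per_gene = 100L) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 genes to size a map")
  max_nodes <- max_nodes %||% nrow(x)
  ev <- prcomp(x, center = TRUE, scale. = FALSE)$sdev^2
  aspect <- if (length(ev) >= 2L && ev[2L] > .Machine$double.eps * ev[1L]) {
    ev[1L] / ev[2L]
  } else {
    warning("degenerate covariance (second eigenvalue ~ 0): 1-row map")
    Inf
  }
  ratio_for <- function(S) {
    dims <- if (is.finite(aspect)) grid_dims_for(S, aspect) else c(S, 1L)
    som <- train_som(x, dims, seed = derive_seed(seed, S),
                     n_iter = n_iter_per_gene * nrow(x))
    list(dims = dims, S = S,
         ratio = variance_explained_ratio(assign_nodes(som, x), x))
  }
  best <- ratio_for(1L)
  if (best$ratio >= target_ratio) {
    return(c(best, list(aspect = aspect)))
  }
  lo <- 1L # largest S known to miss the target
  hi <- NULL
  S <- 2L
  while (is.null(hi)) {
    res <- ratio_for(min(S, max_nodes))
    if (res$ratio >= target_ratio) {
      hi <- res
    } else if (S >= max_nodes) {
      warning(sprintf(
        "variance-explained target %.2f not reached at max_nodes=%d (%.3f)",
        target_ratio, max_nodes, res$ratio))
      return(c(res, list(aspect = aspect)))
    } else {
      lo <- min(S, max_nodes)
      S <- S * 2L
    }
  }
  while (hi$S - lo > 1L) {
    mid <- as.integer(floor((lo + hi$S) / 2))
    res <- ratio_for(mid)
    if (res$ratio >= target_ratio) hi <- res else lo <- mid
  }
  c(hi, list(aspect = aspect))
}

#' Resample a gene's node assignments under its uncertainty
#'
#' Each of the B draws perturbs every timepoint of the raw trace
#' independently (Gaussian, centred on the observed value with spread
#' given by the uncertainty column), re-normalizes the draw to mean 0 /
#' unit variance and assigns it to the nearest codebook vector. With
#' \code{noise_scale = "variance"} the uncertainty column is interpreted
#' as a variance instead of an SD.
#'
#' @param x raw (unnormalized) trace vector, or a genes x timepoints
#'   matrix.
#' @param sd matching uncertainty (vector or matrix).
#' @param som a \code{som_grid}.
#' @param B number of draws (default 500).
#' @param seed integer seed.
#' @param noise_scale "sd" (default) or "variance".
#' @return integer counts over nodes (vector for a single trace, matrix
#'   otherwise); rows always sum to B.
#' @export
resample_assignments <- function(x, sd, som, B = 500L, seed = NULL,
                                 noise_scale = c("sd", "variance")) {
  noise_scale <- match.arg(noise_scale)
  single <- is.vector(x)
  if (single) {
    x <- matrix(x, nrow = 1L)
    sd <- matrix(sd, nrow = 1L)
  }
  x <- as.matrix(x)
  sd <- as.matrix(sd)
  if (ncol(x) == 0L) stop("zero-length trace")
  if (any(sd < 0)) stop("uncertainty must be non-negative")
  if (noise_scale == "variance") sd <- sqrt(sd)
  counts <- with_seed(seed, cpp_resample_counts(x, sd, som$codebook,
                                                as.integer(B)))
  rownames(counts) <- rownames(x)
  if (single) counts[1L, ] else counts
}

#' Probability of two genes mapping to the same node
#'
#' sum_c n1_c n2_c / B^2 over a shared map; symmetric in its arguments.
#'
#' @param counts1,counts2 node-mapping count vectors from the same map
#'   (equal length, equal total B).
#' @return probability in \[0, 1\].
#' @export
co_mapping_probability <- function(counts1, counts2) {
  if (length(counts1) != length(counts2)) {
    stop("counts come from different maps (length mismatch)")
  }
  B1 <- sum(counts1)
  B2 <- sum(counts2)
  if (B1 != B2) stop("counts use different numbers of draws")
  sum(as.numeric(counts1) * as.numeric(counts2)) / (as.numeric(B1)^2)
}

#' Self-consistency of a gene's node mapping
#'
#' sum_c n_c^2 / B^2: the probability that two independent draws of the
#' same gene land on the same node. Equals
#' \code{co_mapping_probability(counts, counts)}.
#'
#' @param counts node-mapping count vector.
#' @return probability in \[0, 1\].
#' @export
self_mapping_probability <- function(counts) {
  co_mapping_probability(counts, counts)
}

#' Ensemble co-mapping probabilities over many maps
#'
#' Trains M maps from distinct derived seeds, runs the resampling loop on
#' each, and records per requested gene pair (and per gene with itself)
#' the mean and SD of the co-mapping probability across maps.
#'
#' @param x raw genes x timepoints matrix (rownames are gene ids).
#' @param sd matching uncertainty matrix.
#' @param dims grid dimensions shared by all maps (from
#'   \code{\link{choose_grid}}).
#' @param pairs two-column matrix/data frame of gene ids to score; NULL
#'   scores all pairs (only sensible for small inputs).
#' @param M ensemble size (default 100; >= 2 so the SD is defined).
#' @param B draws per gene per map (default 500).
#' @param base_seed seed from which the per-map seeds are derived.
#' @param noise_scale forwarded to \code{\link{resample_assignments}}.
#' @return object of class \code{som_ensemble}: \code{pairs} (gene1,
#'   gene2, mu, sigma), \code{self} (gene, mu, sigma), \code{self_per_map}
#'   (genes x M matrix of self-mapping probabilities), \code{dims},
#'   \code{M}, \code{B}.
#' @export
ensemble_probabilities <- function(x, sd, dims, pairs = NULL, M = 100L,
                                   B = 500L, base_seed = 1L,
                                   noise_scale = "sd") {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 genes")
  if (M < 2L) stop("M must be >= 2 for the SD over maps to be defined")
  genes <- rownames(x) %||% sprintf("gene%04d", seq_len(nrow(x)))
  rownames(x) <- genes
  if (is.null(pairs)) {
    pairs <- t(utils::combn(genes, 2L))
  }
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  i1 <- match(pairs[, 1L], genes)
  i2 <- match(pairs[, 2L], genes)
  if (anyNA(i1) || anyNA(i2)) stop("pair gene ids not found in the data")
  xn <- znormalize(x, sd)
  if (length(xn$excluded) > 0) {
    stop("constant traces must be filtered before the ensemble: ",
         paste(xn$excluded, collapse = ", "))
  }
  np <- nrow(pairs)
  pair_p <- matrix(NA_real_, np, M)
  self_p <- matrix(NA_real_, nrow(x), M, dimnames = list(genes, NULL))
  for (m in seq_len(M)) {
    som <- train_som(xn$x, dims, seed = derive_seed(base_seed, 2L * m))
    counts <- resample_assignments(x, sd, som, B = B,
                                   seed = derive_seed(base_seed, 2L * m + 1L),
                                   noise_scale = noise_scale)
    cn <- counts / B
    self_p[, m] <- rowSums(cn^2)
    pair_p[, m] <- rowSums(cn[i1, , drop = FALSE] * cn[i2, , drop = FALSE])
  }
  pair_df <- data.frame(gene1 = pairs[, 1L], gene2 = pairs[, 2L],
                        mu = rowMeans(pair_p),
                        sigma = apply(pair_p, 1L, sd),
                        stringsAsFactors = FALSE)
  self_df <- data.frame(gene = genes, mu = rowMeans(self_p),
                        sigma = apply(self_p, 1L, sd),
                        stringsAsFactors = FALSE)
  structure(list(pairs = pair_df, self = self_df, self_per_map = self_p,
                 dims = dims, M = M, B = B),
            class = "som_ensemble")
}

#' @export
print.som_ensemble <- function(x, ...) {
  cat(sprintf(
    "SOM ensemble: %d maps (%d x %d), %d draws/gene, %d pairs scored\n",
    x$M, x$dims[1L], x$dims[2L], x$B, nrow(x$pairs)))
  invisible(x)
}

#' Derive the clustering-coefficient threshold from self probabilities
#'
#' Per map, a Gaussian kernel density (Silverman bandwidth) is fitted to
#' the self-mapping probabilities restricted to \[0, 0.5\] and its argmax
#' taken; the threshold is the mean of the per-map argmaxes. When no
#' self-probability falls in \[0, 0.5\] (every gene maps consistently) the
#' configured floor is returned with a warning.
#'
#' @param self_per_map genes x maps matrix of self-mapping probabilities
#'   (a vector is treated as a single map).
#' @param floor fallback threshold (default 0.05).
#' @param upper upper end of the density search window (default 0.5).
#' @param min_frac minimum fraction of genes that must fall inside the
#'   window for a map to exhibit a low mode at all; below it the map is
#'   treated as having consistently mapping genes only.
#' @return threshold theta.
#' @export
derive_threshold <- function(self_per_map, floor = 0.05, upper = 0.5,
                             min_frac = 0.05) {
  if (is.vector(self_per_map)) self_per_map <- matrix(self_per_map)
  per_map <- apply(self_per_map, 2L, function(p) {
    n_all <- length(p)
    p <- p[p >= 0 & p <= upper]
    if (length(p) < max(2L, ceiling(min_frac * n_all))) return(NA_real_)
    if (sd(p) == 0) return(p[1L])
    d <- density(p, bw = "nrd0", from = 0, to = upper)
    peak <- d$x[which.max(d$y)]
    # a maximum at the window edge is the tail of the high-consistency
    # mode, not a low mode of its own
    if (peak > upper - d$bw) return(NA_real_)
    peak
  })
  if (all(is.na(per_map))) {
    warning("no low self-consistency mode found; using floor threshold ",
            floor)
    return(floor)
  }
  mean(per_map, na.rm = TRUE)
}
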