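# Synthetic data generation: expression families with known divergence
# patterns, copy-number tables, reciprocal hit tables and sequence pairs
# with planted conserved blocks. Every generator is deterministic given
# (spec, seed) and emits the same tabular formats the analysis consumes.

#' Default sampling days for the developmental time series
#'
#' Seven sampling days spanning a vernalization time course (days 22-72
#' after sowing, with the cold treatment between days 22 and 64). Other
#' lengths fall back to an equally spaced grid over the same span.
#'
#' @param n number of timepoints.
#' @return numeric vector of days, strictly increasing.
#' @export
default_days <- function(n = 7L) {
  if (n == 7L) c(22, 43, 64, 65, 67, 69, 72) else seq(22, 72, length.out = n)
}

#' Specify a synthetic homologue family
#'
#' A family is a set of gene copies assigned to one reference gene whose
#' expression templates realize one of five divergence patterns:
#' \describe{
#'   \item{redundant}{all copies share one template}
#'   \item{distinct}{two or more template groups, each internally identical}
#'   \item{gradated}{templates on a convex interpolation path between two
#'     dissimilar endpoints}
#'   \item{unique}{each copy has its own template, pairwise template
#'     correlations at most \code{max_template_cor}}
#'   \item{mixed}{one internally identical group plus one gradated chain}
#' }
#'
#' @param reference_gene_id identifier of the reference (diploid) gene.
#' @param n_copies number of polyploid copies (at least 1; at least 2 for
#'   unique and 3 for distinct/gradated/mixed so the pattern is realizable).
#' @param pattern one of "redundant", "distinct", "gradated", "unique",
#'   "mixed".
#' @param n_timepoints number of sampling timepoints.
#' @param base_level baseline expression in FPKM.
#' @param amplitude FPKM amplitude of the template shape. Templates have
#'   unit population variance, so with the default amplitude of 1 the
#'   noise_sd is directly the observation noise relative to the signal SD.
#' @param noise_sd per-observation Gaussian noise SD in FPKM; also written
#'   to the trace's uncertainty column.
#' @param max_template_cor upper bound on the correlation between templates
#'   that must be dissimilar (unique copies, distinct groups, and the
#'   isolated group of a mixed family against its chain).
#' @param chain_step_cor correlation between neighbouring templates along
#'   a gradated (or mixed) chain: neighbouring copies along a gradient
#'   are nearly co-regulated, with divergence accumulating over the
#'   chain, so the endpoint correlation is
#'   cos((n - 1) * acos(chain_step_cor)).
#' @param seed integer seed; the family is bit-reproducible given the spec object.
#' @return an object of class \code{family_spec}.
#' @export
family_spec <- function(reference_gene_id, n_copies, pattern,
                        n_timepoints = 7L, base_level = 10, amplitude = 1,
                        noise_sd = 0.5, max_template_cor = 0.2,
                        chain_step_cor = 0.95, seed = NULL) {
  pattern <- match.arg(pattern,
                       c("redundant", "distinct", "gradated", "unique", "mixed"))
  n_copies <- as.integer(n_copies)
  if (n_copies < 1L) stop("invalid family spec: n_copies must be >= 1")
  if (noise_sd < 0) stop("invalid family spec: noise_sd must be >= 0")
  if (pattern == "unique" && n_copies < 2L) {
    stop("invalid family spec: pattern 'unique' requires n_copies >= 2")
  }
  if (pattern %in% c("distinct", "gradated", "mixed") && n_copies < 3L) {
    stop(sprintf(
      "invalid family spec: pattern '%s' requires n_copies >= 3", pattern))
  }
  if (n_timepoints < 2L) stop("invalid family spec: need >= 2 timepoints")
  structure(list(reference_gene_id = as.character(reference_gene_id),
                 n_copies = n_copies, pattern = pattern,
                 n_timepoints = as.integer(n_timepoints),
                 base_level = base_level, amplitude = amplitude,
                 noise_sd = noise_sd, max_template_cor = max_template_cor,
                 chain_step_cor = chain_step_cor, seed = seed),
            class = "family_spec")
}

# Standardize a trace to mean 0 and unit population variance.
standardize <- function(x) {
  s <- pop_sd(x)
  if (s == 0) stop("cannot standardize a constant trace")
  (x - mean(x)) / s
}

# One random piecewise-linear template shape: values drawn at 4 knots and
# linearly interpolated onto the day grid, then standardized.
rand_shape <- function(days) {
  k <- unique(round(seq(1, length(days), length.out = min(4L, length(days)))))
  knots <- days[k]
  vals <- rnorm(length(knots))
  standardize(stats::approx(knots, vals, xout = days)$y)
}

# Draw k template shapes whose pairwise correlations are all <= max_cor.
rand_shape_set <- function(k, days, max_cor, max_tries = 2000L) {
  shapes <- matrix(NA_real_, k, length(days))
  i <- 1L
  tries <- 0L
  while (i <= k) {
    cand <- rand_shape(days)
    ok <- i == 1L ||
      all(apply(shapes[seq_len(i - 1L), , drop = FALSE], 1L,
                function(s) cor(s, cand)) <= max_cor)
    if (ok) {
      shapes[i, ] <- cand
      i <- i + 1L
    }
    tries <- tries + 1L
    if (tries > max_tries) stop("failed to draw dissimilar template shapes")
  }
  shapes
}

# A shape correlated with `base` at exactly `rho` (population correlation).
correlated_shape <- function(base, rho, days) {
  r <- rand_shape(days)
  orth <- r - cor(base, r) * base
  if (pop_sd(orth) == 0) orth <- rand_shape(days) # pathological draw
  standardize(rho * base + sqrt(max(1 - rho^2, 0)) * standardize(orth))
}

# Interpolation ladder of n templates between two endpoint shapes.
chain_templates <- function(e0, e1, n) {
  alpha <- seq(0, 1, length.out = n)
  t(vapply(alpha, function(a) standardize((1 - a) * e0 + a * e1),
           numeric(length(e0))))
}

# Template matrix (n_copies x n_timepoints) realizing the family's pattern.
family_templates <- function(spec) {
  days <- default_days(spec$n_timepoints)
  n <- spec$n_copies
  mc <- spec$max_template_cor
  switch(spec$pattern,
    redundant = {
      s <- rand_shape(days)
      matrix(s, n, length(days), byrow = TRUE)
    },
    unique = rand_shape_set(n, days, mc),
    distinct = {
      sizes <- c(ceiling(n / 2), floor(n / 2))
      g <- rand_shape_set(2L, days, mc)
      g[rep(seq_along(sizes), sizes), , drop = FALSE]
    },
    gradated = {
      e0 <- rand_shape(days)
      rho_end <- cos((n - 1L) * acos(min(spec$chain_step_cor, 1)))
      e1 <- correlated_shape(e0, rho_end, days)
      chain_templates(e0, e1, n)
    },
    mixed = {
      # one internally identical group plus a gradated chain of up to 4
      # copies, the group dissimilar from the whole chain
      n_chain <- min(4L, n - 1L)
      n_group <- n - n_chain
      e0 <- rand_shape(days)
      rho_end <- cos((n_chain - 1L) * acos(min(spec$chain_step_cor, 1)))
      e1 <- correlated_shape(e0, rho_end, days)
      chain <- chain_templates(e0, e1, n_chain)
      g <- NULL
      for (try in 1:2000) {
        cand <- rand_shape(days)
        if (all(apply(chain, 1L, function(s) cor(s, cand)) <= mc)) {
          g <- cand
          break
        }
      }
      if (is.null(g)) stop("failed to draw a group shape apart from the chain")
      rbind(matrix(g, n_group, length(days), byrow = TRUE), chain)
    })
}

#' Generate the expression traces of one homologue family
#'
#' Emits \code{n_copies} FPKM traces over the time course. Copies follow
#' the family's divergence pattern at the template level; independent
#' Gaussian observation noise of SD \code{noise_sd} is added per
#' observation and the same value is written to the per-timepoint
#' uncertainty column. Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{family_spec}}.
#' @param tissue tissue label written to the output.
#' @return a long-format data frame with columns \code{gene_id},
#'   \code{reference_gene_id}, \code{tissue}, \code{day}, \code{fpkm},
#'   \code{fpkm_sd}; the truth pattern and the template matrix are attached
#'   as attributes \code{"pattern"} and \code{"templates"}.
#' @export
generate_family <- function(spec, tissue = "apex") {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    days <- default_days(spec$n_timepoints)
    tmpl <- family_templates(spec)
    gene_ids <- sprintf("%s.c%02d", spec$reference_gene_id,
                        seq_len(spec$n_copies))
    rows <- lapply(seq_len(spec$n_copies), function(i) {
      mu <- spec$base_level + spec$amplitude * tmpl[i, ]
      fpkm <- pmax(mu + rnorm(length(days), 0, spec$noise_sd), 0)
      data.frame(gene_id = gene_ids[i],
                 reference_gene_id = spec$reference_gene_id,
                 tissue = tissue, day = days, fpkm = fpkm,
                 fpkm_sd = spec$noise_sd, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(tmpl) <- gene_ids
    attr(out, "pattern") <- spec$pattern
    attr(out, "templates") <- tmpl
    out
  })
}

#' Generate a cohort of families covering all five divergence patterns
#'
#' Builds \code{n_per_pattern} families per pattern with a fixed
#' copy-number design (4 copies; 5 for mixed so the pattern is cleanly
#' realizable) and returns the pooled expression table plus the truth
#' labels the classifier is scored against.
#'
#' @param n_per_pattern families per pattern.
#' @param noise_sd per-observation noise SD in FPKM.
#' @param seed integer seed.
#' @param patterns patterns to include.
#' @param tissue tissue label.
#' @param ... forwarded to \code{\link{family_spec}}.
#' @return list with \code{expression} (long data frame), \code{truth}
#'   (data frame reference_gene_id, pattern, n_copies) and \code{families}
#'   (gene_id -> reference_gene_id map).
#' @export
generate_cohort <- function(n_per_pattern = 50L, noise_sd = 0.1, seed = 1L,
                            patterns = c("redundant", "distinct", "gradated",
                                         "unique", "mixed"),
                            tissue = "apex", ...) {
  specs <- list()
  k <- 0L
  for (p in patterns) {
    for (i in seq_len(n_per_pattern)) {
      k <- k + 1L
      specs[[k]] <- family_spec(
        reference_gene_id = sprintf("AT%s%03d", toupper(substr(p, 1, 2)), i),
        n_copies = if (p == "mixed") 5L else 4L, pattern = p,
        noise_sd = noise_sd, seed = derive_seed(seed, k), ...)
    }
  }
  fams <- lapply(specs, generate_family, tissue = tissue)
  expression <- do.call(rbind, fams)
  truth <- data.frame(
    reference_gene_id = vapply(specs, `[[`, "", "reference_gene_id"),
    pattern = vapply(specs, `[[`, "", "pattern"),
    n_copies = vapply(specs, `[[`, 0L, "n_copies"),
    stringsAsFactors = FALSE)
  families <- unique(expression[, c("gene_id", "reference_gene_id")])
  list(expression = expression, truth = truth, families = families)
}

#' Specify a synthetic copy-number table
#'
#' @param n_reference_genes number of reference genes.
#' @param copy_probabilities probability of a reference gene having
#'   0, 1, 2, ... copies (must sum to 1).
#' @param enriched_subset_fraction fraction of reference genes flagged as
#'   the enriched subset (deterministic size).
#' @param enrichment_shift log-linear tilt applied to the subset's copy
#'   distribution: p_k is reweighted by exp(shift * k), shifting mass
#'   toward high copy numbers for shift > 0.
#' @return an object of class \code{copy_number_spec}.
#' @export
copy_number_spec <- function(n_reference_genes,
                             copy_probabilities = c(0.1, 0.35, 0.25, 0.15,
                                                    0.08, 0.04, 0.03),
                             enriched_subset_fraction = 0.1,
                             enrichment_shift = 0.5) {
  p <- copy_probabilities
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
    stop("copy_probabilities must lie in [0,1] and sum to 1")
  }
  if (enriched_subset_fraction < 0 || enriched_subset_fraction > 1) {
    stop("enriched_subset_fraction must lie in [0,1]")
  }
  structure(list(n_reference_genes = as.integer(n_reference_genes),
                 copy_probabilities = p,
                 enriched_subset_fraction = enriched_subset_fraction,
                 enrichment_shift = enrichment_shift),
            class = "copy_number_spec")
}

#' Generate a synthetic gene-mapping table with copy-number structure
#'
#' Draws per-reference-gene copy counts from the spec's distribution, with
#' a deterministic-size enriched subset drawn from the tilted distribution,
#' and expands them into a best-hit gene map (one row per polyploid copy).
#'
#' @param spec a \code{\link{copy_number_spec}}.
#' @param seed integer seed.
#' @param tf_fraction,circadian_fraction fractions of reference genes
#'   flagged as transcription-factor / circadian set members.
#' @param syntenic_prob probability that a polyploid copy is syntenic.
#' @return list with \code{map} (polyploid_gene_id, reference_gene_id,
#'   score, evalue, in_flowering_set, in_tf_set, in_circadian_set,
#'   syntenic) and \code{counts} (reference_gene_id, n_copies, enriched).
#' @export
generate_copy_number_table <- function(spec, seed = 1L, tf_fraction = 0.25,
                                       circadian_fraction = 0.05,
                                       syntenic_prob = 0.7) {
  stopifnot(inherits(spec, "copy_number_spec"))
  with_seed(seed, {
    n <- spec$n_reference_genes
    ref_ids <- sprintf("REF%06d", seq_len(n))
    n_enriched <- round(spec$enriched_subset_fraction * n)
    enriched <- logical(n)
    enriched[sample.int(n, n_enriched)] <- TRUE
    kmax <- length(spec$copy_probabilities) - 1L
    p_base <- spec$copy_probabilities
    p_tilt <- p_base * exp(spec$enrichment_shift * (0:kmax))
    p_tilt <- p_tilt / sum(p_tilt)
    counts <- integer(n)
    counts[!enriched] <- sample(0:kmax, sum(!enriched), TRUE, p_base)
    counts[enriched] <- sample(0:kmax, sum(enriched), TRUE, p_tilt)
    tf <- ref_ids %in% sample(ref_ids, round(tf_fraction * n))
    circ <- ref_ids %in% sample(ref_ids, round(circadian_fraction * n))
    idx <- rep.int(seq_len(n), counts)
    map <- data.frame(
      polyploid_gene_id = sprintf("%s.c%02d", ref_ids[idx],
                                  sequence(counts[counts > 0L])),
      reference_gene_id = ref_ids[idx],
      score = round(runif(length(idx), 200, 1500), 1),
      evalue = 10^-runif(length(idx), 60, 180),
      in_flowering_set = enriched[idx],
      in_tf_set = tf[idx],
      in_circadian_set = circ[idx],
      syntenic = runif(length(idx)) < syntenic_prob,
      stringsAsFactors = FALSE)
    counts_df <- data.frame(reference_gene_id = ref_ids, n_copies = counts,
                            enriched = enriched, stringsAsFactors = FALSE)
    list(map = map, counts = counts_df)
  })
}

#' Generate directional hit tables with planted reciprocal best hits
#'
#' Every true pair is the top-scoring hit in both directions with an
#' e-value far below 1e-50. Decoys alternate between one-directional best
#' hits (fail the reciprocity filter) and reciprocal pairs above the
#' e-value threshold (fail the significance filter), so a reciprocal
#' best-hit caller recovers exactly the truth set.
#'
#' @param pairs_truth two-column data frame (a_genome_gene_id,
#'   c_genome_gene_id); ids must be unique within each genome.
#' @param decoy_rate number of decoys as a fraction of the truth set.
#' @param seed integer seed.
#' @return list with \code{ab} and \code{ba} hit tables (query, subject,
#'   pident, bitscore, evalue) and the \code{truth} pairs.
#' @export
generate_hit_tables <- function(pairs_truth, decoy_rate = 0, seed = 1L) {
  pairs_truth <- as.data.frame(pairs_truth)
  names(pairs_truth)[1:2] <- c("a", "b")
  if (anyDuplicated(pairs_truth$a) || anyDuplicated(pairs_truth$b)) {
    stop("invalid input: pair ids must be unique within each genome")
  }
  with_seed(seed, {
    n <- nrow(pairs_truth)
    hit <- function(q, s, bits, ev) {
      data.frame(query = q, subject = s,
                 pident = round(runif(length(q), 80, 100), 2),
                 bitscore = bits, evalue = ev, stringsAsFactors = FALSE)
    }
    bits_true <- runif(n, 600, 1200)
    ev_true <- 10^-runif(n, 80, 180)
    ab <- hit(pairs_truth$a, pairs_truth$b, bits_true, ev_true)
    ba <- hit(pairs_truth$b, pairs_truth$a, bits_true, ev_true)
    # weaker secondary hits to shuffled partners (never outrank the best)
    if (n >= 2L) {
      sh <- c(seq(2, n), 1L)
      ab <- rbind(ab, hit(pairs_truth$a, pairs_truth$b[sh],
                          bits_true * runif(n, 0.2, 0.6), 1e-55))
      ba <- rbind(ba, hit(pairs_truth$b, pairs_truth$a[sh],
                          bits_true * runif(n, 0.2, 0.6), 1e-55))
    }
    n_dec <- round(decoy_rate * n)
    if (n_dec > 0L) {
      for (i in seq_len(n_dec)) {
        if (i %% 2L == 1L) {
          # one-directional: new A-genome gene whose best hit is a taken
          # C-genome gene; the reverse hit is weak so reciprocity fails
          q <- sprintf("A_decoy%04d", i)
          tgt <- pairs_truth$b[1L + (i %% n)]
          ab <- rbind(ab, hit(q, tgt, runif(1, 600, 1200), 1e-70))
          ba <- rbind(ba, hit(tgt, q, runif(1, 50, 200), 1e-55))
        } else {
          # reciprocal but insignificant: e-value above the 1e-50 threshold
          q <- sprintf("A_weak%04d", i)
          s <- sprintf("C_weak%04d", i)
          ab <- rbind(ab, hit(q, s, runif(1, 600, 1200), 1e-40))
          ba <- rbind(ba, hit(s, q, runif(1, 600, 1200), 1e-40))
        }
      }
    }
    list(ab = ab, ba = ba,
         truth = setNames(pairs_truth[, c("a", "b")],
                          c("a_genome_gene_id", "c_genome_gene_id")))
  })
}

#' Generate a nucleotide sequence pair with planted conserved blocks
#'
#' Site-wise substitution model without indels: inside each planted block
#' the per-site substitution probability is 1 - identity/100, outside it
#' is 1 - background_identity/100. Substituted sites always change base.
#'
#' @param length sequence length in bp.
#' @param conserved_blocks data frame with columns \code{start}, \code{end}
#'   (0-based half-open) and \code{identity} (percent); blocks must be
#'   disjoint and within the sequence.
#' @param background_identity percent identity outside blocks.
#' @param seed integer seed.
#' @return list with \code{seq_a}, \code{seq_b} (character strings) and
#'   \code{truth} (the block table).
#' @export
generate_sequence_pair <- function(length, conserved_blocks = NULL,
                                   background_identity = 50, seed = 1L) {
  blocks <- conserved_blocks
  if (is.null(blocks)) {
    blocks <- data.frame(start = integer(), end = integer(),
                         identity = numeric())
  }
  blocks <- assert_cols(as.data.frame(blocks), c("start", "end", "identity"))
  if (nrow(blocks) > 0) {
    if (any(blocks$start < 0 | blocks$end > length |
            blocks$end <= blocks$start)) {
      stop("invalid spec: blocks must lie within [0, length)")
    }
    if (any(blocks$identity < 0 | blocks$identity > 100) ||
        background_identity < 0 || background_identity > 100) {
      stop("invalid spec: identities must lie in [0, 100]")
    }
    o <- order(blocks$start)
    blocks <- blocks[o, , drop = FALSE]
    if (nrow(blocks) > 1 &&
        any(blocks$start[-1] < blocks$end[-nrow(blocks)])) {
      stop("invalid spec: conserved blocks overlap")
    }
  }
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, length, TRUE)
    p_sub <- rep(1 - background_identity / 100, length)
    for (i in seq_len(nrow(blocks))) {
      sel <- (blocks$start[i] + 1L):blocks$end[i]
      p_sub[sel] <- 1 - blocks$identity[i] / 100
    }
    b <- a
    flip <- runif(length) < p_sub
    if (any(flip)) {
      b[flip] <- vapply(a[flip], function(x) sample(setdiff(bases, x), 1L), "")
    }
    list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
         truth = blocks)
  })
}
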