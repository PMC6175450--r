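# Copy-number retention statistics, expression filtering, tissue
# specificity, reciprocal-best-hit pair calling and expression bias.

#' Assign each query its best significant hit
#'
#' Hits with e-value above the threshold are discarded; for each query the
#' highest-bitscore hit is retained, with ties broken by lower e-value and
#' then lexicographic subject id, so the assignment is deterministic.
#'
#' @param hit_table data frame with columns query, subject, bitscore,
#'   evalue (see \code{\link{read_hit_table}}).
#' @param evalue_threshold significance threshold (default 1e-50).
#' @return data frame with one row per assigned query (columns query,
#'   subject, bitscore, evalue); empty input yields an empty map.
#' @export
assign_best_hits <- function(hit_table, evalue_threshold = 1e-50) {
  assert_cols(hit_table, c("query", "subject", "bitscore", "evalue"))
  keep <- hit_table$evalue <= evalue_threshold
  h <- hit_table[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(h[, c("query", "subject", "bitscore", "evalue")])
  }
  o <- order(h$query, -h$bitscore, h$evalue, h$subject)
  h <- h[o, , drop = FALSE]
  best <- h[!duplicated(h$query), c("query", "subject", "bitscore", "evalue")]
  rownames(best) <- NULL
  best
}

.subset_filters <- c("all", "flowering", "tf", "flowering_minus_tf",
                     "flowering_minus_circadian", "syntenic", "non_syntenic",
                     "expressed")

# Apply a named subset filter to the gene map rows.
apply_subset_filter <- function(map, subset_filter, expressed = NULL) {
  if (!subset_filter %in% .subset_filters) {
    stop("unknown subset filter: ", subset_filter, " (expected one of ",
         paste(.subset_filters, collapse = ", "), ")")
  }
  sel <- switch(subset_filter,
    all = rep(TRUE, nrow(map)),
    flowering = map$in_flowering_set,
    tf = map$in_tf_set,
    flowering_minus_tf = map$in_flowering_set & !map$in_tf_set,
    flowering_minus_circadian = map$in_flowering_set & !map$in_circadian_set,
    syntenic = map$syntenic,
    non_syntenic = !map$syntenic,
    expressed = {
      if (is.null(expressed)) {
        stop("subset filter 'expressed' needs an expressed-flag vector ",
             "named by polyploid gene id")
      }
      map$polyploid_gene_id %in% names(expressed)[expressed]
    })
  map[which(sel), , drop = FALSE]
}

#' Copy-number distribution of reference genes
#'
#' Counts, per copy number k >= 1, the reference genes with exactly k
#' polyploid copies in the (filtered) gene map. Proportions use the number
#' of reference genes represented by at least one copy as denominator.
#'
#' @param map gene map data frame (columns polyploid_gene_id,
#'   reference_gene_id and the subset flag columns).
#' @param subset_filter one of "all", "flowering", "tf",
#'   "flowering_minus_tf", "flowering_minus_circadian", "syntenic",
#'   "non_syntenic", "expressed".
#' @param expressed optional named logical vector of expressed flags for
#'   the "expressed" filter.
#' @return data frame (n_copies, n_genes, proportion) plus attributes
#'   \code{denominator} and \code{degenerate} (TRUE when the subset is
#'   empty and proportions are undefined).
#' @export
copy_number_distribution <- function(map, subset_filter = "all",
                                     expressed = NULL) {
  assert_cols(map, c("polyploid_gene_id", "reference_gene_id"))
  sub <- apply_subset_filter(map, subset_filter, expressed)
  tab <- table(table(sub$reference_gene_id))
  k <- as.integer(names(tab))
  denom <- sum(tab)
  out <- data.frame(n_copies = k, n_genes = as.integer(tab),
                    proportion = if (denom > 0) as.integer(tab) / denom
                                 else rep(NaN, length(k)))
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  attr(out, "degenerate") <- denom == 0L
  out
}

#' Two-sample test for the equality of proportions
#'
#' Chi-square test on a 2x2 table with Yates continuity correction by
#' default (the \code{stats::prop.test} convention), df = 1.
#'
#' @param x1,n1 count and denominator of the first sample.
#' @param x2,n2 count and denominator of the second sample.
#' @param correct apply the continuity correction.
#' @return list with proportions, counts, statistic, df and p.value.
#' @export
compare_proportions <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop("undefined test: denominators must be > 0")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must satisfy 0 <= x <= n")
  }
  ht <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = correct))
  list(p1 = x1 / n1, p2 = x2 / n2, x = c(x1, x2), n = c(n1, n2),
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Compare two copy-number distributions category by category
#'
#' For every copy number present in either distribution, runs the
#' two-sample proportion test of subset vs reference proportions. No
#' multiple-testing correction is applied by default; Bonferroni is
#' available via \code{adjust}.
#'
#' @param dist_subset,dist_reference outputs of
#'   \code{\link{copy_number_distribution}}.
#' @param adjust "none" (default) or "bonferroni".
#' @param correct continuity correction for the underlying tests.
#' @return data frame with one row per copy number.
#' @export
compare_copy_number <- function(dist_subset, dist_reference,
                                adjust = c("none", "bonferroni"),
                                correct = TRUE) {
  adjust <- match.arg(adjust)
  n1 <- attr(dist_subset, "denominator")
  n2 <- attr(dist_reference, "denominator")
  if (n1 == 0L || n2 == 0L) stop("undefined test: empty distribution")
  ks <- sort(union(dist_subset$n_copies, dist_reference$n_copies))
  cnt <- function(d, k) {
    i <- match(k, d$n_copies)
    ifelse(is.na(i), 0L, d$n_genes[i])
  }
  res <- lapply(ks, function(k) {
    t <- compare_proportions(cnt(dist_subset, k), n1,
                             cnt(dist_reference, k), n2, correct = correct)
    data.frame(n_copies = k, p_subset = t$p1, p_reference = t$p2,
               statistic = t$statistic, p.value = t$p.value)
  })
  out <- do.call(rbind, res)
  if (adjust == "bonferroni") {
    out$p.adjusted <- stats::p.adjust(out$p.value, "bonferroni")
  }
  out
}

#' Flag expressed genes by maximum FPKM
#'
#' A gene counts as expressed in a tissue when its maximum FPKM across the
#' time series is greater than or equal to the threshold (the inclusive
#' rule; default 2.0 FPKM). Tissues are evaluated independently.
#'
#' @param expression long expression data frame.
#' @param threshold FPKM threshold.
#' @param tissue optional tissue; default flags every tissue present.
#' @return for a single tissue, a named logical vector (gene_id ->
#'   expressed); otherwise a data frame (gene_id, tissue, expressed).
#' @export
filter_expressed <- function(expression, threshold = 2.0, tissue = NULL) {
  assert_cols(expression, c("gene_id", "tissue", "fpkm"))
  if (!is.null(tissue)) {
    df <- expression[expression$tissue == tissue, , drop = FALSE]
    if (nrow(df) == 0L) {
      warning("no expression rows for tissue ", tissue, "; no genes flagged")
      return(setNames(logical(0), character(0)))
    }
    mx <- tapply(df$fpkm, df$gene_id, max)
    return(setNames(as.vector(mx) >= threshold, names(mx)))
  }
  parts <- lapply(sort(unique(expression$tissue)), function(ti) {
    fl <- filter_expressed(expression, threshold, ti)
    data.frame(gene_id = names(fl), tissue = ti, expressed = as.vector(fl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Tissue-specificity counts and chi-square comparison
#'
#' Partitions genes into neither / apex-only / leaf-only / both from the
#' two tissues' expressed flags, and compares the subset's 3-way expressed
#' split (apex-only, leaf-only, both) against a reference split with
#' Pearson's chi-square test (df = 2, no continuity correction).
#'
#' The reference is the full gene set by default (\code{compare = "all"},
#' which reproduces the conventional genome-wide comparison); use
#' \code{compare = "complement"} to test the subset against the remaining
#' genes instead.
#'
#' @param flags_apex,flags_leaf named logical vectors of expressed flags;
#'   names are gene ids and must cover the same genes.
#' @param subset character vector of gene ids forming the subset, or a
#'   logical vector aligned with \code{flags_apex}.
#' @param compare "all" or "complement".
#' @return list with \code{counts} (4-way table for the subset),
#'   \code{table} (2x3 contingency table), \code{statistic}, \code{df},
#'   \code{p.value} and integer \code{percentages} of the subset's
#'   expressed genes per class.
#' @export
tissue_specificity <- function(flags_apex, flags_leaf, subset = NULL,
                               compare = c("all", "complement")) {
  compare <- match.arg(compare)
  genes <- names(flags_apex)
  if (is.null(genes) || !setequal(genes, names(flags_leaf))) {
    stop("flags must be named logical vectors over the same genes")
  }
  fl <- flags_leaf[genes]
  fa <- flags_apex
  cls <- ifelse(fa & fl, "both",
         ifelse(fa, "apex_only", ifelse(fl, "leaf_only", "neither")))
  if (is.null(subset)) subset <- genes
  if (is.logical(subset)) subset <- genes[subset]
  if (length(subset) == 0L) stop("undefined test: subset is empty")
  in_sub <- genes %in% subset
  count3 <- function(sel) {
    vapply(c("apex_only", "leaf_only", "both"),
           function(cl) sum(cls[sel] == cl), 0L)
  }
  sub3 <- count3(in_sub)
  ref3 <- if (compare == "all") count3(rep(TRUE, length(genes)))
          else count3(!in_sub)
  tab <- rbind(subset = sub3, reference = ref3)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  counts4 <- vapply(c("neither", "apex_only", "leaf_only", "both"),
                    function(cl) sum(cls[in_sub] == cl), 0L)
  n_sub <- sum(in_sub)
  list(counts = counts4, table = tab,
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value,
       percentages = c(
         expressed = percent_round(n_sub - counts4[["neither"]], n_sub),
         apex_only = percent_round(counts4[["apex_only"]],
                                   n_sub - counts4[["neither"]]),
         leaf_only = percent_round(counts4[["leaf_only"]],
                                   n_sub - counts4[["neither"]]),
         both = percent_round(counts4[["both"]],
                              n_sub - counts4[["neither"]])))
}

#' Call reciprocal best hits between two genomes
#'
#' A pair (a, c) is returned iff c is a's best significant hit in the
#' A->C table and a is c's best significant hit in the C->A table, with
#' best-hit ties broken as in \code{\link{assign_best_hits}}.
#'
#' @param hits_ab,hits_ba directional hit tables.
#' @param evalue_threshold significance threshold.
#' @return data frame (a_genome_gene_id, c_genome_gene_id), sorted.
#' @export
call_reciprocal_best_hits <- function(hits_ab, hits_ba,
                                      evalue_threshold = 1e-50) {
  best_ab <- assign_best_hits(hits_ab, evalue_threshold)
  best_ba <- assign_best_hits(hits_ba, evalue_threshold)
  back <- best_ba$subject[match(best_ab$subject, best_ba$query)]
  keep <- !is.na(back) & back == best_ab$query
  out <- data.frame(a_genome_gene_id = best_ab$query[keep],
                    c_genome_gene_id = best_ab$subject[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_genome_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pair expression bias calls
#'
#' A pair member is called biased when its maximum FPKM is at least
#' \code{fold} times its homologue's (boundary inclusive). Pairs with both
#' maxima below the expressed threshold are excluded; pairs with a member
#' missing from the expression table are skipped with a warning.
#'
#' @param pairs data frame (a_genome_gene_id, c_genome_gene_id).
#' @param expression long expression data frame.
#' @param tissue tissue evaluated.
#' @param fold bias ratio (default 2).
#' @param threshold expressed threshold in FPKM.
#' @return list with \code{calls} (per-pair data frame with bias in
#'   "A-biased", "C-biased", "unbiased") and \code{summary} counts.
#' @export
expression_bias <- function(pairs, expression, tissue, fold = 2,
                            threshold = 2.0) {
  assert_cols(pairs, c("a_genome_gene_id", "c_genome_gene_id"))
  df <- expression[expression$tissue == tissue, , drop = FALSE]
  mx <- tapply(df$fpkm, df$gene_id, max)
  a_max <- mx[pairs$a_genome_gene_id]
  c_max <- mx[pairs$c_genome_gene_id]
  missing <- is.na(a_max) | is.na(c_max)
  if (any(missing)) {
    warning(sum(missing), " pair(s) skipped: member absent from the ",
            "expression table in tissue ", tissue)
  }
  keep <- !missing & (pmax(a_max, c_max) >= threshold)
  calls <- data.frame(
    a_genome_gene_id = pairs$a_genome_gene_id[keep],
    c_genome_gene_id = pairs$c_genome_gene_id[keep],
    a_max = unname(a_max[keep]), c_max = unname(c_max[keep]),
    stringsAsFactors = FALSE)
  calls$bias <- ifelse(calls$a_max >= fold * calls$c_max, "A-biased",
                ifelse(calls$c_max >= fold * calls$a_max, "C-biased",
                       "unbiased"))
  summary <- c(`A-biased` = sum(calls$bias == "A-biased"),
               `C-biased` = sum(calls$bias == "C-biased"),
               unbiased = sum(calls$bias == "unbiased"),
               excluded = sum(!keep & !missing), skipped = sum(missing))
  list(calls = calls, summary = summary)
}

#' Annotated vs expressed copy counts per reference gene
#'
#' @param map gene map data frame.
#' @param expressed named logical vector of expressed flags per polyploid
#'   gene (genes absent from the map are ignored).
#' @return data frame (reference_gene_id, n_annotated, n_expressed) with
#'   attribute \code{fraction_dropout}: the fraction of reference genes
#'   with fewer expressed than annotated copies.
#' @export
expressed_vs_annotated <- function(map, expressed) {
  assert_cols(map, c("polyploid_gene_id", "reference_gene_id"))
  ex <- expressed[map$polyploid_gene_id]
  ex[is.na(ex)] <- FALSE
  n_ann <- table(map$reference_gene_id)
  n_exp <- tapply(ex, map$reference_gene_id, sum)
  out <- data.frame(reference_gene_id = names(n_ann),
                    n_annotated = as.integer(n_ann),
                    n_expressed = as.integer(n_exp[names(n_ann)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fraction_dropout") <-
    if (nrow(out) > 0) mean(out$n_expressed < out$n_annotated) else NaN
  out
}
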