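test_that("best-hit assignment keeps the top significant hit per query", {
  ht <- data.frame(query = c("q1", "q1"), subject = c("s1", "s2"),
                   bitscore = c(500, 300), evalue = c(1e-80, 1e-80))
  expect_equal(assign_best_hits(ht)$subject, "s1")

  weak <- data.frame(query = "q1", subject = "s1", bitscore = 900,
                     evalue = 1e-40)
  expect_equal(nrow(assign_best_hits(weak)), 0L)

  # tie-breaking: lower evalue, then lexicographic subject
  tie <- data.frame(query = "q1", subject = c("s2", "s1", "s3"),
                    bitscore = 400, evalue = c(1e-60, 1e-70, 1e-70))
  expect_equal(assign_best_hits(tie)$subject, "s1")
})

test_that("best-hit assignment matches an exhaustive max-scan oracle", {
  set.seed(42)
  ht <- data.frame(query = rep(sprintf("q%02d", 1:10), each = 5),
                   subject = sprintf("s%02d", sample(20, 50, TRUE)),
                   bitscore = round(runif(50, 100, 900)),
                   evalue = 10^-runif(50, 40, 120))
  got <- assign_best_hits(ht)
  for (q in unique(ht$query)) {
    h <- ht[ht$query == q & ht$evalue <= 1e-50, ]
    if (nrow(h) == 0) {
      expect_false(q %in% got$query)
    } else {
      h <- h[order(-h$bitscore, h$evalue, h$subject), ]
      expect_equal(got$subject[got$query == q], h$subject[1])
    }
  }
})

test_that("copy-number distributions count reference genes per copy class", {
  map <- data.frame(polyploid_gene_id = c("a", "b", "c"),
                    reference_gene_id = c("X", "X", "Y"))
  d <- copy_number_distribution(map)
  expect_equal(d$n_genes, c(1L, 1L))
  expect_equal(d$proportion, c(0.5, 0.5))
  expect_equal(attr(d, "denominator"), 2L)

  map$in_flowering_set <- FALSE
  d0 <- copy_number_distribution(map, "flowering")
  expect_true(attr(d0, "degenerate"))
  expect_error(copy_number_distribution(map, "nonsense"), "unknown")

  # random fixture vs per-reference tally oracle
  tab <- generate_copy_number_table(copy_number_spec(1000), seed = 5)
  d1 <- copy_number_distribution(tab$map)
  oracle <- table(table(tab$map$reference_gene_id))
  expect_equal(d1$n_genes, as.integer(oracle))
  expect_equal(sum(d1$proportion), 1)
})

test_that("proportion test matches a corrected 2x2 chi-square oracle", {
  eq <- compare_proportions(30, 100, 30, 100)
  expect_gt(eq$p.value, 0.99)
  expect_equal(compare_proportions(30, 100, 30, 100,
                                   correct = FALSE)$statistic, 0)

  oracle <- function(x1, n1, x2, n2) {
    O <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    Y <- min(0.5, abs(O[1, 1] - E[1, 1]))
    sum((abs(O - E) - Y)^2 / E)
  }
  t1 <- compare_proportions(20, 100, 10, 100)
  expect_equal(t1$statistic, oracle(20, 100, 10, 100), tolerance = 1e-12)
  expect_equal(t1$df, 1)

  set.seed(9)
  for (i in 1:100) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- sample.int(n1, 1) - 1L; x2 <- sample.int(n2, 1) - 1L
    if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
    got <- compare_proportions(x1, n1, x2, n2)
    expect_lt(abs(got$statistic - oracle(x1, n1, x2, n2)), 1e-10)
    swapped <- compare_proportions(x2, n2, x1, n1)
    expect_equal(got$p.value, swapped$p.value)
  }
  expect_error(compare_proportions(1, 0, 1, 10), "undefined")
})

test_that("the expressed flag uses an inclusive maximum-FPKM threshold", {
  expr <- trace_df(list(g1 = c(0, 0.5, 2.0, 1, 0, 0, 0),
                        g2 = c(0, 0.5, 1.99, 1, 0, 0, 0),
                        g3 = rep(0, 7)))
  fl <- filter_expressed(expr, tissue = "apex")
  expect_true(fl[["g1"]])
  expect_false(fl[["g2"]])
  expect_false(fl[["g3"]])
})

test_that("tissue specificity partitions genes and matches the chi-square oracle", {
  genes <- sprintf("g%03d", 1:100)
  fa <- setNames(rep(TRUE, 100), genes)
  fl <- setNames(rep(TRUE, 100), genes)
  ts <- tissue_specificity(fa, fl)
  expect_equal(unname(ts$counts), c(0L, 0L, 0L, 100L))
  expect_equal(sum(ts$counts), 100L)

  # subset with the same 3-way split as its complement: no signal
  fa2 <- setNames(rep(c(TRUE, TRUE, FALSE, TRUE), 25), genes)
  fl2 <- setNames(rep(c(FALSE, TRUE, TRUE, TRUE), 25), genes)
  ts2 <- tissue_specificity(fa2, fl2, subset = genes[1:52],
                            compare = "complement")
  expect_equal(ts2$statistic, 0, tolerance = 1e-12)
  expect_equal(ts2$p.value, 1)

  # fixed 2x3 table vs direct sum((O-E)^2/E)
  fa3 <- setNames(c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 25),
                    rep(TRUE, 80), rep(FALSE, 40), rep(TRUE, 120)),
                  sprintf("h%03d", 1:305))
  fl3 <- setNames(c(rep(FALSE, 30), rep(TRUE, 10), rep(TRUE, 25),
                    rep(FALSE, 80), rep(TRUE, 40), rep(TRUE, 120)),
                  sprintf("h%03d", 1:305))
  sub <- sprintf("h%03d", 1:65)
  ts3 <- tissue_specificity(fa3, fl3, subset = sub, compare = "complement")
  O <- ts3$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(ts3$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(ts3$df, 2)
  expect_error(tissue_specificity(fa, fl, subset = character(0)), "empty")
})

test_that("reciprocal best hit calling enforces reciprocity symmetrically", {
  ab <- data.frame(query = "a1", subject = "c1", bitscore = 500,
                   evalue = 1e-80)
  ba <- data.frame(query = "c1", subject = "a1", bitscore = 500,
                   evalue = 1e-80)
  expect_equal(nrow(call_reciprocal_best_hits(ab, ba)), 1L)

  # a1's best is c1 but c1's best is a2: excluded
  ba2 <- data.frame(query = "c1", subject = c("a1", "a2"),
                    bitscore = c(400, 600), evalue = 1e-80)
  expect_equal(nrow(call_reciprocal_best_hits(ab, ba2)), 0L)

  truth <- data.frame(a = sprintf("A%02d", 1:15), b = sprintf("C%02d", 1:15))
  ht <- generate_hit_tables(truth, decoy_rate = 0.4, seed = 6)
  fwd <- call_reciprocal_best_hits(ht$ab, ht$ba)
  rev <- call_reciprocal_best_hits(ht$ba, ht$ab)
  expect_setequal(paste(fwd[[1]], fwd[[2]]), paste(rev[[2]], rev[[1]]))
  expect_setequal(paste(fwd[[1]], fwd[[2]]), paste(truth$a, truth$b))
})

test_that("expression bias calls are inclusive at the fold boundary", {
  expr <- trace_df(list(a1 = c(4, 1, 1, 1, 1, 1, 1),
                        c1 = c(2, 1, 1, 1, 1, 1, 1),
                        a2 = c(3.9, 1, 1, 1, 1, 1, 1),
                        c2 = c(2, 1, 1, 1, 1, 1, 1),
                        a3 = c(1, 0, 0, 0, 0, 0, 0),
                        c3 = c(1.5, 0, 0, 0, 0, 0, 0)))
  pairs <- data.frame(a_genome_gene_id = c("a1", "a2", "a3"),
                      c_genome_gene_id = c("c1", "c2", "c3"))
  eb <- expression_bias(pairs, expr, "apex")
  expect_equal(eb$calls$bias, c("A-biased", "unbiased"))
  expect_equal(unname(eb$summary[["excluded"]]), 1L)

  pairs2 <- rbind(pairs, data.frame(a_genome_gene_id = "missing",
                                    c_genome_gene_id = "c1"))
  expect_warning(eb2 <- expression_bias(pairs2, expr, "apex"), "skipped")
  expect_equal(unname(eb2$summary[["skipped"]]), 1L)

  # random 20-pair fixture vs a direct per-pair tally
  set.seed(3)
  traces <- setNames(lapply(1:40, function(i) runif(7, 0, 12)),
                     c(sprintf("pa%02d", 1:20), sprintf("pc%02d", 1:20)))
  expr3 <- trace_df(traces)
  pairs3 <- data.frame(a_genome_gene_id = sprintf("pa%02d", 1:20),
                       c_genome_gene_id = sprintf("pc%02d", 1:20))
  eb3 <- expression_bias(pairs3, expr3, "apex")
  amax <- vapply(traces[pairs3$a_genome_gene_id], max, 0)
  cmax <- vapply(traces[pairs3$c_genome_gene_id], max, 0)
  keep <- pmax(amax, cmax) >= 2
  oracle <- ifelse(amax[keep] >= 2 * cmax[keep], "A-biased",
                   ifelse(cmax[keep] >= 2 * amax[keep], "C-biased",
                          "unbiased"))
  expect_equal(eb3$calls$bias, unname(oracle))
})

test_that("expressed vs annotated copies track planted drop-outs", {
  map <- data.frame(
    polyploid_gene_id = c("x1", "x2", "x3", "x4", "y1", "y2"),
    reference_gene_id = c("X", "X", "X", "X", "Y", "Y"))
  flags <- setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
                    map$polyploid_gene_id)
  ea <- expressed_vs_annotated(map, flags)
  expect_equal(ea$n_annotated, c(4L, 2L))
  expect_equal(ea$n_expressed, c(2L, 2L))
  expect_equal(attr(ea, "fraction_dropout"), 0.5)
  expect_true(all(ea$n_expressed <= ea$n_annotated))

  all_on <- setNames(rep(TRUE, 6), map$polyploid_gene_id)
  expect_equal(attr(expressed_vs_annotated(map, all_on),
                    "fraction_dropout"), 0)
})
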