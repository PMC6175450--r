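test_that("the clustering coefficient is an erf soft threshold", {
  expect_equal(clustering_coefficient(0.05, 0.2, 0.05), 0.5)
  # (mu - theta)/(sigma*sqrt(2)) = 1; erf(1) = 0.8427007929 (math tables)
  mu <- 0.05 + 0.1 * sqrt(2)
  expect_equal(clustering_coefficient(mu, 0.1, 0.05),
               0.5 * (1 + 0.8427007929497149), tolerance = 1e-9)
  # sigma = 0 limit is a step function
  expect_equal(clustering_coefficient(c(0.2, 0.01, 0.05), 0, 0.05),
               c(1, 0, 0.5))
  # strictly increasing in mu at fixed sigma > 0, saturating at 1
  mus <- seq(0, 1, by = 0.05)
  cc <- clustering_coefficient(mus, 0.1, 0.3)
  expect_true(all(diff(cc) > 0))
  expect_equal(clustering_coefficient(0.9, 1e-6, 0.05), 1, tolerance = 1e-9)
  # approaches the step as sigma shrinks
  expect_gt(clustering_coefficient(0.1, 0.001, 0.05),
            clustering_coefficient(0.1, 0.1, 0.05))
  expect_error(clustering_coefficient(0.5, -1, 0.05), "non-negative")
})

test_that("binarization removes non-robust genes and enumerates maximal cliques", {
  g <- c("a", "b", "c", "d")
  ones <- matrix(1, 4, 4, dimnames = list(g, g))
  self1 <- setNames(rep(1, 4), g)
  bm <- binarize_and_modularize(ones, self1)
  expect_equal(bm$modules, list(c("a", "b", "c", "d")))

  ident <- diag(4)
  dimnames(ident) <- list(g, g)
  bm2 <- binarize_and_modularize(ident, self1)
  expect_equal(length(bm2$modules), 4L)
  expect_true(all(lengths(bm2$modules) == 1L))

  # path graph a-b-c: b belongs to both modules
  path <- matrix(0, 3, 3, dimnames = list(g[1:3], g[1:3]))
  path["a", "b"] <- path["b", "a"] <- 1
  path["b", "c"] <- path["c", "b"] <- 1
  diag(path) <- 1
  bm3 <- binarize_and_modularize(path, setNames(rep(1, 3), g[1:3]))
  expect_equal(bm3$modules, list(c("a", "b"), c("b", "c")))

  # non-robust gene removed before module enumeration
  self2 <- setNames(c(1, 0.2, 1, 1), g)
  bm4 <- binarize_and_modularize(ones, self2)
  expect_equal(bm4$removed, "b")
  expect_equal(bm4$modules, list(c("a", "c", "d")))
})

test_that("clique enumeration agrees with an independent graph library", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    adj <- matrix(rbinom(n * n, 1, 0.4), n)
    adj <- (adj + t(adj)) > 0
    diag(adj) <- TRUE
    ids <- sprintf("v%02d", seq_len(n))
    dimnames(adj) <- list(ids, ids)
    got <- binarize_and_modularize(adj * 1, setNames(rep(1, n), ids))$modules
    g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                             diag = FALSE)
    want <- lapply(igraph::max_cliques(g), function(cl) sort(ids[as.integer(cl)]))
    key <- function(ms) sort(vapply(ms, paste, "", collapse = "|"))
    expect_equal(key(got), key(want))
  }
})

test_that("the five-pattern taxonomy is classified exhaustively", {
  expect_equal(classify_pattern(list(c("a", "b", "c", "d")),
                                c("a", "b", "c", "d")), "redundant")
  expect_equal(classify_pattern(list("a", "b", "c", "d"),
                                c("a", "b", "c", "d")), "unique")
  expect_equal(classify_pattern(list(c("a", "b"), c("c", "d")),
                                c("a", "b", "c", "d")), "distinct")
  expect_equal(classify_pattern(list(c("a", "b", "c"), "d"),
                                c("a", "b", "c", "d")), "distinct")
  expect_equal(classify_pattern(list(c("a", "b"), c("b", "c")),
                                c("a", "b", "c")), "gradated")
  expect_equal(classify_pattern(list(c("a", "b"), c("b", "c"), c("d", "e")),
                                c("a", "b", "c", "d", "e")), "mixed")
  expect_equal(classify_pattern(list(c("a", "b")), "a"), "unclassifiable")
  expect_equal(classify_pattern(list(), c("a", "b")), "unclassifiable")
})

test_that("cohort summaries reproduce planted pattern mixes and pair sharing", {
  calls <- data.frame(reference_gene_id = sprintf("F%02d", 1:10),
                      pattern = rep("redundant", 10))
  fs <- family_divergence_summary(calls)
  expect_equal(fs$pattern_counts$percent[
    fs$pattern_counts$pattern == "redundant"], 100L)

  # pair in overlapping modules counts as same-module
  modules <- list(F1 = list(c("a", "b"), c("b", "c")),
                  F2 = list("x", "y"))
  pairs <- data.frame(a_genome_gene_id = c("a", "x"),
                      c_genome_gene_id = c("b", "y"))
  fs2 <- family_divergence_summary(
    data.frame(reference_gene_id = c("F1", "F2"),
               pattern = c("gradated", "unique")),
    modules = modules, pairs = pairs)
  expect_equal(fs2$pair_calls$same_module, c(TRUE, FALSE))
  expect_equal(fs2$percent_same_module, 50L)
  expect_equal(same_module_intersection(fs2$pair_calls, fs2$pair_calls), 1L)
})

test_that("zero-noise identical traces give coefficient 1 for any map seed", {
  sh <- unit_shape(21)
  x <- rbind(g1 = 10 + sh, g2 = 10 + sh,
             g3 = 10 + unit_shape(22), g4 = 10 + unit_shape(23))
  s <- matrix(0, 4, 7, dimnames = list(rownames(x), NULL))
  for (seed in c(1, 77, 4242)) {
    ens <- ensemble_probabilities(x, s, dims = c(2, 2), M = 3, B = 20,
                                  base_seed = seed)
    p12 <- ens$pairs[ens$pairs$gene1 == "g1" & ens$pairs$gene2 == "g2", ]
    co <- clustering_coefficient(p12$mu, p12$sigma, 0.05)
    expect_equal(co, 1)
  }
})

test_that("the fitted model recovers planted patterns on a small cohort", {
  co <- generate_cohort(n_per_pattern = 6, noise_sd = 0, seed = 31)
  fit <- suppressWarnings(
    som_divergence(co$expression, co$families, M = 5, B = 50, seed = 32))
  truth <- setNames(co$truth$pattern, co$truth$reference_gene_id)
  got <- setNames(fit$calls$pattern, fit$calls$reference_gene_id)
  # patterns with deterministic link structure are recovered exactly
  for (p in c("redundant", "unique", "distinct")) {
    expect_equal(unname(got[names(truth)[truth == p]]),
                 rep(p, 6), info = p)
  }

  # mu/sigma symmetric by construction; coefficient matrices symmetric
  f1 <- fit$families[[1]]
  expect_lt(max(abs(f1$coefficients - t(f1$coefficients))), 1e-12)

  # summary and print methods run
  expect_output(print(fit), "Ensemble-SOM")
  expect_output(print(summary(fit)), "patterns")
  expect_s3_class(coef(fit), "data.frame")
})

test_that("classification accuracy degrades with observation noise", {
  acc_for <- function(noise) {
    co <- generate_cohort(n_per_pattern = 6, noise_sd = noise, seed = 41)
    fit <- suppressWarnings(
      som_divergence(co$expression, co$families, M = 6, B = 60, seed = 42))
    truth <- setNames(co$truth$pattern, co$truth$reference_gene_id)
    got <- setNames(fit$calls$pattern, fit$calls$reference_gene_id)
    mean(truth[names(got)] == got)
  }
  expect_gte(acc_for(0.05), acc_for(1.5))
})
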