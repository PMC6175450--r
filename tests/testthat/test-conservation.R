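# Brute-force alignment oracle: enumerate every global alignment of a and
# b, scoring match/mismatch per column and a gap run of length L as
# -(open + L * extend). Feasible for sequences up to ~6 bases.
enumerate_best_score <- function(a, b, match = 1, mismatch = -1,
                                 open = 5, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) { # gap in b
      cost <- extend + if (prev == "a") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "a"))
    }
    if (j <= length(bv)) { # gap in a
      cost <- extend + if (prev == "b") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "b"))
    }
    best
  }
  rec(1, 1, "m")
}

test_that("global alignment scores match hand and exhaustive oracles", {
  id <- global_align("ACGTACGT", "ACGTACGT")
  expect_equal(id$score, 8)
  expect_false(grepl("-", id$aligned_a, fixed = TRUE))

  a4 <- global_align("ACGT", "ACGA")
  expect_equal(a4$score, 2) # 3 matches - 1 mismatch, no gaps
  expect_false(grepl("-", a4$aligned_a, fixed = TRUE))

  set.seed(16)
  for (i in 1:12) {
    la <- sample(3:6, 1)
    lb <- sample(3:6, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, enumerate_best_score(a, b),
                 info = paste(a, b))
  }

  expect_error(global_align("ACGTX", "ACGT"), "position")
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("sliding identity counts matches per window, gaps as mismatch", {
  pair <- generate_sequence_pair(300, background_identity = 100, seed = 1)
  aln <- global_align(pair$seq_a, pair$seq_b)
  prof <- sliding_identity(aln, window = 100)
  expect_true(all(prof$identity == 100))
  expect_equal(nrow(prof), 201)

  # synthetic alignment with a known match pattern
  m <- c(rep(TRUE, 70), rep(FALSE, 30), rep(TRUE, 50))
  fake <- structure(list(
    aligned_a = paste(ifelse(m, "A", "C"), collapse = ""),
    aligned_b = paste(rep("A", 150), collapse = "")),
    class = "pairwise_alignment")
  p <- sliding_identity(fake, window = 100)
  expect_equal(p$identity[1], 70)
  # recount oracle at every window
  for (i in seq_len(nrow(p))) {
    expect_equal(p$identity[i], 100 * sum(m[(p$start[i] + 1):p$end[i]]) / 100)
  }

  # swapping the sequences leaves the profile unchanged
  sw <- generate_sequence_pair(400, background_identity = 70, seed = 2)
  p1 <- sliding_identity(global_align(sw$seq_a, sw$seq_b), window = 50)
  p2 <- sliding_identity(global_align(sw$seq_b, sw$seq_a), window = 50)
  expect_equal(p1$identity, p2$identity)

  expect_warning(sliding_identity(fake, window = 500), "truncated")
})

test_that("region calling merges threshold runs and is monotone in the threshold", {
  pair <- generate_sequence_pair(300, background_identity = 100, seed = 3)
  prof <- sliding_identity(global_align(pair$seq_a, pair$seq_b))
  regs <- call_regions(prof, threshold = 70)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start, 0)
  expect_equal(regs$end, max(prof$end))

  expect_equal(nrow(call_regions(prof, threshold = 101)), 0L)

  blocks <- data.frame(start = 500, end = 800, identity = 95)
  p2 <- generate_sequence_pair(1500, blocks, background_identity = 40,
                               seed = 4)
  aln2 <- global_align(p2$seq_a, p2$seq_b)
  prof2 <- sliding_identity(aln2)
  regs2 <- call_regions(prof2, threshold = 70)
  expect_equal(nrow(regs2), 1L)
  expect_lt(regs2$start, 800)
  expect_gt(regs2$end, 500)

  # raising the threshold never lengthens the called regions; regions
  # sorted and non-overlapping, covering every hot window
  total <- vapply(c(50, 60, 70, 80, 90, 99),
                  function(th) {
                    r <- call_regions(prof2, th)
                    if (nrow(r) == 0) 0 else sum(r$end - r$start)
                  }, 0)
  expect_true(all(diff(total) <= 0))
  r70 <- call_regions(prof2, 70)
  if (nrow(r70) > 1) {
    expect_true(all(diff(r70$start) > 0))
    expect_true(all(r70$start[-1] >= r70$end[-nrow(r70)]))
  }
  hot <- prof2[prof2$identity >= 70, ]
  inside <- vapply(seq_len(nrow(hot)), function(i) {
    any(hot$start[i] >= r70$start & hot$end[i] <= r70$end)
  }, FALSE)
  expect_true(all(inside))
})

test_that("feature overlap summaries follow interval arithmetic", {
  regs <- data.frame(start = c(100, 400), end = c(200, 600),
                     mean_identity = c(90, 85), max_identity = c(95, 92))
  prof <- data.frame(start = 0:599, centre = 0:599 + 50, end = 0:599 + 100,
                     identity = 80)
  attr(prof, "alignment_length") <- 700L
  feats <- data.frame(start = c(120, 250, 150, 1000),
                      end = c(180, 300, 450, 1100),
                      name = c("inside", "outside", "half", "beyond"))
  ov <- annotate_overlap(regs, feats, prof)
  expect_equal(ov$covered_fraction[1], 1)
  expect_equal(ov$covered_fraction[2], 0)
  expect_equal(ov$covered_fraction[3], (200 - 150 + 450 - 400) / 300)
  expect_true(ov$outside_alignment[4])
  expect_equal(ov$covered_fraction[4], 0)
})

test_that("alignment coordinates project onto each ungapped sequence", {
  fake <- structure(list(aligned_a = "AC--GT", aligned_b = "ACGTGT"),
                    class = "pairwise_alignment")
  pr <- project_coordinates(fake, c(0, 1, 2, 3, 4, 5))
  expect_equal(pr$pos_a, c(0, 1, 1, 1, 2, 3))
  expect_equal(pr$pos_b, c(0, 1, 2, 3, 4, 5))
})
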