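# Shared fixture builders; everything is generated in code, seeded.

# Unit-variance shape on the default day grid.
unit_shape <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- stats::approx(c(22, 64, 67, 72), rnorm(4), xout = default_days())$y
  (v - mean(v)) / sqrt(mean((v - mean(v))^2))
}

# Long expression table from a named list of fpkm traces.
trace_df <- function(traces, tissue = "apex", fpkm_sd = 0.1,
                     days = default_days()) {
  do.call(rbind, lapply(names(traces), function(g) {
    data.frame(gene_id = g, tissue = tissue, day = days,
               fpkm = traces[[g]], fpkm_sd = fpkm_sd,
               stringsAsFactors = FALSE)
  }))
}

# A vector with exact population correlation rho to `a` (both unit shapes).
shape_with_cor <- function(a, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- unit_shape()
  orth <- r - cor(a, r) * a
  orth <- (orth - mean(orth)) / sqrt(mean((orth - mean(orth))^2))
  v <- rho * a + sqrt(1 - rho^2) * orth
  (v - mean(v)) / sqrt(mean((v - mean(v))^2))
}

# Rand index between two partitions given as label vectors.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Two planted orthogonal blocks of correlated profiles plus noise profiles.
planted_blocks <- function(n_per_block = 40L, noise_sd = 0.3,
                           n_noise = 0L, seed = 1L) {
  set.seed(seed)
  u1 <- unit_shape()
  u2 <- shape_with_cor(u1, 0)
  mk <- function(u, k, tag) {
    m <- t(vapply(seq_len(k), function(i) u + rnorm(length(u), 0, noise_sd),
                  numeric(length(u))))
    rownames(m) <- sprintf("%s%03d", tag, seq_len(k))
    m
  }
  x <- rbind(mk(u1, n_per_block, "blockA"), mk(u2, n_per_block, "blockB"))
  if (n_noise > 0L) {
    x <- rbind(x, mk(rep(0, length(u1)), n_noise, "noise") +
                 matrix(rnorm(n_noise * length(u1)), n_noise))
  }
  truth <- rep(c(1L, 2L), each = n_per_block)
  list(x = x, truth = truth)
}
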