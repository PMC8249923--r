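# Independent oracles used to freeze expected values.

# Brute-force SVD via eigendecomposition of the Gram matrix: independent of
# base svd() as used by surprisal_decompose().
gram_svd <- function(X) {
  n <- nrow(X); m <- ncol(X)
  if (m <= n) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    v <- e$vectors
    u <- sweep(X %*% v, 2L, pmax(d, .Machine$double.eps), "/")
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    u <- e$vectors
    v <- sweep(crossprod(X, u), 2L, pmax(d, .Machine$double.eps), "/")
  }
  list(d = d, u = u, v = v)
}

# Two-sided permutation p-value for a difference in means.
perm_t_pvalue <- function(x, y, n_perm = 2000L, seed = 1L) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  n1 <- length(x)
  stat <- replicate(n_perm, {
    idx <- sample.int(length(pooled), n1)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  (sum(stat >= obs - 1e-12) + 1L) / (n_perm + 1L)
}

# Write a small delimited table (id column first) for reader tests.
write_fixture_table <- function(values, path, sep = ",", id_header = "id") {
  header <- paste(c(id_header, colnames(values)), collapse = sep)
  rows <- vapply(seq_len(nrow(values)), function(i) {
    cells <- ifelse(is.na(values[i, ]), "", format(values[i, ], digits = 15))
    paste(c(rownames(values)[i], cells), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# Small well-formed secretome matrix for reuse.
make_secretome <- function(n = 3, m = 4, seed = 1, floor = 0.1) {
  set.seed(seed)
  vals <- matrix(rlnorm(n * m, log(50), 1), n,
                 dimnames = list(paste0("CK", seq_len(n)),
                                 paste0("S", seq_len(m))))
  secretome_matrix(vals, detection_floor = floor)
}
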