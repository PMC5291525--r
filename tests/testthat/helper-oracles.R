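# Independent reference implementations used to cross-check the package.
# These deliberately take the slow, literal route: per-position recounts and
# stats::cor as the textbook Pearson.

random_dna <- function(n, ambiguous = FALSE) {
  alphabet <- c("A", "C", "G", "T")
  if (ambiguous) alphabet <- c(alphabet, "N", "R", "Y")
  paste(sample(alphabet, n, replace = TRUE,
               prob = if (ambiguous) c(rep(0.3, 4) / 1.2 * 0.95,
                                       rep(0.05 / 3, 3)) else NULL),
        collapse = "")
}

# Brute-force Z-curve: recount each prefix from scratch.
oracle_zcurve <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  N <- length(chars)
  count_prefix <- function(base) {
    vapply(0:N, function(n) sum(chars[seq_len(n)] == base), 0L)
  }
  A <- count_prefix("A"); C <- count_prefix("C")
  G <- count_prefix("G"); T <- count_prefix("T")
  list(A = A, C = C, G = G, T = T,
       x = (A + G) - (C + T), y = (A + C) - (G + T), z = (A + T) - (C + G))
}

# Naive ZCC: a literal per-base loop accumulator plus stats::cor.
oracle_zcc <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  at <- numeric(length(chars)); gc <- numeric(length(chars))
  a <- 0L; t <- 0L; g <- 0L; c <- 0L
  for (i in seq_along(chars)) {
    switch(chars[i], A = a <- a + 1L, T = t <- t + 1L,
           G = g <- g + 1L, C = c <- c + 1L)
    at[i] <- a - t
    gc[i] <- g - c
  }
  if (stats::sd(at) == 0 || stats::sd(gc) == 0) return(NA_real_)
  stats::cor(at, gc)
}

oracle_rymk <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  x <- numeric(length(chars)); y <- numeric(length(chars))
  xv <- 0L; yv <- 0L
  for (i in seq_along(chars)) {
    xv <- xv + switch(chars[i], A = 1L, G = 1L, C = -1L, T = -1L, 0L)
    yv <- yv + switch(chars[i], A = 1L, C = 1L, G = -1L, T = -1L, 0L)
    x[i] <- xv; y[i] <- yv
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Exact two-sided binomial confidence bounds on a count.
binom_ci <- function(n, p, conf = 0.99) {
  alpha <- 1 - conf
  c(lower = stats::qbinom(alpha / 2, n, p) / n,
    upper = stats::qbinom(1 - alpha / 2, n, p) / n)
}

# Circular distance between two positions on an N-circle.
circ_dist <- function(a, b, N) pmin((a - b) %% N, (b - a) %% N)

make_fasta <- function(path, seqs) {
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}
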