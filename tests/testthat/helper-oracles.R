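# Independent brute-force reference implementations used as oracles.
# Everything here is written as literal loops over the defining sets, kept
# deliberately separate from the package's vectorised / C++ code paths.

ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

brute_pair_dists <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d[i, j] <- ham(seqs[i], seqs[j])
  }
  d
}

brute_pi <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  tot <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + ham(seqs[i], seqs[j]); cnt <- cnt + 1
  }
  tot / cnt
}

brute_pi_b <- function(seqs1, seqs2) {
  tot <- 0; cnt <- 0
  for (a in seqs1) for (b in seqs2) { tot <- tot + ham(a, b); cnt <- cnt + 1 }
  tot / cnt
}

brute_S <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  sum(apply(mat, 2, function(col) length(unique(col)) > 1))
}

brute_watterson <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  brute_S(seqs) / sum(1 / (1:(n - 1)))
}

# Tajima (1989) coefficient algebra, written out independently
brute_sd_pi_theta <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  S <- brute_S(seqs)
  if (S == 0) return(0)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

brute_shannon <- function(seqs) {
  p <- as.numeric(table(seqs)) / length(seqs)
  -sum(p * log(p))
}

# correlation over all ordered pairs of sequence-pairs sharing exactly one
# member, enumerated literally
brute_wakeley_within <- function(seqs) {
  n <- length(seqs)
  if (n < 3) return(NA_real_)
  d <- brute_pair_dists(seqs)
  xs <- c(); ys <- c()
  pairs <- t(utils::combn(n, 2))
  for (p in seq_len(nrow(pairs))) for (q in seq_len(nrow(pairs))) {
    if (p == q) next
    shared <- intersect(pairs[p, ], pairs[q, ])
    if (length(shared) == 1) {
      xs <- c(xs, d[pairs[p, 1], pairs[p, 2]])
      ys <- c(ys, d[pairs[q, 1], pairs[q, 2]])
    }
  }
  m1 <- mean(xs); v <- mean(xs^2) - m1^2
  if (v <= 0) return(0)
  (mean(xs * ys) - m1 * mean(ys)) / v
}

brute_wakeley_cross <- function(seqs1, seqs2) {
  n1 <- length(seqs1); n2 <- length(seqs2)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) {
    return(list(s_xy = NA_real_, psi_w = NA_real_))
  }
  seqs <- c(seqs1, seqs2)
  d <- brute_pair_dists(seqs)
  cross <- expand.grid(x = 1:n1, y = n1 + (1:n2))
  xs <- c(); ys <- c()
  for (p in seq_len(nrow(cross))) for (q in seq_len(nrow(cross))) {
    if (p == q) next
    shared <- length(intersect(unlist(cross[p, ]), unlist(cross[q, ])))
    if (shared == 1) {
      xs <- c(xs, d[cross$x[p], cross$y[p]])
      ys <- c(ys, d[cross$x[q], cross$y[q]])
    }
  }
  dall <- c()
  for (p in seq_len(nrow(cross))) dall <- c(dall, d[cross$x[p], cross$y[p]])
  m1 <- mean(dall)
  v <- mean(dall^2) - m1^2
  cv <- mean(xs * ys) - m1^2
  list(s_xy = if (v > 0) cv / v else 0,
       psi_w = if (m1 > 0) cv / m1 else 0)
}

random_alignment <- function(n1, n2, L = 20, pair_id = 1L, locus_id = 1L) {
  seqs <- replicate(n1 + n2,
                    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                                 prob = c(0.4, 0.3, 0.2, 0.1)),
                          collapse = ""))
  locus_alignment(seqs, c(rep(1L, n1), rep(2L, n2)),
                  pair_id = pair_id, locus_id = locus_id)
}

# demographic parameter row helpers for simulator tests
const_pop_params <- function(theta, tau = 0) {
  tibble::tibble(theta_a = theta, theta_a1 = theta / 2, theta_a2 = theta / 2,
                 theta_b1 = theta / 2, theta_b2 = theta / 2,
                 tau_b1 = 0, tau_b2 = 0, tau = tau, nm = 0)
}

ss_cols_test <- function(tbl) grep("^ss_", names(tbl), value = TRUE)
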