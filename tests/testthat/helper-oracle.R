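# Shared fixtures: random score banks and a deliberately naive scalar
# transcription of the fusion equations, used as the independent oracle for
# the vectorized implementation.

# random bank with uniform-Dirichlet rows (normalized exponentials)
random_bank <- function(n, C, M, seed) {
  set.seed(seed)
  mats <- lapply(seq_len(M), function(i) {
    m <- matrix(stats::rexp(n * C), n, C)
    m <- m / rowSums(m)
    dimnames(m) <- list(paste0("s", seq_len(n)), paste0("class", seq_len(C)))
    m
  })
  score_set(mats)
}

# scalar, loop-everything transcription of the fusion rule; independent of
# the package's vectorized code path
oracle_fuse <- function(matrices, k, variant = "complement") {
  M <- length(matrices)
  n <- nrow(matrices[[1]]); C <- ncol(matrices[[1]])
  f <- function(x) 2 * (1 - 2^(x - 1))
  frs <- ccfs <- matrix(0, n, C)
  label <- integer(n)
  for (s in seq_len(n)) {
    ranks <- vector("list", M); member <- vector("list", M)
    for (i in seq_len(M)) {
      r <- numeric(C)
      for (c in seq_len(C)) r[c] <- f(matrices[[i]][s, c])
      ord <- rank(r, ties.method = "first")
      ranks[[i]] <- r
      member[[i]] <- ord <= k
    }
    for (c in seq_len(C)) {
      fr <- 0; cs <- 0
      for (i in seq_len(M)) {
        if (member[[i]][c]) {
          fr <- fr + ranks[[i]][c]
          cs <- cs + matrices[[i]][s, c]
        } else {
          fr <- fr + 1   # P_R
          cs <- cs + 0   # P_CoF
        }
      }
      frs[s, c] <- fr
      ccfs[s, c] <- if (variant == "complement") 1 - cs / M else cs / M
    }
    label[s] <- which.min(frs[s, ] * ccfs[s, ])
  }
  list(frs = frs, ccfs = ccfs, fds = frs * ccfs, label = label)
}

# one-sample worked bank used across tests
worked_bank <- function() {
  mk <- function(v) matrix(v, 1, dimnames = list("s1", c("c1", "c2", "c3")))
  score_set(list(mk(c(0.7, 0.2, 0.1)), mk(c(0.6, 0.3, 0.1)),
                 mk(c(0.1, 0.8, 0.1))))
}
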