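# Independent brute-force reference implementations used as oracles.
# Plain-R double loops, written directly from the estimator definitions;
# deliberately naive and independent of the package internals.

oracle_apen <- function(x, m = 2, r = 0.15 * sd(x)) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    tpl <- sapply(seq_len(n), function(i) x[i:(i + mm - 1)])
    tpl <- matrix(tpl, nrow = mm)
    cnt <- sapply(seq_len(n), function(i) {
      sum(sapply(seq_len(n), function(j)
        max(abs(tpl[, i] - tpl[, j])) <= r))
    })
    mean(log(cnt / n))
  }
  phi(m) - phi(m + 1)
}

oracle_sampen_counts <- function(x, m = 2, r = 0.15 * sd(x)) {
  N <- length(x)
  n <- N - m
  A <- 0; B <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

oracle_sampen <- function(x, m = 2, r = 0.15 * sd(x)) {
  ab <- oracle_sampen_counts(x, m, r)
  -log(ab[["A"]] / ab[["B"]])
}

oracle_fuzzyen <- function(x, m = 2, r = 0.15 * sd(x), p = 2) {
  N <- length(x)
  n <- N - m
  phi <- function(mm) {
    tpl <- lapply(seq_len(n), function(i) {
      v <- x[i:(i + mm - 1)]
      v - mean(v)
    })
    acc <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- max(abs(tpl[[i]] - tpl[[j]]))
      acc <- acc + exp(-(d / r)^p)
    }
    2 * acc / (n * (n - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

oracle_permen <- function(x, m = 6, tau = 1, normalize = FALSE) {
  N <- length(x)
  n <- N - (m - 1) * tau
  pats <- sapply(seq_len(n), function(t) {
    v <- x[t + (0:(m - 1)) * tau]
    paste(order(v), collapse = "-") # order() is stable: ties by index
  })
  q <- table(pats) / n
  h <- -sum(q * log(q))
  if (normalize) h / log(factorial(m)) else h
}

oracle_sse <- function(x, L = min(500, floor(2 * length(x) / 3))) {
  N <- length(x)
  K <- N - L + 1
  X <- matrix(0, L, K)
  for (j in seq_len(K)) X[, j] <- x[j:(j + L - 1)]
  s <- svd(X)$d
  p <- s / sum(s)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) { w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2 }
  else { w[1] <- 1; w[2:((n + 1) / 2)] <- 2 }
  a <- Mod(fft(X * w, inverse = TRUE) / n)
  p <- a / sum(a)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_logen <- function(x) sum(log(x^2 + .Machine$double.xmin))

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_exact <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  W_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(x), n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(Ws)
  list(p = mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12),
       z = (W_obs - mu) / sd(Ws))
}

# hand step-up BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by exhaustive concordant-pair counting (ties count half)
oracle_auc <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  acc <- 0
  for (i in pos) for (j in neg)
    acc <- acc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  acc / (length(pos) * length(neg))
}
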