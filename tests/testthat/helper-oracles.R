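# Independent brute-force oracles. Deliberately written as plain loops over
# the defining formulas, sharing no code with the package implementation.

# scalar biweight midcorrelation straight from the definition
naive_bicor <- function(x, y) {
  center <- function(v) {
    m <- median(v)
    mad0 <- median(abs(v - m))
    if (mad0 == 0) return(v - mean(v))
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      u <- (v[i] - m) / (9 * mad0)
      w <- if (abs(u) < 1) (1 - u^2)^2 else 0
      out[i] <- (v[i] - m) * w
    }
    out
  }
  a <- center(x); b <- center(y)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    da <- da + a[i]^2
    db <- db + b[i]^2
  }
  num / sqrt(da * db)
}

# pairwise |bicor| similarity by explicit double loop
naive_similarity <- function(X) {
  n <- nrow(X)
  S <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    s <- abs(naive_bicor(X[i, ], X[j, ]))
    S[i, j] <- s
    S[j, i] <- s
  }
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

# elementwise power by repeated multiplication (integer beta)
naive_power <- function(S, beta) {
  A <- S
  if (beta > 1) for (b in seq_len(beta - 1)) A <- A * S
  diag(A) <- 1
  A
}

# topological overlap by triple loop
naive_tom <- function(A) {
  n <- nrow(A)
  TOM <- diag(1, n)
  k <- numeric(n)
  for (i in seq_len(n)) for (u in seq_len(n)) if (u != i) k[i] <- k[i] + A[i, u]
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    TOM[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(TOM) <- dimnames(A)
  TOM
}

# quadratic-time average-linkage agglomeration; returns merge heights in
# merge order (heights are averages over ORIGINAL pairwise dissimilarities)
naive_average_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) if (a < b) {
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < bestd) { bestd <- d; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# total and intramodular connectivity by double loop
naive_connectivity <- function(A, labels) {
  n <- nrow(A)
  ktot <- numeric(n); kwit <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    ktot[i] <- ktot[i] + A[i, j]
    if (labels[i] == labels[j]) kwit[i] <- kwit[i] + A[i, j]
  }
  list(kTotal = ktot, kWithin = kwit)
}

# upper-tail hypergeometric probability as an explicit choose() sum
hyper_choose_sum <- function(k, K, n, N) {
  tot <- 0
  for (i in k:min(K, n)) tot <- tot + choose(K, i) * choose(N - K, n - i)
  tot / choose(N, n)
}

# exhaustive enumeration over every possible draw (tiny N only)
hyper_enumerate <- function(k, K, n, N) {
  draws <- combn(N, n)
  hits <- 0
  for (c in seq_len(ncol(draws)))
    if (sum(draws[, c] <= K) >= k) hits <- hits + 1
  hits / ncol(draws)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random symmetric similarity-like matrix with unit diagonal
random_similarity <- function(n, seed) {
  set.seed(seed)
  S <- matrix(runif(n * n, 0.05, 0.95), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  rownames(S) <- colnames(S) <- sprintf("g%02d", seq_len(n))
  S
}
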