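# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most literal method available (enumeration,
# normal equations, O(n^2) scans) so they stay independent of the package's
# implementation paths.

# OLS via the normal equations (X'X)^-1 X'y on an explicit design matrix
oracle_ols <- function(X, y) {
  Xd <- cbind(1, X)
  drop(solve(t(Xd) %*% Xd, t(Xd) %*% y))
}

# Kennard-Stone by literal max-min selection on a precomputed distance matrix
oracle_kennard_stone <- function(X, n_train) {
  Z <- scale(X)
  Z[, apply(X, 2, sd) == 0] <- 0
  D <- as.matrix(dist(Z))
  n <- nrow(X)
  best <- c(Inf, NA, NA)
  maxd <- -Inf
  pair <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > maxd) { maxd <- D[i, j]; pair <- c(i, j) }
  sel <- pair
  while (length(sel) < n_train) {
    rem <- setdiff(seq_len(n), sel)
    score <- sapply(rem, function(r) min(D[r, sel]))
    sel <- c(sel, rem[which.max(score)])
  }
  sort(sel)
}

# O(n^2) dominance scan
oracle_pareto <- function(f1, f2) {
  n <- length(f1)
  keep <- logical(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    key <- paste(f1[i], f2[i])
    if (key %in% seen) next
    seen <- c(seen, key)
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (f1[j] <= f1[i] && f2[j] <= f2[i] && (f1[j] < f1[i] || f2[j] < f2[i]))
        dominated <- TRUE
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# knee by direct distance minimization on min-max normalized objectives
oracle_knee <- function(f1, f2) {
  nz <- function(v) if (max(v) == min(v)) rep(0, length(v))
                    else (v - min(v)) / (max(v) - min(v))
  d <- sqrt(nz(f1)^2 + nz(f2)^2)
  order(d, f1)[1]
}

# explicit hat matrix
oracle_leverage <- function(X) diag(X %*% solve(t(X) %*% X) %*% t(X))

# small random analyte table for property tests
random_table <- function(n = 20, K = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * K), n, K,
              dimnames = list(NULL, paste0("d", 1:K)))
  analyte_table(paste0("a", 1:n), X, t_obs = runif(n, 1, 30))
}
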