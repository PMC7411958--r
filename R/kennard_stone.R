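#' Kennard-Stone train/test split
#'
#' Deterministic max-min-distance selection of a representative training
#' set. Distances are Euclidean in autoscaled descriptor space (each column
#' centred and scaled to unit variance over the full table). The first two
#' training points are the pair at maximum distance; each subsequent point
#' maximizes its minimum distance to the points already selected. Ties are
#' broken by lowest row index. The remaining rows form the external
#' validation (test) set.
#'
#' @param table an \code{\link{analyte_table}} with n >= 3.
#' @param ratio training fraction in (0, 1); the training size is
#'   \code{round(ratio * n)}.
#' @return A list of class \code{split_result}: \code{train_indices},
#'   \code{test_indices} (each sorted ascending), \code{ratio_achieved}.
#' @export
kennard_stone_split <- function(table, ratio = 0.70) {
  stopifnot(inherits(table, "analyte_table"))
  n <- table$n
  if (n < 3) stop("need at least 3 analytes to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly between 0 and 1")
  n_train <- as.integer(floor(ratio * n + 0.5))
  n_train <- max(2L, min(n_train, n - 1L))
  Z <- autoscale(table$X)
  D <- as.matrix(stats::dist(Z))

  # seed pair: maximum pairwise distance, lexicographically smallest indices
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- as.integer(idx[1, ])

  remaining <- setdiff(seq_len(n), sel)
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_train) {
    cand <- remaining[which.max(mind[remaining])]  # which.max: first = lowest index
    sel <- c(sel, cand)
    remaining <- setdiff(remaining, cand)
    mind <- pmin(mind, D[, cand])
  }
  structure(list(train_indices = sort(sel),
                 test_indices = sort(remaining),
                 ratio_achieved = n_train / n),
            class = "split_result")
}

# column-wise autoscale; constant columns left centred (sd 0 -> divisor 1)
autoscale <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
}

#' Apply a split to a table's set labels
#'
#' @param table an \code{analyte_table}.
#' @param split a \code{split_result}.
#' @return The table with \code{set_label} filled in.
#' @export
apply_split <- function(table, split) {
  stopifnot(inherits(table, "analyte_table"), inherits(split, "split_result"))
  lbl <- rep("unassigned", table$n)
  lbl[split$train_indices] <- "train"
  lbl[split$test_indices] <- "test"
  analyte_table(table$ids, table$X, table$t_obs, lbl)
}
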