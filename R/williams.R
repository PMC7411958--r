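#' Critical leverage h*
#'
#' Warning limit for the leverage axis of the Williams plot. The default
#' (\code{"k_minus_1"}) computes 3(K - 1)/N with K counted as the
#' number of model variables including the intercept; the conventional
#' alternative is 3(K + 1)/N with K predictors.
#'
#' @param K number of model variables (>= 1).
#' @param N number of training observations (>= 1).
#' @param formula \code{"k_minus_1"} or \code{"conventional_k_plus_1"}.
#' @return h* (scalar).
#' @export
critical_leverage <- function(K, N,
                              formula = c("k_minus_1",
                                          "conventional_k_plus_1")) {
  formula <- match.arg(formula)
  if (K < 1 || N < 1) stop("K and N must be positive")
  if (formula == "k_minus_1") {
    if (K == 1) warning("K = 1 gives h* = 0 under the 3(K-1)/N formula")
    3 * (K - 1) / N
  } else {
    3 * (K + 1) / N
  }
}

#' Leverages of query points with respect to a training design
#'
#' h_q = x_q' (X'X)^{-1} x_q where X is the training design matrix
#' (intercept column + descriptors). Training leverages lie in (0, 1] and
#' sum to the number of model parameters (the hat-matrix trace).
#'
#' @param train_design numeric training design matrix, full column rank.
#' @param query_design rows to compute leverages for (default: training).
#' @return Numeric leverage vector, one per query row.
#' @export
leverages <- function(train_design, query_design = train_design) {
  train_design <- as.matrix(train_design)
  query_design <- as.matrix(query_design)
  if (qr(train_design)$rank < ncol(train_design))
    stop("singular training design")
  XtX_inv <- chol2inv(chol(crossprod(train_design)))
  rowSums((query_design %*% XtX_inv) * query_design)
}

#' Standardize residuals by the training residual standard deviation
#'
#' @param residuals numeric residual vector, minutes.
#' @param train_sd training residual sd; default: sample sd of
#'   \code{residuals} itself.
#' @return Unitless standardized residuals. Zero residual variance yields an
#'   all-zero vector with a warning.
#' @export
standardized_residuals <- function(residuals, train_sd = stats::sd(residuals)) {
  if (length(residuals) < 2 && missing(train_sd))
    stop("need at least 2 residuals to estimate the standard deviation")
  if (!is.finite(train_sd) || train_sd == 0) {
    warning("zero residual variance; standardized residuals set to 0")
    return(rep(0, length(residuals)))
  }
  residuals / train_sd
}

#' Williams-plot applicability-domain report
#'
#' Computes leverages and standardized residuals for every analyte (training
#' and test) under a fitted model, the critical leverage h*, and per-analyte
#' flags: \code{x_outlier} (leverage > h*, |std residual| <= 3),
#' \code{y_outlier} (|std residual| > 3, leverage <= h*), \code{xy_outlier}
#' (both), else \code{inside}. Residual standardization uses the training
#' residual standard deviation for all rows.
#'
#' @param model a \code{\link{qsrr_model}} fitted on the split's training rows.
#' @param table an \code{\link{analyte_table}}.
#' @param split a \code{split_result} from \code{\link{kennard_stone_split}}.
#' @param leverage_formula passed to \code{\link{critical_leverage}}.
#' @return An \code{ad_report}: data frame \code{analytes} (id, set_label,
#'   leverage, std_residual, flag), plus \code{h_star}, \code{K_used},
#'   \code{N_used}, and \code{counts} of the flag partition.
#' @export
williams_report <- function(model, table, split,
                            leverage_formula = "k_minus_1") {
  stopifnot(inherits(model, "qsrr_model"), inherits(table, "analyte_table"),
            inherits(split, "split_result"))
  tr <- split$train_indices
  Xd_all <- cbind(1, table$X[, model$descriptor_names, drop = FALSE])
  h <- leverages(Xd_all[tr, , drop = FALSE], Xd_all)
  resid <- table$t_obs - predict(model, table)
  train_sd <- stats::sd(resid[tr])
  # an exact fit leaves sd at rounding-error level; treat it as zero
  if (train_sd < 1e-10 * max(stats::sd(table$t_obs), 1)) train_sd <- 0
  sr <- standardized_residuals(resid, train_sd)
  K_used <- length(model$descriptor_names) + 1L   # model variables incl. intercept
  N_used <- length(tr)
  h_star <- critical_leverage(K_used, N_used, leverage_formula)
  x_out <- h > h_star
  y_out <- abs(sr) > 3
  flag <- ifelse(x_out & y_out, "xy_outlier",
          ifelse(x_out, "x_outlier",
          ifelse(y_out, "y_outlier", "inside")))
  lbl <- rep("unassigned", table$n)
  lbl[tr] <- "train"; lbl[split$test_indices] <- "test"
  analytes <- data.frame(id = table$ids, set_label = lbl,
                         leverage = h, std_residual = sr, flag = flag,
                         stringsAsFactors = FALSE)
  structure(list(analytes = analytes, h_star = h_star,
                 K_used = K_used, N_used = N_used,
                 counts = table(factor(flag, levels = c("inside", "x_outlier",
                                                        "y_outlier", "xy_outlier")))),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report> h* = %.4f (K = %d, N = %d)\n",
              x$h_star, x$K_used, x$N_used))
  print(x$counts)
  invisible(x)
}
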