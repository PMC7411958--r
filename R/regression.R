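#' Fit the linear QSRR model by ordinary least squares
#'
#' Fits tR = alpha0 + alpha1 x1 + ... + alphaK xK + eps on the raw
#' (unscaled) descriptors of the training rows, the control model that the
#' multi-objective stage starts from.
#'
#' @param table an \code{\link{analyte_table}}.
#' @param train integer indices of the training rows (|train| >= K + 2).
#' @return An object of class \code{qsrr_model}: \code{intercept} (minutes),
#'   \code{coefficients} (named, minutes per descriptor unit),
#'   \code{descriptor_names}, \code{n_train}, \code{residual_sd} (minutes).
#' @export
fit_mlr <- function(table, train = seq_len(table$n)) {
  stopifnot(inherits(table, "analyte_table"))
  train <- as.integer(train)
  K <- table$K
  if (length(train) < K + 2)
    stop(sprintf("need at least K + 2 = %d training rows", K + 2))
  df <- data.frame(.tR = table$t_obs[train],
                   table$X[train, , drop = FALSE], check.names = FALSE)
  fit <- stats::lm(.tR ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("singular design: descriptor columns are collinear")
  qsrr_model(intercept = unname(cf[1]),
             coefficients = stats::setNames(unname(cf[-1]), table$descriptor_names),
             descriptor_names = table$descriptor_names,
             n_train = length(train),
             residual_sd = stats::sd(stats::residuals(fit)))
}

#' Construct a QSRR model from explicit coefficients
#'
#' @param intercept alpha0, minutes.
#' @param coefficients named numeric vector alpha1..alphaK.
#' @param descriptor_names descriptor column names the coefficients refer to.
#' @param n_train training-set size the model was derived from (optional).
#' @param residual_sd training residual standard deviation, minutes (optional).
#' @return A \code{qsrr_model}.
#' @export
qsrr_model <- function(intercept, coefficients, descriptor_names = names(coefficients),
                       n_train = NA_integer_, residual_sd = NA_real_) {
  force(descriptor_names)
  coefficients <- as.numeric(coefficients)
  if (!all(is.finite(c(intercept, coefficients))))
    stop("model coefficients must be finite")
  if (length(coefficients) != length(descriptor_names))
    stop("one coefficient per descriptor required")
  structure(list(intercept = intercept,
                 coefficients = stats::setNames(coefficients, descriptor_names),
                 descriptor_names = descriptor_names,
                 n_train = n_train, residual_sd = residual_sd),
            class = "qsrr_model")
}

#' @export
print.qsrr_model <- function(x, ...) {
  cat("<qsrr_model> tR =", format(x$intercept, digits = 5))
  for (k in seq_along(x$coefficients))
    cat(sprintf(" %s %s*%s", ifelse(x$coefficients[k] < 0, "-", "+"),
                format(abs(x$coefficients[k]), digits = 5),
                x$descriptor_names[k]))
  cat(sprintf("\n  n_train = %s, residual sd = %s min\n",
              x$n_train, format(x$residual_sd, digits = 4)))
  invisible(x)
}

#' Predict retention times
#'
#' @param object a \code{qsrr_model}.
#' @param table an \code{analyte_table} containing the model's descriptors.
#' @param indices rows to predict (default all).
#' @param ... unused.
#' @return Numeric vector of predicted retention times, minutes.
#' @export
predict.qsrr_model <- function(object, table, indices = seq_len(table$n), ...) {
  stopifnot(inherits(table, "analyte_table"))
  missing <- setdiff(object$descriptor_names, table$descriptor_names)
  if (length(missing) > 0)
    stop(sprintf("table lacks descriptor column(s): %s",
                 paste(missing, collapse = ", ")))
  X <- table$X[indices, object$descriptor_names, drop = FALSE]
  drop(object$intercept + X %*% object$coefficients)
}

#' Percent RMSE of retention time
#'
#' Default variant: \code{100 * sqrt(mean(((pred - obs) / obs)^2))}, the
#' relative root-mean-square error in percent; zero iff prediction equals
#' observation. The \code{"literal_eq6"} variant is the signed mean relative
#' error \code{100 * mean((pred - obs) / obs)} retained for auditing; it can
#' be negative and is not used by the optimizer by default.
#'
#' @param t_obs,t_pred observed and predicted retention times, minutes;
#'   equal lengths, all \code{t_obs > 0}.
#' @param variant \code{"relative_rmse"} (default) or \code{"literal_eq6"}.
#' @return Percent error (scalar).
#' @export
percent_rmse_tr <- function(t_obs, t_pred,
                            variant = c("relative_rmse", "literal_eq6")) {
  variant <- match.arg(variant)
  if (length(t_obs) != length(t_pred)) stop("length mismatch")
  if (length(t_obs) < 1) stop("need at least one observation")
  if (any(t_obs <= 0)) stop("all observed retention times must be > 0")
  rel <- (t_pred - t_obs) / t_obs
  if (variant == "relative_rmse") 100 * sqrt(mean(rel^2)) else 100 * mean(rel)
}

#' Elution ranks of a retention-time vector
#'
#' Rank i is the position of analyte i when the times are sorted ascending;
#' ties are broken by original row order (stable), so the output is always a
#' permutation of 1..n.
#'
#' @param t numeric vector of retention times.
#' @return Integer permutation of \code{1:length(t)}.
#' @export
elution_ranks <- function(t) {
  if (length(t) < 1) stop("need at least one value")
  as.integer(rank(t, ties.method = "first"))
}

#' Percent RMSE of elution order
#'
#' Same functional form as \code{\link{percent_rmse_tr}} applied to elution
#' ranks: relative rank errors are large for early-eluting analytes (small
#' observed rank), so the metric weights the front of the chromatogram
#' heavily and can exceed 100\%.
#'
#' @param obs_ranks,pred_ranks permutations of 1..n (observed and predicted
#'   elution order).
#' @param variant as in \code{\link{percent_rmse_tr}}.
#' @return Percent error (scalar); 0 iff the rankings are identical.
#' @export
percent_rmse_order <- function(obs_ranks, pred_ranks,
                               variant = c("relative_rmse", "literal_eq6")) {
  check_permutation(obs_ranks)
  check_permutation(pred_ranks)
  if (length(obs_ranks) != length(pred_ranks)) stop("length mismatch")
  percent_rmse_tr(as.numeric(obs_ranks), as.numeric(pred_ranks),
                  variant = match.arg(variant))
}

check_permutation <- function(r) {
  r <- as.integer(r)
  if (!identical(sort(r), seq_along(r)))
    stop("input is not a permutation of 1..n")
  invisible(r)
}

#' Evaluate the two objectives of a model on an index subset
#'
#' f1 = \%RMSE of retention time, f2 = \%RMSE of elution order, computed
#' within the given subset only (ranks are re-derived inside the subset so
#' train/test metrics are self-contained).
#'
#' @param model a \code{qsrr_model}.
#' @param table an \code{analyte_table}.
#' @param indices rows to evaluate on (default all).
#' @param variant error-metric variant.
#' @return Named numeric vector \code{c(f1 = , f2 = )}, percent.
#' @export
evaluate_model <- function(model, table, indices = seq_len(table$n),
                           variant = "relative_rmse") {
  t_obs <- table$t_obs[indices]
  t_pred <- predict(model, table, indices)
  f1 <- percent_rmse_tr(t_obs, t_pred, variant)
  f2 <- percent_rmse_order(elution_ranks(t_obs), elution_ranks(t_pred), variant)
  c(f1 = f1, f2 = f2)
}
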