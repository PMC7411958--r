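#' Analyte descriptor/retention table
#'
#' The central data container: one row per analyte, carrying a unique
#' identifier, a matrix of K molecular descriptors (columns named after the
#' descriptors, units as provided), and an observed gradient retention time
#' in minutes. Retention times must be strictly positive because both error
#' metrics divide by the observed value.
#'
#' @param ids character vector of unique analyte identifiers.
#' @param X numeric matrix (n x K) of finite descriptor values with column
#'   names; a data.frame of numeric columns is accepted and coerced.
#' @param t_obs numeric vector of observed retention times, minutes, all > 0.
#' @param set_label optional per-row tag in \code{c("train","test","unassigned")};
#'   defaults to \code{"unassigned"}.
#' @return An object of class \code{analyte_table}: a list with elements
#'   \code{ids}, \code{descriptor_names}, \code{X}, \code{t_obs},
#'   \code{set_label}, \code{n}, \code{K}.
#' @examples
#' X <- cbind(mu = c(1, 2, 3), delta_min = c(-0.2, -0.1, -0.3),
#'            SASA = c(200, 250, 300))
#' tab <- analyte_table(c("a", "b", "c"), X, t_obs = c(5.1, 5.2, 7.0))
#' tab$K
#' @export
analyte_table <- function(ids, X, t_obs, set_label = NULL) {
  ids <- as.character(ids)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix or data.frame of numeric columns")
  if (is.null(colnames(X)) && ncol(X) > 0)
    stop("descriptor columns must be named")
  t_obs <- as.numeric(t_obs)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("analyte ids must be unique")
  if (nrow(X) != n || length(t_obs) != n)
    stop("ids, X and t_obs must have one entry per analyte")
  if (ncol(X) < 1) stop("at least one descriptor column is required (K >= 1)")
  if (!all(is.finite(X))) {
    bad <- which(!apply(is.finite(X), 1, all))
    stop(sprintf("non-finite descriptor value in row(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(t_obs) & t_obs > 0)) {
    bad <- which(!(is.finite(t_obs) & t_obs > 0))
    stop(sprintf("retention times must be finite and > 0; offending row(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(set_label)) set_label <- rep("unassigned", n)
  set_label <- match.arg(as.character(set_label),
                         c("train", "test", "unassigned"),
                         several.ok = TRUE)
  if (length(set_label) == 1L) set_label <- rep(set_label, n)
  if (length(set_label) != n) stop("set_label must have one entry per analyte")
  structure(list(ids = ids,
                 descriptor_names = colnames(X),
                 X = X, t_obs = t_obs, set_label = set_label,
                 n = n, K = ncol(X)),
            class = "analyte_table")
}

#' @export
print.analyte_table <- function(x, ...) {
  cat(sprintf("<analyte_table> %d analytes, %d descriptors (%s)\n",
              x$n, x$K, paste(x$descriptor_names, collapse = ", ")))
  cat(sprintf("  t_obs: %.2f-%.2f min; split: %d train / %d test / %d unassigned\n",
              min(x$t_obs), max(x$t_obs),
              sum(x$set_label == "train"), sum(x$set_label == "test"),
              sum(x$set_label == "unassigned")))
  invisible(x)
}

#' @export
as.data.frame.analyte_table <- function(x, ...) {
  data.frame(id = x$ids, as.data.frame(x$X), tR = x$t_obs,
             set_label = x$set_label, stringsAsFactors = FALSE)
}

#' Subset an analyte table by row indices
#'
#' @param table an \code{analyte_table}.
#' @param indices integer row indices to keep (order preserved as given).
#' @return An \code{analyte_table} restricted to \code{indices}.
#' @export
subset_table <- function(table, indices) {
  stopifnot(inherits(table, "analyte_table"))
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("empty index set")
  if (any(indices < 1L | indices > table$n)) stop("index out of range")
  analyte_table(table$ids[indices],
                table$X[indices, , drop = FALSE],
                table$t_obs[indices],
                table$set_label[indices])
}
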