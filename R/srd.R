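#' Sum of ranking differences between two rankings
#'
#' Distance between a model's ranking of the analytes and a reference
#' (usually the experimental elution order). Absolute mode is the Spearman
#' footrule sum |r_i - ref_i|; squared mode sums the squared differences.
#' Zero iff the rankings agree; symmetric in its arguments.
#'
#' @param ranking,reference permutations of 1..n.
#' @param mode \code{"absolute"} (default) or \code{"squared"}.
#' @return Non-negative scalar.
#' @export
srd_value <- function(ranking, reference, mode = c("absolute", "squared")) {
  mode <- match.arg(mode)
  ranking <- check_permutation(ranking)
  reference <- check_permutation(reference)
  if (length(ranking) != length(reference)) stop("length mismatch")
  d <- as.numeric(ranking) - as.numeric(reference)
  if (mode == "absolute") sum(abs(d)) else sum(d^2)
}

#' Maximum attainable SRD value
#'
#' Used to normalize SRD to percent. Absolute mode: n^2/2 for even n,
#' (n^2 - 1)/2 for odd n; squared mode: n(n^2 - 1)/3. Both maxima are
#' attained by the reversal permutation.
#'
#' @param n number of ranked objects (>= 2).
#' @param mode \code{"absolute"} or \code{"squared"}.
#' @return Positive scalar.
#' @export
srd_max <- function(n, mode = c("absolute", "squared")) {
  mode <- match.arg(mode)
  if (n < 2) stop("need n >= 2")
  if (mode == "absolute") {
    if (n %% 2 == 0) n^2 / 2 else (n^2 - 1) / 2
  } else {
    n * (n^2 - 1) / 3
  }
}

#' Rank a set of models by SRD against a reference elution order
#'
#' @param pred_orders named list of permutations (one predicted elution
#'   order per model/column).
#' @param reference reference permutation (experimental elution order).
#' @param mode SRD mode.
#' @param crnn optional \code{crnn_stats} used to flag models whose SRD
#'   percent falls below the first icosaile (XX1) of the random-ranking
#'   distribution, i.e. statistically closer to the reference than random.
#' @return An \code{srd_report}: data frame \code{models} with
#'   \code{model_label}, \code{srd_raw}, \code{srd_percent} (and
#'   \code{significant_vs_random} when \code{crnn} is given), sorted
#'   ascending by \code{srd_percent}; plus \code{mode}, \code{n}, \code{crnn}.
#' @export
rank_models <- function(pred_orders, reference, mode = c("absolute", "squared"),
                        crnn = NULL) {
  mode <- match.arg(mode)
  reference <- check_permutation(reference)
  n <- length(reference)
  if (is.null(names(pred_orders)))
    names(pred_orders) <- paste0("model_", seq_along(pred_orders))
  raw <- vapply(pred_orders, srd_value, numeric(1),
                reference = reference, mode = mode)
  pct <- 100 * raw / srd_max(n, mode)
  df <- data.frame(model_label = names(pred_orders),
                   srd_raw = unname(raw), srd_percent = unname(pct),
                   stringsAsFactors = FALSE)
  if (!is.null(crnn)) {
    stopifnot(inherits(crnn, "crnn_stats"))
    df$significant_vs_random <- df$srd_percent < crnn$xx1
  }
  df <- df[order(df$srd_percent, df$model_label), ]
  rownames(df) <- NULL
  structure(list(models = df, mode = mode, n = n, crnn = crnn),
            class = "srd_report")
}

#' @export
print.srd_report <- function(x, ...) {
  cat(sprintf("<srd_report> %d models, n = %d objects, mode = %s\n",
              nrow(x$models), x$n, x$mode))
  print(x$models, digits = 4)
  if (!is.null(x$crnn))
    cat(sprintf("  CRNN: XX1 = %.2f, median = %.2f, XX9 = %.2f\n",
                x$crnn$xx1, x$crnn$median, x$crnn$xx9))
  invisible(x)
}

#' CRNN null distribution of SRD for random rankings
#'
#' Comparison of ranks of random numbers: the SRD-percent distribution
#' obtained when rankings are uniformly random permutations (equivalently,
#' ranks of i.i.d. continuous random numbers). A model whose SRD percent
#' falls below the first icosaile (XX1, 5th percentile) ranks the objects
#' statistically significantly more like the reference than chance does.
#'
#' @param n_objects number of ranked objects (>= 2).
#' @param n_draws Monte-Carlo draws (>= 1000).
#' @param seed RNG seed.
#' @param mode SRD mode.
#' @return A \code{crnn_stats}: \code{xx1} (5th percentile), \code{median},
#'   \code{xx9} (95th percentile), all in percent; \code{n_objects},
#'   \code{n_draws}, \code{seed}, \code{mode}, and \code{curve}, a histogram
#'   data frame (\code{srd_percent}, \code{density}) for plotting.
#' @export
crnn_distribution <- function(n_objects, n_draws = 1e5, seed = 1L,
                              mode = c("absolute", "squared")) {
  mode <- match.arg(mode)
  if (n_objects < 2) stop("need n_objects >= 2")
  if (n_draws < 1000) stop("need n_draws >= 1000")
  reference <- seq_len(n_objects)
  smax <- srd_max(n_objects, mode)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  vals <- vapply(seq_len(n_draws), function(i) {
    p <- sample.int(n_objects)
    if (mode == "absolute") sum(abs(p - reference)) else sum((p - reference)^2)
  }, numeric(1))
  pct <- 100 * vals / smax
  q <- stats::quantile(pct, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  h <- graphics::hist(pct, breaks = 50, plot = FALSE)
  structure(list(xx1 = q[1], median = q[2], xx9 = q[3],
                 n_objects = n_objects, n_draws = n_draws,
                 seed = as.integer(seed), mode = mode,
                 curve = data.frame(srd_percent = h$mids, density = h$density)),
            class = "crnn_stats")
}

#' @export
print.crnn_stats <- function(x, ...) {
  cat(sprintf(
    "<crnn_stats> n = %d objects, %d draws (%s mode): XX1 = %.2f, median = %.2f, XX9 = %.2f\n",
    x$n_objects, x$n_draws, x$mode, x$xx1, x$median, x$xx9))
  invisible(x)
}

#' Exact SRD-percent distribution by full permutation enumeration
#'
#' Test oracle: enumerates all n! permutations (n <= 8) and returns the
#' exact multiset of normalized SRD values.
#'
#' @param n_objects number of objects, 2..8.
#' @param mode SRD mode.
#' @return List with \code{percent} (sorted vector of n! values),
#'   \code{raw}, and \code{mean_raw}.
#' @export
exhaustive_crnn <- function(n_objects, mode = c("absolute", "squared")) {
  mode <- match.arg(mode)
  if (n_objects < 2 || n_objects > 8) stop("n_objects must be in 2..8")
  perms <- all_permutations(n_objects)
  reference <- seq_len(n_objects)
  raw <- apply(perms, 1, function(p)
    if (mode == "absolute") sum(abs(p - reference)) else sum((p - reference)^2))
  list(percent = sort(100 * raw / srd_max(n_objects, mode)),
       raw = sort(raw), mean_raw = mean(raw))
}

# all n! permutations of 1..n as rows (recursive; n <= 8 keeps this small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
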