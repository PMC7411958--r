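#' Specification for the synthetic descriptor/retention generator
#'
#' Describes a linear-Gaussian QSRR world: descriptors drawn from a
#' correlated multivariate normal, retention generated as
#' tR = alpha0 + sum(alpha_k x_k) + eps with Gaussian noise, optionally
#' heteroscedastic (noise sd proportional to the noise-free retention, as
#' gradient data show larger deviations toward the retention extremes).
#' Rows whose observed retention would be non-positive are redrawn.
#'
#' @param n analyte count.
#' @param K descriptor count.
#' @param true_coefficients numeric vector alpha0..alphaK (length K + 1).
#' @param descriptor_correlation common pairwise descriptor correlation in
#'   [0, 1).
#' @param noise_sd noise scale, minutes (for the heteroscedastic option this
#'   is the sd at the mean noise-free retention).
#' @param heteroscedastic logical; noise sd proportional to the noise-free
#'   retention time.
#' @param descriptor_names optional column names (default d1..dK).
#' @param seed RNG seed.
#' @return A list of class \code{generator_spec}.
#' @export
generator_spec <- function(n, K, true_coefficients,
                           descriptor_correlation = 0,
                           noise_sd = 0, heteroscedastic = FALSE,
                           descriptor_names = paste0("d", seq_len(K)),
                           seed = 1L) {
  if (length(true_coefficients) != K + 1)
    stop("true_coefficients must have length K + 1 (alpha0..alphaK)")
  if (descriptor_correlation < 0 || descriptor_correlation >= 1)
    stop("descriptor_correlation must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (isTRUE(heteroscedastic) && true_coefficients[1] <= 0)
    stop("heteroscedastic noise requires a positive intercept alpha0")
  stopifnot(n >= 1, K >= 1, length(descriptor_names) == K)
  structure(list(n = as.integer(n), K = as.integer(K),
                 true_coefficients = as.numeric(true_coefficients),
                 descriptor_correlation = descriptor_correlation,
                 noise_sd = noise_sd, heteroscedastic = isTRUE(heteroscedastic),
                 descriptor_names = descriptor_names, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic analyte table from a linear QSRR model
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return List with \code{table} (an \code{\link{analyte_table}}) and
#'   \code{true_model} (a \code{\link{qsrr_model}} holding the generating
#'   coefficients, for parameter-recovery tests).
#' @export
generate_linear_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  K <- spec$K
  Sigma <- matrix(spec$descriptor_correlation, K, K)
  diag(Sigma) <- 1
  L <- chol(Sigma)
  a0 <- spec$true_coefficients[1]
  a <- spec$true_coefficients[-1]

  draw_rows <- function(m) {
    X <- matrix(stats::rnorm(m * K), m, K) %*% L
    t_true <- drop(a0 + X %*% a)
    sd_i <- if (spec$heteroscedastic && spec$noise_sd > 0) {
      # sd proportional to the noise-free retention, scaled so that the sd
      # at the population mean retention (= alpha0) equals noise_sd
      spec$noise_sd * pmax(t_true, 0) / abs(a0)
    } else rep(spec$noise_sd, m)
    t_obs <- t_true + stats::rnorm(m) * sd_i
    list(X = X, t_obs = t_obs, ok = is.finite(t_obs) & t_obs > 0 & t_true > 0)
  }

  X <- matrix(0, spec$n, K)
  t_obs <- numeric(spec$n)
  filled <- 0L
  for (attempt in seq_len(1000L)) {
    d <- draw_rows(spec$n - filled)
    k <- sum(d$ok)
    if (k > 0) {
      rows <- filled + seq_len(k)
      X[rows, ] <- d$X[d$ok, , drop = FALSE]
      t_obs[rows] <- d$t_obs[d$ok]
      filled <- filled + k
    }
    if (filled == spec$n) break
  }
  if (filled < spec$n)
    stop("could not generate positive retention times within 1000 attempts; spec infeasible")
  colnames(X) <- spec$descriptor_names
  table <- analyte_table(sprintf("syn_%03d", seq_len(spec$n)), X, t_obs)
  true_model <- qsrr_model(a0, stats::setNames(a, spec$descriptor_names),
                           n_train = spec$n)
  list(table = table, true_model = true_model)
}

#' Case-study-shaped generator presets
#'
#' \code{preset_cs1_like()}: 62 analytes, 3 descriptors, homoscedastic noise
#' sized so the control-model percent RMSE of retention time lands near 10
#' percent. \code{preset_cs2_like()}: 98 analytes, 3 descriptors,
#' heteroscedastic noise (sd proportional to retention) near 15 percent
#' relative error, the regime in which plain least squares misorders
#' early-eluting analytes and the multi-objective stage has room to trade.
#'
#' @param seed RNG seed for the generated table.
#' @return A \code{\link{generator_spec}}.
#' @export
preset_cs1_like <- function(seed = 1L) {
  generator_spec(n = 62, K = 3,
                 true_coefficients = c(18, 5, 2, 1.5),
                 descriptor_correlation = 0.3,
                 noise_sd = 1.5, heteroscedastic = FALSE,
                 descriptor_names = c("mu", "delta_min", "SASA"),
                 seed = seed)
}

#' @rdname preset_cs1_like
#' @export
preset_cs2_like <- function(seed = 1L) {
  generator_spec(n = 98, K = 3,
                 true_coefficients = c(25, 6, 2.5, 1.5),
                 descriptor_correlation = 0.5,
                 noise_sd = 4, heteroscedastic = TRUE,
                 descriptor_names = c("logSum_AA", "clogP", "log_vdW_vol"),
                 seed = seed)
}

#' Synthetic Pareto-front fixtures with known knee location
#'
#' @param shape \code{"convex"}, \code{"L_shaped"}, or \code{"single_point"}.
#' @param size number of solutions (>= 1; fixed at 3 for L_shaped, 1 for
#'   single_point).
#' @param seed unused for the deterministic shapes; kept for interface
#'   stability.
#' @return A \code{pareto_front} with placeholder coefficients.
#' @export
generate_front_fixture <- function(shape = c("convex", "L_shaped", "single_point"),
                                   size = 10, seed = 1L) {
  shape <- match.arg(shape)
  if (size < 1) stop("size must be >= 1")
  pts <- switch(shape,
    single_point = cbind(f1 = 1, f2 = 1),
    L_shaped = cbind(f1 = c(0, 0.1, 1), f2 = c(1, 0.1, 0)),
    convex = {
      th <- seq(0, pi / 2, length.out = size)
      cbind(f1 = 1 - cos(th), f2 = 1 - sin(th))
    })
  o <- order(pts[, 1], pts[, 2])
  pts <- pts[o, , drop = FALSE]
  coefs <- matrix(0, nrow(pts), 2,
                  dimnames = list(NULL, c("(Intercept)", "d1")))
  front <- structure(list(coefficients = coefs,
                          f1 = unname(pts[, 1]), f2 = unname(pts[, 2]),
                          knee_index = NA_integer_,
                          selected_index = NA_integer_,
                          control = c(f1 = max(pts[, 1]), f2 = max(pts[, 2])),
                          control_model = NULL),
                     class = "pareto_front")
  front$knee_index <- knee_point(front)
  front
}
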