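#' Genetic-algorithm hyperparameters
#'
#' Settings for the elitist non-dominated-sorting GA that re-optimizes the
#' regression coefficients. The initial population is the MLR coefficient
#' vector plus \code{population_size - 1} component-wise Gaussian
#' perturbations with sd \code{init_spread * max(|alpha_k|, 1e-3)}.
#'
#' @param population_size even integer >= 4.
#' @param generations integer >= 1.
#' @param crossover_prob probability of simulated-binary crossover per pair.
#' @param mutation_prob per-gene polynomial-mutation probability; default
#'   \code{NA} means \code{1/(K+1)} (one expected gene per individual).
#' @param init_spread relative scale of the Gaussian seeding perturbations.
#' @param seed integer RNG seed for the GA run.
#' @return A list of class \code{ga_params}.
#' @export
ga_params <- function(population_size = 100L, generations = 200L,
                      crossover_prob = 0.9, mutation_prob = NA_real_,
                      init_spread = 0.1, seed = 1L) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  if (population_size < 4L) stop("population_size must be >= 4")
  if (population_size %% 2L != 0L) population_size <- population_size + 1L
  if (generations < 1L) stop("generations must be >= 1")
  for (p in c(crossover_prob, if (!is.na(mutation_prob)) mutation_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (init_spread <= 0) stop("init_spread must be positive")
  structure(list(population_size = population_size, generations = generations,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 init_spread = init_spread, seed = as.integer(seed)),
            class = "ga_params")
}

#' Case-study configuration
#'
#' Bundles the schema (descriptor/ID/retention column names), the
#' Kennard-Stone split ratio, the GA settings, the user bound on retention
#' predictive-ability loss, and the metric/formula variants.
#'
#' @param descriptor_names character vector naming the descriptor columns.
#' @param id_col,tr_col names of the identifier and retention-time columns.
#' @param split_ratio training fraction for the Kennard-Stone split (0, 1).
#' @param ga GA settings, see \code{\link{ga_params}}.
#' @param max_tr_loss_percent user bound on the allowed relative increase of
#'   \%RMSE(tR) over the MLR control, in percent (>= 0).
#' @param rmse_variant \code{"relative_rmse"} (default) or
#'   \code{"literal_eq6"} (signed mean relative error, audit only).
#' @param srd_mode \code{"absolute"} (Spearman footrule, default) or
#'   \code{"squared"}.
#' @param leverage_formula \code{"k_minus_1"} (default, h* = 3(K-1)/N
#'   with K counting the intercept) or \code{"conventional_k_plus_1"}.
#' @param seed root seed for all randomness in a pipeline run.
#' @return A list of class \code{case_study_config}.
#' @export
case_study_config <- function(descriptor_names,
                              id_col = "id", tr_col = "tR",
                              split_ratio = 0.70,
                              ga = ga_params(),
                              max_tr_loss_percent = 10,
                              rmse_variant = c("relative_rmse", "literal_eq6"),
                              srd_mode = c("absolute", "squared"),
                              leverage_formula = c("k_minus_1",
                                                   "conventional_k_plus_1"),
                              seed = 1L) {
  rmse_variant <- match.arg(rmse_variant)
  srd_mode <- match.arg(srd_mode)
  leverage_formula <- match.arg(leverage_formula)
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("split_ratio must lie strictly between 0 and 1")
  if (max_tr_loss_percent < 0) stop("max_tr_loss_percent must be >= 0")
  stopifnot(inherits(ga, "ga_params"), is.character(descriptor_names),
            length(descriptor_names) >= 1)
  structure(list(descriptor_names = descriptor_names,
                 id_col = id_col, tr_col = tr_col,
                 split_ratio = split_ratio, ga = ga,
                 max_tr_loss_percent = max_tr_loss_percent,
                 rmse_variant = rmse_variant, srd_mode = srd_mode,
                 leverage_formula = leverage_formula,
                 seed = as.integer(seed)),
            class = "case_study_config")
}

#' Preset configurations for the two case-study schemas
#'
#' \code{config_cs1()}: organic compounds with descriptors total dipole
#' moment (mu), most negative atomic charge (delta_min), and solvent
#' accessible surface area (SASA). \code{config_cs2()}: synthetic peptides
#' with descriptors logSum_AA (log sum of amino-acid gradient retention
#' times), clogP, and log van der Waals volume.
#'
#' @param ... overrides passed on to \code{\link{case_study_config}}.
#' @return A \code{case_study_config}.
#' @export
config_cs1 <- function(...)
  case_study_config(c("mu", "delta_min", "SASA"), ...)

#' @rdname config_cs1
#' @export
config_cs2 <- function(...)
  case_study_config(c("logSum_AA", "clogP", "log_vdW_vol"), ...)

#' Validate a configuration, warning about non-default variants
#'
#' Returns a character vector of warnings (empty for the defaults): the
#' literal signed-mean error form, the squared SRD mode, and the
#' conventional critical-leverage formula each deviate from the package's
#' default reading and are flagged for auditability.
#'
#' @param config a \code{case_study_config}.
#' @return character vector of warnings (possibly empty).
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "case_study_config"))
  w <- character(0)
  if (config$rmse_variant == "literal_eq6")
    w <- c(w, paste("rmse_variant=literal_eq6: the printed error formula is a",
                    "signed mean relative error with no squaring or square",
                    "root; it can be negative and is kept for auditing only"))
  if (config$srd_mode == "squared")
    w <- c(w, "srd_mode=squared: CRNN reference statistics assume absolute (footrule) mode")
  if (config$leverage_formula == "conventional_k_plus_1")
    w <- c(w, "leverage_formula=conventional_k_plus_1: h* = 3(K+1)/N with K predictors")
  w
}
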