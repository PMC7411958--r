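#' Non-dominated (Pareto) filter for a two-objective point set
#'
#' A point dominates another if it is no worse in both objectives and
#' strictly better in at least one. Returns the indices of the non-dominated
#' points in their original order; exact duplicates in objective space
#' collapse to the first occurrence.
#'
#' @param f1,f2 numeric objective vectors (minimized), equal length, finite.
#' @return Integer indices of the non-dominated subset.
#' @export
pareto_filter <- function(f1, f2) {
  stopifnot(length(f1) == length(f2))
  n <- length(f1)
  if (n == 0) return(integer(0))
  if (!all(is.finite(f1)) || !all(is.finite(f2)))
    stop("objective values must be finite")
  dup <- duplicated(cbind(f1, f2))
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (dup[i]) next
    dominated <- any(f1 <= f1[i] & f2 <= f2[i] & (f1 < f1[i] | f2 < f2[i]))
    keep[i] <- !dominated
  }
  which(keep)
}

# ---- NSGA-II internals ----------------------------------------------------

# front number per point (1 = non-dominated), O(n^2) via dominance counts
nondominated_rank <- function(f1, f2) {
  n <- length(f1)
  dom <- outer(f1, f1, "<=") & outer(f2, f2, "<=") &
    (outer(f1, f1, "<") | outer(f2, f2, "<"))      # dom[i,j]: i dominates j
  n_dominators <- colSums(dom)
  rank <- integer(n)
  front <- 1L
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    current <- remaining & n_dominators == 0L
    if (!any(current)) { rank[remaining] <- front; break }  # safety net
    rank[current] <- front
    remaining[current] <- FALSE
    n_dominators <- n_dominators - colSums(dom[current, , drop = FALSE])
    front <- front + 1L
  }
  rank
}

crowding_distance <- function(f1, f2, rank) {
  n <- length(f1)
  cd <- numeric(n)
  for (fr in unique(rank)) {
    idx <- which(rank == fr)
    if (length(idx) <= 2) { cd[idx] <- Inf; next }
    for (f in list(f1, f2)) {
      o <- idx[order(f[idx])]
      rng <- f[o[length(o)]] - f[o[1]]
      cd[o[1]] <- cd[o[length(o)]] <- Inf
      if (rng > 0)
        cd[o[2:(length(o) - 1)]] <- cd[o[2:(length(o) - 1)]] +
          (f[o[3:length(o)]] - f[o[1:(length(o) - 2)]]) / rng
    }
  }
  cd
}

# binary tournament: lower front rank wins, ties by larger crowding distance
tournament_select <- function(rank, cd, n_pick) {
  n <- length(rank)
  a <- sample.int(n, n_pick, replace = TRUE)
  b <- sample.int(n, n_pick, replace = TRUE)
  pick_a <- rank[a] < rank[b] | (rank[a] == rank[b] & cd[a] >= cd[b])
  ifelse(pick_a, a, b)
}

# simulated binary crossover (SBX), bounded, eta_c distribution index
sbx_crossover <- function(p1, p2, lower, upper, prob, eta_c = 15) {
  d <- length(p1)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= prob) {
    do_gene <- stats::runif(d) <= 0.5
    u <- stats::runif(d)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta_c + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta_c + 1)))
    ch1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
    ch2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
    c1[do_gene] <- ch1[do_gene]
    c2[do_gene] <- ch2[do_gene]
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

# polynomial mutation, bounded, eta_m distribution index
poly_mutation <- function(p, lower, upper, prob, eta_m = 20) {
  d <- length(p)
  do_gene <- stats::runif(d) <= prob
  if (!any(do_gene)) return(p)
  u <- stats::runif(d)
  span <- upper - lower
  delta <- ifelse(u < 0.5,
                  (2 * u)^(1 / (eta_m + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta_m + 1)))
  p[do_gene] <- p[do_gene] + delta[do_gene] * span[do_gene]
  pmin(pmax(p, lower), upper)
}

# evaluate a coefficient population (rows) on the training subset; vectorized
evaluate_population <- function(A, Xd, t_obs, r_obs, variant) {
  That <- Xd %*% t(A)                         # n x pop
  rel <- (That - t_obs) / t_obs
  if (variant == "relative_rmse") {
    f1 <- 100 * sqrt(colMeans(rel^2))
  } else {
    f1 <- 100 * colMeans(rel)
  }
  f2 <- apply(That, 2, function(th) {
    rp <- rank(th, ties.method = "first")
    rr <- (rp - r_obs) / r_obs
    if (variant == "relative_rmse") 100 * sqrt(mean(rr^2)) else 100 * mean(rr)
  })
  bad <- !is.finite(f1) | !is.finite(f2)      # worst rank for broken individuals
  f1[bad] <- 1e18; f2[bad] <- 1e18
  cbind(f1 = f1, f2 = f2)
}

#' Re-optimize QSRR coefficients by a multi-objective genetic algorithm
#'
#' Runs an elitist non-dominated-sorting GA (NSGA-II-style ranking and
#' crowding, simulated-binary crossover, polynomial mutation) over the
#' coefficient vector (alpha0..alphaK), minimizing simultaneously the
#' percent RMSE of retention time (f1) and of elution order (f2) on the
#' training rows. The MLR coefficients seed the initial population (the
#' remaining individuals are Gaussian perturbations around them), so with
#' elitism the returned front can never be worse than the control in either
#' objective. The search box is \code{alpha_k +/- 10 * init_spread *
#' max(|alpha_k|, 1e-3)} around the start.
#'
#' @param table an \code{\link{analyte_table}}.
#' @param train training row indices; objectives are evaluated on these only.
#' @param init the control \code{\link{qsrr_model}} (MLR fit on \code{train}).
#' @param params \code{\link{ga_params}}.
#' @param variant error-metric variant (see \code{\link{percent_rmse_tr}}).
#' @return A \code{pareto_front}: coefficient matrix \code{coefficients}
#'   (one row per solution, columns \code{(Intercept)}, descriptors), vectors
#'   \code{f1}, \code{f2} sorted ascending by f1, \code{knee_index},
#'   \code{selected_index} (NA until \code{\link{select_solution}}),
#'   \code{control} (objective pair of \code{init}) and \code{control_model}.
#' @export
optimize_moo <- function(table, train, init, params = ga_params(),
                         variant = "relative_rmse") {
  stopifnot(inherits(table, "analyte_table"), inherits(init, "qsrr_model"),
            inherits(params, "ga_params"))
  train <- as.integer(train)
  Xd <- cbind(1, table$X[train, init$descriptor_names, drop = FALSE])
  t_obs <- table$t_obs[train]
  r_obs <- elution_ranks(t_obs)
  alpha0 <- c(init$intercept, init$coefficients)
  d <- length(alpha0)
  pop <- params$population_size
  pm <- if (is.na(params$mutation_prob)) 1 / d else params$mutation_prob
  scale <- params$init_spread * pmax(abs(alpha0), 1e-3)
  lower <- alpha0 - 10 * scale
  upper <- alpha0 + 10 * scale

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  A <- matrix(rep(alpha0, each = pop), nrow = pop)
  A[-1, ] <- A[-1, , drop = FALSE] +
    matrix(stats::rnorm((pop - 1) * d), ncol = d) * rep(scale, each = pop - 1)
  A <- pmin(pmax(A, rep(lower, each = pop)), rep(upper, each = pop))
  Fv <- evaluate_population(A, Xd, t_obs, r_obs, variant)
  if (all(Fv[, 1] >= 1e18)) stop("all initial individuals infeasible")

  for (gen in seq_len(params$generations)) {
    rk <- nondominated_rank(Fv[, 1], Fv[, 2])
    cd <- crowding_distance(Fv[, 1], Fv[, 2], rk)
    parents <- tournament_select(rk, cd, pop)
    Off <- matrix(0, nrow = pop, ncol = d)
    for (i in seq(1, pop, by = 2)) {
      ch <- sbx_crossover(A[parents[i], ], A[parents[i + 1], ],
                          lower, upper, params$crossover_prob)
      Off[i, ] <- poly_mutation(ch[[1]], lower, upper, pm)
      Off[i + 1, ] <- poly_mutation(ch[[2]], lower, upper, pm)
    }
    Fo <- evaluate_population(Off, Xd, t_obs, r_obs, variant)
    # elitist environmental selection on the combined population
    Ac <- rbind(A, Off); Fc <- rbind(Fv, Fo)
    rk <- nondominated_rank(Fc[, 1], Fc[, 2])
    cd <- crowding_distance(Fc[, 1], Fc[, 2], rk)
    keep <- order(rk, -cd)[seq_len(pop)]
    A <- Ac[keep, , drop = FALSE]
    Fv <- Fc[keep, , drop = FALSE]
  }

  nd <- pareto_filter(Fv[, 1], Fv[, 2])
  o <- nd[order(Fv[nd, 1], Fv[nd, 2])]
  coefs <- A[o, , drop = FALSE]
  colnames(coefs) <- c("(Intercept)", init$descriptor_names)
  ctrl <- evaluate_model(init, table, train, variant)
  front <- structure(list(coefficients = coefs,
                          f1 = unname(Fv[o, 1]), f2 = unname(Fv[o, 2]),
                          knee_index = NA_integer_,
                          selected_index = NA_integer_,
                          control = ctrl, control_model = init),
                     class = "pareto_front")
  front$knee_index <- knee_point(front)
  front
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d solutions; control (f1, f2) = (%.3f, %.3f)\n",
              length(x$f1), x$control[1], x$control[2]))
  cat(sprintf("  f1 range %.3f-%.3f, f2 range %.3f-%.3f; knee = %s, selected = %s\n",
              min(x$f1), max(x$f1), min(x$f2), max(x$f2),
              x$knee_index, x$selected_index))
  invisible(x)
}

#' Knee point of a Pareto front
#'
#' Objectives are min-max normalized to [0, 1] over the front; the knee is
#' the solution closest (Euclidean) to the normalized ideal point (0, 0).
#' Ties break toward lower f1. A single-point front returns index 1.
#'
#' @param front a \code{pareto_front}, or a list with \code{f1}, \code{f2}.
#' @return Integer index into the front's solutions.
#' @export
knee_point <- function(front) {
  f1 <- front$f1; f2 <- front$f2
  if (length(f1) == 0) stop("empty front")
  norm01 <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  d <- sqrt(norm01(f1)^2 + norm01(f2)^2)
  order(d, f1)[1]
}

#' Select a Pareto solution under a retention-error budget
#'
#' Feasible solutions are those whose f1 exceeds the control's f1 by at most
#' \code{max_tr_loss_percent} percent (relative); among them the one with
#' minimum f2 is returned (ties toward lower f1). If no solution is
#' feasible, the solution with minimum f1 is returned as fallback.
#'
#' @param front a \code{pareto_front} with \code{control} set.
#' @param max_tr_loss_percent allowed relative increase of f1 over the
#'   control, percent (>= 0).
#' @return The front with \code{selected_index} filled in.
#' @export
select_solution <- function(front, max_tr_loss_percent = 10) {
  stopifnot(inherits(front, "pareto_front"), length(front$f1) >= 1)
  c1 <- front$control[["f1"]]
  loss <- 100 * (front$f1 - c1) / c1
  feasible <- which(loss <= max_tr_loss_percent)
  front$selected_index <- if (length(feasible) > 0) {
    feasible[order(front$f2[feasible], front$f1[feasible])[1]]
  } else {
    which.min(front$f1)
  }
  front
}

#' Extract a front solution as a qsrr_model
#'
#' @param front a \code{pareto_front}.
#' @param index solution index (defaults to the selected one, else the knee).
#' @return A \code{\link{qsrr_model}}.
#' @export
front_model <- function(front, index = NULL) {
  stopifnot(inherits(front, "pareto_front"))
  if (is.null(index))
    index <- if (!is.na(front$selected_index)) front$selected_index
             else front$knee_index
  cf <- front$coefficients[index, ]
  qsrr_model(intercept = unname(cf[1]), coefficients = cf[-1],
             descriptor_names = names(cf)[-1],
             n_train = front$control_model$n_train)
}

#' Relative change of the selected solution versus the control
#'
#' Component-wise \code{100 * (selected - control) / control} for the
#' objective pair; a negative second component means the elution-order error
#' decreased.
#'
#' @param control,selected numeric objective pairs \code{(f1, f2)}, control
#'   components strictly positive.
#' @return Named vector \code{c(delta_f1 = , delta_f2 = )}, percent.
#' @export
compare_to_control <- function(control, selected) {
  control <- as.numeric(control); selected <- as.numeric(selected)
  if (any(control == 0)) stop("control objectives must be non-zero")
  d <- 100 * (selected - control) / control
  c(delta_f1 = d[1], delta_f2 = d[2])
}

#' Export a Pareto front as a data frame / CSV
#'
#' @param front a \code{pareto_front}.
#' @param path optional CSV destination; when given the frame is written.
#' @return Data frame with \code{solution_index}, \code{f1}, \code{f2},
#'   \code{is_knee}, \code{is_selected} and the coefficient columns.
#' @export
front_as_df <- function(front, path = NULL) {
  stopifnot(inherits(front, "pareto_front"))
  df <- data.frame(solution_index = seq_along(front$f1),
                   f1 = front$f1, f2 = front$f2,
                   is_knee = seq_along(front$f1) == front$knee_index,
                   is_selected = !is.na(front$selected_index) &
                     seq_along(front$f1) == front$selected_index)
  df <- cbind(df, as.data.frame(front$coefficients, check.names = FALSE))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
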