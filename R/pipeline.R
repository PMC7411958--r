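#' Run the full elution-order workflow on one analyte table
#'
#' Kennard-Stone split, MLR control fit, multi-objective coefficient
#' re-optimization on the training rows, knee-point detection and bounded
#' solution selection, Williams-plot applicability-domain report, and the
#' SRD comparison of the control and MOO orderings against the experimental
#' elution order (with CRNN validation).
#'
#' @param table an \code{\link{analyte_table}}.
#' @param config a \code{\link{case_study_config}}; its \code{seed} drives
#'   the GA and the CRNN draws.
#' @param crnn_draws Monte-Carlo draws for the CRNN validation.
#' @return A \code{run_summary} list: \code{config}, \code{split},
#'   \code{control_model}, \code{control_metrics} (train/test/all rows of
#'   f1, f2), \code{front}, \code{selected_model},
#'   \code{selected_metrics}, \code{delta} (relative change vs control on
#'   the training objectives), \code{ad}, \code{srd}, \code{seed},
#'   \code{version}.
#' @export
run_pipeline <- function(table, config, crnn_draws = 20000) {
  stopifnot(inherits(table, "analyte_table"),
            inherits(config, "case_study_config"))
  for (w in validate_config(config)) warning(w)
  split <- kennard_stone_split(table, config$split_ratio)
  tr <- split$train_indices; te <- split$test_indices
  control <- fit_mlr(table, tr)
  metrics_on <- function(model) rbind(
    train = evaluate_model(model, table, tr, config$rmse_variant),
    test = evaluate_model(model, table, te, config$rmse_variant),
    all = evaluate_model(model, table, seq_len(table$n), config$rmse_variant))
  control_metrics <- metrics_on(control)

  ga <- config$ga
  ga$seed <- config$seed
  front <- optimize_moo(table, tr, control, ga, config$rmse_variant)
  front <- select_solution(front, config$max_tr_loss_percent)
  selected <- front_model(front)
  selected_metrics <- metrics_on(selected)
  sel_obj <- c(front$f1[front$selected_index], front$f2[front$selected_index])
  delta <- if (all(front$control > 0)) {
    compare_to_control(front$control, sel_obj)
  } else {
    c(delta_f1 = NA_real_, delta_f2 = NA_real_)  # perfect control: undefined
  }

  ad <- williams_report(control, table, split, config$leverage_formula)

  ref <- elution_ranks(table$t_obs)
  crnn <- crnn_distribution(table$n, n_draws = crnn_draws,
                            seed = config$seed + 1L, mode = config$srd_mode)
  srd <- rank_models(list(MLR = elution_ranks(predict(control, table)),
                          `MLR-MOO` = elution_ranks(predict(selected, table))),
                     ref, mode = config$srd_mode, crnn = crnn)

  structure(list(config = config, split = split,
                 control_model = control, control_metrics = control_metrics,
                 front = front, selected_model = selected,
                 selected_metrics = selected_metrics, delta = delta,
                 ad = ad, srd = srd, seed = config$seed,
                 version = as.character(utils::packageVersion("qsrrmoo"))),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("== qsrrmoo run summary ==\n")
  cat(sprintf("n = %d (%d train / %d test), seed = %d\n",
              nrow(x$ad$analytes), length(x$split$train_indices),
              length(x$split$test_indices), x$seed))
  cat("control (MLR) %RMSE [f1 = tR, f2 = order]:\n")
  print(round(x$control_metrics, 3))
  cat("selected MOO solution %RMSE:\n")
  print(round(x$selected_metrics, 3))
  cat(sprintf("train-set change vs control: delta f1 = %+.2f%%, delta f2 = %+.2f%%\n",
              x$delta[1], x$delta[2]))
  cat(sprintf("applicability domain: h* = %.4f; flags: %s\n", x$ad$h_star,
              paste(names(x$ad$counts), as.integer(x$ad$counts),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# ---- command-line front end ----------------------------------------------

#' Command-line entry point
#'
#' Thin shell over the package functions, used by the
#' \code{inst/exec/qsrrmoo} Rscript. Subcommands: \code{simulate}
#' (write a synthetic table), \code{fit} (split + MLR + control metrics),
#' \code{moo} (full pipeline, front + summary files), \code{ad}
#' (Williams report), \code{srd} (SRD of stored orders vs reference).
#' Flags are \code{--key value} pairs.
#'
#' @param args character vector, e.g. \code{c("simulate", "--preset", "cs1",
#'   "--out", "data.csv", "--seed", "7")}.
#' @return Invisibly, the result object of the subcommand (also written to
#'   the requested files). Errors propagate as R conditions; the Rscript
#'   wrapper maps them to a nonzero exit status.
#' @export
qsrr_cli <- function(args) {
  if (length(args) < 1)
    stop("usage: qsrrmoo <simulate|fit|moo|ad|srd> [--key value ...]")
  cmd <- args[1]
  opt <- parse_flags(args[-1])
  get_opt <- function(key, default = NULL) {
    if (!is.null(opt[[key]])) opt[[key]] else default
  }
  seed <- as.integer(get_opt("seed", 1L))
  preset <- get_opt("preset", "cs1")
  config <- make_config(preset, seed,
                        split = as.numeric(get_opt("split", 0.70)),
                        bound = as.numeric(get_opt("bound", 10)))

  switch(cmd,
    simulate = {
      spec <- switch(preset, cs1 = preset_cs1_like(seed),
                     cs2 = preset_cs2_like(seed),
                     stop(sprintf("unknown preset: %s", preset)))
      gen <- generate_linear_dataset(spec)
      out <- get_opt("out", stop("simulate needs --out"))
      write_analyte_table(gen$table, out, config)
      message(sprintf("wrote %d analytes to %s", gen$table$n, out))
      invisible(gen$table)
    },
    fit = {
      table <- read_analyte_table(get_opt("data", stop("fit needs --data")), config)
      split <- kennard_stone_split(table, config$split_ratio)
      model <- fit_mlr(table, split$train_indices)
      m <- rbind(train = evaluate_model(model, table, split$train_indices),
                 test = evaluate_model(model, table, split$test_indices),
                 all = evaluate_model(model, table))
      out <- get_opt("out")
      if (!is.null(out))
        utils::write.csv(data.frame(set = rownames(m), m, row.names = NULL),
                         out, row.names = FALSE)
      print(model); print(round(m, 3))
      invisible(list(model = model, split = split, metrics = m))
    },
    moo = {
      table <- read_analyte_table(get_opt("data", stop("moo needs --data")), config)
      summary <- run_pipeline(table, config)
      out <- get_opt("out")
      if (!is.null(out)) {
        front_as_df(summary$front, paste0(out, "_front.csv"))
        utils::write.csv(summary$ad$analytes, paste0(out, "_ad.csv"),
                         row.names = FALSE)
        utils::write.csv(summary$srd$models, paste0(out, "_srd.csv"),
                         row.names = FALSE)
      }
      print(summary)
      invisible(summary)
    },
    ad = {
      table <- read_analyte_table(get_opt("data", stop("ad needs --data")), config)
      split <- kennard_stone_split(table, config$split_ratio)
      model <- fit_mlr(table, split$train_indices)
      rep <- williams_report(model, table, split, config$leverage_formula)
      out <- get_opt("out")
      if (!is.null(out))
        utils::write.csv(rep$analytes, out, row.names = FALSE)
      print(rep)
      invisible(rep)
    },
    srd = {
      orders <- utils::read.csv(get_opt("orders", stop("srd needs --orders")))
      ref <- orders[[1]]
      preds <- as.list(orders[-1])
      crnn <- crnn_distribution(length(ref),
                                n_draws = as.integer(get_opt("draws", 20000)),
                                seed = seed, mode = config$srd_mode)
      rep <- rank_models(preds, ref, mode = config$srd_mode, crnn = crnn)
      out <- get_opt("out")
      if (!is.null(out))
        utils::write.csv(rep$models, out, row.names = FALSE)
      print(rep)
      invisible(rep)
    },
    stop(sprintf("unknown subcommand: %s", cmd))
  )
}

parse_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop(sprintf("expected --flag, got: %s", args[i]))
    if (i + 1L > length(args)) stop(sprintf("flag %s needs a value", args[i]))
    opt[[substring(args[i], 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}

make_config <- function(preset, seed, split = 0.70, bound = 10) {
  base <- switch(preset, cs1 = config_cs1, cs2 = config_cs2,
                 stop(sprintf("unknown preset: %s", preset)))
  base(split_ratio = split, max_tr_loss_percent = bound, seed = seed)
}
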