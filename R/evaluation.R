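# Reported metrics: per-client MAE, the sample-size-weighted overall MAE
# across clients, Pearson correlations with t-distribution p-values, and the
# brain-age-difference (BAD) bias diagnostic.

#' Mean absolute error
#'
#' @param truth Numeric vector of true values.
#' @param predicted Numeric vector of predictions (same length).
#' @return Mean of `|truth - predicted|`.
#' @export
mae <- function(truth, predicted) {
  if (length(truth) < 1L || length(truth) != length(predicted))
    stop_fedbids("need equal-length, non-empty truth and prediction vectors",
                 "fedbids_input_error")
  mean(abs(truth - predicted))
}

#' Sample-size-weighted overall MAE across clients
#'
#' Combines per-client test MAEs into the overall figure
#' `sum_i MAE_i * n_i / N`, `N = sum_i n_i` — the weighting used when test
#' sets cannot be pooled across clients.
#'
#' @param client_mae Numeric vector of per-client MAEs.
#' @param n Integer vector of per-client test sample sizes.
#' @return The weighted overall MAE.
#' @export
overall_mae <- function(client_mae, n) {
  if (length(client_mae) < 1L || length(client_mae) != length(n))
    stop_fedbids("client_mae and n must be non-empty and equal length",
                 "fedbids_input_error")
  if (any(n <= 0))
    stop_fedbids("client sample sizes must be positive", "fedbids_input_error")
  sum(client_mae * n) / sum(n)
}

#' Pearson correlation with two-sided t-test p-value
#'
#' Thin wrapper around [stats::cor.test()]; correlations that are undefined
#' because a margin is constant surface as a flagged result (`defined` is
#' `FALSE` and the correlation is `NA`), never as a silent zero.
#'
#' @param x,y Numeric vectors (length >= 3).
#' @return List with `r`, `p`, `n`, `defined`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_fedbids("pearson needs at least 3 paired observations",
                 "fedbids_input_error")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Brain-age-difference bias diagnostic
#'
#' The brain-age difference (BAD) is predicted age minus calendar age; its
#' Pearson correlation with calendar age diagnoses the regression-to-the-mean
#' bias of age-prediction models (typically negative: young brains are
#' overestimated, old brains underestimated). No bias correction is applied —
#' this is a diagnostic only.
#'
#' @param calendar_age Numeric vector of true ages.
#' @param predicted_age Numeric vector of predicted ("brain") ages.
#' @return List with `bad` (the difference vector), `r`, `p`, `defined`.
#' @export
bad_diagnostics <- function(calendar_age, predicted_age) {
  if (length(calendar_age) != length(predicted_age) ||
      length(calendar_age) < 3L)
    stop_fedbids("bad_diagnostics needs at least 3 paired observations",
                 "fedbids_input_error")
  bad <- predicted_age - calendar_age
  if (sd(bad) == 0 || sd(calendar_age) == 0)
    return(list(bad = bad, r = NA_real_, p = NA_real_, defined = FALSE))
  pr <- pearson(calendar_age, bad)
  list(bad = bad, r = pr$r, p = pr$p, defined = pr$defined)
}

#' Evaluate per-client prediction pairs
#'
#' @param pairs A data.frame with columns `truth` and `predicted` (e.g. from
#'   [evaluate_on_test()]).
#' @param client_name Label attached to the result.
#' @param bad Whether to add the BAD bias diagnostic (brain-age runs).
#' @return A one-row data.frame of class `evaluation_result`: `client_name`,
#'   `n_test`, `mae`, `pearson_r`, `pearson_p`, and `bad_r`/`bad_p` when
#'   requested (NA when undefined).
#' @export
evaluate_predictions <- function(pairs, client_name = "client",
                                 bad = FALSE) {
  stopifnot(all(c("truth", "predicted") %in% names(pairs)))
  pr <- if (nrow(pairs) >= 3L) pearson(pairs$truth, pairs$predicted)
        else list(r = NA_real_, p = NA_real_, defined = FALSE)
  out <- data.frame(client_name = client_name, n_test = nrow(pairs),
                    mae = mae(pairs$truth, pairs$predicted),
                    pearson_r = pr$r, pearson_p = pr$p,
                    stringsAsFactors = FALSE)
  if (bad) {
    bd <- if (nrow(pairs) >= 3L)
      bad_diagnostics(pairs$truth, pairs$predicted)
    else list(r = NA_real_, p = NA_real_)
    out$bad_r <- bd$r
    out$bad_p <- bd$p
  }
  class(out) <- c("evaluation_result", "data.frame")
  out
}

#' Write the evaluation report
#'
#' Emits a tab-separated metrics table (one row per client plus an `overall`
#' row combining them with the sample-size weighting), a JSON summary, the
#' per-round loss-curve data (mean validation MAE and 95% CI across
#' bootstraps) and per-client scatter data, all as plain text. PNG figures
#' are rendered when `plots = TRUE` and ggplot2 is installed.
#'
#' @param results A data.frame of per-client evaluation rows
#'   (rbind of [evaluate_predictions()] outputs).
#' @param history An `fl_history` from [run_federation()], or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param scatter Optional data.frame with `client_name`, `truth`,
#'   `predicted` for scatter files.
#' @param plots Render PNG figures (requires ggplot2).
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(results, history = NULL, out_dir, scatter = NULL,
                        plots = FALSE) {
  if (nrow(results) < 1L)
    stop_fedbids("no evaluation results to report", "fedbids_input_error")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_fedbids(sprintf("cannot create report directory '%s'", out_dir),
                 "fedbids_io_error")
  ov <- overall_mae(results$mae, results$n_test)
  tab <- results
  tab$mae <- round(tab$mae, 6)
  overall_row <- tab[1, , drop = FALSE]
  overall_row[1, ] <- NA
  overall_row$client_name <- "overall"
  overall_row$n_test <- sum(results$n_test)
  overall_row$mae <- round(ov, 6)
  tab <- rbind(tab, overall_row)
  paths <- character(0)
  mt <- file.path(out_dir, "metrics.tsv")
  write.table(tab, mt, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, mt)
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(overall_mae = ov,
         clients = results,
         n_rounds = if (!is.null(history)) nrow(history$rounds) else NULL),
    js, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  paths <- c(paths, js)
  if (!is.null(history)) {
    ht <- file.path(out_dir, "round_history.tsv")
    write.table(history$per_client, ht, sep = "\t", quote = FALSE,
                row.names = FALSE)
    st <- file.path(out_dir, "round_summary.tsv")
    write.table(history$rounds, st, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, ht, st)
  }
  if (!is.null(scatter)) {
    sc <- file.path(out_dir, "scatter.tsv")
    write.table(scatter, sc, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, sc)
  }
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    if (!is.null(history)) {
      p <- plot_history(history)
      f <- file.path(out_dir, "validation_mae.png")
      ggplot2::ggsave(f, p, width = 7, height = 4, dpi = 120)
      paths <- c(paths, f)
    }
    if (!is.null(scatter)) {
      p <- plot_predictions(scatter)
      f <- file.path(out_dir, "predictions.png")
      ggplot2::ggsave(f, p, width = 8, height = 3.5, dpi = 120)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Plot the per-round validation-MAE curves
#'
#' @param history An `fl_history` object.
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_fedbids("ggplot2 is required for plotting", "fedbids_input_error")
  pc <- history$per_client
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$round, y = .data$val_mae_mean,
                                   colour = .data$client)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$val_mae_ci_lo,
                                      ymax = .data$val_mae_ci_hi,
                                      fill = .data$client),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = history$rounds,
                       ggplot2::aes(x = .data$round, y = .data$avg_val_mae),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::labs(x = "federation round", y = "validation MAE",
                  colour = "client", fill = "client") +
    ggplot2::theme_minimal()
}

#' Plot true-versus-predicted scatter per client
#'
#' @param scatter Data.frame with `client_name`, `truth`, `predicted`.
#' @return A ggplot object.
#' @export
plot_predictions <- function(scatter) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_fedbids("ggplot2 is required for plotting", "fedbids_input_error")
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$truth,
                                        y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~client_name) +
    ggplot2::labs(x = "true value", y = "predicted value") +
    ggplot2::theme_minimal()
}
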