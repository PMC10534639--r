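#' Read a control-point ground-truth file
#'
#' Whitespace-delimited text with four numeric columns per row:
#' `x_src y_src x_tgt y_tgt`, one control point per row; lines starting
#' with `#` are ignored. This is the layout used by fundus registration
#' ground truth (typically 10 points per image pair).
#'
#' @param path file path.
#' @return Object of class `control_points`: data.frame with columns
#'   `x_src`, `y_src`, `x_tgt`, `y_tgt`.
#' @export
read_control_points <- function(path) {
  if (!file.exists(path))
    stopf("control-point file '%s' not found", path,
          class = "fundusreg_io_error")
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lapply(which(keep), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 4L || anyNA(f))
      stopf("malformed control-point row at line %d of '%s'", i, path,
            class = "fundusreg_parse_error")
    f
  })
  if (length(rows) == 0L)
    stopf("no control points in '%s'", path, class = "fundusreg_parse_error")
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("x_src", "y_src", "x_tgt", "y_tgt")
  structure(tab, class = c("control_points", "data.frame"))
}

#' Write control points in the whitespace text format
#' @param cps a `control_points` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_control_points <- function(cps, path) {
  utils::write.table(as.data.frame(cps)[, c("x_src", "y_src", "x_tgt", "y_tgt")],
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Registration error of a fitted transform over control points
#'
#' Mean Euclidean distance, in pixels, between each transformed source
#' control point and its target counterpart.
#'
#' @param model a `transform_model` (source-to-target).
#' @param cps a `control_points` table.
#' @return Scalar mean error in pixels.
#' @export
registration_error <- function(model, cps) {
  if (nrow(cps) == 0L)
    stopf("empty control-point set", class = "fundusreg_bad_input")
  proj <- apply_transform(model, cbind(cps$x_src, cps$y_src))
  mean(sqrt((proj[, 1L] - cps$x_tgt)^2 + (proj[, 2L] - cps$y_tgt)^2))
}

#' Success curve and normalized AUC over error thresholds
#'
#' For integer thresholds t = 0..`max_threshold` px, the success rate is
#' the fraction of pairs whose registration error is at most t (failed
#' registrations enter as `Inf` and never succeed). The AUC is the
#' trapezoidal integral of the rate over [0, `max_threshold`], normalized
#' by `max_threshold` so a method that is exact on every pair scores 1.
#'
#' @param errors numeric vector of per-pair registration errors (`Inf` for
#'   failures).
#' @param max_threshold largest threshold in px; default 25.
#' @return Object of class `success_curve`: list with `thresholds`,
#'   `rates` and `auc`.
#' @export
success_curve <- function(errors, max_threshold = 25L) {
  if (length(errors) == 0L)
    stopf("no errors supplied", class = "fundusreg_bad_input")
  thresholds <- 0:max_threshold
  rates <- vapply(thresholds, function(t) mean(errors <= t), numeric(1))
  auc <- sum((rates[-1L] + rates[-length(rates)]) / 2) / max_threshold
  structure(list(thresholds = thresholds, rates = rates, auc = auc),
            class = "success_curve")
}

#' @export
print.success_curve <- function(x, ...) {
  cat(sprintf("<success_curve> AUC = %.3f, success at %d px = %.1f%%\n",
              x$auc, max(x$thresholds), 100 * x$rates[length(x$rates)]))
  invisible(x)
}

#' Plot a success curve
#' @param x a `success_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.success_curve <- function(x, ...) {
  graphics::plot(x$thresholds, 100 * x$rates, type = "s",
                 xlab = "error threshold (px)",
                 ylab = "successful registrations (%)",
                 ylim = c(0, 100), ...)
  graphics::mtext(sprintf("AUC = %.3f", x$auc), side = 3, line = 0.2,
                  adj = 1, cex = 0.8)
  invisible(x)
}

#' Evaluate a batch of registrations FIRE-style
#'
#' Takes per-pair registration outcomes, computes each pair's control-point
#' error, flags success within the 0--25 px band, and summarises per
#' category (S/P/A-style) and overall: min/max/mean/SD of the errors of
#' successful pairs, successful-registration counts, and the success-curve
#' AUC. Pairs whose registration did not converge are scored as failures at
#' every threshold rather than dropped.
#'
#' @param results list of per-pair entries, each a list with `id`, `model`
#'   (a `transform_model` or `NULL` for failed registrations), `cps`
#'   (a `control_points` table), and optionally `category`; when absent the
#'   category is the first letter of `id`.
#' @param max_threshold success band upper limit in px; default 25.
#' @return List of class `evaluation_batch`: `per_pair` data.frame
#'   (`id`, `category`, `error_px`, `success`), `curves` (named list of
#'   `success_curve`, one per category plus `"overall"`), and `summary`
#'   data.frame with per-category error statistics and AUC.
#' @export
evaluate_batch <- function(results, max_threshold = 25L) {
  if (length(results) == 0L)
    stopf("empty pair list", class = "fundusreg_bad_input")
  per <- do.call(rbind, lapply(results, function(r) {
    err <- if (is.null(r$model)) Inf else registration_error(r$model, r$cps)
    data.frame(id = r$id,
               category = r$category %||% substr(r$id, 1L, 1L),
               error_px = err,
               success = err <= max_threshold)
  }))
  rownames(per) <- NULL
  cats <- unique(per$category)
  curves <- lapply(cats, function(cc)
    success_curve(per$error_px[per$category == cc], max_threshold))
  names(curves) <- cats
  curves$overall <- success_curve(per$error_px, max_threshold)
  summarise <- function(sub, label) {
    ok <- sub$error_px[sub$success]
    data.frame(category = label, n_pairs = nrow(sub),
               successful = sum(sub$success),
               min = if (length(ok)) min(ok) else NA_real_,
               max = if (length(ok)) max(ok) else NA_real_,
               mean = if (length(ok)) mean(ok) else NA_real_,
               sd = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
               auc = if (label == "overall") curves$overall$auc
                     else curves[[label]]$auc)
  }
  summary <- do.call(rbind, c(lapply(cats, function(cc)
    summarise(per[per$category == cc, , drop = FALSE], cc)),
    list(summarise(per, "overall"))))
  rownames(summary) <- NULL
  structure(list(per_pair = per, curves = curves, summary = summary),
            class = "evaluation_batch")
}

#' @export
print.evaluation_batch <- function(x, ...) {
  cat("<evaluation_batch>\n")
  print(x$summary)
  invisible(x)
}

#' Write batch evaluation results as CSV + JSON
#'
#' @param batch an `evaluation_batch`.
#' @param csv_path per-pair CSV path.
#' @param json_path summary JSON path (per-category and overall AUC and
#'   error statistics).
#' @return Invisibly, a list of the two paths.
#' @export
write_evaluation <- function(batch, csv_path, json_path) {
  utils::write.csv(batch$per_pair, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(summary = batch$summary,
         auc = lapply(batch$curves, function(cv) cv$auc)),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(csv = csv_path, json = json_path))
}
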