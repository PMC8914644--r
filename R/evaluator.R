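#' Round a regression output to an integer count
#'
#' Rounds half away from zero, then clips at zero: `Ac = max(0,
#' round_half_away(y_hat))`. Half-away rounding is used (not banker's
#' rounding) so 2.5 becomes 3; negativity of the unbounded regression head
#' is handled here rather than by an output activation.
#'
#' @param y_hat numeric vector of raw predictions (finite).
#' @return Integer vector of non-negative counts.
#' @export
round_prediction <- function(y_hat) {
  if (any(!is.finite(y_hat))) stop("non-finite prediction")
  as.integer(pmax(0, sign(y_hat) * floor(abs(y_hat) + 0.5)))
}

#' Counting accuracy alpha
#'
#' The per-image counting accuracy `alpha = 1 - |Mc - Ac| / Mc`, where `Mc`
#' is the true number of insects and `Ac` the automatically counted number.
#' As written the statistic is undefined for the background class `Mc = 0`;
#' this implementation substitutes the denominator `max(Mc, 1)`, which
#' reduces to exact-match scoring for empty scenes and is continuous with
#' the definition at `Mc = 1`. Alpha can be negative for large errors
#' (e.g. `Mc = 1, Ac = 3` gives -1) and is deliberately not floored.
#'
#' @param Mc true counts (non-negative integers).
#' @param Ac predicted counts (non-negative integers).
#' @return Numeric vector of per-image alpha values, each `<= 1`.
#' @export
count_accuracy <- function(Mc, Ac) {
  if (any(Mc < 0) || any(Ac < 0)) stop("counts must be non-negative")
  if (any(!is.finite(Mc)) || any(!is.finite(Ac))) stop("non-finite count")
  1 - abs(Mc - Ac) / pmax(Mc, 1)
}

#' Evaluate a counting model on a labeled test set
#'
#' Runs the model on every scene of the manifest's test split (or all
#' records if `split = NULL`), rounds predictions to counts, and reports
#' per-class mean alpha, the overall per-image mean alpha, and the
#' exact-match rate.
#'
#' @param model a `trap_count_regressor`, `trap_quantized_regressor`, or a
#'   function `(list of images) -> numeric` (useful as an oracle).
#' @param manifest a `trap_manifest` with ground-truth counts.
#' @param bank sprite bank, if images must be re-rendered.
#' @param split which split to evaluate (default `"test"`).
#' @return An `trap_evaluation` list: `per_class_alpha`, `mean_alpha`,
#'   `exact_match_rate`, `n_per_class`, `per_image` data.frame,
#'   `rounding_rule`, `zero_class_convention`, `model_id`.
#' @export
evaluate_dataset <- function(model, manifest, bank = NULL, split = "test") {
  recs <- manifest$records
  rows <- if (is.null(split)) seq_len(nrow(recs)) else which(recs$split == split)
  if (length(rows) == 0) stop("empty manifest split")
  input_size <- if (is.function(model)) {
    rep(manifest$config$img_size, 2)
  } else {
    model$config$input_size
  }
  x <- load_images(manifest, rows, bank, input_size)
  yhat <- if (is.function(model)) {
    model(lapply(seq_len(dim(x)[3]), function(j) x[, , j]))
  } else {
    predict_count(model, x)
  }
  Mc <- recs$count[rows]
  Ac <- round_prediction(yhat)
  alpha <- count_accuracy(Mc, Ac)
  classes <- 0:manifest$config$max_count
  per_class <- vapply(classes, function(k) mean(alpha[Mc == k]), 1.0)
  names(per_class) <- classes
  structure(list(
    per_class_alpha = per_class,
    mean_alpha = mean(alpha),
    exact_match_rate = mean(Mc == Ac),
    n_per_class = vapply(classes, function(k) sum(Mc == k), 1L),
    per_image = data.frame(filename = recs$filename[rows], Mc = Mc,
                           y_hat = yhat, Ac = Ac, alpha = alpha),
    rounding_rule = "half away from zero, clipped at 0",
    zero_class_convention = "denominator max(Mc, 1)",
    model_id = if (is.function(model)) "oracle" else class(model)[1]),
    class = "trap_evaluation")
}

#' @export
print.trap_evaluation <- function(x, ...) {
  cat("Counting accuracy (alpha = 1 - |Mc - Ac|/Mc, denominator max(Mc,1))\n")
  cat(sprintf("  model: %s; rounding: %s\n", x$model_id, x$rounding_rule))
  cat("  Insects per image   Accuracy (mean alpha)   n\n")
  for (k in names(x$per_class_alpha)) {
    cat(sprintf("  %-19s %-23.3f %d\n", k, x$per_class_alpha[[k]],
                x$n_per_class[[as.integer(k) + 1L]]))
  }
  cat(sprintf("  %-19s %-23.3f %d\n", "Mean", x$mean_alpha, sum(x$n_per_class)))
  cat(sprintf("  Exact-match rate: %.3f\n", x$exact_match_rate))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report a `trap_evaluation`.
#' @param path output `.json` path; per-image results go to a sibling `.csv`.
#' @return Invisibly, `path`.
#' @export
write_evaluation <- function(report, path) {
  out <- unclass(report)
  per_image <- out$per_image
  out$per_image <- NULL
  out$per_class_alpha <- as.list(out$per_class_alpha)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  write.csv(per_image, sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
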