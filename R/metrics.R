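# Classification metrics on the three ordinal risk bands, threshold
# adjustment for false-negative control, and intraclass correlation of
# total scores.

check_class_pair <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  list(truth = risk_factor(truth), predicted = risk_factor(predicted))
}

#' Confusion matrix and ordinal MSE
#'
#' The MSE is the mean squared difference of the ordinal codes (high = 0,
#' medium = 1, low = 2), so an adjacent-band error contributes 1 and a
#' high/low swap contributes 4.
#'
#' @param truth,predicted Risk labels (character or factor).
#' @return List with `confusion` (3x3 matrix, rows = truth, columns =
#'   predicted), `mse`, and `accuracy`.
#' @export
confusion_and_mse <- function(truth, predicted) {
  p <- check_class_pair(truth, predicted)
  cm <- table(truth = p$truth, predicted = p$predicted)
  cm <- unclass(cm)
  mse <- mean((risk_code(p$truth) - risk_code(p$predicted))^2)
  list(confusion = cm, mse = mse,
       accuracy = mean(as.character(p$truth) == as.character(p$predicted)))
}

#' Support-weighted precision, recall, and F1
#'
#' Per-class precision/recall/F1 averaged with weights proportional to the
#' class support in `truth`.  A class with no predictions contributes
#' precision 0; a class with no support is dropped from the average.
#'
#' @param truth,predicted Risk labels.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
weighted_prf <- function(truth, predicted) {
  p <- check_class_pair(truth, predicted)
  lev <- risk_levels()
  support <- vapply(lev, function(cl) sum(p$truth == cl), numeric(1))
  prec <- rec <- f1 <- numeric(length(lev))
  for (i in seq_along(lev)) {
    cl <- lev[i]
    tp <- sum(p$truth == cl & p$predicted == cl)
    fp <- sum(p$truth != cl & p$predicted == cl)
    fn <- sum(p$truth == cl & p$predicted != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  w <- support / sum(support)
  c(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

#' Threshold-adjusted predictions for false-negative control
#'
#' Given per-subject, per-class scores (e.g. one-vs-one SVM vote fractions
#' or ensemble vote shares), predicts the highest-risk class whose
#' normalized score reaches `tau`; if none does, falls back to the modal
#' class.  Lowering `tau` can only move predictions toward higher risk, so
#' the count of high-risk calls (and hence missed high-risk subjects) is
#' monotone in `tau`.
#'
#' @param scores n x 3 matrix of non-negative per-class scores, columns
#'   named `high`, `medium`, `low` (any order).
#' @param tau Threshold in [0, 1].
#' @return Factor of predicted risk labels.
#' @export
adjust_thresholds <- function(scores, tau) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores) || !all(risk_levels() %in% colnames(scores))) {
    stop("scores must be a matrix with columns high, medium, low", call. = FALSE)
  }
  if (any(scores < 0) || anyNA(scores)) {
    stop("scores must be non-negative and complete", call. = FALSE)
  }
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  scores <- scores[, risk_levels(), drop = FALSE]
  rs <- rowSums(scores)
  if (any(rs == 0)) stop("each subject needs a positive total score", call. = FALSE)
  norm <- scores / rs
  out <- character(nrow(norm))
  for (i in seq_len(nrow(norm))) {
    hit <- which(norm[i, ] >= tau)  # columns ordered by decreasing risk
    out[i] <- if (length(hit) > 0L) risk_levels()[hit[1L]] else
      risk_levels()[which.max(norm[i, ])]
  }
  risk_factor(out)
}

#' Intraclass correlation of total scores, two-way mixed, single measure
#'
#' Consistency form: ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE) from the
#' two-way (subject x rater) mean squares; the absolute-agreement variant
#' adds the rater mean square to the denominator.
#'
#' @param table Numeric matrix / data frame of total scores, subjects in
#'   rows, raters in columns.
#' @param pair Two column names or indices selecting the rater pair
#'   (default: the first two columns).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return ICC estimate in [-1, 1].
#' @export
icc_3_1 <- function(table, pair = c(1L, 2L), type = c("consistency", "agreement")) {
  type <- match.arg(type)
  table <- as.matrix(table)
  if (length(pair) != 2L) stop("pair must select exactly 2 raters", call. = FALSE)
  m <- table[, pair, drop = FALSE]
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(m)) stop("rater table must be complete", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse <= 0) {
    stop("ICC undefined: no between-subject variance", call. = FALSE)
  }
  if (type == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
}

#' Rater table of total scores
#'
#' Builds the subjects x raters matrix of BBS totals used for inter-rater
#' ICC, including the conservative `min` column (per-subject minimum of two
#' raters) when requested.
#'
#' @param ... Named numeric vectors of total scores (equal length), e.g.
#'   `rater_a = ..., rater_d = ..., ml = ...`.
#' @param include_min Names of two raters to combine into a `min_<a>_<b>`
#'   column, or `NULL`.
#' @return Numeric matrix with one column per rater.
#' @export
rater_table <- function(..., include_min = NULL) {
  cols <- list(...)
  if (length(cols) < 2L) stop("need at least two raters", call. = FALSE)
  n <- unique(lengths(cols))
  if (length(n) != 1L) stop("rater columns must have equal length", call. = FALSE)
  m <- do.call(cbind, cols)
  if (any(m < 0 | m > 56, na.rm = TRUE)) {
    stop("total scores must lie in 0-56", call. = FALSE)
  }
  if (!is.null(include_min)) {
    if (length(include_min) != 2L || !all(include_min %in% colnames(m))) {
      stop("include_min must name two raters", call. = FALSE)
    }
    m <- cbind(m, pmin(m[, include_min[1]], m[, include_min[2]]))
    colnames(m)[ncol(m)] <- paste0("min_", include_min[1], "_", include_min[2])
  }
  m
}
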