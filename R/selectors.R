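# Greedy next-task selectors.
#
# Given the current administered subset CSS and the unused tasks UT, each
# selector scores every candidate T in UT by a weighted count of training
# subjects the augmented predictor {CSS, T} classifies correctly:
#
#   Method 1:  sum_i I(Pred({CSS,T}, x_i) = y_i)
#   Method 2:  ... x I(Conf(CSS, x_i) < CT)
#   Method 3:  ... x d(CSS(x_i), CSS(x_p))        (patient-adaptive)
#   Method 4:  ... x I(y_i = yhat_i),  yhat_i = Pred(AT, x_i)
#
# with similarity kernel d(u, v) = exp(-||u - v||^2 / sigma^2).  Methods 1-2
# are patient-independent (constant task order); 3-4 adapt to the patient's
# scores on the administered tasks.  The sums run over the training subjects
# with no missing score on {CSS, T} (method 4 additionally requires the
# all-task prediction, hence completeness on the whole battery).

#' Selector configuration
#'
#' @param method Selector method, 1-4.
#' @param ct Confidence threshold CT in (0, 1]; also the early-stopping
#'   threshold of a session using this selector.
#' @param sigma2 Similarity-kernel width for methods 3-4: a positive number,
#'   or `"auto"` (median pairwise squared distance of the training
#'   restrictions to CSS, recomputed each step, floored at 1e-6).
#' @return A `selector_config` list.
#' @export
selector_config <- function(method = 1L, ct = 0.96, sigma2 = "auto") {
  method <- as.integer(method)
  if (!method %in% 1:4) stop("method must be 1, 2, 3, or 4", call. = FALSE)
  if (ct <= 0 || ct > 1) stop("ct must lie in (0, 1]", call. = FALSE)
  if (!identical(sigma2, "auto") && (!is.numeric(sigma2) || sigma2 <= 0)) {
    stop("sigma2 must be positive or \"auto\"", call. = FALSE)
  }
  structure(list(method = method, ct = ct, sigma2 = sigma2),
            class = "selector_config")
}

#' Score-vector similarity on a task subset
#'
#' `exp(-||u - v||^2 / sigma2)` over the restrictions of the two vectors to
#' the subset; 1 for identical restrictions (and for the empty subset).
#'
#' @param vi,vp Score vectors complete on `task_ids`.
#' @param task_ids Subset the comparison is restricted to.
#' @param sigma2 Positive kernel width.
#' @param battery A `bbs_battery`.
#' @return Similarity in (0, 1].
#' @export
similarity <- function(vi, vp, task_ids, sigma2, battery = bbs_battery()) {
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("sigma2 must be a positive number", call. = FALSE)
  }
  u <- restrict(vi, task_ids, battery)
  w <- restrict(vp, task_ids, battery)
  exp(-sum((u - w)^2) / sigma2)
}

# Median pairwise squared distance of the training restrictions to css,
# floored; the scale-free default for the similarity kernel.
auto_sigma2 <- function(bank, css) {
  idx <- complete_on(bank$cohort, css)
  m <- bank$scores[idx, task_cols(css), drop = FALSE]
  if (nrow(m) < 2L) return(1)
  d2 <- as.numeric(stats::dist(m))^2
  max(stats::median(d2), 1e-6)
}

#' Choose the next task to administer
#'
#' Evaluates the configured selector objective for every unused task and
#' returns the argmax (ties broken by lowest task number).  If every
#' candidate's objective is annihilated by the weighting (e.g. no training
#' subject below CT), the selector falls back to the Method-1 objective and
#' reports it via a message and the `fallback` attribute.
#'
#' @param bank A `predictor_bank` built on the training cohort.
#' @param css Current administered subset (non-empty for methods 2-4).
#' @param ut Candidate (unused) tasks; non-empty.
#' @param config A `selector_config`.
#' @param patient Patient score vector, complete on `css`; required by
#'   methods 3-4.
#' @return The selected task number (integer), with attributes `objective`
#'   (named vector of candidate objective values) and `fallback` (logical).
#' @export
select_next_task <- function(bank, css, ut, config, patient = NULL) {
  css <- sort(as.integer(css))
  ut <- sort(as.integer(ut))
  if (length(ut) == 0L) stop("no candidate tasks to select from", call. = FALSE)
  if (length(intersect(css, ut)) > 0L) {
    stop("css and ut must be disjoint", call. = FALSE)
  }
  if (config$method >= 3L && is.null(patient)) {
    stop("methods 3-4 require the patient's scores on the administered tasks",
         call. = FALSE)
  }
  w <- selector_weights(bank, css, config, patient)
  obj <- vapply(ut, function(tt) {
    p <- bank_predictor(bank, c(css, tt))
    correct <- p$train_pred == bank$y[p$train_idx]
    sum(correct * w[p$train_idx])
  }, numeric(1))
  names(obj) <- as.character(ut)
  fallback <- FALSE
  if (all(obj == 0) && config$method > 1L) {
    fallback <- TRUE
    message("selector method ", config$method,
            ": all candidate objectives weighted to zero; falling back to method 1")
    obj <- vapply(ut, function(tt) {
      p <- bank_predictor(bank, c(css, tt))
      sum(p$train_pred == bank$y[p$train_idx])
    }, numeric(1))
    names(obj) <- as.character(ut)
  }
  nt <- ut[which.max(obj)]  # which.max takes the first (lowest id) on ties
  structure(as.integer(nt), objective = obj, fallback = fallback)
}

# Per-training-subject weights shared by all candidates at one step:
# I(Conf(CSS, x_i) < CT) (methods 2-4), similarity to the patient on CSS
# (methods 3-4), and I(y_i = Pred(AT, x_i)) (method 4).  Indexed by cohort
# row; NA-free (subjects outside a factor's domain get weight 0).
selector_weights <- function(bank, css, config, patient) {
  n <- nrow(bank$cohort)
  w <- rep(1, n)
  if (config$method == 1L) return(w)
  if (length(css) == 0L) {
    stop("methods 2-4 require a non-empty current subset", call. = FALSE)
  }
  css_pred <- bank_predictor(bank, css)
  below <- rep(0, n)
  below[css_pred$train_idx] <- as.numeric(css_pred$train_conf < config$ct)
  w <- w * below
  if (config$method >= 3L) {
    sigma2 <- if (identical(config$sigma2, "auto")) auto_sigma2(bank, css) else config$sigma2
    xp <- restrict(patient, css, bank$battery)
    sim <- rep(0, n)
    m <- bank$scores[css_pred$train_idx, task_cols(css), drop = FALSE]
    d2 <- rowSums((m - matrix(xp, nrow(m), length(xp), byrow = TRUE))^2)
    sim[css_pred$train_idx] <- exp(-d2 / sigma2)
    w <- w * sim
  }
  if (config$method == 4L) {
    yhat <- bank_yhat(bank)
    agree <- rep(0, n)
    agree[yhat$idx] <- as.numeric(yhat$pred == bank$y[yhat$idx])
    w <- w * agree
  }
  w
}

# Cached all-task predictions Pred(AT, x_i) for the training cohort
# (defined for subjects complete on the whole battery).
bank_yhat <- function(bank) {
  if (!is.null(bank$yhat)) return(bank$yhat)
  at <- bank$battery$task_id
  p <- bank_predictor(bank, at)
  bank$yhat <- list(idx = p$train_idx, pred = p$train_pred)
  bank$yhat
}
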