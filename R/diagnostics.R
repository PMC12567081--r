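# Diagnostic-performance arithmetic: confusion counts, sensitivity /
# specificity / accuracy with half-up rounding to the printed precision,
# accuracy grading, a transparent leave-one-out threshold classifier, and a
# verification harness for published confusion-count tables.

# round half-up to `digits` decimals (base round() is round-half-even)
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x*p + 0.5)/p
}

#' Confusion counts for one marker
#'
#' @param n_tp True positives `N` (experimental group called positive).
#' @param n_fn False negatives `n`; `N + n` must equal the experimental group
#'   size `Q`.
#' @param h_tn True negatives `H` (control group called negative).
#' @param h_fp False positives `h`; `H + h` must equal the control group size
#'   `G`.
#' @return A list of class `confusion_counts` with the six counts
#'   (`q_size = N + n`, `g_size = H + h`).
#' @export
confusion_counts <- function(n_tp, n_fn, h_tn, h_fp) {
  counts <- c(n_tp = n_tp, n_fn = n_fn, h_tn = h_tn, h_fp = h_fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    .stop_jtez("confusion counts must be non-negative integers", "jtez_invalid_argument")
  }
  structure(list(n_tp = n_tp, n_fn = n_fn, q_size = n_tp + n_fn,
                 h_tn = h_tn, h_fp = h_fp, g_size = h_tn + h_fp),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy of confusion counts
#'
#' `Se = 100 N/Q`, `Sp = 100 H/G`, and `Ac = 100 (N + H)/(Q + G)` — the
#' proportion of correct results among all samples, which equals the balanced
#' accuracy `(Se + Sp)/2` when the group sizes match. All three are rounded
#' half-up to one decimal, matching the convention of printed percentages.
#'
#' @param counts A [confusion_counts()].
#' @param marker_id Optional marker label carried into the result.
#' @return A list of class `diagnostic_result` with `se`, `sp`, `ac`
#'   (percentages, 1 decimal), the `grade` label of [accuracy_grade()], the
#'   counts, and `balanced = TRUE` when `Q = G`.
#' @examples
#' se_sp_ac(confusion_counts(24, 2, 23, 3)) # Se 92.3, Sp 88.5, Ac 90.4
#' @export
se_sp_ac <- function(counts, marker_id = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$q_size == 0 || counts$g_size == 0) {
    .stop_jtez("group sizes must be positive", "jtez_invalid_argument")
  }
  se <- .round_half_up(100*counts$n_tp/counts$q_size)
  sp <- .round_half_up(100*counts$h_tn/counts$g_size)
  ac <- .round_half_up(100*(counts$n_tp + counts$h_tn)/(counts$q_size + counts$g_size))
  structure(list(se = se, sp = sp, ac = ac,
                 grade = accuracy_grade(ac),
                 counts = counts,
                 marker_id = marker_id,
                 balanced = counts$q_size == counts$g_size),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("<diagnostic_result>%s Se %.1f%%  Sp %.1f%%  Ac %.1f%%  (%s)\n",
              if (is.na(x$marker_id)) "" else paste0(" ", x$marker_id, ":"),
              x$se, x$sp, x$ac, x$grade))
  invisible(x)
}

#' Grade an accuracy percentage
#'
#' Maps balanced accuracy onto the standard five-level scale. The printed
#' bands (below 80, 81-85, 86-90, 91-95, above 95) leave gaps at their
#' boundaries; this implementation closes them with half-open intervals
#' anchored at 80, 85, 90 and 95: accuracy of at most 80 is unsatisfactory,
#' up to 85 satisfactory, up to 90 good, up to 95 very good, and above 95
#' excellent.
#'
#' @param ac Accuracy percentage in `[0, 100]` (vectorized).
#' @return Character vector of grade labels.
#' @examples
#' accuracy_grade(c(96.2, 94.2, 80)) # excellent, very good, unsatisfactory
#' @export
accuracy_grade <- function(ac) {
  if (any(ac < 0 | ac > 100)) {
    .stop_jtez("accuracy must lie in [0, 100]", "jtez_invalid_argument")
  }
  cut_lab <- c("unsatisfactory", "satisfactory", "good", "very good", "excellent")
  as.character(cut(ac, breaks = c(-Inf, 80, 85, 90, 95, Inf),
                   labels = cut_lab, right = TRUE))
}

# Youden-optimal threshold on training values; ties resolved toward the
# midpoint of the two group means. Returns c(threshold, polarity) with
# polarity +1 when the experimental group lies above the threshold.
.youden_threshold <- function(x_ctrl, x_exp) {
  polarity <- if (mean(x_exp) >= mean(x_ctrl)) 1 else -1
  vals <- sort(unique(c(x_ctrl, x_exp)))
  if (length(vals) == 1L) {
    return(c(threshold = vals[1], polarity = polarity))
  }
  cand <- (vals[-1] + vals[-length(vals)])/2
  j <- vapply(cand, function(th) {
    if (polarity > 0) {
      mean(x_exp > th) + mean(x_ctrl <= th) - 1
    } else {
      mean(x_exp < th) + mean(x_ctrl >= th) - 1
    }
  }, numeric(1))
  best <- which(j == max(j))
  if (length(best) > 1L) {
    mid <- (mean(x_ctrl) + mean(x_exp))/2
    best <- best[which.min(abs(cand[best] - mid))]
  }
  c(threshold = cand[best], polarity = polarity)
}

#' Leave-one-out threshold classification of two marker groups
#'
#' For each held-out sample, the threshold maximizing the Youden index
#' `Se + Sp - 1` on the remaining samples is computed (ties resolved toward
#' the midpoint of the group means, polarity fixed by the group means); the
#' held-out sample is classified by its side of the threshold and the
#' confusion counts accumulate over all folds. Fully deterministic.
#'
#' @param markers_control Numeric marker values of the control group.
#' @param markers_experimental Numeric marker values of the experimental
#'   group.
#' @return A [confusion_counts()]; when the pooled values are all identical a
#'   `jtez_degenerate_separation` warning is emitted and chance-level counts
#'   are still returned.
#' @export
classify_loo <- function(markers_control, markers_experimental) {
  x_c <- as.numeric(markers_control)
  x_e <- as.numeric(markers_experimental)
  if (length(x_c) < 2 || length(x_e) < 2) {
    .stop_jtez("need at least 2 samples per group", "jtez_invalid_argument")
  }
  if (length(unique(c(x_c, x_e))) == 1L) {
    warning("all marker values identical across both groups; separation is degenerate",
            call. = FALSE)
  }
  h_tn <- h_fp <- 0
  for (i in seq_along(x_c)) {
    th <- .youden_threshold(x_c[-i], x_e)
    neg <- if (th["polarity"] > 0) x_c[i] <= th["threshold"] else x_c[i] >= th["threshold"]
    if (neg) h_tn <- h_tn + 1 else h_fp <- h_fp + 1
  }
  n_tp <- n_fn <- 0
  for (i in seq_along(x_e)) {
    th <- .youden_threshold(x_c, x_e[-i])
    pos <- if (th["polarity"] > 0) x_e[i] > th["threshold"] else x_e[i] < th["threshold"]
    if (pos) n_tp <- n_tp + 1 else n_fn <- n_fn + 1
  }
  confusion_counts(n_tp, n_fn, h_tn, h_fp)
}

#' Representativeness of markers across leave-one-out folds
#'
#' Computes, for every marker column, the standard deviation of the group-mean
#' estimate across leave-one-out folds and flags markers whose deviation
#' exceeds the threshold — the sample-size adequacy check used to fix the
#' group size.
#'
#' @param marker_values Numeric vector, or a data frame whose numeric columns
#'   are each checked.
#' @param threshold Maximal admissible fold deviation (default 0.025).
#' @return A tibble with `marker`, `fold_sd` and `pass` (deviation at the
#'   threshold passes).
#' @export
representativeness <- function(marker_values, threshold = 0.025) {
  if (is.data.frame(marker_values)) {
    cols <- names(marker_values)[vapply(marker_values, is.numeric, logical(1))]
    vals <- lapply(cols, function(cc) marker_values[[cc]])
    names(vals) <- cols
  } else {
    vals <- list(marker = as.numeric(marker_values))
  }
  fold_sd <- vapply(vals, function(x) {
    n <- length(x)
    if (n < 3) return(NA_real_)
    means <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
    sd(means)
  }, numeric(1))
  tibble::tibble(marker = names(vals), fold_sd = unname(fold_sd),
                 pass = !is.na(fold_sd) & fold_sd <= threshold)
}

#' Bundled published confusion counts
#'
#' Loads the package's worked-example table of confusion counts for two
#' facies-mapping modalities (matrix theziography, `JT`, and diffuse matrix
#' tomography, `MMT`) across three group comparisons (early-stage detection,
#' later-stage detection, stage differentiation) and four anisotropy
#' parameters, together with the percentages printed alongside them.
#'
#' @return A tibble with columns `method`, `comparison`, `parameter`, `n_tp`,
#'   `n_fn`, `h_tn`, `h_fp`, `se_printed`, `sp_printed`, `ac_printed`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "diagnostic_counts.csv", package = "jtez",
                      mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Recompute metrics from a table of printed confusion counts
#'
#' Applies [se_sp_ac()] and [accuracy_grade()] to every row of a counts table
#' (by default the bundled [reference_counts()]) and compares the recomputed
#' percentages with the printed ones. Rows violating the count invariants are
#' reported as row-level errors without aborting the run.
#'
#' @param counts Data frame with columns `n_tp`, `n_fn`, `h_tn`, `h_fp` and
#'   optionally printed `se_printed`, `sp_printed`, `ac_printed` for
#'   comparison.
#' @return The input tibble extended with `se`, `sp`, `ac`, `grade`,
#'   `se_match`, `sp_match`, `ac_match` (`NA` when no printed value) and
#'   `row_error`.
#' @export
verify_printed_counts <- function(counts = reference_counts()) {
  need <- c("n_tp", "n_fn", "h_tn", "h_fp")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    .stop_jtez(paste("counts table missing column(s):", paste(miss, collapse = ", ")),
               "jtez_schema_error")
  }
  out <- tibble::as_tibble(counts)
  n <- nrow(out)
  out$se <- out$sp <- out$ac <- NA_real_
  out$grade <- NA_character_
  out$row_error <- NA_character_
  for (i in seq_len(n)) {
    res <- tryCatch(
      se_sp_ac(confusion_counts(out$n_tp[i], out$n_fn[i], out$h_tn[i], out$h_fp[i])),
      jtez_error = function(e) e
    )
    if (inherits(res, "error")) {
      out$row_error[i] <- conditionMessage(res)
    } else {
      out$se[i] <- res$se; out$sp[i] <- res$sp; out$ac[i] <- res$ac
      out$grade[i] <- res$grade
    }
  }
  cmp <- function(recomputed, printed) {
    if (is.null(printed)) return(rep(NA, n))
    abs(recomputed - printed) < 0.05
  }
  out$se_match <- cmp(out$se, out[["se_printed"]])
  out$sp_match <- cmp(out$sp, out[["sp_printed"]])
  out$ac_match <- cmp(out$ac, out[["ac_printed"]])
  out
}

#' @export
tidy.diagnostic_result <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "accuracy"),
    estimate = c(x$se, x$sp, x$ac)
  )
}

#' @export
glance.diagnostic_result <- function(x, ...) {
  tibble::tibble(
    marker_id = x$marker_id,
    se = x$se, sp = x$sp, ac = x$ac, grade = x$grade,
    n_tp = x$counts$n_tp, n_fn = x$counts$n_fn,
    h_tn = x$counts$h_tn, h_fp = x$counts$h_fp,
    balanced = x$balanced
  )
}
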