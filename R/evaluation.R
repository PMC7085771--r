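#' Build a confusion matrix (sick = positive class)
#'
#' @param truth,estimate Character vectors of `"healthy"`/`"sick"` labels.
#' @param tp,fp,tn,fn Alternatively, the four cell counts directly.
#' @return An object of class `confusion_matrix` (named integer vector with
#'   elements `tp`, `fp`, `tn`, `fn`).
#' @export
confusion_matrix <- function(truth = NULL, estimate = NULL,
                             tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(truth)) {
    truth <- .assert_labels(truth)
    estimate <- .assert_labels(estimate)
    stopifnot(length(truth) == length(estimate))
    cells <- c(
      tp = sum(truth == "sick" & estimate == "sick"),
      fp = sum(truth == "healthy" & estimate == "sick"),
      tn = sum(truth == "healthy" & estimate == "healthy"),
      fn = sum(truth == "sick" & estimate == "healthy")
    )
  } else {
    cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    if (any(is.na(cells)) || any(cells < 0)) {
      stop("tp, fp, tn, fn must all be non-negative", call. = FALSE)
    }
  }
  structure(as.integer(cells), names = c("tp", "fp", "tn", "fn"),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x["tp"], x["fn"], x["fp"], x["tn"]), 2, 2,
              dimnames = list(truth = c("sick", "healthy"),
                              predicted = c("sick", "healthy")))
  print(m)
  invisible(x)
}

#' Confusion-matrix performance battery
#'
#' Computes the standard measure battery from a pooled confusion matrix with
#' sick as the positive class: accuracy, sensitivity, specificity, balanced
#' accuracy, Youden's J (`Sens + Spec - 1`), Cohen's kappa, the F score
#' (`2 * Prec * Sens / (Prec + Sens)`), precision, Matthews correlation
#' coefficient, negative predictive value, and lift
#' (`Prec / prevalence`, prevalence = `(TP + FN) / total`). A measure whose
#' denominator is zero is returned as `NA`.
#'
#' @param cm A `confusion_matrix`, or anything [confusion_matrix()] accepts
#'   via `tp`/`fp`/`tn`/`fn` as a named vector/list.
#' @return A one-row tibble with columns `acc`, `sens`, `spec`,
#'   `balanced_acc`, `youden_j`, `kappa`, `f_score`, `prec`, `mcc`, `npv`,
#'   `lift`.
#' @export
performance_measures <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    cm <- confusion_matrix(tp = cm[["tp"]], fp = cm[["fp"]],
                           tn = cm[["tn"]], fn = cm[["fn"]])
  }
  tp <- as.numeric(cm[["tp"]]); fp <- as.numeric(cm[["fp"]])
  tn <- as.numeric(cm[["tn"]]); fn <- as.numeric(cm[["fn"]])
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  prec <- sdiv(tp, tp + fp)
  npv <- sdiv(tn, tn + fn)
  acc <- (tp + tn) / total
  prevalence <- (tp + fn) / total
  p_yes <- ((tp + fp) / total) * ((tp + fn) / total)
  p_no <- ((tn + fn) / total) * ((tn + fp) / total)
  pe <- p_yes + p_no
  kappa <- if (pe == 1) NA_real_ else (acc - pe) / (1 - pe)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  f_score <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  tibble::tibble(
    acc = acc,
    sens = sens,
    spec = spec,
    balanced_acc = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    youden_j = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1,
    kappa = kappa,
    f_score = f_score,
    prec = prec,
    mcc = mcc,
    npv = npv,
    lift = sdiv(prec, prevalence)
  )
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with mid-rank ties. The exact null distribution is used when
#' both groups have at most 20 observations and there are no ties; otherwise
#' the normal approximation with tie correction (no continuity correction) is
#' applied. Wraps [stats::wilcox.test()].
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   `NULL` picks automatically as above.
#' @return A one-row tibble `u`, `p_value`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- max(length(x), length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    n_x = length(x),
    n_y = length(y),
    method = if (exact && !ties) "exact" else "normal_approx"
  )
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` simultaneous tests; screening the 20-feature schema at
#' `alpha = 0.05` gives 0.0025.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (positive integer).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != as.integer(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Screen features for class differences
#'
#' Per feature (pairwise complete): healthy and sick sample means and
#' standard deviations (n-1 denominator), the two-sided Mann-Whitney p-value,
#' and a significance flag at the Bonferroni-corrected level
#' `alpha / n_features`.
#'
#' @inheritParams relief_rank
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with one row per feature: `feature`, `n_healthy`,
#'   `n_sick`, `mean_healthy`, `sd_healthy`, `mean_sick`, `sd_sick`,
#'   `p_value`, `significant`.
#' @export
compare_features <- function(features, labels, alpha = 0.05) {
  x <- .feature_matrix(features)
  labels <- .assert_labels(labels)
  stopifnot(nrow(x) == length(labels))
  thr <- bonferroni_threshold(alpha, ncol(x))
  out <- purrr::map_dfr(colnames(x), function(f) {
    vh <- x[labels == "healthy", f]
    vs <- x[labels == "sick", f]
    vh <- vh[!is.na(vh)]
    vs <- vs[!is.na(vs)]
    if (length(vh) == 0 || length(vs) == 0) {
      stop("feature '", f, "' observed in only one class", call. = FALSE)
    }
    p <- mann_whitney_u(vh, vs)$p_value
    tibble::tibble(
      feature = f,
      n_healthy = length(vh), n_sick = length(vs),
      mean_healthy = mean(vh), sd_healthy = sd(vh),
      mean_sick = mean(vs), sd_sick = sd(vs),
      p_value = p,
      significant = p < thr
    )
  })
  attr(out, "bonferroni_threshold") <- thr
  out
}
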