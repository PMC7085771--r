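#' The canonical 20-feature health/location/climate schema
#'
#' One row per feature, in schema order: body condition score (BCS, visual
#' 1-5 scale) and back-fat thickness (BFT, mm) at 8 weeks and 3 weeks before
#' calving and on the day of calving; maximum pre-partum NEFA (mmol/L);
#' 305-day milk-yield equivalent (kg); maximum fat/protein ratio of the
#' previous lactation; parity coded -1 (primiparous) / +1 (multiparous);
#' nine location features from three functional barn areas (FA1 cubicles,
#' FA2 feed alley, FA3 passageways) over the two weeks before calving; and
#' the number of hours in the last pre-partum week with a temperature-humidity
#' index (THI) of at least 72 (moderate heat stress).
#'
#' `lower`/`upper` are validation bounds (`NA` = unbounded); `location` marks
#' the nine features dropped when location data are excluded; `missing_rate`
#' is the default masking rate used by [apply_missingness()].
#'
#' @param include_location Keep the nine location features (default TRUE).
#' @return A tibble with columns `feature`, `lower`, `upper`, `location`,
#'   `missing_rate`, `mean_healthy`, `sd_healthy`, `mean_sick`, `sd_sick`.
#' @export
feature_schema <- function(include_location = TRUE) {
  s <- tibble::tribble(
    ~feature,              ~lower, ~upper, ~location, ~missing_rate, ~mean_healthy, ~sd_healthy, ~mean_sick, ~sd_sick,
    "bcs_8w",                   1,      5,     FALSE,        0.3145,        3.190,       0.432,      3.377,     0.446,
    "bcs_3w",                   1,      5,     FALSE,        0.1103,        3.426,       0.428,      3.613,     0.445,
    "bcs_d0",                   1,      5,     FALSE,        0.0119,        3.298,       0.410,      3.395,     0.424,
    "bft_8w",                   0,     NA,     FALSE,        0.3145,       13.425,       5.002,     15.527,     5.830,
    "bft_3w",                   0,     NA,     FALSE,        0.1103,       15.393,       5.261,     17.581,     5.261,
    "bft_d0",                   0,     NA,     FALSE,        0.0119,       15.248,       4.846,     16.892,     5.577,
    "nefa_max",                 0,     NA,     FALSE,        0.0179,        0.296,       0.222,      0.384,     0.256,
    "milk305",                  0,     NA,     FALSE,        0.0015,    11538.300,    1528.180,  11317.700,  1713.150,
    "max_fp_ratio",             0,     NA,     FALSE,        0.0000,        1.686,       0.327,      1.676,     0.372,
    "parity",                  -1,      1,     FALSE,        0.0015,        0.096,       0.996,      0.151,     0.993,
    "loc_only_fa1_ratio",       0,      1,      TRUE,        0.2623,        0.703,       0.090,      0.748,     0.093,
    "loc_fa3_gt_fa1_ratio",     0,      1,      TRUE,        0.2623,        0.074,       0.032,      0.059,     0.026,
    "loc_fa2_gt_fa1_ratio",     0,      1,      TRUE,        0.2623,        0.098,       0.042,      0.080,     0.037,
    "mean_fa1",                 0,     60,      TRUE,        0.2623,       50.658,       3.188,     52.285,     2.960,
    "mean_fa2",                 0,     60,      TRUE,        0.2623,        5.564,       1.853,      4.705,     1.857,
    "mean_fa3",                 0,     60,      TRUE,        0.2623,        3.563,       1.478,      2.825,     1.155,
    "sd_fa1",                   0,     NA,      TRUE,        0.2623,       16.821,       2.937,     15.336,     2.811,
    "sd_fa2",                   0,     NA,      TRUE,        0.2623,       11.711,       2.309,     10.538,     2.374,
    "sd_fa3",                   0,     NA,      TRUE,        0.2623,       10.233,       2.577,      8.799,     2.039,
    "hours_thi_ge72",           0,    168,     FALSE,        0.0000,        6.981,      11.911,     10.858,    12.576
  )
  if (!include_location) s <- s[!s$location, , drop = FALSE]
  s
}

# feature matrix from a data frame: numeric, animal_id dropped; columns known
# to the schema come first in schema order (the Relief tie-break order),
# other numeric columns follow in input order. Name validation against the
# canonical schema is the CSV reader's job.
.feature_matrix <- function(features) {
  df <- as.data.frame(features)
  df$animal_id <- NULL
  known <- intersect(feature_schema()$feature, names(df))
  other <- setdiff(names(df), known)
  df <- df[, c(known, other), drop = FALSE]
  all_na <- vapply(df, function(v) is.logical(v) && all(is.na(v)), logical(1))
  df[all_na] <- lapply(df[all_na], as.numeric) # fully-missing columns
  not_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric feature column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(df)
}

#' Rank features with the original Relief algorithm
#'
#' Deterministic Relief for binary classes: features are min-max normalised
#' over the complete-case subset; for every complete example the nearest hit
#' (same class) and nearest miss (other class) are found by Manhattan
#' distance, and each feature accumulates
#' `|x_f - miss_f| - |x_f - hit_f|`, averaged over examples. Larger weights
#' mean better class separation; a constant feature scores exactly 0.
#' Examples with any missing feature are excluded (Relief needs complete
#' rows). Ties in weight rank by schema order; nearest-neighbour ties break
#' to the lowest row index.
#'
#' @param features Data frame with (a subset of) the [feature_schema()]
#'   columns, optionally an `animal_id` column; `NA` = missing.
#' @param labels Character vector `"healthy"`/`"sick"`, one per row.
#' @return A tibble `feature`, `weight`, `rank`, ordered by rank.
#' @export
relief_rank <- function(features, labels) {
  x <- .feature_matrix(features)
  labels <- .assert_labels(labels)
  stopifnot(nrow(x) == length(labels))
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  labels <- labels[cc]
  if (nrow(x) == 0) stop("no complete-case examples for Relief", call. = FALSE)
  counts <- table(factor(labels, .classes))
  if (any(counts < 2)) {
    stop("Relief needs >= 2 complete examples per class", call. = FALSE)
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1 # constant feature: normalised differences all 0
  z <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  d <- as.matrix(stats::dist(z, method = "manhattan"))
  diag(d) <- Inf
  m <- nrow(z)
  w <- numeric(ncol(z))
  for (i in seq_len(m)) {
    same <- labels == labels[i]
    same[i] <- FALSE
    hit <- which(same)[which.min(d[i, same])]
    miss <- which(!same)[which.min(d[i, !same])]
    w <- w + abs(z[i, ] - z[miss, ]) - abs(z[i, ] - z[hit, ])
  }
  w <- w / m
  ord <- order(-w, seq_along(w)) # ties keep schema order
  tibble::tibble(
    feature = colnames(x)[ord],
    weight = unname(w[ord]),
    rank = seq_along(ord)
  )
}

#' Choose how many top-ranked features to keep
#'
#' Evaluates the prefixes of a Relief ranking (`k = 1..K`) by stratified
#' inner cross-validation on the complete-case training subset: for each
#' fold and each `k`, a Gaussian naive Bayes model on the top-`k` features is
#' fit on the training part and scored by balanced accuracy on the held-out
#' part. Returns the `k` with the highest mean balanced accuracy; ties go to
#' the smallest `k` (the more parsimonious model).
#'
#' @inheritParams relief_rank
#' @param ranking A tibble from [relief_rank()] (or a character vector of
#'   feature names in rank order).
#' @param k_folds Number of inner folds (default 10).
#' @param seed Optional seed for the fold assignment.
#' @return Integer `k`; the per-`k` mean balanced accuracies are attached as
#'   attribute `"balanced_accuracy"`.
#' @export
select_feature_count <- function(features, labels, ranking, k_folds = 10,
                                 seed = NULL) {
  ranked <- if (is.data.frame(ranking)) ranking$feature else as.character(ranking)
  x <- .feature_matrix(features)[, ranked, drop = FALSE]
  labels <- .assert_labels(labels)
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  labels <- labels[cc]
  if (nrow(x) < k_folds) {
    stop("fewer complete cases (", nrow(x), ") than folds (", k_folds, ")",
         call. = FALSE)
  }
  folds <- stratified_kfold(labels, k = k_folds, seed = seed)
  K <- ncol(x)
  ba <- matrix(NA_real_, k_folds, K)
  # the naive Bayes log-likelihood is additive over features, so the models
  # for every ranking prefix k share their per-feature moments; one
  # cumulative sum over the ranked log-densities scores all k at once,
  # identically to fitting each prefix model separately
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    te <- !tr
    counts <- table(factor(labels[tr], .classes))
    if (any(counts < 2)) {
      stop("a class has fewer than 2 complete training examples in an inner fold",
           call. = FALSE)
    }
    lp <- log(prop.table(counts))
    ld <- lapply(.classes, function(cl) {
      xc <- x[tr & labels == cl, , drop = FALSE]
      mu <- colMeans(xc)
      v <- apply(xc, 2, var)
      v <- pmax(v, 1e-9 * max(c(v, 1)))
      m <- dnorm(t(x[te, , drop = FALSE]), mu, sqrt(v), log = TRUE)
      m <- matrix(m, nrow = K)
      t(apply(m, 2, cumsum)) |> matrix(ncol = K, byrow = FALSE)
    })
    d <- ld[[2]] + lp[["sick"]] - (ld[[1]] + lp[["healthy"]])
    truth_te <- labels[te]
    for (k in seq_len(K)) {
      pred <- ifelse(d[, k] > 0, "sick", "healthy")
      sens <- mean(pred[truth_te == "sick"] == "sick")
      spec <- mean(pred[truth_te == "healthy"] == "healthy")
      ba[f, k] <- (sens + spec) / 2
    }
  }
  mba <- colMeans(ba)
  best <- which(mba >= max(mba) - 1e-12)[1] # smallest k among ties
  structure(as.integer(best), balanced_accuracy = mba)
}

#' Fit a Gaussian naive Bayes model tolerant of missing features
#'
#' Per class and feature, a Gaussian is fit by the sample mean and sample
#' variance of the *available* values only; rows missing a feature simply do
#' not contribute to that feature's moments. A variance floor
#' (`var_floor_frac` times the largest per-class feature variance) guards
#' constant features. Class priors are empirical frequencies by default.
#'
#' @inheritParams relief_rank
#' @param selected_features Character vector of features to use (default:
#'   all columns present).
#' @param priors `"empirical"` (training frequencies) or `"uniform"`.
#' @param var_floor_frac Fraction of the largest variance used as floor.
#' @param threshold Sick-posterior decision threshold (default 0.5); can be
#'   retuned later with [tune_threshold()].
#' @return An object of class `gnb_model`.
#' @export
fit_gnb <- function(features, labels, selected_features = NULL,
                    priors = c("empirical", "uniform"),
                    var_floor_frac = 1e-9, threshold = 0.5) {
  priors <- match.arg(priors)
  x <- .feature_matrix(features)
  labels <- .assert_labels(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(selected_features)) selected_features <- colnames(x)
  missing_cols <- setdiff(selected_features, colnames(x))
  if (length(missing_cols) > 0) {
    stop("selected features absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, selected_features, drop = FALSE]
  mom <- lapply(.classes, function(cl) {
    xc <- x[labels == cl, , drop = FALSE]
    n_obs <- colSums(!is.na(xc))
    if (any(n_obs < 2)) {
      stop("feature(s) ", paste(selected_features[n_obs < 2], collapse = ", "),
           " observed fewer than twice in class '", cl, "'", call. = FALSE)
    }
    list(mean = colMeans(xc, na.rm = TRUE),
         var = apply(xc, 2, var, na.rm = TRUE))
  })
  names(mom) <- .classes
  vmax <- max(c(mom$healthy$var, mom$sick$var, 1))
  floorv <- var_floor_frac * vmax
  for (cl in .classes) mom[[cl]]$var <- pmax(mom[[cl]]$var, floorv)
  pri <- if (priors == "uniform") c(healthy = 0.5, sick = 0.5) else {
    p <- prop.table(table(factor(labels, .classes)))
    setNames(as.numeric(p), .classes)
  }
  structure(
    list(
      features = selected_features,
      moments = mom,
      priors = pri,
      prior_mode = priors,
      threshold = threshold,
      n = length(labels)
    ),
    class = "gnb_model"
  )
}

#' Predict with a Gaussian naive Bayes model, omitting missing features
#'
#' The class posterior multiplies the prior by the Gaussian density of every
#' *observed* selected feature; the likelihood terms of missing features are
#' simply omitted, so the prediction for a row with feature `j` missing is
#' identical to that of a model that never used `j` for this row. An animal
#' with *all* selected features missing gets `NA` (undecided signal for the
#' caller). The label is `"sick"` when the sick posterior exceeds the model
#' threshold.
#'
#' @param object A `gnb_model`.
#' @param newdata Data frame with the model's feature columns (`NA` = missing).
#' @param threshold Optional threshold overriding the model's.
#' @param ... Unused.
#' @return A tibble `label`, `posterior_sick`, `n_features_used`.
#' @export
predict.gnb_model <- function(object, newdata, threshold = NULL, ...) {
  thr <- threshold %||% object$threshold
  x <- .feature_matrix(newdata)
  missing_cols <- setdiff(object$features, colnames(x))
  if (length(missing_cols) > 0) {
    stop("newdata lacks feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, object$features, drop = FALSE]
  ll <- sapply(.classes, function(cl) {
    m <- object$moments[[cl]]
    lg <- matrix(
      dnorm(as.vector(x), rep(m$mean, each = nrow(x)),
            rep(sqrt(m$var), each = nrow(x)), log = TRUE),
      nrow = nrow(x)
    )
    lg[is.na(x)] <- 0 # omitted likelihood term
    rowSums(lg) + log(object$priors[[cl]])
  })
  ll <- matrix(ll, ncol = 2, dimnames = list(NULL, .classes))
  post_sick <- unname(1 / (1 + exp(ll[, "healthy"] - ll[, "sick"])))
  used <- rowSums(!is.na(x))
  post_sick[used == 0] <- NA_real_
  tibble::tibble(
    label = ifelse(is.na(post_sick), NA_character_,
                   ifelse(post_sick > thr, "sick", "healthy")),
    posterior_sick = post_sick,
    n_features_used = as.integer(used)
  )
}

#' Tune the sick-posterior threshold for a target training sensitivity
#'
#' Finds the largest threshold under which at least `target_sensitivity` of
#' the sick training examples are classified sick (posterior strictly above
#' the threshold). Useful when the screen should pre-select a guaranteed
#' share of truly sick animals at the cost of precision. `target = 0` returns
#' the maximal threshold 1 (no constraint); an unreachable target returns the
#' minimal feasible threshold with a warning.
#'
#' @param model A `gnb_model`.
#' @inheritParams relief_rank
#' @param target_sensitivity Required fraction of sick training examples
#'   classified sick, in \[0, 1\].
#' @return A threshold in \[0, 1\].
#' @export
tune_threshold <- function(model, features, labels, target_sensitivity) {
  stopifnot(target_sensitivity >= 0, target_sensitivity <= 1)
  labels <- .assert_labels(labels)
  if (!any(labels == "sick")) stop("no sick training examples", call. = FALSE)
  if (target_sensitivity == 0) return(1)
  p <- predict(model, features)$posterior_sick[labels == "sick"]
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no sick example has any selected feature", call. = FALSE)
  m <- length(p)
  eps <- 1e-9
  cand <- sort(unique(p), decreasing = TRUE)
  for (v in cand) {
    thr <- v - eps
    if (mean(p > thr) >= target_sensitivity) return(max(thr, 0))
  }
  warning("target sensitivity ", target_sensitivity,
          " unreachable; returning minimal threshold")
  max(min(p) - eps, 0)
}

#' @export
print.gnb_model <- function(x, ...) {
  cat("<gnb_model> ", length(x$features), " features, priors: ",
      x$prior_mode, " (healthy ", signif(x$priors[["healthy"]], 3),
      " / sick ", signif(x$priors[["sick"]], 3), "), threshold ",
      format(x$threshold), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gnb_model <- function(x, ...) {
  purrr::map_dfr(.classes, function(cl) {
    tibble::tibble(
      class = cl,
      feature = x$features,
      mean = unname(x$moments[[cl]]$mean),
      variance = unname(x$moments[[cl]]$var)
    )
  })
}

#' @export
glance.gnb_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    prior_sick = x$priors[["sick"]],
    threshold = x$threshold,
    n_train = x$n
  )
}
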