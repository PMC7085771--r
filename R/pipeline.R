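#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals it round-robin into `k` folds
#' from a randomly rotated starting fold, so every fold's class counts are
#' within one example of the even split. The partition is exhaustive,
#' disjoint, and reproducible from `seed`.
#'
#' @param labels Character vector `"healthy"`/`"sick"`.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed (uses the current RNG state when NULL).
#' @return Integer vector of fold ids in `1..k`, one per label.
#' @export
stratified_kfold <- function(labels, k = 10, seed = NULL) {
  labels <- .assert_labels(labels)
  counts <- table(factor(labels, .classes))
  if (any(counts < k)) {
    stop("each class needs at least k = ", k, " examples (have ",
         paste(counts, collapse = "/"), ")", call. = FALSE)
  }
  assign_one <- function() {
    folds <- integer(length(labels))
    for (cl in .classes) {
      idx <- sample(which(labels == cl))
      start <- sample.int(k, 1)
      folds[idx] <- ((start - 1 + seq_along(idx) - 1) %% k) + 1
    }
    folds
  }
  if (is.null(seed)) assign_one() else withr::with_seed(seed, assign_one())
}

#' Configure an evaluation experiment
#'
#' The four study configurations cross the sensor time frame (pre- vs
#' post-partum week) with inclusion/exclusion of the nine location features;
#' further options select the strict unanimous ensemble vote, uniform naive
#' Bayes priors, or a tuned sick-posterior threshold targeting a training
#' sensitivity.
#'
#' @param time_frame `"pre"` (week before calving) or `"post"` (week after).
#' @param include_location_features Keep features 11-19 (default TRUE).
#' @param votes_required Stream votes needed at the ensemble stage (4 = the
#'   default 4-of-5 rule, 5 = strict unanimity).
#' @param k_folds Outer cross-validation folds (default 10).
#' @param seed Single global seed governing fold assignment and any sampling.
#' @param priors Naive Bayes prior mode (`"empirical"` or `"uniform"`).
#' @param target_sensitivity When non-NULL, tune the naive Bayes threshold on
#'   the training folds so this fraction of sick examples is caught.
#' @param tie Nearest-centroid distance-tie label (default `"sick"`).
#' @param fallback Label for test animals undecidable at every stage
#'   (no stream votes and all selected features missing); default
#'   `"healthy"`, the majority class.
#' @param rebuild_sign Rebuild the sign matrix inside every leave-one-out
#'   split of the lambda search (default FALSE: one-time construction per
#'   training fold).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(time_frame = c("post", "pre"),
                              include_location_features = TRUE,
                              votes_required = 4,
                              k_folds = 10,
                              seed = 1L,
                              priors = c("empirical", "uniform"),
                              target_sensitivity = NULL,
                              tie = "sick",
                              fallback = "healthy",
                              rebuild_sign = FALSE) {
  stopifnot(votes_required %in% c(4, 5))
  structure(
    list(
      time_frame = match.arg(time_frame),
      include_location_features = include_location_features,
      votes_required = votes_required,
      k_folds = k_folds,
      seed = as.integer(seed),
      priors = match.arg(priors),
      target_sensitivity = target_sensitivity,
      tie = match.arg(tie, .classes),
      fallback = match.arg(fallback, .classes),
      rebuild_sign = rebuild_sign
    ),
    class = "experiment_config"
  )
}

# active feature set under a config
.config_features <- function(config) {
  feature_schema(include_location = config$include_location_features)$feature
}

#' Classify one outer fold (the three-step algorithm)
#'
#' Step 1: for each of the five behaviour streams, the blend parameter
#' lambda is learned on the training fold by leave-one-out balanced error
#' ([select_lambda()]) and a nearest-centroid model is fit. Step 2: a test
#' animal whose five stream votes agree at least `votes_required` times is
#' labelled by the ensemble. Step 3: the remaining animals are classified by
#' the feature route - Relief ranking on the training fold's complete cases,
#' inner-CV choice of the feature count, and a missing-tolerant Gaussian
#' naive Bayes. Every test animal receives exactly one final label (a
#' configured fallback covers the degenerate no-data case).
#'
#' @param train,test `sck_cohort`-like lists (see [filter_cohort()]).
#' @param config An [experiment_config()].
#' @return A tibble `animal_id`, `truth`, `prediction`, `stage`
#'   (`"ensemble"`, `"features"` or `"fallback"`), with the per-stream
#'   lambdas, chosen features and inner-CV `k` as attributes.
#' @export
run_fold <- function(train, test, config = experiment_config()) {
  frame <- if (config$time_frame == "pre") "series_pre" else "series_post"
  series_length <- ncol_series(train[[frame]])
  train_ids <- train$labels$animal_id
  test_ids <- test$labels$animal_id
  train_labels <- .assert_labels(train$labels$label)
  test_labels <- .assert_labels(test$labels$label)
  tr_mats <- .stream_matrices(train[[frame]], train_ids, series_length)
  te_mats <- .stream_matrices(test[[frame]], test_ids, series_length)

  # Step 1: per-stream lambda + NCC models
  lambdas <- numeric(0)
  votes <- matrix(NA_character_, length(test_ids), length(.stream_names),
                  dimnames = list(test_ids, .stream_names))
  for (s in .stream_names) {
    m <- tr_mats[[s]]
    ok <- !apply(m, 1, anyNA)
    lam <- select_lambda(m[ok, , drop = FALSE], train_labels[ok],
                         tie = config$tie, rebuild_sign = config$rebuild_sign)
    lambdas[s] <- as.numeric(lam)
    mod <- fit_stream_ncc(m[ok, , drop = FALSE], train_labels[ok],
                          lambdas[s], stream_name = s, tie = config$tie)
    votes[, s] <- predict(mod, te_mats[[s]])
  }

  # Step 2: 4-of-5 (or unanimous) ensemble decision
  decision <- ensemble_vote(votes, votes_required = config$votes_required)
  prediction <- ifelse(decision == "undecided", NA_character_, decision)
  stage <- ifelse(is.na(prediction), NA_character_, "ensemble")

  # Step 3: feature route for the undecided
  active <- intersect(.config_features(config), names(train$features))
  chosen <- character(0)
  k_sel <- NA_integer_
  undec <- which(is.na(prediction))
  if (length(undec) > 0) {
    ftr <- train$features[match(train_ids, train$features$animal_id),
                          c("animal_id", active)]
    ranking <- relief_rank(ftr, train_labels)
    cc <- stats::complete.cases(.feature_matrix(ftr))
    k_inner <- min(10, min(table(factor(train_labels[cc], .classes))))
    k_sel <- select_feature_count(ftr, train_labels, ranking,
                                  k_folds = max(k_inner, 2))
    chosen <- ranking$feature[seq_len(k_sel)]
    gnb <- fit_gnb(ftr, train_labels, chosen, priors = config$priors)
    if (!is.null(config$target_sensitivity)) {
      gnb$threshold <- tune_threshold(gnb, ftr, train_labels,
                                      config$target_sensitivity)
    }
    fte <- test$features[match(test_ids[undec], test$features$animal_id),
                         c("animal_id", active)]
    p <- predict(gnb, fte)
    prediction[undec] <- p$label
    stage[undec] <- ifelse(is.na(p$label), "fallback", "features")
    prediction[is.na(prediction)] <- config$fallback
  }
  out <- tibble::tibble(
    animal_id = test_ids,
    truth = test_labels,
    prediction = prediction,
    stage = stage
  )
  attr(out, "lambdas") <- lambdas
  attr(out, "features_chosen") <- chosen
  attr(out, "k_selected") <- k_sel
  out
}

ncol_series <- function(series) {
  max(series$hour) + 1L
}

#' Subset a cohort by animal id
#'
#' @param cohort An `sck_cohort`.
#' @param ids Character vector of animal ids to keep.
#' @return An `sck_cohort` restricted to `ids`.
#' @export
filter_cohort <- function(cohort, ids) {
  out <- cohort
  out$series_pre <- dplyr::filter(cohort$series_pre, .data$animal_id %in% ids)
  out$series_post <- dplyr::filter(cohort$series_post, .data$animal_id %in% ids)
  out$features <- dplyr::filter(cohort$features, .data$animal_id %in% ids)
  out$labels <- dplyr::filter(cohort$labels, .data$animal_id %in% ids)
  if (!is.null(out$bhb)) out$bhb <- dplyr::filter(cohort$bhb, .data$animal_id %in% ids)
  out
}

#' Run a full stratified cross-validated experiment
#'
#' Splits the cohort into stratified outer folds, runs the three-step
#' algorithm on each ([run_fold()]), pools the out-of-fold predictions into
#' one confusion matrix ("the results are added up"), and computes the
#' measure battery. Per-fold lambdas and chosen features are logged in the
#' report. The whole run is deterministic given the config seed.
#'
#' @param cohort An `sck_cohort`.
#' @param config An [experiment_config()].
#' @return An object of class `sck_report` with elements `predictions`,
#'   `confusion`, `measures`, `fold_lambdas`, `fold_features`, `fold_k`,
#'   `stage_counts`, `config`.
#' @export
run_experiment <- function(cohort, config = experiment_config()) {
  stopifnot(inherits(cohort, "sck_cohort"))
  labels <- .assert_labels(cohort$labels$label)
  withr::with_seed(config$seed, {
    folds <- stratified_kfold(labels, k = config$k_folds)
    ids <- cohort$labels$animal_id
    fold_results <- purrr::map(seq_len(config$k_folds), function(f) {
      run_fold(filter_cohort(cohort, ids[folds != f]),
               filter_cohort(cohort, ids[folds == f]),
               config)
    })
  })
  predictions <- dplyr::bind_rows(fold_results, .id = "fold") |>
    dplyr::mutate(fold = as.integer(.data$fold))
  cm <- confusion_matrix(predictions$truth, predictions$prediction)
  fold_lambdas <- purrr::imap_dfr(fold_results, function(r, f) {
    tibble::tibble(fold = as.integer(f), stream = .stream_names,
                   lambda = unname(attr(r, "lambdas")[.stream_names]))
  })
  fold_features <- purrr::imap_dfr(fold_results, function(r, f) {
    ch <- attr(r, "features_chosen")
    if (length(ch) == 0) return(tibble::tibble(fold = integer(), feature = character()))
    tibble::tibble(fold = as.integer(f), feature = ch)
  })
  fold_k <- vapply(fold_results, function(r) attr(r, "k_selected"), integer(1))
  structure(
    list(
      predictions = predictions,
      confusion = cm,
      measures = performance_measures(cm),
      fold_lambdas = fold_lambdas,
      fold_features = fold_features,
      fold_k = fold_k,
      stage_counts = table(factor(predictions$stage,
                                  c("ensemble", "features", "fallback"))),
      config = config
    ),
    class = "sck_report"
  )
}

#' @export
print.sck_report <- function(x, ...) {
  cat("<sck_report> ", sum(x$confusion), " animals, time frame: ",
      x$config$time_frame, ", location features: ",
      x$config$include_location_features, ", votes required: ",
      x$config$votes_required, "\n", sep = "")
  print(x$confusion)
  m <- x$measures
  cat(sprintf(
    "Acc %.4f | Sens %.4f | Spec %.4f | J %.4f | F %.4f | kappa %.4f | MCC %.4f\n",
    m$acc, m$sens, m$spec, m$youden_j, m$f_score, m$kappa, m$mcc))
  cat("decided at ensemble/features/fallback: ",
      paste(x$stage_counts, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sck_report <- function(x, ...) {
  tidyr::pivot_longer(x$measures, dplyr::everything(),
                      names_to = "measure", values_to = "value")
}

#' @export
glance.sck_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      time_frame = x$config$time_frame,
      location_features = x$config$include_location_features,
      votes_required = x$config$votes_required,
      n = sum(x$confusion),
      seed = x$config$seed
    ),
    x$measures
  )
}

#' Count how often each feature entered the final naive Bayes model
#'
#' Aggregates the per-fold chosen feature sets across one or more experiment
#' reports: e.g. two 10-fold experiments give 20 feature-selection
#' procedures, so counts range from 0 to 20.
#'
#' @param reports An `sck_report` or a list of them.
#' @return A tibble `feature`, `times_chosen`, `n_folds`, in schema order.
#' @export
selection_frequencies <- function(reports) {
  if (inherits(reports, "sck_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  all_feats <- unique(unlist(lapply(reports, function(r) {
    .config_features(r$config)
  })))
  all_feats <- intersect(feature_schema()$feature, all_feats)
  counts <- setNames(integer(length(all_feats)), all_feats)
  n_folds <- 0L
  for (r in reports) {
    n_folds <- n_folds + r$config$k_folds
    tab <- table(r$fold_features$feature)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  tibble::tibble(
    feature = all_feats,
    times_chosen = unname(counts),
    n_folds = n_folds
  )
}
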