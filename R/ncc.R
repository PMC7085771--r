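#' Fit a per-stream nearest-centroid classifier
#'
#' Stores the class centroids of one behaviour stream, the sign matrix trained
#' from them, and the blend parameter `lambda`. Prediction assigns the label
#' of the nearer centroid under [dima_distance()] with weights
#' `blend_weights(G, lambda)`; exact distance ties go to `"sick"` by default
#' (a screening context favours sensitivity).
#'
#' Because centroids are class means, the classifier is invariant to class
#' prevalence: duplicating training examples of one class leaves its centroid,
#' and hence every prediction, unchanged.
#'
#' @param series Numeric matrix, one weekly stream per row (columns = hours).
#' @param labels Character vector `"healthy"`/`"sick"` per row.
#' @param lambda Blend parameter in \[0, 1\] (see [select_lambda()]).
#' @param stream_name Optional stream identifier
#'   (`"lying"`, `"ruminating"`, `"inactive"`, `"active"`, `"highly_active"`).
#' @param tie Label returned on an exact distance tie (default `"sick"`).
#' @return An object of class `stream_ncc`.
#' @export
fit_stream_ncc <- function(series, labels, lambda, stream_name = NULL,
                           tie = "sick") {
  centroids <- class_centroids(series, labels)
  G <- build_sign_matrix(centroids)
  structure(
    list(
      stream_name = stream_name,
      centroids = centroids,
      sign_matrix = G,
      lambda = lambda,
      weights = blend_weights(G, lambda),
      tie = match.arg(tie, .classes)
    ),
    class = "stream_ncc"
  )
}

#' @export
print.stream_ncc <- function(x, ...) {
  cat("<stream_ncc>",
      if (!is.null(x$stream_name)) paste0(" stream: ", x$stream_name), "\n",
      "  n = ", length(x$centroids$healthy_mean),
      ", lambda = ", format(x$lambda),
      ", training: ", x$centroids$n_healthy, " healthy / ",
      x$centroids$n_sick, " sick\n", sep = "")
  invisible(x)
}

#' Predict with a per-stream nearest-centroid model
#'
#' @param object A `stream_ncc` model.
#' @param newdata Numeric vector (one series) or matrix (one series per row).
#' @param ... Unused.
#' @return Character vector of labels; `NA` for series containing missing
#'   values (the ensemble treats those animals as undecided).
#' @export
predict.stream_ncc <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(x) != length(object$centroids$healthy_mean)) {
    stop("series length does not match model (", ncol(x), " vs ",
         length(object$centroids$healthy_mean), ")", call. = FALSE)
  }
  w <- unclass(object$weights)
  vapply(seq_len(nrow(x)), function(r) {
    xi <- x[r, ]
    if (anyNA(xi)) return(NA_character_)
    dh <- dima_cross_sum(xi, object$centroids$healthy_mean, w, 1)
    ds <- dima_cross_sum(xi, object$centroids$sick_mean, w, 1)
    if (ds < dh) "sick" else if (dh < ds) "healthy" else object$tie
  }, character(1))
}

# Leave-one-out sufficient statistics for the lambda search. For held-out
# example i, its own class centroid is exactly downdated ((mean*n - x)/(n-1));
# the sign matrix G stays fixed (rebuild_sign = TRUE rebuilds it per split).
# Distances under blend(G, lambda) are affine in lambda:
#   d(x, c; lambda) = (1 - lambda) * Q(x, c; G) + lambda * Manhattan(x, c),
# so one pass yields the error for every lambda in the grid.
.loo_stats <- function(series, labels) {
  series <- as.matrix(series)
  labels <- .assert_labels(labels)
  cen <- class_centroids(series, labels)
  if (cen$n_healthy < 2 || cen$n_sick < 2) {
    stop("leave-one-out needs >= 2 examples per class", call. = FALSE)
  }
  G <- unclass(build_sign_matrix(cen))
  n <- ncol(series)
  m <- nrow(series)
  out <- matrix(NA_real_, m, 4,
                dimnames = list(NULL, c("q_h", "q_s", "man_h", "man_s")))
  for (i in seq_len(m)) {
    xi <- series[i, ]
    if (labels[i] == "healthy") {
      ch <- (cen$healthy_mean * cen$n_healthy - xi) / (cen$n_healthy - 1)
      cs <- cen$sick_mean
    } else {
      ch <- cen$healthy_mean
      cs <- (cen$sick_mean * cen$n_sick - xi) / (cen$n_sick - 1)
    }
    out[i, ] <- c(dima_cross_sum(xi, ch, G, 1), dima_cross_sum(xi, cs, G, 1),
                  sum(abs(xi - ch)), sum(abs(xi - cs)))
  }
  list(stats = out, labels = labels, G = G, centroids = cen)
}

.loo_error_from_stats <- function(st, lambda, tie = "sick") {
  d_h <- (1 - lambda) * st$stats[, "q_h"] + lambda * st$stats[, "man_h"]
  d_s <- (1 - lambda) * st$stats[, "q_s"] + lambda * st$stats[, "man_s"]
  pred <- ifelse(d_s < d_h, "sick", ifelse(d_h < d_s, "healthy", tie))
  sens <- mean(pred[st$labels == "sick"] == "sick")
  spec <- mean(pred[st$labels == "healthy"] == "healthy")
  1 - (sens + spec) / 2
}

#' Leave-one-out balanced error of a stream NCC at a given lambda
#'
#' Each training example is held out, its own class centroid recomputed
#' without it (exact mean downdate), and the example classified by the nearer
#' centroid under `blend_weights(G, lambda)`. Returns the balanced error
#' `1 - (sensitivity + specificity) / 2` over all held-out predictions. By
#' default the sign matrix G is built once from the full training set, as a
#' one-time construction; set `rebuild_sign = TRUE` to rebuild it within every
#' leave-one-out split.
#'
#' @inheritParams fit_stream_ncc
#' @param rebuild_sign Rebuild G per leave-one-out split (slow; default FALSE).
#' @return Balanced error in \[0, 1\].
#' @export
loo_balanced_error <- function(series, labels, lambda, tie = "sick",
                               rebuild_sign = FALSE) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  if (!rebuild_sign) {
    st <- .loo_stats(series, labels)
    return(.loo_error_from_stats(st, lambda, tie))
  }
  series <- as.matrix(series)
  labels <- .assert_labels(labels)
  counts <- table(factor(labels, .classes))
  if (any(counts < 2)) stop("leave-one-out needs >= 2 examples per class", call. = FALSE)
  pred <- character(nrow(series))
  for (i in seq_len(nrow(series))) {
    mod <- fit_stream_ncc(series[-i, , drop = FALSE], labels[-i], lambda, tie = tie)
    pred[i] <- predict(mod, series[i, ])
  }
  sens <- mean(pred[labels == "sick"] == "sick")
  spec <- mean(pred[labels == "healthy"] == "healthy")
  1 - (sens + spec) / 2
}

#' Select the blend parameter by leave-one-out balanced error
#'
#' Evaluates [loo_balanced_error()] on every element of [lambda_grid()] and
#' returns the minimiser; among ties the *largest* lambda is chosen (the
#' closest to the plain Manhattan distance).
#'
#' @inheritParams loo_balanced_error
#' @return A single lambda from the grid; the full error profile is attached
#'   as attribute `"errors"` (named numeric vector).
#' @export
select_lambda <- function(series, labels, tie = "sick", rebuild_sign = FALSE) {
  grid <- lambda_grid()
  errs <- if (rebuild_sign) {
    vapply(grid, function(l) loo_balanced_error(series, labels, l, tie, TRUE),
           numeric(1))
  } else {
    st <- .loo_stats(series, labels)
    vapply(grid, function(l) .loo_error_from_stats(st, l, tie), numeric(1))
  }
  best <- max(grid[errs <= min(errs) + 1e-12])
  structure(best, errors = setNames(errs, format(grid)))
}

#' Combine five per-stream votes into an ensemble decision
#'
#' An animal is labelled `"sick"` (or `"healthy"`) only when at least
#' `votes_required` of its five stream classifiers agree; otherwise the
#' decision is `"undecided"` and the animal falls through to the
#' feature-based stage. With `votes_required = 5` this is the strict
#' unanimous variant. Any missing stream vote (`NA`, e.g. a sensor gap)
#' makes the animal undecided.
#'
#' @param votes Character vector of per-stream labels (length 5), or a
#'   data frame / matrix with one column per stream and one row per animal.
#' @param votes_required Agreeing votes needed for a decision (4 or 5).
#' @return For a vector input, a single label in
#'   `c("healthy", "sick", "undecided")`; for tabular input, a character
#'   vector with one decision per row.
#' @export
ensemble_vote <- function(votes, votes_required = 4) {
  if (is.data.frame(votes) || is.matrix(votes)) {
    m <- as.matrix(votes)
    return(vapply(seq_len(nrow(m)), function(r) {
      ensemble_vote(as.character(m[r, ]), votes_required)
    }, character(1)))
  }
  votes <- as.character(votes)
  if (length(votes) > length(.stream_names)) {
    stop("at most ", length(.stream_names), " stream votes expected", call. = FALSE)
  }
  if (anyNA(votes) || length(votes) < length(.stream_names)) {
    return("undecided")
  }
  .assert_labels(votes)
  n_sick <- sum(votes == "sick")
  n_healthy <- sum(votes == "healthy")
  if (n_sick >= votes_required) "sick"
  else if (n_healthy >= votes_required) "healthy"
  else "undecided"
}

#' Serialise / restore a stream NCC model as JSON
#'
#' The layout stores the stream name, both centroids, the dense sign matrix,
#' and the selected lambda; `read_stream_ncc()` reconstructs an identical
#' model (blended weights are recomputed).
#'
#' @param model A `stream_ncc`.
#' @param path File path.
#' @return `write_stream_ncc()` returns `path` invisibly; `read_stream_ncc()`
#'   a `stream_ncc`.
#' @export
write_stream_ncc <- function(model, path) {
  stopifnot(inherits(model, "stream_ncc"))
  payload <- list(
    stream_name = model$stream_name,
    lambda = model$lambda,
    tie = model$tie,
    n_healthy = model$centroids$n_healthy,
    n_sick = model$centroids$n_sick,
    healthy_mean = model$centroids$healthy_mean,
    sick_mean = model$centroids$sick_mean,
    sign_matrix = unclass(model$sign_matrix)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stream_ncc
#' @export
read_stream_ncc <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cen <- structure(
    list(
      healthy_mean = as.numeric(p$healthy_mean),
      sick_mean = as.numeric(p$sick_mean),
      n_healthy = as.integer(p$n_healthy),
      n_sick = as.integer(p$n_sick)
    ),
    class = "centroid_pair"
  )
  G <- structure(as.matrix(p$sign_matrix),
                 class = c("weight_matrix", "matrix", "array"))
  dimnames(G) <- NULL
  structure(
    list(
      stream_name = p$stream_name,
      centroids = cen,
      sign_matrix = G,
      lambda = as.numeric(p$lambda),
      weights = blend_weights(G, as.numeric(p$lambda)),
      tie = p$tie
    ),
    class = "stream_ncc"
  )
}

#' @export
tidy.stream_ncc <- function(x, ...) {
  n <- length(x$centroids$healthy_mean)
  tibble::tibble(
    hour = rep(seq_len(n) - 1L, 2L),
    class = rep(.classes, each = n),
    centroid = c(x$centroids$healthy_mean, x$centroids$sick_mean)
  )
}

#' @export
glance.stream_ncc <- function(x, ...) {
  tibble::tibble(
    stream = x$stream_name %||% NA_character_,
    lambda = x$lambda,
    n_healthy = x$centroids$n_healthy,
    n_sick = x$centroids$n_sick,
    series_length = length(x$centroids$healthy_mean)
  )
}
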