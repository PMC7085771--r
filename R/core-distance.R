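#' Weighted elementwise time-series dissimilarity (DIMA)
#'
#' Computes the dissimilarity
#' \deqn{D(a, b) = \Big(\sum_{i=1}^n \sum_{j=1}^n |a_i - b_j|^p \, w_{ij}\Big)^{1/p},}
#' a double sum over *all* index pairs of two equal-length series, weighted by
#' an \eqn{n \times n} matrix. With the identity weight matrix this is the
#' Minkowski distance (the Manhattan distance at `p = 1`); with a trained sign
#' matrix (see [build_sign_matrix()]) it emphasises index pairs whose absolute
#' differences separate healthy from sick class means and penalises pairs that
#' do not.
#'
#' For diagonal weight matrices with strictly positive entries and `p >= 1`
#' the function is a metric on \eqn{R^n}. General (signed) weight matrices may
#' return negative values; the nearest-centroid classifier only compares
#' values, so this is harmless there. `p != 1` requires non-negative weights
#' (the outer `1/p` root of a negative sum is undefined).
#'
#' @param a,b Numeric vectors of equal length (behaviour streams are minutes
#'   per hour, in \[0, 60\]).
#' @param w Square numeric weight matrix with `nrow(w) == length(a)`, or
#'   `NULL` for the identity matrix.
#' @param p Positive exponent; the pipeline uses `p = 1` throughout.
#' @return A single numeric value.
#' @examples
#' dima_distance(c(1, 2), c(3, 4))                      # Manhattan: 4
#' dima_distance(c(1, 0), c(0, 1), matrix(1, 2, 2))     # all-pairs sum: 2
#' @export
dima_distance <- function(a, b, w = NULL, p = 1) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("series lengths differ: ", length(a), " vs ", length(b), call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0) {
    stop("p must be a single positive number", call. = FALSE)
  }
  if (is.null(w)) {
    return(sum(abs(a - b)^p)^(1 / p))
  }
  w <- as.matrix(w)
  if (nrow(w) != ncol(w) || nrow(w) != length(a)) {
    stop("weight matrix must be ", length(a), "x", length(a), call. = FALSE)
  }
  if (p != 1 && any(w < 0)) {
    stop("p != 1 requires non-negative weights", call. = FALSE)
  }
  s <- dima_cross_sum(a, b, w, p)
  if (p == 1) s else s^(1 / p)
}

#' Per-class mean series (centroids)
#'
#' Pointwise arithmetic means of the healthy and sick training series; these
#' are the centroids the nearest-centroid classifier compares against and the
#' inputs from which the sign matrix is trained.
#'
#' @param series Numeric matrix, one series per row.
#' @param labels Character vector (`"healthy"`/`"sick"`), one per row.
#' @return An object of class `centroid_pair`: a list with `healthy_mean`,
#'   `sick_mean`, `n_healthy`, `n_sick`.
#' @export
class_centroids <- function(series, labels) {
  series <- as.matrix(series)
  labels <- .assert_labels(labels)
  if (nrow(series) != length(labels)) {
    stop("nrow(series) must equal length(labels)", call. = FALSE)
  }
  h <- labels == "healthy"
  s <- labels == "sick"
  if (!any(h) || !any(s)) stop("both classes must be present", call. = FALSE)
  structure(
    list(
      healthy_mean = colMeans(series[h, , drop = FALSE]),
      sick_mean = colMeans(series[s, , drop = FALSE]),
      n_healthy = sum(h),
      n_sick = sum(s)
    ),
    class = "centroid_pair"
  )
}

#' Train the sign weight matrix from class centroids
#'
#' Builds the \eqn{n \times n} matrix
#' \deqn{G_{ij} = \mathrm{sign}\big(\min\{|\bar h_i - \bar s_j|, |\bar s_i - \bar h_j|\}
#'  - \max\{|\bar h_i - \bar h_j|, |\bar s_i - \bar s_j|\}\big)}
#' from the healthy (\eqn{\bar h}) and sick (\eqn{\bar s}) mean series. Entry
#' \eqn{(i,j)} is +1 when the between-class absolute differences at hours
#' \eqn{i,j} exceed the within-class ones (a discriminative index pair), -1
#' when the reverse holds, and 0 on ties (`sign(0) = 0`). The result is
#' symmetric with entries in \{-1, 0, 1\}.
#'
#' @param centroids A `centroid_pair` from [class_centroids()].
#' @return A `weight_matrix` object (numeric matrix with class attribute).
#' @export
build_sign_matrix <- function(centroids) {
  stopifnot(inherits(centroids, "centroid_pair"))
  h <- centroids$healthy_mean
  s <- centroids$sick_mean
  if (length(h) != length(s)) stop("centroid lengths differ", call. = FALSE)
  hs <- abs(outer(h, s, "-")) # |h_i - s_j|
  hh <- abs(outer(h, h, "-"))
  ss <- abs(outer(s, s, "-"))
  g <- sign(pmin(hs, t(hs)) - pmax(hh, ss))
  structure(g, class = c("weight_matrix", class(g)))
}

#' Blend a trained sign matrix with the identity
#'
#' Returns \eqn{G(\lambda) = (1-\lambda) G + \lambda I}. At `lambda = 0` the
#' trained matrix is used unchanged; at `lambda = 1` the weights reduce to the
#' identity and [dima_distance()] with `p = 1` becomes the Manhattan distance.
#'
#' @param G Square numeric matrix (typically from [build_sign_matrix()]).
#' @param lambda Blend parameter in \[0, 1\].
#' @return A `weight_matrix`.
#' @export
blend_weights <- function(G, lambda) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("G must be square", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  out <- (1 - lambda) * G + lambda * diag(nrow(G))
  structure(out, class = c("weight_matrix", "matrix", "array"), lambda = lambda)
}

#' Candidate blend parameters
#'
#' The dyadic search grid \eqn{\{2^{-i}\} \cup \{1 - 2^{-i}\}}, `i = 0..15`,
#' sorted with duplicates removed: 31 values densely covering both ends of
#' \[0, 1\] (0, 1 and 0.5 included). The leave-one-out search in
#' [select_lambda()] evaluates every element.
#'
#' @return Sorted numeric vector of length 31.
#' @export
lambda_grid <- function() {
  i <- 0:15
  sort(unique(c(2^-i, 1 - 2^-i)))
}

#' Write / read a weight matrix as dense CSV
#'
#' Round-trips the \eqn{n \times n} weights for external inspection; the
#' header row carries the 1-based column indices.
#'
#' @param w Square numeric matrix.
#' @param path File path.
#' @return `write_weight_matrix()` returns `path` invisibly;
#'   `read_weight_matrix()` returns a `weight_matrix`.
#' @export
write_weight_matrix <- function(w, path) {
  w <- as.matrix(w)
  df <- as.data.frame(w)
  names(df) <- as.character(seq_len(ncol(w)))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    .default = readr::col_double()
  ))
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square", call. = FALSE)
  structure(m, class = c("weight_matrix", "matrix", "array"))
}
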