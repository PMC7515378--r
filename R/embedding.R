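# Time-delay embedding and ordinal symbolization: the shared front end of
# every entropy in the package (PE, WPE, IPE, NPE).

#' Validate a univariate signal
#'
#' @param x numeric vector.
#' @param n_min minimum required length.
#' @return the signal, invisibly, after checks.
#' @keywords internal
check_signal <- function(x, n_min = 1L) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("invalid signal: need a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(x)))
    stop("invalid signal: non-finite samples (NaN/Inf/NA)", call. = FALSE)
  if (length(x) < n_min)
    stop("series too short: N = ", length(x), " < ", n_min, call. = FALSE)
  invisible(x)
}

check_dim <- function(d) {
  if (length(d) != 1L || d != as.integer(d) || d < 3L || d > 9L)
    stop("embedding dimension d must be an integer in 3..9", call. = FALSE)
  as.integer(d)
}

#' Embed a time series into overlapping d-vectors
#'
#' Unit-lag time-delay reconstruction: row i of the returned matrix is
#' `(x[i], x[i+1], ..., x[i+d-1])`, for i = 1..N-d+1.
#'
#' @param x numeric vector, the signal (all samples finite).
#' @param d embedding dimension (window length), `2 <= d <= N`.
#' @return an `(N-d+1) x d` numeric matrix of overlapping windows.
#' @examples
#' embed_series(c(1, 3, 4, 5, 4, 5, 3, 1, 2, 4, 5, 3), 3)
#' @export
embed_series <- function(x, d) {
  if (length(d) != 1L || d != as.integer(d) || d < 2L)
    stop("d must be an integer >= 2", call. = FALSE)
  check_signal(x, n_min = d)
  n <- length(x) - d + 1L
  X <- vapply(seq_len(d), function(k) x[k:(n + k - 1L)], numeric(n))
  if (n == 1L) X <- matrix(X, nrow = 1L)
  X
}

#' Ordinal (Bandt-Pompe) pattern of a vector
#'
#' Returns the permutation of original indices that sorts the vector into
#' increasing order. Ties are broken by original position (stable sort), so
#' equal values keep their temporal order.
#'
#' @param v numeric vector with at least 2 finite entries.
#' @return integer vector of ranks; a permutation of `1:length(v)`.
#' @examples
#' ordinal_pattern(c(4, 5, 4)) # 1 3 2
#' @export
ordinal_pattern <- function(v) {
  if (length(v) < 2L || !all(is.finite(v)))
    stop("need >= 2 finite entries", call. = FALSE)
  order(v) # radix order: stable, earlier index first on ties
}

#' Base-10 code of an ordinal pattern
#'
#' Serializes a rank tuple `(r1, ..., rd)` as the integer
#' `sum(r_k * 10^(d-k))`; e.g. ranks (1,3,2) -> 132. Unique for d <= 9.
#'
#' @param ranks integer permutation of `1:d` (from [ordinal_pattern()]).
#' @return a single numeric code.
#' @export
pattern_code <- function(ranks) {
  d <- length(ranks)
  if (d > 9L) stop("base-10 pattern codes are only defined for d <= 9", call. = FALSE)
  sum(ranks * 10^((d - 1L):0))
}

#' Ordinal pattern codes for every embedded vector
#'
#' @param X embedding matrix from [embed_series()].
#' @return numeric vector of pattern codes, one per row of `X`.
#' @export
pattern_codes <- function(X) {
  pow <- 10^((ncol(X) - 1L):0)
  apply(X, 1L, function(r) sum(order(r) * pow))
}

#' Signed variance weight of an embedded vector
#'
#' The magnitude is the population variance of the vector (divisor d); the
#' sign is positive when the mean of the interior elements (positions
#' 2..d-1) is at least the mean of the whole vector, negative otherwise.
#' For d = 3 the interior is the single middle element.
#'
#' @param v numeric vector of length d >= 3.
#' @return signed real weight.
#' @examples
#' signed_weight(c(1, 3, 4)) # +1.5556
#' signed_weight(c(5, 4, 5)) # -0.2222
#' @export
signed_weight <- function(v) {
  d <- length(v)
  if (d < 3L) stop("flag undefined: signed weight needs d >= 3", call. = FALSE)
  m <- mean(v)
  w <- mean((v - m)^2)
  if (mean(v[2:(d - 1L)]) - m >= 0) w else -w
}

#' Signed variance weights for every embedded vector
#'
#' Vectorized form of [signed_weight()] over the rows of an embedding matrix.
#'
#' @param X embedding matrix from [embed_series()], `ncol(X) >= 3`.
#' @return numeric vector of signed weights, one per row.
#' @export
signed_weights <- function(X) {
  d <- ncol(X)
  if (d < 3L) stop("flag undefined: signed weight needs d >= 3", call. = FALSE)
  m <- rowMeans(X)
  w <- rowMeans((X - m)^2)
  flag <- rowMeans(X[, 2:(d - 1L), drop = FALSE]) - m
  ifelse(flag >= 0, w, -w)
}

#' Amplitude quantization of embedded vectors (IPE symbolization)
#'
#' Quantizes the signal range `[xmin, xmax]` into `L` equal bins of width
#' `Delta = (xmax - xmin)/L`. The first column of each embedded vector is
#' binned directly (the top bin closed, so `x = xmax` maps to `L-1`); each
#' remaining column k gets `S1 + floor((x_k - x_1)/Delta)`, clamped to
#' `[0, L-1]`.
#'
#' @param x numeric signal with `max(x) > min(x)`.
#' @param d embedding dimension.
#' @param L number of quantization levels, `>= 2`.
#' @return integer matrix `(N-d+1) x d` with entries in `0:(L-1)`.
#' @export
ipe_symbolize <- function(x, d, L) {
  d <- check_dim(d)
  check_signal(x, n_min = d)
  if (length(L) != 1L || L != as.integer(L) || L < 2L)
    stop("L must be an integer >= 2", call. = FALSE)
  xmin <- min(x); xmax <- max(x)
  if (xmax == xmin) stop("degenerate range: constant signal", call. = FALSE)
  delta <- (xmax - xmin) / L
  X <- embed_series(x, d)
  s1 <- pmin(floor((X[, 1L] - xmin) / delta), L - 1L)
  S <- matrix(0L, nrow(X), d)
  S[, 1L] <- as.integer(s1)
  for (k in 2:d) {
    sk <- s1 + floor((X[, k] - X[, 1L]) / delta)
    S[, k] <- as.integer(pmax(0L, pmin(sk, L - 1L)))
  }
  S
}
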