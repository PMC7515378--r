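# Baseline entropies: permutation entropy (PE), weighted PE (WPE), and
# improved PE (IPE). Each is the Shannon entropy (natural log) of a
# probability distribution over symbols, normalized to [0, 1].

# 0 * log 0 := 0
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Bandt-Pompe pattern distribution
#'
#' Relative frequencies of the ordinal pattern codes over the N-d+1
#' embedded vectors of a signal. Only observed patterns are listed.
#'
#' @param x numeric signal.
#' @param d embedding dimension (3..9).
#' @return data frame with columns `pattern` (base-10 code), `count`, and
#'   `prob`, sorted by decreasing probability.
#' @examples
#' bp_distribution(rep(1:5, length.out = 100), 3)
#' @export
bp_distribution <- function(x, d) {
  d <- check_dim(d)
  check_signal(x, n_min = d)
  codes <- pattern_codes(embed_series(x, d))
  tab <- table(codes)
  out <- data.frame(
    pattern = as.numeric(names(tab)),
    count = as.integer(tab),
    prob = as.numeric(tab) / length(codes)
  )
  out[order(-out$prob, out$pattern), , drop = FALSE]
}

#' Permutation entropy
#'
#' Normalized Shannon entropy of the Bandt-Pompe pattern distribution:
#' `PE = -sum(p * ln p) / ln(d!)`, in `[0, 1]`.
#'
#' @inheritParams bp_distribution
#' @return PE value in `[0, 1]`.
#' @examples
#' pe(rep(1:5, length.out = 20480), 3) # 0.5303
#' @export
pe <- function(x, d) {
  dist <- bp_distribution(x, d)
  shannon(dist$prob) / log(factorial(d))
}

#' Weighted permutation entropy
#'
#' Each embedded vector contributes its (unsigned) population variance as
#' weight instead of a unit count; the weighted pattern distribution is
#' normalized by its total weight and the Shannon entropy by `ln(d!)`.
#'
#' @inheritParams bp_distribution
#' @return WPE value in `[0, 1]`.
#' @export
wpe <- function(x, d) {
  d <- check_dim(d)
  check_signal(x, n_min = d)
  X <- embed_series(x, d)
  codes <- pattern_codes(X)
  m <- rowMeans(X)
  w <- rowMeans((X - m)^2)
  total <- sum(w)
  if (total == 0)
    stop("degenerate weights: all embedded vectors have zero variance", call. = FALSE)
  pw <- as.numeric(tapply(w, codes, sum)) / total
  shannon(pw) / log(factorial(d))
}

#' Improved permutation entropy
#'
#' Shannon entropy of the distribution of quantized symbol words (see
#' [ipe_symbolize()]), normalized by `ln(L^d)` since each word is one of
#' `L^d` possibilities.
#'
#' @inheritParams bp_distribution
#' @param L number of quantization levels (default 4).
#' @return IPE value in `[0, 1]`.
#' @export
ipe <- function(x, d, L = 4L) {
  S <- ipe_symbolize(x, d, L)
  words <- apply(S, 1L, paste, collapse = ",")
  p <- as.numeric(table(words)) / length(words)
  shannon(p) / (d * log(L))
}
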