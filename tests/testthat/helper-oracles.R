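# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops, explicit enumeration, scalar
# transcriptions of the defining formulas.

all_perms <- function(d) {
  if (d == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(d - 1L)) {
    for (pos in 0:(d - 1L)) {
      out[[length(out) + 1L]] <- append(p, d, after = pos)
    }
  }
  out
}

# stable-tie match: v follows permutation p iff v[p] is nondecreasing and
# equal neighbours keep ascending original indices
perm_matches <- function(v, p) {
  s <- v[p]
  if (any(diff(s) < 0)) return(FALSE)
  for (k in seq_len(length(p) - 1L)) {
    if (s[k] == s[k + 1L] && p[k] > p[k + 1L]) return(FALSE)
  }
  TRUE
}

naive_pe <- function(x, d) {
  n <- length(x) - d + 1L
  perms <- all_perms(d)
  counts <- integer(length(perms))
  for (i in seq_len(n)) {
    v <- x[i:(i + d - 1L)]
    for (q in seq_along(perms)) {
      if (perm_matches(v, perms[[q]])) {
        counts[q] <- counts[q] + 1L
        break
      }
    }
  }
  p <- counts[counts > 0] / n
  -sum(p * log(p)) / log(factorial(d))
}

naive_signed_weight <- function(v) {
  d <- length(v)
  m <- sum(v) / d
  w <- sum((v - m)^2) / d
  if (sum(v[2:(d - 1L)]) / (d - 2L) - m >= 0) w else -w
}

naive_wpe <- function(x, d) {
  n <- length(x) - d + 1L
  key <- character(n); w <- numeric(n)
  for (i in seq_len(n)) {
    v <- x[i:(i + d - 1L)]
    key[i] <- paste(order(v), collapse = "-")
    m <- mean(v)
    w[i] <- mean((v - m)^2)
  }
  num <- tapply(w, key, sum)
  p <- as.numeric(num) / sum(w)
  p <- p[p > 0]
  -sum(p * log(p)) / log(factorial(d))
}

# literal double-loop transcription of the network scan
naive_network <- function(x, d, error, floor = 1e-5) {
  n <- length(x) - d + 1L
  pats <- vector("list", n); w <- numeric(n)
  for (i in seq_len(n)) {
    v <- x[i:(i + d - 1L)]
    pats[[i]] <- order(v)
    w[i] <- naive_signed_weight(v)
  }
  raw <- rep(floor, n)
  edges <- matrix(integer(0), 0L, 2L)
  for (i in 2:n) {
    for (j in seq_len(i - 1L)) {
      if (identical(pats[[i]], pats[[j]]) && abs(w[i] - w[j]) <= error) {
        raw[j] <- raw[j] + 1
        edges <- rbind(edges, c(i, j))
        break
      }
    }
  }
  list(raw = raw, edges = edges)
}

naive_npe <- function(x, d, error) {
  net <- naive_network(x, d, error)
  p <- net$raw / sum(net$raw)
  -sum(p * log(p)) / log(length(p))
}

# scalar per-element transcription of the quantization rules
naive_ipe_symbols <- function(x, d, L) {
  xmin <- min(x); xmax <- max(x)
  delta <- (xmax - xmin) / L
  n <- length(x) - d + 1L
  S <- matrix(0L, n, d)
  for (i in seq_len(n)) {
    v <- x[i:(i + d - 1L)]
    s1 <- if (v[1L] == xmax) L - 1L else floor((v[1L] - xmin) / delta)
    S[i, 1L] <- as.integer(s1)
    for (k in 2:d) {
      sk <- s1 + floor((v[k] - v[1L]) / delta)
      S[i, k] <- as.integer(min(max(sk, 0L), L - 1L))
    }
  }
  S
}

classic_henon_x <- function(a, b, n, x0, y0) {
  x <- numeric(n); xp <- x0; yp <- y0
  for (i in seq_len(n)) {
    xi <- 1 - a * xp^2 + yp
    yi <- b * xp
    x[i] <- xi
    xp <- xi; yp <- yi
  }
  x
}

lorenz_rhs_oracle <- function(s, c_par) {
  c(10 * (s[2L] - s[1L]),
    (24 - 4 * c_par) * s[1L] - s[1L] * s[3L] + c_par * s[2L],
    s[1L] * s[2L] - 8 * s[3L] / 3)
}

rk4_step_oracle <- function(s, h, c_par) {
  k1 <- lorenz_rhs_oracle(s, c_par)
  k2 <- lorenz_rhs_oracle(s + h / 2 * k1, c_par)
  k3 <- lorenz_rhs_oracle(s + h / 2 * k2, c_par)
  k4 <- lorenz_rhs_oracle(s + h * k3, c_par)
  s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# mixed corpus of short signals exercising ties, periodicity, and noise
short_signal_corpus <- function(seed = 421L) {
  set.seed(seed)
  sigs <- list(
    rep(2, 9),
    rep(c(1, 2, 3, 4, 5), length.out = 23),
    rep(c(1, 2, 3, 4), length.out = 18),
    c(1, 3, 4, 5, 4, 5, 3, 1, 2, 4, 5, 3),
    round(runif(25), 1) # many ties
  )
  for (k in 1:6) sigs[[length(sigs) + 1L]] <- runif(sample(10:30, 1))
  for (k in 1:3) sigs[[length(sigs) + 1L]] <- sample(1:4, sample(12:30, 1), replace = TRUE)
  sigs
}
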