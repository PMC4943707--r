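# Independent brute-force oracles used to check the package implementations.
# These are deliberately naive and share no code with R/.

# Landau's index straight from the defining formula, given a 0/1 direction
# matrix D (D[i, j] = 1 iff i dominates j)
oracle_landau_from_directions <- function(D) {
  n <- nrow(D)
  V <- rowSums(D)
  12 / (n^3 - n) * sum((V - (n - 1) / 2)^2)
}

# all 2^(n(n-1)/2) direction assignments of an n-individual tournament,
# returned as a list of direction matrices
oracle_all_tournaments <- function(n) {
  pairs <- utils::combn(n, 2)
  n_dyads <- ncol(pairs)
  lapply(0:(2^n_dyads - 1), function(m) {
    bits <- as.integer(intToBits(m))[seq_len(n_dyads)]
    D <- matrix(0L, n, n)
    for (d in seq_len(n_dyads)) {
      i <- pairs[1, d]; j <- pairs[2, d]
      if (bits[d] == 1) D[i, j] <- 1L else D[j, i] <- 1L
    }
    D
  })
}

# exhaustive I&SI: best (I, SI) over every permutation of n individuals
oracle_isi_exhaustive <- function(X) {
  n <- nrow(X)
  perms <- asplit(permutations_of(n), 1)
  best <- c(I = Inf, SI = Inf)
  for (ord in perms) {
    Xo <- X[ord, ord]
    I <- 0L; SI <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (Xo[j, i] > Xo[i, j]) { I <- I + 1L; SI <- SI + (j - i) }
    }
    if (I < best["I"] || (I == best["I"] && SI < best["SI"]))
      best <- c(I = I, SI = SI)
  }
  best
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# rank correlation from first principles (midranks + Pearson on ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Gaussian class table for discriminant tests: g classes x m calls, p
# features, class means spaced `delta` apart on the first feature
make_class_table <- function(g, m, p = 3, delta = 0, seed = 1,
                             sexes = NULL) {
  withr::with_seed(seed, {
    caller <- rep(sprintf("c%02d", seq_len(g)), each = m)
    X <- matrix(rnorm(g * m * p), g * m, p)
    X[, 1] <- X[, 1] + rep(delta * seq_len(g), each = m)
    tab <- data.frame(caller = caller, X)
    names(tab)[-1] <- paste0("f", seq_len(p))
    if (!is.null(sexes)) tab$sex <- rep(sexes, each = m)[seq_len(g * m)]
    tab
  })
}

# flat-envelope noise burst for detector tests
make_burst <- function(duration_s, fs = 48000, freq_hz = 1000, seed = 1) {
  n <- round(duration_s * fs)
  withr::with_seed(seed, sin(2 * pi * freq_hz * (0:(n - 1)) / fs) +
                     0.05 * rnorm(n))
}

place_bursts <- function(bursts, gaps_s, fs = 48000, pad_s = 0.05) {
  out <- rep(0, round(pad_s * fs))
  for (i in seq_along(bursts)) {
    out <- c(out, bursts[[i]])
    if (i < length(bursts)) out <- c(out, rep(0, round(gaps_s[i] * fs)))
  }
  c(out, rep(0, round(pad_s * fs)))
}
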