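# Nonlinear signal descriptors. The O(n^2) kernels (sample/approximate
# entropy, LZ76) live in src/; everything here is thin parameterization.

#' Sample entropy of a series
#'
#' Embedding dimension `m`, Chebyshev tolerance `r` (default a quarter of the
#' series SD), strict `< r` matching, self-matches excluded. Returns 0 for
#' degenerate series (constant, or no template matches).
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param r Tolerance; defaults to `0.25 * sd(x)`.
#' @return Sample entropy in nats.
#' @export
sample_entropy <- function(x, m = 1, r = 0.25 * sd(x)) {
  if (any(!is.finite(x))) stop("non-finite values in series", call. = FALSE)
  if (!is.finite(r) || r <= 0) return(0)
  sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Approximate entropy of a series
#'
#' Pincus' ApEn: `phi(m) - phi(m+1)` with `<= r` matching and self-matches
#' included.
#'
#' @inheritParams sample_entropy
#' @return Approximate entropy in nats.
#' @export
approx_entropy <- function(x, m = 1, r = 0.25 * sd(x)) {
  if (any(!is.finite(x))) stop("non-finite values in series", call. = FALSE)
  if (!is.finite(r) || r <= 0) return(0)
  apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Normalized permutation entropy
#'
#' Ordinal-pattern entropy of order `m` (delay 1), ties broken by temporal
#' order, normalized by `log(m!)` so the result lies in `[0, 1]`. A constant
#' series gives 0.
#'
#' @param x Numeric series.
#' @param m Pattern order (default 3).
#' @return Normalized permutation entropy.
#' @export
perm_entropy <- function(x, m = 3) {
  n <- length(x)
  if (n < m + 1) return(0)
  if (m == 3) {
    # vectorized order-3 fast path; ranks with ties to the earlier index
    a <- x[1:(n - 2)]; b <- x[2:(n - 1)]; cc <- x[3:n]
    r1 <- 1 + (b < a) + (cc < a)
    r2 <- 1 + (a <= b) + (cc < b)
    r3 <- 1 + (a <= cc) + (b <= cc)
    codes <- r1 * 100 + r2 * 10 + r3
  } else {
    emb <- vapply(seq_len(m), function(k) x[k:(n - m + k)], numeric(n - m + 1))
    codes <- apply(emb, 1, function(row) {
      paste(rank(row, ties.method = "first"), collapse = "")
    })
  }
  p <- tabulate(factor(codes)) / length(codes)
  h <- -sum(p * log(p))
  h / log(factorial(m))
}

#' Lempel-Ziv (LZ76) complexity of a signal binarized at its median
#'
#' @param x Numeric series (binarized as `x > median(x)`) or a logical/0-1
#'   vector used as-is.
#' @param normalize Divide by `n / log2(n)` (the expected complexity of a
#'   random sequence) when `TRUE`.
#' @return Complexity count, normalized if requested.
#' @export
lz_complexity <- function(x, normalize = TRUE) {
  b <- if (is.logical(x) || all(x %in% c(0, 1))) as.integer(x)
       else as.integer(x > median(x))
  n <- length(b)
  if (n < 2) return(0)
  cc <- lz76_cpp(b)
  if (normalize) cc / (n / log2(n)) else as.numeric(cc)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' DFA-1 on the integrated, mean-centred profile: the slope of
#' `log F(s)` vs `log s` over box sizes `scales`, with linear detrending in
#' each box.
#'
#' @param x Numeric series.
#' @param scales Box sizes in samples (default ~12 log-spaced in 10..300).
#' @return The scaling exponent alpha.
#' @export
dfa_exponent <- function(x, scales = NULL) {
  n <- length(x)
  if (is.null(scales))
    scales <- unique(round(exp(seq(log(10), log(min(300, floor(n / 4))),
                                   length.out = 12))))
  scales <- scales[scales >= 4 & scales <= floor(n / 2)]
  if (length(scales) < 2 || sd(x) == 0) return(0)
  y <- cumsum(x - mean(x))
  f <- vapply(scales, function(s) {
    nb <- floor(n / s)
    m <- matrix(y[seq_len(nb * s)], nrow = s)
    tt <- cbind(1, seq_len(s))
    resid <- m - tt %*% solve(crossprod(tt), crossprod(tt, m))
    sqrt(mean(resid^2))
  }, numeric(1))
  ok <- f > 0
  if (sum(ok) < 2) return(0)
  unname(stats::coef(stats::lm(log(f[ok]) ~ log(scales[ok])))[2])
}

#' Central tendency measure of second-order differences
#'
#' Fraction of consecutive second-difference pairs falling inside a circle of
#' radius `rho` — a dispersion measure of the second-order difference plot.
#'
#' @param x Numeric series.
#' @param rho Circle radius (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
ctm_measure <- function(x, rho = 1) {
  dd <- diff(x, differences = 2)
  if (length(dd) < 2) return(0)
  a <- dd[-length(dd)]
  b <- dd[-1]
  mean(sqrt(a^2 + b^2) < rho)
}

#' Phase-rectified signal averaging of decelerations
#'
#' Anchors at every sample lower than its predecessor; windows of `2 * t_win`
#' samples centred on the anchors are averaged into a PRSA curve. Returns the
#' central capacity (Bauer quad formula), the curve amplitude, the central
#' slope, and the slopes of the curve before and after the anchor.
#'
#' @param x Numeric series.
#' @param t_win Half-window in samples (default 10).
#' @return Named numeric: `prsa_c`, `prsa_ad`, `prsa_s`, `prsa_sb`, `prsa_sa`.
#' @export
prsa_features <- function(x, t_win = 10) {
  zero <- c(prsa_c = 0, prsa_ad = 0, prsa_s = 0, prsa_sb = 0, prsa_sa = 0)
  n <- length(x)
  anchors <- which(diff(x) < 0) + 1L
  anchors <- anchors[anchors > t_win & anchors + t_win - 1 <= n]
  if (length(anchors) == 0) return(zero)
  offs <- seq(-t_win, t_win - 1)
  win_idx <- outer(anchors, offs, "+")
  curve <- colMeans(matrix(x[win_idx], nrow = nrow(win_idx)))
  k0 <- t_win + 1 # position of offset 0
  cap <- (curve[k0] + curve[k0 + 1] - curve[k0 - 1] - curve[k0 - 2]) / 4
  sb <- unname(stats::coef(stats::lm(curve[1:t_win] ~ offs[1:t_win]))[2])
  sa <- unname(stats::coef(stats::lm(curve[(t_win + 1):(2 * t_win)] ~
                                       offs[(t_win + 1):(2 * t_win)]))[2])
  c(prsa_c = unname(cap), prsa_ad = max(curve) - min(curve),
    prsa_s = unname((curve[k0 + 1] - curve[k0 - 1]) / 2),
    prsa_sb = sb, prsa_sa = sa)
}

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapping segments, one-sided density normalized so
#' that the integral of the PSD over frequency equals the signal variance
#' (Parseval).
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param seg_len Segment length in samples (default 512, shrunk to the
#'   largest power of two available).
#' @return Tibble with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = 1, seg_len = 512) {
  n <- length(x)
  seg_len <- min(seg_len, 2^floor(log2(n)))
  step <- seg_len / 2
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / seg_len) # Hann
  u <- sum(w^2)
  acc <- numeric(seg_len %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs * u)
    half <- p[seq_len(seg_len %/% 2 + 1)]
    half[2:(seg_len %/% 2)] <- 2 * half[2:(seg_len %/% 2)]
    acc <- acc + half
  }
  tibble::tibble(freq = (0:(seg_len %/% 2)) * fs / seg_len,
                 psd = acc / length(starts))
}
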