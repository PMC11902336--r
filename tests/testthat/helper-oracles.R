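# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# sample entropy: direct O(n^2) template matching, strict < r, no self-match
sampen_bf <- function(x, m, r) {
  n <- length(x)
  a <- 0L
  b <- 0L
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        b <- b + 1L
        if (i + m <= n && j + m <= n &&
            max(abs(x[i:(i + m)] - x[j:(j + m)])) < r) a <- a + 1L
      }
    }
  }
  if (a == 0L || b == 0L) return(0)
  -log(a / b)
}

# approximate entropy: Pincus phi(m) - phi(m+1), <= r, self-match included
apen_bf <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cs <- vapply(1:nt, function(i) {
      sum(vapply(1:nt, function(j) {
        max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r
      }, logical(1)))
    }, numeric(1))
    mean(log(cs / nt))
  }
  phi(m) - phi(m + 1)
}

# LZ76 phrase count via exhaustive-history substring parsing
lz76_bf <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  if (n == 0) return(0L)
  cplx <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && grepl(substr(s, i, j), substr(s, 1, j - 1), fixed = TRUE)) {
      j <- j + 1L
    }
    cplx <- cplx + 1L
    if (j > n) break
    i <- j + 1L
  }
  cplx
}

# permutation entropy by explicit pattern tabulation
permen_bf <- function(x, m = 3) {
  n <- length(x)
  pats <- vapply(1:(n - m + 1), function(i) {
    paste(rank(x[i:(i + m - 1)], ties.method = "first"), collapse = "")
  }, character(1))
  p <- table(pats) / length(pats)
  -sum(p * log(p)) / log(factorial(m))
}

# ICC(2,1) from a two-way fixed-effects ANOVA table fitted with aov()
icc21_aov <- function(y_true, y_pred) {
  n <- length(y_true)
  d <- data.frame(
    value = c(y_true, y_pred),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  tab <- summary(stats::aov(value ~ subject + rater, data = d))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# macro F1 via per-class tabulation, classes present in truth or prediction
mf1_bf <- function(y_true, y_pred) {
  lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  f1s <- vapply(lev, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  }, numeric(1))
  mean(f1s)
}

# direct ridge solve used as the BLS oracle
ridge_oracle <- function(a, y, lambda) {
  solve(crossprod(a) + lambda * diag(ncol(a)), crossprod(a, y))
}

# hand-built recording for preprocessing tests
make_rec <- function(spo2, hypnogram, events = NULL, fs = 1,
                     ahi = 0, id = "T001") {
  structure(list(
    spo2 = spo2, fs = fs, hypnogram = hypnogram,
    events = if (is.null(events)) {
      tibble::tibble(start_s = numeric(), duration_s = numeric(),
                     type = character())
    } else events,
    demographics = tibble::tibble(age = 50, bmi = 25, sex = 0, smoking = 0),
    ahi_label = ahi, subject_id = id
  ), class = "oxi_recording")
}

# shared small cohort, built once per test session
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recs <- simulate_cohort(6, seed = 31, ahi_range = c(5, 45),
                              duration_min = 330)
      cache <<- prepare_cohort(recs)
    }
    cache
  }
})
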