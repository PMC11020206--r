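# Independent term-by-term evaluation of the weighted mean and its
# Taylor-linearized variance, written as plain loops so it shares no code
# path with the package implementation.
oracle_mean_se <- function(data, strata, psu, weight, y,
                           domain = rep(TRUE, nrow(data))) {
  yv <- data[[y]]
  D <- domain & !is.na(yv)
  W <- 0
  total <- 0
  for (i in seq_len(nrow(data))) {
    if (D[i]) {
      W <- W + data[[weight]][i]
      total <- total + data[[weight]][i] * yv[i]
    }
  }
  est <- total / W
  u <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    if (D[i]) u[i] <- data[[weight]][i] * (yv[i] - est) / W
  }
  variance <- 0
  for (h in unique(data[[strata]])) {
    rows_h <- which(data[[strata]] == h)
    psus <- unique(data[[psu]][rows_h])
    z <- vapply(psus, function(pj) {
      sum(u[rows_h][data[[psu]][rows_h] == pj])
    }, numeric(1))
    n_h <- length(z)
    zbar <- sum(z) / n_h
    ss <- 0
    for (zj in z) ss <- ss + (zj - zbar)^2
    variance <- variance + n_h / (n_h - 1) * ss
  }
  list(estimate = est, se = sqrt(variance), variance = variance)
}
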