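# Fixture builders and independent oracles shared across the test files.

# A ratings row with all fields zero unless overridden.
make_assessment <- function(biopsy_id = "b1", rater_id = "r1", ...) {
  base <- list(biopsy_id = biopsy_id, rater_id = rater_id, cab_count = 0,
               crypt_destruction = 0, crypt_loss = 0,
               epithelial_denudation = 0, architectural_distortion = 0,
               eosinophils_increased = 0, neutrophils_increased = 0)
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

# k raters for one biopsy; each ... argument is a length-k vector (or
# scalar) for one field.
make_panel <- function(biopsy_id = "b1", k = 4, ...) {
  over <- lapply(list(...), rep_len, k)
  rows <- lapply(seq_len(k), function(r) {
    do.call(make_assessment,
            c(list(biopsy_id = biopsy_id, rater_id = paste0("r", r)),
              lapply(over, `[[`, r)))
  })
  do.call(rbind, rows)
}

# --- Independent oracles ---------------------------------------------------

# Fleiss (1971) kappa, written as an explicit elementwise loop.
fleiss_oracle <- function(counts) {
  n <- nrow(counts)
  k <- sum(counts[1, ])
  P <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (cc in seq_len(ncol(counts))) {
      s <- s + counts[i, cc] * (counts[i, cc] - 1)
    }
    P[i] <- s / (k * (k - 1))
  }
  p <- numeric(ncol(counts))
  for (cc in seq_len(ncol(counts))) p[cc] <- sum(counts[, cc]) / (n * k)
  (mean(P) - sum(p^2)) / (1 - sum(p^2))
}

# ICC(A,1) with the mean squares taken from a stats::aov fit.
icc_oracle <- function(x) {
  d <- data.frame(y = as.vector(x),
                  subj = factor(as.vector(row(x))),
                  rater = factor(as.vector(col(x))))
  # a noise-free layout fits perfectly; the F-test warning is irrelevant
  # because only the mean squares are consumed
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ subj + rater, data = d))
  )[["Mean Sq"]]
  n <- nrow(x)
  k <- ncol(x)
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}

# Adjusted standardized residuals from the textbook formula.
beasley_oracle <- function(tab) {
  N <- sum(tab)
  r <- rowSums(tab)
  cs <- colSums(tab)
  E <- outer(r, cs) / N
  (tab - E) / sqrt(E * outer(1 - r / N, 1 - cs / N))
}

# Spearman rho as the Pearson correlation of average ranks, computed by
# hand (covariance over product of standard deviations).
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
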