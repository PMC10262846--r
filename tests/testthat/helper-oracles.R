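# Independent brute-force oracles and small fixture builders. These are
# deliberately written as direct transcriptions of the definitions, separate
# from the package's implementation paths.

# Weighted least squares through the origin: closed form.
bf_ivw <- function(be, bo, se_out) {
  w <- 1 / se_out^2
  beta <- sum(w * be * bo) / sum(w * be^2)
  se <- 1 / sqrt(sum(w * be^2))
  list(beta = beta, se = se)
}

# Weighted regression with intercept via the 2x2 normal equations.
bf_egger <- function(be, bo, se_out) {
  flip <- sign(be)
  flip[flip == 0] <- 1
  x <- be * flip; y <- bo * flip
  w <- 1 / se_out^2
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  intercept <- (swxx * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  resid <- y - intercept - slope * x
  q <- sum(w * resid^2)
  J <- length(x)
  sigma2 <- max(1, q / (J - 2))
  slope_se <- sqrt(sigma2 * sw / det)
  int_se <- sqrt(sigma2 * swxx / det)
  list(slope = slope, intercept = intercept, slope_se = slope_se,
       int_se = int_se, q = q)
}

# Direct transcription of the weighted-median interpolation rule.
bf_weighted_median <- function(ratio, w) {
  o <- order(ratio)
  b <- ratio[o]; ww <- w[o] / sum(w)
  s <- numeric(length(b))
  acc <- 0
  for (j in seq_along(b)) {
    s[j] <- acc + ww[j] / 2
    acc <- acc + ww[j]
  }
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  k <- max(which(s <= 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Grid-KDE argmax with explicit loops.
bf_mode <- function(ratio, w, phi = 1, weighted = TRUE) {
  J <- length(ratio)
  if (!weighted) w <- rep(1, J)
  w <- w / sum(w)
  h <- phi * 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * J^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratio[which.max(w)])
  grid <- seq(min(ratio) - h, max(ratio) + h, length.out = 512)
  best <- grid[1]; best_d <- -Inf
  for (g in grid) {
    d <- 0
    for (j in seq_len(J))
      d <- d + w[j] * exp(-(g - ratio[j])^2 / (2 * h^2)) / (h * sqrt(2 * pi))
    if (d > best_d) { best_d <- d; best <- g }
  }
  best
}

# Greedy clumping by literal restatement of the rule, on plain vectors.
bf_clump_ids <- function(df, ld, window_kb = 5000, r2_threshold = 0.01) {
  remaining <- df[order(df$pval, df$chrom, df$pos, df$variant_id), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$variant_id)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      r <- remaining[i, ]
      if (r$chrom != idx$chrom) next
      if (abs(r$pos - idx$pos) > window_kb * 1000) next
      r2 <- if (idx$variant_id %in% rownames(ld) &&
                r$variant_id %in% colnames(ld))
        ld[idx$variant_id, r$variant_id] else 0
      drop[i] <- r2 > r2_threshold
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# Numerical delta-method SE for the ratio bo/be.
bf_numeric_delta_se <- function(be, se_exp, bo, se_out,
                                second_order = FALSE, eps = 1e-6) {
  f <- function(x, y) y / x
  gx <- (f(be + eps, bo) - f(be - eps, bo)) / (2 * eps)
  gy <- (f(be, bo + eps) - f(be, bo - eps)) / (2 * eps)
  if (second_order) sqrt(gx^2 * se_exp^2 + gy^2 * se_out^2)
  else sqrt(gy^2 * se_out^2)
}

# Small harmonized set drawn directly from the two-sample model (independent
# of the package's generator).
make_hset <- function(J, theta = 0.7, seed = 1, alpha = rep(0, J),
                      gamma = NULL, se_exp = 0.005, se_out = 0.01) {
  set.seed(seed)
  if (is.null(gamma)) gamma <- rnorm(J, 0.08, 0.02)
  se_exp <- rep(se_exp, length.out = J)
  se_out <- rep(se_out, length.out = J)
  harmonized_set(variant_id = sprintf("v%03d", seq_len(J)),
                 beta_exp = rnorm(J, gamma, se_exp), se_exp = se_exp,
                 beta_out = rnorm(J, theta * gamma + alpha, se_out),
                 se_out = se_out)
}

# Tiny generic summary-stats data.frame.
make_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(variant_id = sprintf("rs%04d", seq_len(n)),
             chrom = as.character(sample(1:2, n, replace = TRUE)),
             pos = sort(sample.int(1e8, n)),
             effect_allele = sample(c("A", "G"), n, replace = TRUE),
             other_allele = "C",
             eaf = runif(n, 0.05, 0.95),
             beta = rnorm(n, 0, 0.1),
             se = runif(n, 0.005, 0.05),
             pval = runif(n),
             n = 1e5,
             stringsAsFactors = FALSE)
}
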