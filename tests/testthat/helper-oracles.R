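# Naive, independent reimplementations used as oracles. Each characteristic
# is written directly from its definition, one small function per
# characteristic, sharing no code with the package implementation.

oracle_characteristics <- list(
  maximum = function(x) max(x),
  minimum = function(x) min(x),
  mean = function(x) sum(x) / length(x),
  variance = function(x) sum((x - mean(x))^2) / length(x),
  std = function(x) sqrt(sum((x - mean(x))^2) / length(x)),
  skewness = function(x) {
    n <- length(x)
    s <- sqrt(sum((x - mean(x))^2) / n)
    if (s == 0 || n < 3) return(0)
    g1 <- (sum((x - mean(x))^3) / n) / s^3
    g1 * sqrt(n * (n - 1)) / (n - 2)
  },
  kurtosis = function(x) {
    n <- length(x)
    m2 <- sum((x - mean(x))^2) / n
    if (m2 == 0 || n < 4) return(0)
    g2 <- (sum((x - mean(x))^4) / n) / m2^2 - 3
    ((n - 1) / ((n - 2) * (n - 3))) * ((n + 1) * g2 + 6)
  },
  median = function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  },
  abs_energy = function(x) sum(x^2),
  abs_sum_changes = function(x) {
    total <- 0
    for (i in seq_len(length(x) - 1)) total <- total + abs(x[i + 1] - x[i])
    total
  },
  var_gt_std = function(x) {
    v <- sum((x - mean(x))^2) / length(x)
    as.numeric(v > sqrt(v))
  },
  count_above_mean = function(x) sum(x > mean(x)),
  count_below_mean = function(x) sum(x < mean(x)),
  first_loc_max = function(x) (which(x == max(x))[1] - 1) / length(x),
  last_loc_max = function(x) {
    idx <- which(x == max(x))
    idx[length(idx)] / length(x)
  },
  first_loc_min = function(x) (which(x == min(x))[1] - 1) / length(x),
  last_loc_min = function(x) {
    idx <- which(x == min(x))
    idx[length(idx)] / length(x)
  },
  has_duplicate = function(x) as.numeric(any(duplicated(x))),
  has_duplicate_max = function(x) as.numeric(sum(x == max(x)) > 1),
  has_duplicate_min = function(x) as.numeric(sum(x == min(x)) > 1),
  longest_strike_above_mean = function(x) {
    r <- rle(x > mean(x))
    if (!any(r$values)) 0 else max(r$lengths[r$values])
  },
  longest_strike_below_mean = function(x) {
    r <- rle(x < mean(x))
    if (!any(r$values)) 0 else max(r$lengths[r$values])
  },
  mean_abs_change = function(x) mean(abs(diff(x))),
  mean_change = function(x) (x[length(x)] - x[1]) / (length(x) - 1),
  pct_reoccurring_points = function(x) {
    dup_vals <- unique(x[duplicated(x)])
    sum(x %in% dup_vals) / length(x)
  },
  ratio_unique_values = function(x) length(unique(x)) / length(x),
  sum_reoccurring_points = function(x) {
    dup_vals <- unique(x[duplicated(x)])
    sum(x[x %in% dup_vals])
  },
  sum_reoccurring_values = function(x) {
    sum(unique(x[duplicated(x)]))
  },
  sum_values = function(x) sum(x),
  range = function(x) max(x) - min(x)
)

# univariate regression F from the explicit SSR/SSE decomposition
oracle_f_ols <- function(feature, y) {
  fit <- stats::lm(y ~ feature)
  ssr <- sum((stats::fitted(fit) - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  (ssr / 1) / (sse / (length(y) - 2))
}

# textbook Pearson r and t-based p value
oracle_pearson <- function(a, b) {
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# soft-thresholding map
oracle_soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
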