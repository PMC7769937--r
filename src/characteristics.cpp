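#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// The 30-characteristic catalogue, computed per column of `x`.
// Row order matches ts_characteristic_names() on the R side:
//  0 maximum                  15 last_loc_min
//  1 minimum                  16 (see below)
//  2 mean                     17 has_duplicate
//  3 variance (population)    18 has_duplicate_max
//  4 std                      19 has_duplicate_min
//  5 skewness (adj. F-P)      20 longest_strike_above_mean
//  6 kurtosis (adj. excess)   21 longest_strike_below_mean
//  7 median                   22 mean_abs_change
//  8 abs_energy               23 mean_change
//  9 abs_sum_changes          24 pct_reoccurring_points
// 10 var_gt_std               25 ratio_unique_values
// 11 count_above_mean         26 sum_reoccurring_points
// 12 count_below_mean         27 sum_reoccurring_values
// 13 first_loc_max            28 sum_values
// 14 last_loc_max             29 range
// (13..16: first/last location of maximum, then of minimum; first locations
// are 0-based-index/n, last locations are 1-based-index/n)

// [[Rcpp::export]]
NumericMatrix cpp_characteristics(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  if (n < 2) stop("each series must have at least 2 observations");
  NumericMatrix out(30, m);
  std::vector<double> v(n), s(n);

  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      v[i] = x(i, j);
      if (!R_finite(v[i])) stop("non-finite value in series");
    }

    // accumulate in long double and refine the mean with a second pass,
    // matching base R's mean()/sum() so that exact ties with the mean are
    // classified identically
    long double sum_l = 0.0L, energy_l = 0.0L;
    double mx = v[0], mn = v[0];
    int first_argmax = 0, last_argmax = 0, first_argmin = 0, last_argmin = 0;
    for (int i = 0; i < n; ++i) {
      sum_l += v[i];
      energy_l += (long double)v[i] * v[i];
      if (v[i] > mx) { mx = v[i]; first_argmax = i; last_argmax = i; }
      else if (v[i] == mx && i > 0) { last_argmax = i; }
      if (v[i] < mn) { mn = v[i]; first_argmin = i; last_argmin = i; }
      else if (v[i] == mn && i > 0) { last_argmin = i; }
    }
    long double mean_l = sum_l / n;
    long double corr = 0.0L;
    for (int i = 0; i < n; ++i) corr += v[i] - mean_l;
    mean_l += corr / n;
    const double mean = (double)mean_l;
    const double sum = (double)sum_l;
    const double energy = (double)energy_l;

    // central moments (population) + counts and strikes around the mean
    long double m2_l = 0.0L, m3_l = 0.0L, m4_l = 0.0L;
    int above = 0, below = 0;
    int strike_above = 0, strike_below = 0, cur_above = 0, cur_below = 0;
    for (int i = 0; i < n; ++i) {
      const long double d = v[i] - mean;
      const long double d2 = d * d;
      m2_l += d2; m3_l += d2 * d; m4_l += d2 * d2;
      if (v[i] > mean) {
        ++above; ++cur_above; cur_below = 0;
        if (cur_above > strike_above) strike_above = cur_above;
      } else if (v[i] < mean) {
        ++below; ++cur_below; cur_above = 0;
        if (cur_below > strike_below) strike_below = cur_below;
      } else {
        cur_above = 0; cur_below = 0;
      }
    }
    const double m2 = (double)(m2_l / n);
    const double m3 = (double)(m3_l / n);
    const double m4 = (double)(m4_l / n);
    const double variance = m2;
    const double stdev = std::sqrt(variance);

    double skew = 0.0, kurt = 0.0;
    if (stdev > 0.0 && n >= 3) {
      const double g1 = m3 / (stdev * stdev * stdev);
      skew = g1 * std::sqrt((double)n * (n - 1.0)) / (n - 2.0);
    }
    if (stdev > 0.0 && n >= 4) {
      const double g2 = m4 / (variance * variance) - 3.0;
      kurt = ((n - 1.0) / ((n - 2.0) * (n - 3.0))) * ((n + 1.0) * g2 + 6.0);
    }

    long double abs_changes_l = 0.0L;
    for (int i = 1; i < n; ++i) abs_changes_l += std::fabs(v[i] - v[i - 1]);
    const double abs_changes = (double)abs_changes_l;

    // sorted copy: median + duplicate-value accounting
    std::copy(v.begin(), v.end(), s.begin());
    std::sort(s.begin(), s.end());
    const double med = (n % 2 == 1)
      ? s[n / 2]
      : 0.5 * (s[n / 2 - 1] + s[n / 2]);

    int n_unique = 0, n_reoccurring_points = 0;
    long double sum_reoccurring_points = 0.0L, sum_reoccurring_values = 0.0L;
    bool has_dup = false;
    int i = 0;
    while (i < n) {
      int k = i + 1;
      while (k < n && s[k] == s[i]) ++k;
      const int run = k - i;
      ++n_unique;
      if (run > 1) {
        has_dup = true;
        n_reoccurring_points += run;
        sum_reoccurring_points += s[i] * run;
        sum_reoccurring_values += s[i];
      }
      i = k;
    }
    const bool dup_max = (n >= 2) && (s[n - 1] == s[n - 2]);
    const bool dup_min = (n >= 2) && (s[0] == s[1]);

    out(0, j) = mx;
    out(1, j) = mn;
    out(2, j) = mean;
    out(3, j) = variance;
    out(4, j) = stdev;
    out(5, j) = skew;
    out(6, j) = kurt;
    out(7, j) = med;
    out(8, j) = energy;
    out(9, j) = abs_changes;
    out(10, j) = (variance > stdev) ? 1.0 : 0.0;
    out(11, j) = above;
    out(12, j) = below;
    out(13, j) = (double)first_argmax / n;
    out(14, j) = (double)(last_argmax + 1) / n;
    out(15, j) = (double)first_argmin / n;
    out(16, j) = (double)(last_argmin + 1) / n;
    out(17, j) = has_dup ? 1.0 : 0.0;
    out(18, j) = dup_max ? 1.0 : 0.0;
    out(19, j) = dup_min ? 1.0 : 0.0;
    out(20, j) = strike_above;
    out(21, j) = strike_below;
    out(22, j) = abs_changes / (n - 1.0);
    out(23, j) = (v[n - 1] - v[0]) / (n - 1.0);
    out(24, j) = (double)n_reoccurring_points / n;
    out(25, j) = (double)n_unique / n;
    out(26, j) = (double)sum_reoccurring_points;
    out(27, j) = (double)sum_reoccurring_values;
    out(28, j) = sum;
    out(29, j) = mx - mn;
  }
  return out;
}

// recursive AR(1) filter per column: out[0,] = x[0,]; out[t,] = x[t,] +
// phi * out[t-1,]
// [[Rcpp::export]]
NumericMatrix cpp_ar1_filter(NumericMatrix x, double phi) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    double prev = x(0, j);
    out(0, j) = prev;
    for (int i = 1; i < n; ++i) {
      prev = x(i, j) + phi * prev;
      out(i, j) = prev;
    }
  }
  return out;
}
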