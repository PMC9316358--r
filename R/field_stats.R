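#' Summarize an environmental logger series per depth
#'
#' Computes, for each depth label present, the temperature minimum, maximum,
#' mean and coefficient of variation (sample sd / mean, on the raw degrees-C
#' scale unless `kelvin = TRUE`), the mean light, and the maximum light among
#' records whose local clock time falls inside a daily window (default
#' 10:00-16:00 inclusive, the diurnal light peak).
#'
#' @param series data.frame with columns timestamp (ISO-8601 local time),
#'   temperature_C, light_lux, depth.
#' @param window length-2 character vector `c(start, end)` in `HH:MM`.
#' @param kelvin compute the temperature CV on the Kelvin scale.
#' @return data.frame with one row per depth: depth, n, temp_min, temp_max,
#'   temp_mean, temp_cv, light_mean, light_max_window, window_start,
#'   window_end.
#' @export
summarize_logger <- function(series, window = c("10:00", "16:00"),
                             kelvin = FALSE) {
  need <- c("timestamp", "temperature_C", "light_lux", "depth")
  if (!all(need %in% names(series))) {
    fail("logger series must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(series$light_lux < 0)) fail("light must be >= 0")
  to_min <- function(hm) {
    p <- as.integer(strsplit(hm, ":")[[1]])
    p[1] * 60L + p[2]
  }
  w0 <- to_min(window[1]); w1 <- to_min(window[2])
  out <- lapply(unique(series$depth), function(d) {
    s <- series[series$depth == d, , drop = FALSE]
    if (nrow(s) < 2) fail("fewer than 2 records for depth %s", d)
    s <- s[order(s$timestamp), , drop = FALSE]
    clock <- vapply(s$timestamp, function(ts) {
      hm <- sub("^.*[T ](\\d{2}):(\\d{2}).*$", "\\1:\\2", ts)
      to_min(hm)
    }, integer(1))
    in_window <- clock >= w0 & clock <= w1
    temp <- s$temperature_C + if (kelvin) 273.15 else 0
    data.frame(
      depth = d, n = nrow(s),
      temp_min = min(s$temperature_C),
      temp_max = max(s$temperature_C),
      temp_mean = mean(s$temperature_C),
      temp_cv = stats::sd(temp) / mean(temp),
      light_mean = mean(s$light_lux),
      light_max_window = if (any(in_window)) max(s$light_lux[in_window]) else NA_real_,
      window_start = window[1], window_end = window[2],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval via Beta-distribution quantiles:
#' lower = qbeta(a/2; k, n-k+1) (0 when k = 0) and
#' upper = qbeta(1-a/2; k+1, n-k) (1 when k = n), with a = 1 - conf.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, > 0.
#' @param conf confidence level in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(k, n, conf = 0.95) {
  if (!is_count(n) || n == 0) fail("n must be a positive integer")
  if (!is_count(k) || k > n) fail("k must be an integer in [0, n]")
  if (conf <= 0 || conf >= 1) fail("conf must be in (0, 1)")
  a <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction the statistic has the closed form
#' N (ad - bc)^2 / (r1 r2 c1 c2); the Yates correction subtracts N/2 from
#' |ad - bc| first (floored at 0). The p-value comes from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param continuity_correction apply the Yates correction.
#' @return list with `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) fail("table must be 2x2")
  if (any(table < 0)) fail("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) fail("zero margin in 2x2 table")
  det <- abs(table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])
  if (continuity_correction) det <- max(0, det - n / 2)
  stat <- n * det^2 / prod(rs, cs)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare survival between groups at each timepoint
#'
#' At every census time, builds the 2x2 alive/dead by group table and runs an
#' independent chi-square test with Clopper-Pearson intervals per group.
#'
#' @param survival data.frame with columns group, timepoint, n_alive,
#'   n_total (two groups).
#' @param conf confidence level for the per-group survival intervals.
#' @param continuity_correction passed to [chisq_2x2()].
#' @return data.frame with one row per timepoint x group carrying the shared
#'   chi-square statistic/p and the group's survival proportion and CI.
#' @export
survival_tests <- function(survival, conf = 0.95, continuity_correction = FALSE) {
  groups <- unique(survival$group)
  if (length(groups) != 2) fail("survival table must contain exactly two groups")
  out <- list()
  for (tp in unique(survival$timepoint)) {
    s <- survival[survival$timepoint == tp, , drop = FALSE]
    s <- s[match(groups, s$group), , drop = FALSE]
    tab <- cbind(alive = s$n_alive, dead = s$n_total - s$n_alive)
    ct <- chisq_2x2(tab, continuity_correction)
    for (i in 1:2) {
      ci <- clopper_pearson_ci(s$n_alive[i], s$n_total[i], conf)
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp, group = groups[i],
        n_alive = s$n_alive[i], n_total = s$n_total[i],
        proportion = s$n_alive[i] / s$n_total[i],
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        chisq = ct$statistic, p_value = ct$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
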