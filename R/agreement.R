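#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements combining precision (Pearson's r)
#' and accuracy (bias-correction factor Cb):
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' plug-in (1/n) moments, and `Cb = CCC / r`. The confidence interval is a
#' seeded percentile bootstrap over paired resampling.
#'
#' @param x,y paired numeric vectors (length >= 3)
#' @param n_boot bootstrap replicates (default 2000)
#' @param seed integer seed for the bootstrap
#' @param conf confidence level (default 0.95)
#' @return a `ccc_result`: list with `ccc`, `ci95`, `pearson_r`, `cb`, `n`
#' @export
ccc <- function(x, y, n_boot = 2000, seed = 1, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  est <- function(x, y) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    sx <- mean((x - mx)^2); sy <- mean((y - my)^2)
    sxy <- mean((x - mx) * (y - my))
    if (sx == 0 || sy == 0) return(NA_real_)
    2 * sxy / (sx + sy + (mx - my)^2)
  }
  point <- est(x, y)
  if (is.na(point)) stop("CCC undefined: zero variance in one input")
  r <- stats::cor(x, y)
  boot <- with_seed(seed, {
    n <- length(x)
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      est(x[i], y[i])
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(ccc = point, ci95 = ci, pearson_r = r, cb = point / r,
                 n = length(x)),
            class = "ccc_result")
}

#' Two one-sided tests (TOST) for equivalence of paired differences
#'
#' Paired t-based TOST against symmetric bounds on the log scale: the mean
#' difference is tested above `-bound` and below `+bound` with one-sided
#' t-tests; equivalence is declared when both reject at `alpha`, which is
#' identical to the 90% CI of the mean difference lying inside
#' `(-bound, +bound)`. Zero-variance differences degenerate to an exact
#' point comparison of the mean against the bounds.
#'
#' @param diffs vector of paired differences (ln units), length >= 3
#' @param bound equivalence half-width (default 0.05 ln units)
#' @param alpha one-sided test level (default 0.05)
#' @return a `tost_result`: list with `mean_diff`, `ci90`, `bound`,
#'   `p_lower`, `p_upper`, `p_tost`, `equivalent`, `n`
#' @export
tost <- function(diffs, bound = 0.05, alpha = 0.05) {
  stopifnot(length(diffs) >= 3, bound > 0)
  n <- length(diffs)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  df <- n - 1
  if (s == 0) {
    inside <- abs(m) < bound
    return(structure(list(mean_diff = m, ci90 = c(m, m), bound = bound,
                          p_lower = as.numeric(!inside & m <= -bound),
                          p_upper = as.numeric(!inside & m >= bound),
                          p_tost = as.numeric(!inside),
                          equivalent = inside, n = n),
                     class = "tost_result"))
  }
  se <- s / sqrt(n)
  t_lower <- (m + bound) / se          # H0: m <= -bound
  t_upper <- (m - bound) / se          # H0: m >= +bound
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  ci90 <- m + c(-1, 1) * stats::qt(1 - alpha, df) * se
  p_tost <- max(p_lower, p_upper)
  structure(list(mean_diff = m, ci90 = ci90, bound = bound,
                 p_lower = p_lower, p_upper = p_upper, p_tost = p_tost,
                 equivalent = p_tost < alpha, n = n),
            class = "tost_result")
}

#' Holm step-down multiple-testing adjustment
#'
#' Family-wise error control by the step-down Holm procedure with
#' monotonicity enforcement, capped at 1.
#'
#' @param p_values vector of p-values in `[0, 1]`
#' @return adjusted p-values in the original order
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression robust to measurement error in both variables:
#' the slope is the shifted median of all pairwise slopes (pairs with equal
#' x are skipped; slopes exactly -1 are excluded; the offset K counts
#' slopes below -1), the intercept is `median(y - slope * x)`, and the
#' slope CI is rank-based. Slope different from 1 indicates proportional
#' bias; intercept different from 0, constant bias.
#'
#' @param x,y paired numeric vectors (n >= 10 recommended, positive
#'   association assumed)
#' @param conf confidence level (default 0.95)
#' @return a `pbr_fit`: list with `slope`, `intercept`, `slope_ci95`,
#'   `intercept_ci95`, `n`
#' @export
passing_bablok <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  ok <- dx != 0
  s <- dy[ok] / dx[ok]
  s <- s[s != -1]
  if (length(s) == 0) stop("undefined slope: all x values identical")
  K <- sum(s < -1)
  S <- sort(s)
  N <- length(S)
  med_at <- function(offset) {
    # shifted median with offset, clamped to valid ranks
    if (N %% 2 == 1) {
      S[min(max((N + 1) / 2 + offset, 1), N)]
    } else {
      i <- min(max(N / 2 + offset, 1), N - 1)
      0.5 * (S[i] + S[i + 1])
    }
  }
  slope <- med_at(K)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  slope_ci <- c(S[min(max(M1 + K, 1), N)], S[min(max(M2 + K, 1), N)])
  intercept <- stats::median(y - slope * x)
  intercept_ci <- sort(c(stats::median(y - slope_ci[2] * x),
                         stats::median(y - slope_ci[1] * x)))
  structure(list(slope = slope, intercept = intercept,
                 slope_ci95 = slope_ci, intercept_ci95 = intercept_ci,
                 n = n),
            class = "pbr_fit")
}

#' Bland-Altman limits of agreement
#'
#' Bias (mean difference), SD of differences (sample, n-1) and the 95%
#' limits of agreement `bias +/- 1.96 SD`. Differences are oriented
#' `x - y` (test minus reference; PPG minus ECG in the benchmark).
#'
#' @param x,y paired numeric vectors (length >= 2)
#' @return a `ba_result`: list with `bias`, `sd_diff`, `loa`, `n`
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_d,
                 loa = c(bias - 1.96 * sd_d, bias + 1.96 * sd_d),
                 n = length(d)),
            class = "ba_result")
}

#' Integrated agreement report over paired index tables
#'
#' Joins a test-method index table (PPG) with a reference table (ECG) on
#' `(subject, segment)` and, for every combination of band (`ln_hf`,
#' `ln_lf`, `ln_vlf`) and configuration (`filter`, `fs`) present in the
#' test table, computes Lin's CCC with bootstrap CI, the paired TOST, a
#' Passing-Bablok fit and Bland-Altman summaries. Equivalence verdicts use
#' Holm-adjusted TOST p-values with the family spanning every row of the
#' report. Differences are oriented test minus reference.
#'
#' @param test data.frame with columns `subject`, `segment`, `filter`,
#'   `fs`, `ln_vlf`, `ln_lf`, `ln_hf`
#' @param reference data.frame with columns `subject`, `segment`,
#'   `ln_vlf`, `ln_lf`, `ln_hf`
#' @param bound TOST equivalence half-width (default 0.05 ln units)
#' @param alpha test level (default 0.05)
#' @param n_boot bootstrap replicates for the CCC CI
#' @param seed integer seed
#' @return data.frame with one row per (band, filter, fs): columns `band`,
#'   `filter`, `fs`, `n`, `ccc`, `ci_lo`, `ci_hi`, `r`, `cb`, `mean_diff`,
#'   `ci90_lo`, `ci90_hi`, `pb_slope`, `pb_intercept`, `ba_bias`,
#'   `ba_loa_lo`, `ba_loa_hi`, `p_tost`, `p_tost_adj`, `equivalent`
#' @export
build_report <- function(test, reference, bound = 0.05, alpha = 0.05,
                         n_boot = 2000, seed = 1) {
  need_t <- c("subject", "segment", "filter", "fs", "ln_vlf", "ln_lf", "ln_hf")
  need_r <- c("subject", "segment", "ln_vlf", "ln_lf", "ln_hf")
  stopifnot(all(need_t %in% names(test)), all(need_r %in% names(reference)))
  merged <- merge(test, reference, by = c("subject", "segment"),
                  suffixes = c("_ppg", "_ecg"))
  if (nrow(merged) < nrow(test)) {
    miss <- setdiff(paste(test$subject, test$segment),
                    paste(reference$subject, reference$segment))
    stop("unmatched (subject, segment) pairs: ", paste(miss, collapse = ", "))
  }
  configs <- unique(test[, c("filter", "fs")])
  configs <- configs[order(configs$filter, configs$fs), ]
  bands <- c("ln_hf", "ln_lf", "ln_vlf")
  rows <- list()
  for (band in bands) {
    for (ci in seq_len(nrow(configs))) {
      sub <- merged[merged$filter == configs$filter[ci] &
                    merged$fs == configs$fs[ci], ]
      sub <- sub[order(sub$subject, sub$segment), ]
      px <- sub[[paste0(band, "_ppg")]]
      ex <- sub[[paste0(band, "_ecg")]]
      cc <- ccc(px, ex, n_boot = n_boot,
                seed = derive_seed(seed, match(band, bands), ci))
      ts <- tost(px - ex, bound = bound, alpha = alpha)
      pb <- passing_bablok(ex, px)     # reference on x, test on y
      ba <- bland_altman(px, ex)
      rows[[length(rows) + 1]] <- data.frame(
        band = band, filter = configs$filter[ci], fs = configs$fs[ci],
        n = nrow(sub),
        ccc = cc$ccc, ci_lo = cc$ci95[1], ci_hi = cc$ci95[2],
        r = cc$pearson_r, cb = cc$cb,
        mean_diff = ts$mean_diff, ci90_lo = ts$ci90[1], ci90_hi = ts$ci90[2],
        pb_slope = pb$slope, pb_intercept = pb$intercept,
        ba_bias = ba$bias, ba_loa_lo = ba$loa[1], ba_loa_hi = ba$loa[2],
        p_tost = ts$p_tost, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_tost_adj <- holm_adjust(out$p_tost)
  out$equivalent <- out$p_tost_adj < alpha
  rownames(out) <- NULL
  out
}
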