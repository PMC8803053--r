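#' Paired per-subject measurements from two methods
#'
#' Rows with a missing value in either method are dropped (listwise
#' deletion); the number dropped is recorded.
#'
#' @param subject_ids subject identifiers.
#' @param method_a,method_b numeric measurements, one per subject.
#' @param variable_name label of the measured variable (e.g. `"area"`).
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(subject_ids, method_a, method_b,
                                variable_name = "value") {
  if (length(method_a) != length(method_b) ||
      length(subject_ids) != length(method_a))
    stop("subject_ids, method_a and method_b must have equal length")
  ok <- is.finite(method_a) & is.finite(method_b)
  n_dropped <- sum(!ok)
  if (sum(ok) < 2) stop("need at least 2 complete subject pairs")
  structure(list(subject_ids = subject_ids[ok],
                 method_a = as.numeric(method_a[ok]),
                 method_b = as.numeric(method_b[ok]),
                 variable_name = variable_name,
                 n_dropped = n_dropped),
            class = "paired_measurements")
}

# two-way (subject x rater) ANOVA mean squares from an n x k matrix
.two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1),
       msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)),
       n = n, k = k)
}

.reliability_label <- function(ci_low) {
  if (!is.finite(ci_low)) return(NA_character_)
  if (ci_low >= 0.90) "excellent"
  else if (ci_low >= 0.75) "good"
  else if (ci_low >= 0.50) "moderate"
  else "poor"
}

#' Intraclass correlation, two-way mixed effects, single measures
#'
#' The consistency form ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE) from
#' the two-way ANOVA decomposition of the n x k subject-by-method matrix;
#' it ignores a fixed shift between methods. The F statistic MSR/MSE with
#' df (n-1) and (n-1)(k-1) gives the test of ICC = 0 and the confidence
#' interval (Shrout-Fleiss). The absolute-agreement form ICC(A,1), which
#' penalizes fixed shifts, is available via `type = "agreement"` with its
#' McGraw-Wong interval.
#'
#' @param data a [paired_measurements()] or an n x k numeric matrix
#'   (subjects in rows, methods/raters in columns).
#' @param alpha two-sided confidence level is `1 - alpha`.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `f_stat`, `f_df1`, `f_df2`, `f_pvalue`, `n`, `k`, `type`,
#'   `reliability` (label from the lower CI bound), `status`
#'   (`"ok"` or `"degenerate"` when all values are identical).
#' @export
icc_consistency <- function(data, alpha = 0.05,
                            type = c("consistency", "agreement")) {
  type <- match.arg(type)
  m <- if (inherits(data, "paired_measurements"))
    cbind(data$method_a, data$method_b) else as.matrix(data)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 subjects and 2 methods")
  ms <- .two_way_ms(m)
  n <- ms$n; k <- ms$k
  if (ms$msr < .Machine$double.eps && ms$mse < .Machine$double.eps) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, f_stat = NA_real_,
                          f_df1 = n - 1, f_df2 = (n - 1) * (k - 1),
                          f_pvalue = NA_real_, n = n, k = k, type = type,
                          reliability = NA_character_,
                          status = "degenerate"),
                     class = "icc_result"))
  }
  f <- ms$msr / ms$mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  if (type == "consistency") {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    ci_low <- (fl - 1) / (fl + k - 1)
    ci_high <- (fu - 1) / (fu + k - 1)
  } else {
    icc <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k / n * (ms$msc - ms$mse))
    # McGraw & Wong (1996) interval with Satterthwaite df
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f_star <- qf(1 - alpha / 2, n - 1, v)
    ci_low <- n * (ms$msr - f_star * ms$mse) /
      (f_star * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    f_star2 <- qf(1 - alpha / 2, v, n - 1)
    ci_high <- n * (f_star2 * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_star2 * ms$msr)
  }
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 f_stat = f, f_df1 = df1, f_df2 = df2,
                 f_pvalue = pf(f, df1, df2, lower.tail = FALSE),
                 n = n, k = k, type = type,
                 reliability = .reliability_label(ci_low),
                 status = "ok"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (identical(x$status, "degenerate")) {
    cat("<icc_result> degenerate (no variance)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<icc_result> ICC(%s,1) = %.3f [%.3f, %.3f], F(%d,%d) = %.2f, p = %.3g (%s)\n",
    if (x$type == "consistency") "C" else "A",
    x$icc, x$ci_low, x$ci_high, x$f_df1, x$f_df2, x$f_stat, x$f_pvalue,
    x$reliability))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are method A minus method B. Limits of agreement are
#' `mean_diff +/- 1.96 * sd_diff` (sample SD). The per-subject
#' (mean, difference) table for plotting is included.
#'
#' @param data a [paired_measurements()].
#' @param loa_multiplier multiplier for the limits of agreement.
#' @return List of class `bland_altman_result`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and data.frame `points`
#'   (`subject_id`, `mean`, `diff`).
#' @export
bland_altman <- function(data, loa_multiplier = 1.96) {
  stopifnot(inherits(data, "paired_measurements"))
  d <- data$method_a - data$method_b
  if (length(d) < 2) stop("need at least 2 subject pairs")
  md <- mean(d); s <- sd(d)
  structure(
    list(mean_diff = md, sd_diff = s,
         loa_low = md - loa_multiplier * s,
         loa_high = md + loa_multiplier * s,
         loa_multiplier = loa_multiplier,
         n = length(d),
         points = data.frame(subject_id = data$subject_ids,
                             mean = (data$method_a + data$method_b) / 2,
                             diff = d)),
    class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.4g (SD %.4g), LoA [%.4g, %.4g], n = %d\n",
    x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Ordinary least-squares regression of method B on method A
#'
#' @param data a [paired_measurements()] with at least 3 pairs and
#'   non-constant method A.
#' @return List: `slope`, `intercept`, `r` (Pearson), `n`.
#' @export
paired_regression <- function(data) {
  stopifnot(inherits(data, "paired_measurements"))
  a <- data$method_a; b <- data$method_b
  if (length(a) < 3) stop("need at least 3 subject pairs")
  if (var(a) <= 0) stop("method A has zero variance")
  fit <- lm(b ~ a)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(a, b), n = length(a))
}

#' Full inter-method agreement analysis
#'
#' Combines [icc_consistency()], [bland_altman()] and
#' [paired_regression()] into one result.
#'
#' @param data a [paired_measurements()].
#' @param alpha significance level for the ICC interval.
#' @return List of class `agreement_result` with elements `icc`,
#'   `bland_altman`, `regression`, `variable_name`, `n`.
#' @export
agreement_analysis <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "paired_measurements"))
  structure(
    list(icc = icc_consistency(data, alpha = alpha),
         bland_altman = bland_altman(data),
         regression = if (length(data$method_a) >= 3 && var(data$method_a) > 0)
           paired_regression(data) else NULL,
         variable_name = data$variable_name,
         n = length(data$method_a),
         n_dropped = data$n_dropped),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> variable '%s', n = %d (%d dropped)\n",
              x$variable_name, x$n, x$n_dropped))
  print(x$icc)
  print(x$bland_altman)
  if (!is.null(x$regression))
    cat(sprintf("  regression: B = %.4g + %.4g A, r = %.4f\n",
                x$regression$intercept, x$regression$slope, x$regression$r))
  invisible(x)
}

#' Read paired measurements from CSV
#'
#' Accepts wide format (columns `subject_id`, `a_value`, `b_value`) or
#' long format (columns `subject_id`, `method`, `variable`, `value` with
#' exactly two method levels).
#'
#' @param path CSV file.
#' @param variable in long format, which variable to extract; default the
#'   first present.
#' @return A [paired_measurements()].
#' @export
read_paired_csv <- function(path, variable = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("subject_id", "a_value", "b_value") %in% names(df))) {
    return(paired_measurements(df$subject_id, df$a_value, df$b_value,
                               variable_name = variable %||% "value"))
  }
  if (all(c("subject_id", "method", "variable", "value") %in% names(df))) {
    if (is.null(variable)) variable <- df$variable[1]
    df <- df[df$variable == variable, ]
    methods <- sort(unique(df$method))
    if (length(methods) != 2) stop("long format needs exactly 2 methods")
    a <- df[df$method == methods[1], c("subject_id", "value")]
    b <- df[df$method == methods[2], c("subject_id", "value")]
    mg <- merge(a, b, by = "subject_id", suffixes = c("_a", "_b"))
    return(paired_measurements(mg$subject_id, mg$value_a, mg$value_b,
                               variable_name = variable))
  }
  stop("unrecognized paired-measurement CSV layout")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an agreement result (and its plot tables) to CSV
#'
#' One-row summary CSV plus, optionally, the Bland-Altman point table.
#'
#' @param result an [agreement_analysis()] result.
#' @param path summary CSV path.
#' @param points_path optional path for the per-subject (mean, diff)
#'   table.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(result, path, points_path = NULL) {
  stopifnot(inherits(result, "agreement_result"))
  icc <- result$icc; ba <- result$bland_altman; rg <- result$regression
  df <- data.frame(
    variable = result$variable_name, n = result$n,
    icc = icc$icc, ci_low = icc$ci_low, ci_high = icc$ci_high,
    f_stat = icc$f_stat, f_pvalue = icc$f_pvalue,
    reliability = icc$reliability %||% NA_character_,
    mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    slope = if (is.null(rg)) NA_real_ else rg$slope,
    intercept = if (is.null(rg)) NA_real_ else rg$intercept,
    r = if (is.null(rg)) NA_real_ else rg$r)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(points_path))
    write.csv(ba$points, points_path, row.names = FALSE)
  invisible(path)
}
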