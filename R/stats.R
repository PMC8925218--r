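# Cohort statistics layer: median/range summary tables by side and
# condition, Pearson correlation matrices with p-values, and paired
# Wilcoxon comparisons between loading conditions.

PROPERTY_COLUMNS <- c("primary_thickness", "peak_strain", "peak_stress",
                      "elastic_modulus", "viscous_modulus", "edr")

check_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("'records' must be a non-empty data frame of cohort records",
          class = "empty_input_error")
  needed <- c("subject_id", "side", "condition", PROPERTY_COLUMNS)
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stopf("cohort records are missing columns: %s",
          paste(missing, collapse = ", "), class = "invalid_input_error")
  key <- interaction(records$subject_id, records$side, records$condition,
                     drop = TRUE)
  if (anyDuplicated(key))
    stopf("duplicate (subject_id, side, condition) records",
          class = "invalid_input_error")
  invisible(records)
}

#' Median / range summary table by side and condition
#'
#' For each of the six heel-pad properties, in each loading condition,
#' reports the median and min-max range for the left side, the right side,
#' and both sides combined. Cells with no records are marked absent
#' (`n = 0`, `NA` statistics), never zero.
#'
#' @param records data frame of cohort records: columns `subject_id`,
#'   `side` (`left`/`right`), `condition` (`time_zero`/`post_loading`) and
#'   the six property columns (`primary_thickness`, `peak_strain`,
#'   `peak_stress`, `elastic_modulus`, `viscous_modulus`, `edr`).
#' @return Long data frame of class `summary_table`: `property`,
#'   `condition`, `side` (including `"combined"`), `n`, `median`, `min`,
#'   `max`.
#' @export
summarize_cohort <- function(records) {
  check_records(records)
  grid <- expand.grid(property = PROPERTY_COLUMNS,
                      condition = c("time_zero", "post_loading"),
                      side = c("left", "right", "combined"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sel <- records$condition == g$condition &
      (g$side == "combined" | records$side == g$side)
    v <- records[[g$property]][sel]
    v <- v[is.finite(v)]
    data.frame(property = g$property, condition = g$condition, side = g$side,
               n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Pearson correlation matrix with p-values
#'
#' Correlation matrix over covariates and heel-pad properties for one
#' loading condition, heels pooled as observations (two per subject, as the
#' source tables pool left and right; set `unit = "per_subject_mean"` to
#' average sides first, since intra-subject correlation violates
#' independence either way). Two-sided p-values come from the t transform
#' with n - 2 degrees of freedom. Constant variables yield `NA` entries and
#' are listed in `flagged_constant` rather than failing silently.
#'
#' @param records cohort record data frame (see [summarize_cohort()]) with
#'   `age` and `bmi` columns.
#' @param variables variables to correlate.
#' @param condition restrict to one condition (`"time_zero"` or
#'   `"post_loading"`); NULL uses all rows.
#' @param unit `"per_heel"` (default) or `"per_subject_mean"`.
#' @return List of class `pearson_matrix`: `r`, `p` (symmetric matrices),
#'   `n` observations, `flagged_constant`.
#' @export
pearson_matrix <- function(records,
                           variables = c("bmi", "age", PROPERTY_COLUMNS),
                           condition = NULL,
                           unit = c("per_heel", "per_subject_mean")) {
  unit <- match.arg(unit)
  check_records(records)
  if (!is.null(condition)) records <- records[records$condition == condition, ]
  missing <- setdiff(variables, names(records))
  if (length(missing))
    stopf("variables not present in records: %s",
          paste(missing, collapse = ", "), class = "invalid_input_error")
  dat <- records[, variables, drop = FALSE]
  if (unit == "per_subject_mean") {
    dat <- aggregate(dat, by = list(subject_id = records$subject_id), mean)
    dat <- dat[, variables, drop = FALSE]
  }
  n <- nrow(dat)
  if (n < 3L)
    stopf("at least 3 observations are required for correlations (have %d)",
          n, class = "insufficient_data_error")
  k <- length(variables)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(variables, variables)
  const <- variables[vapply(dat, function(v) sd(v) == 0, logical(1))]
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    vi <- variables[i]; vj <- variables[j]
    if (vi %in% const || vj %in% const) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- cor.test(dat[[vi]], dat[[vj]], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (length(const)) diag(r)[match(const, variables)] <- NA_real_
  structure(list(r = r, p = p, n = n, flagged_constant = const),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlation matrix (%d observations)\n", x$n))
  print(round(x$r, digits))
  if (length(x$flagged_constant))
    cat("constant variables flagged:",
        paste(x$flagged_constant, collapse = ", "), "\n")
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences `post - pre`. Zero differences are
#' dropped (Wilcoxon's original convention); `n_effective` excludes them.
#' The exact null distribution is used when `n_effective <= 25` and the
#' absolute differences carry no tied ranks; otherwise the normal
#' approximation with continuity correction and tie-corrected variance.
#'
#' @param pre,post paired measurement vectors.
#' @param ids optional pairing identifiers: list with elements `pre` and
#'   `post`; `post` is reordered to match `pre` by id. NULL pairs
#'   positionally.
#' @return List: `statistic` (V, rank sum of positive differences),
#'   `p_value` (two-sided), `n_effective`, `exact` (logical).
#' @export
#' @examples
#' paired_wilcoxon(c(1, 2, 3, 4, 5), c(2, 4, 5, 7, 9))$p_value # 0.0625
paired_wilcoxon <- function(pre, post, ids = NULL) {
  if (!is.null(ids)) {
    m <- match(ids$pre, ids$post)
    if (anyNA(m))
      stopf("pairing ids do not match between conditions",
            class = "invalid_input_error")
    post <- post[m]
  }
  if (length(pre) != length(post))
    stopf("'pre' and 'post' must have equal length", class = "invalid_input_error")
  d <- post - pre
  d <- d[is.finite(d) & d != 0]
  n_eff <- length(d)
  if (n_eff == 0L)
    stopf("all paired differences are zero; the signed-rank statistic is undefined",
          class = "all_ties_error")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n_eff <= 25L && !ties
  wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = n_eff, exact = exact)
}

#' Compare loading conditions property by property
#'
#' For each heel-pad property: time-zero median, post-loading median, and a
#' paired Wilcoxon signed-rank p-value over heels matched by
#' `(subject_id, side)`. All-tie comparisons are reported as `p = 1`. A long
#' table of per-heel standardized values (z-scores per property, pooled over
#' both conditions) is attached for paired-plot export.
#'
#' @param records cohort record data frame containing both conditions.
#' @return Data frame of class `condition_comparison` (one row per
#'   property: `property`, `median_time_zero`, `median_post_loading`,
#'   `statistic`, `p_value`, `n_effective`), with attribute `standardized`.
#' @export
compare_conditions <- function(records) {
  check_records(records)
  tz <- records[records$condition == "time_zero", ]
  pl <- records[records$condition == "post_loading", ]
  key <- function(x) paste(x$subject_id, x$side, sep = "::")
  common <- intersect(key(tz), key(pl))
  if (length(common) < 3L)
    stopf("need >= 3 heels measured under both conditions (have %d)",
          length(common), class = "insufficient_data_error")
  tz <- tz[match(common, key(tz)), ]
  pl <- pl[match(common, key(pl)), ]
  rows <- lapply(PROPERTY_COLUMNS, function(prop) {
    pre <- tz[[prop]]; post <- pl[[prop]]
    res <- tryCatch(paired_wilcoxon(pre, post),
                    all_ties_error = function(e)
                      list(statistic = NA_real_, p_value = 1,
                           n_effective = 0L, exact = NA))
    data.frame(property = prop,
               median_time_zero = median(pre),
               median_post_loading = median(post),
               statistic = res$statistic, p_value = res$p_value,
               n_effective = res$n_effective, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  both <- rbind(tz, pl)
  std <- do.call(rbind, lapply(PROPERTY_COLUMNS, function(prop) {
    v <- both[[prop]]
    s <- sd(v)
    data.frame(subject_id = both$subject_id, side = both$side,
               condition = both$condition, property = prop,
               z = if (s > 0) (v - mean(v)) / s else rep(0, length(v)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "standardized") <- std
  class(out) <- c("condition_comparison", "data.frame")
  out
}
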