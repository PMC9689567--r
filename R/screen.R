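#' Paired two-class screening of the feature table
#'
#' For every feature column, tests whether the NO_RISK and RISK classes
#' differ across paired lifts. Pairing follows the repeated-trials design:
#' the i-th lift of a subject's NO_RISK trial is paired with the i-th lift of
#' the same subject's RISK trial (`pairing = "lift"`; 13 subjects x 20 lifts
#' gives 260 pairs). Normality of each class's paired values is assessed with
#' a Shapiro-Wilk test at the same alpha; if both classes pass, a two-tailed
#' paired t-test is used, otherwise a Wilcoxon signed-rank test. No
#' multiple-testing correction is applied by default (`p_adjust = "none"`);
#' Benjamini-Hochberg is available via `p_adjust = "BH"`.
#'
#' @param table Feature table from [build_feature_table()] (columns `subject`,
#'   `trial`, `lift_index`, `label`, then features).
#' @param alpha Significance level (default 0.05).
#' @param pairing `"lift"` (per-lift pairs, default) or `"subject"`
#'   (per-subject means, 13 pairs).
#' @param normality_on `"values"` (each class's values, default) or
#'   `"differences"` (paired differences).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()].
#' @return A tibble of class `lift_screen`, one row per feature, with class
#'   means and SDs, Shapiro-Wilk p-values, the test used, `p_value` and
#'   `significant`.
#' @export
screen_features <- function(table, alpha = 0.05, pairing = c("lift", "subject"),
                            normality_on = c("values", "differences"),
                            p_adjust = "none") {
  pairing <- match.arg(pairing)
  normality_on <- match.arg(normality_on)
  feats <- setdiff(names(table), c("subject", "trial", "lift_index", "label"))
  classes <- unique(table$label)
  if (!all(c("NO_RISK", "RISK") %in% classes)) {
    abort("both classes (NO_RISK, RISK) must be present in `table`")
  }
  long <- table[c("subject", "lift_index", "label", feats)]
  if (pairing == "subject") {
    long <- long |>
      dplyr::group_by(.data$subject, .data$label) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(feats), mean),
                       .groups = "drop") |>
      dplyr::mutate(lift_index = 1L)
  }
  a <- long[long$label == "NO_RISK", c("subject", "lift_index", feats)]
  b <- long[long$label == "RISK", c("subject", "lift_index", feats)]
  paired <- dplyr::inner_join(a, b, by = c("subject", "lift_index"),
                              suffix = c("__a", "__b"))
  n_dropped <- (nrow(a) + nrow(b)) - 2L * nrow(paired)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d unpaired lift instance(s)", n_dropped))
  }
  if (nrow(paired) < 8) {
    abort(sprintf("only %d pairs available; need >= 8 for screening", nrow(paired)))
  }
  res <- purrr::map_dfr(feats, function(f) {
    xa <- paired[[paste0(f, "__a")]]
    xb <- paired[[paste0(f, "__b")]]
    d <- xb - xa
    sw_p <- function(v) {
      if (length(unique(v)) < 3) return(0)  # (near-)constant: not plausibly normal
      shapiro.test(if (length(v) > 5000) sample(v, 5000) else v)$p.value
    }
    norm_a <- sw_p(xa); norm_b <- sw_p(xb)
    normal <- if (normality_on == "values") {
      norm_a >= alpha && norm_b >= alpha
    } else {
      sw_p(d) >= alpha
    }
    if (all(d == 0)) {
      test_used <- "paired_t"; p <- 1; stat <- 0
    } else if (normal) {
      tt <- t.test(xb, xa, paired = TRUE)
      test_used <- "paired_t"; p <- tt$p.value; stat <- unname(tt$statistic)
    } else {
      wt <- suppressWarnings(wilcox.test(xb, xa, paired = TRUE, exact = FALSE))
      test_used <- "wilcoxon"; p <- wt$p.value; stat <- unname(wt$statistic)
    }
    tibble::tibble(
      feature = f,
      mean_no_risk = mean(xa), sd_no_risk = sd(xa),
      mean_risk = mean(xb), sd_risk = sd(xb),
      normality_p_no_risk = norm_a, normality_p_risk = norm_b,
      test_used = test_used, statistic = stat, p_value = p
    )
  })
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  res$significant <- res$p_value < alpha
  structure(res, class = c("lift_screen", class(res)),
            alpha = alpha, n_pairs = nrow(paired), pairing = pairing)
}

#' Format screening results as a publication-style table
#'
#' @param x A `lift_screen` tibble.
#' @param digits Decimal places for the mean +/- SD columns.
#' @return Tibble with `feature`, formatted `no_risk` and `risk`
#'   ("mean +/- SD") columns and `p_value`.
#' @export
format_screen_table <- function(x, digits = 2) {
  fmt <- function(m, s) sprintf("%.*f ± %.*f", digits, m, digits, s)
  tibble::tibble(
    feature = x$feature,
    no_risk = fmt(x$mean_no_risk, x$sd_no_risk),
    risk = fmt(x$mean_risk, x$sd_risk),
    p_value = ifelse(x$p_value < 0.001, "<0.001", sprintf("%.4f", x$p_value))
  )
}
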