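#' Normality-dispatched group comparison
#'
#' Implements the standard dispatch for comparing measurement groups:
#' each group's distribution is assessed with the Shapiro-Wilk test at
#' `alpha`; for two groups, a two-tailed Student's t test when all groups
#' are normal, otherwise a Mann-Whitney rank-sum test; for more than two
#' groups, a one-way ANOVA followed by Dunnett's multiple-comparison tests
#' against the designated control. Zero-variance groups cannot be assessed
#' for normality and route to the rank test (two-group case) with a note.
#'
#' @param data A data frame.
#' @param value Bare column name of the measured values.
#' @param group Bare column name of the group labels.
#' @param control Control group label for Dunnett comparisons (default: the
#'   first factor level).
#' @param alpha Significance level for the normality check (default 0.05).
#' @return An object of class `group_comparison` with fields `method`
#'   (`"t"`, `"wilcoxon"`, or `"anova_dunnett"`), `statistic`, `p_value`,
#'   `normality` (per-group tibble), `comparisons` (Dunnett tibble, or the
#'   single two-group contrast), `groups` (n / mean / SEM summary),
#'   `control`, `alpha`. [generics::tidy()] returns the per-comparison
#'   table and [generics::glance()] the one-row summary.
#' @export
#' @examples
#' d <- data.frame(y = c(rnorm(10), rnorm(10, 2)),
#'                 g = rep(c("a", "b"), each = 10))
#' compare_groups(d, y, g)
compare_groups <- function(data, value, group, control = NULL,
                           alpha = 0.05) {
  v <- rlang::as_name(rlang::enquo(value))
  g <- rlang::as_name(rlang::enquo(group))
  df <- data.frame(y = data[[v]], g = factor(data[[g]]))
  df <- df[stats::complete.cases(df), ]
  ns <- table(df$g)
  if (length(ns) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 3)) stop("each group needs n >= 3", call. = FALSE)
  if (!is.null(control)) {
    if (!control %in% levels(df$g)) {
      stop("`control` is not a group label", call. = FALSE)
    }
    df$g <- stats::relevel(df$g, ref = control)
  }
  control <- levels(df$g)[1]

  normality <- dplyr::bind_rows(lapply(levels(df$g), function(lv) {
    x <- df$y[df$g == lv]
    sw <- if (stats::sd(x) == 0 || length(x) < 3 || length(x) > 5000) {
      NULL
    } else tryCatch(stats::shapiro.test(x), error = function(e) NULL)
    tibble::tibble(
      group = lv, n = length(x),
      shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
      normal = if (is.null(sw)) FALSE else sw$p.value >= alpha
    )
  }))
  all_normal <- all(normality$normal)

  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$g),
    n = dplyr::n(), mean = mean(.data$y),
    sem = stats::sd(.data$y) / sqrt(dplyr::n()), .groups = "drop"
  )
  names(summ)[1] <- "group"

  comparisons <- NULL
  if (length(ns) == 2) {
    x <- df$y[df$g == levels(df$g)[2]]
    y0 <- df$y[df$g == control]
    if (all_normal) {
      ht <- stats::t.test(x, y0, var.equal = TRUE)
      method <- "t"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y0, exact = FALSE))
      method <- "wilcoxon"
    }
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
    comparisons <- tibble::tibble(
      contrast = paste(levels(df$g)[2], "-", control),
      estimate = mean(x) - mean(y0),
      statistic = statistic, p_value = p_value
    )
  } else {
    fit <- stats::aov(y ~ g, data = df)
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]
    p_value <- an[["Pr(>F)"]][1]
    method <- "anova_dunnett"
    dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
    comparisons <- tibble::tibble(
      contrast = names(dn$test$coefficients),
      estimate = unname(dn$test$coefficients),
      statistic = unname(dn$test$tstat),
      p_value = unname(dn$test$pvalues)
    )
  }

  structure(list(
    method = method, statistic = statistic, p_value = p_value,
    normality = normality, comparisons = comparisons, groups = summ,
    control = control, alpha = alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lbl <- c(t = "Student's t test",
           wilcoxon = "Mann-Whitney rank-sum test",
           anova_dunnett = "one-way ANOVA + Dunnett vs control")
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              lbl[[x$method]], x$statistic, x$p_value))
  if (x$method == "anova_dunnett") {
    print(x$comparisons)
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return `tidy()`: one row per contrast (`contrast`, `estimate`,
#'   `statistic`, `p.value`); `glance()`: a one-row summary (`method`,
#'   `statistic`, `p.value`, `n_groups`, `all_normal`).
#' @export
tidy.group_comparison <- function(x, ...) {
  out <- x$comparisons
  names(out)[names(out) == "p_value"] <- "p.value"
  out
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, p.value = x$p_value,
    n_groups = nrow(x$groups), n = sum(x$groups$n),
    all_normal = all(x$normality$normal)
  )
}
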