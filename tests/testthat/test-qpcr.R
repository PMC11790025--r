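make_ct <- function(...) tibble::tibble(...)

test_that("2^-dCt closed forms and reference-QC exclusion", {
  ct <- make_ct(
    animal_id = rep(1:3, each = 2),
    group = "CTL",
    gene = rep(c("Gapdh", "BiP"), 3),
    ct = c(20, 25, # dCt = 5
           21, 21, # dCt = 0
           24.5, 26) # Gapdh Ct > 24 -> excluded
  )
  expect_message(expr <- relative_expression(ct), "excluded")
  expect_equal(expr$rel_expr, c(2^-5, 1))
  excl <- attr(expr, "excluded")
  expect_equal(excl$animal_id, 3)
  expect_match(excl$reason, "Ct > 24")
  # boundary: Ct exactly 24 is kept
  ct$ct[5] <- 24
  expr2 <- relative_expression(ct)
  expect_equal(nrow(expr2), 3L)
})

test_that("control folds average exactly 1 and shift with Ct cycles", {
  set.seed(42)
  ct <- make_ct(
    animal_id = rep(1:12, each = 2),
    group = rep(c("CTL", "noise"), each = 12),
    gene = rep(c("Gapdh", "Chop"), 12),
    ct = as.vector(rbind(rnorm(12, 20, 0.3), rnorm(12, 24, 0.5)))
  )
  folds <- fold_vs_control(relative_expression(ct))
  expect_equal(mean(folds$fold[folds$group == "CTL"]), 1)

  # +1 cycle on every target-gene Ct halves every fold against the same
  # control... and against its own recomputed control leaves folds fixed
  ct2 <- ct
  ct2$ct[ct2$gene == "Chop"] <- ct2$ct[ct2$gene == "Chop"] + 1
  folds2 <- fold_vs_control(relative_expression(ct2))
  expect_equal(folds2$rel_expr, folds$rel_expr / 2)
  expect_equal(folds2$fold, folds$fold)

  expect_error(fold_vs_control(relative_expression(ct), control = "none"),
               "control")
})

test_that("the Chop/S-Xbp1 ratio is reference-free", {
  ct <- make_ct(
    animal_id = rep(1, 3), group = "CTL",
    gene = c("Gapdh", "Chop", "S-Xbp1"),
    ct = c(20, 23, 25) # Chop 2^-3, S-Xbp1 2^-5 -> ratio 4
  )
  r <- expression_ratio(relative_expression(ct))
  expect_equal(r$ratio, 4)
  # shifting the reference Ct leaves the ratio unchanged
  ct2 <- ct; ct2$ct[1] <- 22
  expect_equal(expression_ratio(relative_expression(ct2))$ratio, 4)
  # missing either gene drops the sample
  expect_equal(nrow(expression_ratio(relative_expression(ct[-2, ]))), 0L)
})

test_that("ROUT-style removal is quiet on clean normal samples", {
  n_sim <- 300
  clean <- flagged_counts <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    set.seed(7000 + s)
    out <- rout_outliers(rnorm(20), q = 0.01)
    flagged_counts[s] <- length(out$removed)
  }
  expect_gte(mean(flagged_counts == 0), 0.95)
  expect_gte(mean(flagged_counts <= ceiling(0.01 * 20) + 1), 0.95)
})

test_that("a 10-robust-SD point is removed, and small groups are skipped", {
  set.seed(99)
  x <- rnorm(20)
  out0 <- rout_outliers(x, q = 0.01)
  spike <- median(x) + 10 * out0$rsdr
  out <- rout_outliers(c(x, spike), q = 0.01)
  expect_equal(out$removed, spike)
  expect_equal(sum(out$outlier), 1L)

  out3 <- rout_outliers(rnorm(3))
  expect_false(out3$attempted)
  expect_equal(length(out3$removed), 0L)
  expect_error(rout_outliers(x, q = 0.6), "`q`")
})

test_that("remove_outliers flags per group in a data frame", {
  set.seed(17)
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = 12),
    y = c(rnorm(11), 30, rnorm(12))
  )
  out <- remove_outliers(d, y, by = "group")
  expect_true(out$.outlier[12])
  expect_equal(sum(out$.outlier), 1L)
})

test_that("group comparison dispatches on normality and group count", {
  set.seed(21)
  x <- rnorm(30)
  d_same <- tibble::tibble(y = c(x, x), g = rep(c("a", "b"), each = 30))
  cmp <- compare_groups(d_same, y, g)
  expect_equal(cmp$method, "t")
  expect_gt(cmp$p_value, 0.9)

  d_shift <- tibble::tibble(y = c(rnorm(10), rnorm(10, 5)),
                            g = rep(c("ctl", "trt"), each = 10))
  expect_lt(compare_groups(d_shift, y, g)$p_value, 0.001)

  set.seed(22)
  d_exp <- tibble::tibble(y = c(rexp(40), rexp(40)),
                          g = rep(c("a", "b"), each = 40))
  expect_equal(compare_groups(d_exp, y, g)$method, "wilcoxon")

  # zero-variance group routes to the rank test without erroring
  d_const <- tibble::tibble(y = c(rep(1, 10), rnorm(10)),
                            g = rep(c("a", "b"), each = 10))
  expect_equal(compare_groups(d_const, y, g)$method, "wilcoxon")

  expect_error(compare_groups(d_shift[1:12, ], y, g), "n >= 3")
})

test_that("three or more groups use ANOVA with Dunnett contrasts", {
  set.seed(31)
  d <- tibble::tibble(
    y = c(rnorm(10), rnorm(10, 0.2), rnorm(10, 3)),
    g = rep(c("CTL", "low", "high"), each = 10)
  )
  cmp <- compare_groups(d, y, g, control = "CTL")
  expect_equal(cmp$method, "anova_dunnett")
  expect_equal(nrow(cmp$comparisons), 2L)
  p_high <- cmp$comparisons$p_value[grepl("high", cmp$comparisons$contrast)]
  expect_lt(p_high, 0.01)

  td <- tidy(cmp)
  expect_named(td, c("contrast", "estimate", "statistic", "p.value"))
  gl <- glance(cmp)
  expect_equal(gl$n_groups, 3L)
  expect_equal(gl$method, "anova_dunnett")
})

test_that("Dunnett comparisons hold their size under the null", {
  n_sig <- 0L
  n_sim <- 25
  for (s in seq_len(n_sim)) {
    set.seed(8000 + s)
    d <- tibble::tibble(
      y = rnorm(40),
      g = rep(c("CTL", "t1", "t2", "t3"), each = 10)
    )
    cmp <- compare_groups(d, y, g, control = "CTL")
    if (any(cmp$comparisons$p_value < 0.05)) n_sig <- n_sig + 1L
  }
  expect_gte((n_sim - n_sig) / n_sim, 0.9)
})

test_that("the panel workflow recovers a known fold change", {
  set.seed(55)
  # Chop shifted -1 cycle in the noise group -> fold 2 vs control
  ct <- make_ct(
    animal_id = rep(1:16, each = 2),
    group = rep(c("CTL", "noise"), each = 16),
    gene = rep(c("Gapdh", "Chop"), 16),
    ct = as.vector(rbind(
      rnorm(16, 20, 0.05),
      c(rnorm(8, 24, 0.05), rnorm(8, 23, 0.05))
    ))
  )
  panel <- upr_panel(ct)
  expect_equal(panel$gene, "Chop")
  expect_equal(panel$fold, 2, tolerance = 0.1)
  expect_lt(panel$p_value, 1e-6)
  panel_bh <- upr_panel(ct, adjust = "BH")
  expect_true("p_adj" %in% names(panel_bh))
})
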