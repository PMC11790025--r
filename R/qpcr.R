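#' Relative expression by the 2^-dCt method
#'
#' Computes per-sample relative expression against a reference gene:
#' `2^-(Ct_gene - Ct_ref)`. Samples with inadequate reference levels
#' (reference Ct above `max_reference_ct`, default 24) are excluded, as are
#' rows with a missing Ct; exclusions are reported in the `excluded`
#' attribute with a reason.
#'
#' @param ct_data Long tibble of Ct values with columns `animal_id`,
#'   `group`, `gene`, `ct` (extra columns such as `sex` are carried
#'   through).
#' @param reference Reference gene symbol (default `"Gapdh"`).
#' @param max_reference_ct QC cutoff on the reference Ct (default 24;
#'   samples with reference Ct strictly above it are dropped).
#' @return A tibble with one row per valid sample x non-reference gene:
#'   input columns plus `ct_ref`, `delta_ct`, `rel_expr`. Attribute
#'   `excluded` is a tibble of dropped sample/gene rows with a `reason`
#'   column.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   animal_id = rep(1:2, each = 2), group = "CTL",
#'   gene = rep(c("Gapdh", "BiP"), 2), ct = c(20, 25, 21, 24)
#' )
#' relative_expression(ct)$rel_expr # 2^-5, 2^-3
relative_expression <- function(ct_data, reference = "Gapdh",
                                max_reference_ct = 24) {
  stopifnot(all(c("animal_id", "gene", "ct") %in% names(ct_data)))
  ref <- ct_data[ct_data$gene == reference,
                 c("animal_id", "ct"), drop = FALSE]
  names(ref)[2] <- "ct_ref"
  ref <- ref[!duplicated(ref$animal_id), , drop = FALSE]
  out <- ct_data[ct_data$gene != reference, , drop = FALSE]
  out <- dplyr::left_join(out, ref, by = "animal_id")

  reason <- rep(NA_character_, nrow(out))
  reason[is.na(out$ct)] <- "missing Ct"
  reason[is.na(out$ct_ref)] <- paste0("missing ", reference, " Ct")
  reason[!is.na(out$ct_ref) & out$ct_ref > max_reference_ct] <-
    sprintf("%s Ct > %g", reference, max_reference_ct)
  excluded <- out[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- reason[!is.na(reason)]
    message(nrow(excluded), " sample-gene rows excluded (",
            paste(unique(excluded$reason), collapse = "; "), ")")
  }
  out <- out[is.na(reason), , drop = FALSE]
  out$delta_ct <- out$ct - out$ct_ref
  out$rel_expr <- 2^(-out$delta_ct)
  out <- tibble::as_tibble(out)
  attr(out, "excluded") <- tibble::as_tibble(excluded)
  out
}

#' Normalize expression to the control-group mean
#'
#' Divides each sample's relative expression by the arithmetic mean of the
#' control group's relative expression, per gene, so the control group
#' averages exactly 1.
#'
#' @param expr Output of [relative_expression()].
#' @param control Control group label (default `"CTL"`).
#' @return `expr` with `fold` (and `control_mean`) columns added.
#' @export
fold_vs_control <- function(expr, control = "CTL") {
  stopifnot("group" %in% names(expr))
  ctrl <- dplyr::summarise(
    dplyr::group_by(expr[expr$group == control, ], .data$gene),
    control_mean = mean(.data$rel_expr), .groups = "drop"
  )
  if (!nrow(ctrl) || any(!expr$gene %in% ctrl$gene)) {
    stop("control group is empty for at least one gene", call. = FALSE)
  }
  out <- dplyr::left_join(expr, ctrl, by = "gene")
  out$fold <- out$rel_expr / out$control_mean
  out
}

#' Per-sample ratio of two genes' relative expressions
#'
#' The ratio of a proapoptotic to a prohomeostatic marker (canonically
#' Chop / S-Xbp1) indexes the balance of the unfolded protein response; it
#' is computed per sample and is algebraically independent of the reference
#' gene (the reference Ct cancels). Samples missing either gene are
#' excluded.
#'
#' @param expr Output of [relative_expression()].
#' @param numerator,denominator Gene symbols (defaults `"Chop"`,
#'   `"S-Xbp1"`).
#' @return A tibble with one row per sample: `animal_id`, `group` (and
#'   `sex` when present), `ratio`.
#' @export
expression_ratio <- function(expr, numerator = "Chop",
                             denominator = "S-Xbp1") {
  keep <- intersect(c("animal_id", "group", "sex"), names(expr))
  num <- expr[expr$gene == numerator, c(keep, "rel_expr")]
  den <- expr[expr$gene == denominator, c("animal_id", "rel_expr")]
  names(num)[names(num) == "rel_expr"] <- "num"
  names(den)[2] <- "den"
  out <- dplyr::inner_join(num, den, by = "animal_id")
  out$ratio <- out$num / out$den
  tibble::as_tibble(out[, c(keep, "ratio")])
}

#' Robust FDR-controlled outlier removal (univariate ROUT-style)
#'
#' Adapts the ROUT idea (robust fit + FDR-controlled outlier calls) to a
#' single sample of values: the robust center is the median; the robust
#' scale (RSDR) is the 68.27th percentile of the absolute residuals with
#' the small-sample correction `n / (n - 1)`; each point's studentized
#' residual gets a two-tailed p-value from a t distribution on `n - 1`
#' degrees of freedom; Benjamini-Hochberg at level `q` (default 1%) flags
#' outliers, which are removed in a single pass. Groups smaller than
#' `min_n` are returned untouched.
#'
#' @param x Numeric vector.
#' @param q FDR level for outlier calls (0 < q < 0.5; default 0.01).
#' @param min_n Minimum group size to attempt removal (default 5).
#' @return A list with `kept`, `removed`, `outlier` (logical per input
#'   point), `center`, `rsdr`, and `attempted`.
#' @export
#' @examples
#' x <- c(rnorm(15), 25)
#' rout_outliers(x)$removed
rout_outliers <- function(x, q = 0.01, min_n = 5) {
  if (q <= 0 || q >= 0.5) stop("`q` must be in (0, 0.5)", call. = FALSE)
  n <- length(x)
  if (n < min_n) {
    return(list(kept = x, removed = numeric(), outlier = rep(FALSE, n),
                center = stats::median(x), rsdr = NA_real_,
                attempted = FALSE))
  }
  center <- stats::median(x)
  resid <- x - center
  rsdr <- unname(stats::quantile(abs(resid), 0.6827, type = 7)) * n / (n - 1)
  if (rsdr == 0) {
    return(list(kept = x, removed = numeric(), outlier = rep(FALSE, n),
                center = center, rsdr = 0, attempted = TRUE))
  }
  tstat <- abs(resid) / rsdr
  p <- 2 * stats::pt(-tstat, df = n - 1)
  flag <- stats::p.adjust(p, method = "BH") <= q
  list(kept = x[!flag], removed = x[flag], outlier = flag,
       center = center, rsdr = rsdr, attempted = TRUE)
}

#' Flag outliers per group in a data frame
#'
#' Data-frame interface to [rout_outliers()]: flags outliers within each
#' group and returns the input with an `.outlier` column.
#'
#' @param data A data frame.
#' @param value Bare column name holding the values.
#' @param by Character vector of grouping columns (default `"group"`;
#'   intersected with the columns present, so gene-wise grouping works with
#'   `by = c("gene", "group")`).
#' @param q,min_n Passed to [rout_outliers()].
#' @return `data` with a logical `.outlier` column.
#' @export
remove_outliers <- function(data, value, by = "group", q = 0.01,
                            min_n = 5) {
  value <- rlang::as_name(rlang::enquo(value))
  by <- intersect(by, names(data))
  split_idx <- if (length(by)) {
    split(seq_len(nrow(data)), data[by], drop = TRUE)
  } else list(seq_len(nrow(data)))
  flag <- rep(FALSE, nrow(data))
  for (idx in split_idx) {
    flag[idx] <- rout_outliers(data[[value]][idx], q, min_n)$outlier
  }
  data$.outlier <- flag
  data
}

#' Per-gene fold-change panel with per-gene t tests
#'
#' The expression-panel workflow: relative expression by 2^-dCt, fold
#' change versus the control-group mean, and for each gene and each
#' non-control group a two-tailed Student's t test of the 2^-dCt values
#' against control. No multiple-testing correction is applied across genes
#' by default, mirroring the per-gene reporting convention; set
#' `adjust = "BH"` to add an adjusted-p column.
#'
#' @param ct_data Long Ct tibble (see [relative_expression()]).
#' @param reference Reference gene (default `"Gapdh"`).
#' @param control Control group label (default `"CTL"`).
#' @param genes Genes to analyse (default all non-reference genes present).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per gene x non-control group: `gene`,
#'   `group`, `fold` (mean group fold), `p_value`, `n_control`, `n_group`
#'   (+ `p_adj` when `adjust = "BH"`).
#' @export
upr_panel <- function(ct_data, reference = "Gapdh", control = "CTL",
                      genes = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  expr <- relative_expression(ct_data, reference)
  if (!is.null(genes)) expr <- expr[expr$gene %in% genes, ]
  expr <- fold_vs_control(expr, control)
  grps <- setdiff(unique(expr$group), control)
  rows <- list()
  for (g in unique(expr$gene)) {
    ctrl <- expr$rel_expr[expr$gene == g & expr$group == control]
    for (gr in grps) {
      x <- expr$rel_expr[expr$gene == g & expr$group == gr]
      if (length(x) < 2 || length(ctrl) < 2) next
      tt <- stats::t.test(x, ctrl, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = g, group = gr, fold = mean(x) / mean(ctrl),
        p_value = tt$p.value, n_control = length(ctrl), n_group = length(x)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH" && nrow(out)) {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
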