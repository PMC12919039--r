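# Group-statistics layer over tidy delta-summary tables. The sampling unit
# throughout is the ROI image (shank x region), without a mouse-level random
# effect.

test_result_row <- function(comparison, statistic, value, df = NA_real_,
                            n = NA_integer_, p_raw = NA_real_,
                            p_adj = NA_real_) {
  data.frame(comparison = comparison, statistic = statistic, value = value,
             df = df, n = n, p_raw = p_raw, p_adj = p_adj,
             stringsAsFactors = FALSE)
}

#' Factorial ANOVA on a delta-summary table
#'
#' Fits a between-factors linear model of the response on the given design
#' factors and reports type-II F tests (the conventional choice for
#' unbalanced main-effects designs). Two-way interactions are included when
#' requested and estimable; if any interaction cell is empty, interactions
#' are dropped with a warning.
#'
#' @param table data frame of per-ROI-image values.
#' @param response name of the value column (e.g. `"delta_neun"`).
#' @param factors character vector of factor column names; factors with
#'   fewer than two observed levels are dropped with a message.
#' @param interactions include two-way interactions?
#' @return Data frame with one row per term: `comparison`, `statistic`
#'   (`"F"`), `value`, `df`, `n`, `p_raw`, `p_adj` (`p_adj` equals `p_raw`
#'   here; correction applies to the post-hoc stage).
#' @export
factorial_anova <- function(table, response, factors, interactions = TRUE) {
  stopifnot(response %in% names(table), all(factors %in% names(table)))
  tab <- table[stats::complete.cases(table[c(response, factors)]), ,
               drop = FALSE]
  keep <- vapply(factors, function(f) {
    length(unique(tab[[f]])) >= 2L
  }, logical(1))
  if (!all(keep)) {
    message("dropping single-level factor(s): ",
            paste(factors[!keep], collapse = ", "))
    factors <- factors[keep]
  }
  if (length(factors) == 0L) stop("no factor with >= 2 levels", call. = FALSE)
  for (f in factors) tab[[f]] <- factor(tab[[f]])
  if (stats::var(tab[[response]]) == 0) {
    # degenerate: constant response; report F = 0, p = 1 per term
    return(do.call(rbind, lapply(factors, function(f) {
      test_result_row(f, "F", 0, df = length(unique(tab[[f]])) - 1,
                      n = nrow(tab), p_raw = 1, p_adj = 1)
    })))
  }
  rhs <- paste(factors, collapse = " + ")
  if (interactions && length(factors) > 1L) {
    cells <- table(tab[factors])
    if (all(cells > 0)) {
      rhs <- paste0("(", paste(factors, collapse = " + "), ")^2")
    } else {
      warning("empty design cells; fitting main effects only")
    }
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = tab)
  a <- car::Anova(fit, type = 2, singular.ok = TRUE)
  terms <- rownames(a)
  keep_rows <- !terms %in% c("Residuals")
  res <- data.frame(
    comparison = terms[keep_rows],
    statistic = "F",
    value = a[keep_rows, "F value"],
    df = a[keep_rows, "Df"],
    n = nrow(tab),
    p_raw = a[keep_rows, "Pr(>F)"],
    p_adj = a[keep_rows, "Pr(>F)"],
    stringsAsFactors = FALSE
  )
  attr(res, "fit") <- fit
  res
}

#' Pairwise post-hoc t-tests with Bonferroni correction
#'
#' Two-sample (equal-variance, two-sided) t-tests over all level pairs of
#' one factor, with the Bonferroni family-wise adjustment
#' `p_adj = min(1, p_raw * m)`.
#'
#' @param table data frame.
#' @param response value column name.
#' @param factor_col factor column name.
#' @param correction multiple-comparison method (passed to
#'   [stats::p.adjust()]).
#' @param var_equal use the pooled-variance t statistic.
#' @return Data frame of `test_result` rows, one per level pair, statistic
#'   `"t"`.
#' @export
posthoc_ttests <- function(table, response, factor_col,
                           correction = "bonferroni", var_equal = TRUE) {
  g <- factor(table[[factor_col]])
  v <- table[[response]]
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- v[g == pr[1]]; y <- v[g == pr[2]]
    if (length(x) < 2L || length(y) < 2L) {
      stop("each group needs at least 2 observations", call. = FALSE)
    }
    if (stats::sd(c(x, y)) == 0) {
      tt <- list(statistic = c(t = 0), parameter = length(c(x, y)) - 2,
                 p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    test_result_row(paste(pr, collapse = " vs "), "t",
                    unname(tt$statistic), df = unname(tt$parameter),
                    n = length(x) + length(y), p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = correction)
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic against the chi-squared reference
#' distribution.
#'
#' @param values numeric vector (or a data frame when `groups` names a
#'   column).
#' @param groups grouping vector (or column names when `values` is a data
#'   frame: `kruskal_wallis(df, "value_col", "group_col")` also works via
#'   [kw_from_table()]).
#' @return One `test_result` row, statistic `"H"`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(test_result_row("all groups", "H", 0,
                           df = nlevels(g) - 1, n = length(values),
                           p_raw = 1, p_adj = 1))
  }
  kt <- stats::kruskal.test(values, g)
  test_result_row("all groups", "H", unname(kt$statistic),
                  df = unname(kt$parameter), n = length(values),
                  p_raw = kt$p.value, p_adj = kt$p.value)
}

#' @rdname kruskal_wallis
#' @param table data frame.
#' @param response,factor_col column names.
#' @export
kw_from_table <- function(table, response, factor_col) {
  kruskal_wallis(table[[response]], table[[factor_col]])
}

#' Dunn post-hoc test
#'
#' Pairwise mean-rank comparisons after Kruskal-Wallis, with tie-corrected
#' variance:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}
#' with two-sided normal p values and Bonferroni adjustment.
#'
#' @param values numeric vector.
#' @param groups grouping vector.
#' @param correction adjustment method for [stats::p.adjust()].
#' @return Data frame of `test_result` rows, one per pair, statistic `"z"`
#'   (positive when the first-named group has the higher mean rank).
#' @export
dunn_test <- function(values, groups, correction = "bonferroni") {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  nn <- tabulate(g)
  if (any(nn == 1L)) warning("singleton group(s) present")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  mr <- tapply(r, g, mean)
  lv <- levels(g)
  pairs <- utils::combn(seq_along(lv), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(v0 * (1 / nn[i] + 1 / nn[j]))
    z <- if (se > 0) (mr[[i]] - mr[[j]]) / se else 0
    test_result_row(paste(lv[i], "vs", lv[j]), "z", z,
                    n = nn[i] + nn[j],
                    p_raw = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = correction)
  out
}

#' Linear regression of the tissue-reaction index on probe design
#'
#' Ordinary least squares of the index on material, tethering, cortical ROI
#' and shank cross-section (width x thickness, um^2), restricted to the
#' cortical ROIs. Aliased terms are dropped and reported.
#'
#' @param table data frame with columns `idx_tissue_reaction`, `material`,
#'   `tether`, `region`, `cross_section_um2`.
#' @return Data frame of per-coefficient `test_result` rows (statistic
#'   `"t"`, `value` is the t statistic, with columns `estimate` and `se`
#'   added); the fitted `lm` is attached as attribute `"fit"`.
#' @export
cross_section_regression <- function(table) {
  req <- c("idx_tissue_reaction", "material", "tether", "region",
           "cross_section_um2")
  stopifnot(all(req %in% names(table)))
  tab <- table[table$region %in% c("upper_cortex", "lower_cortex"), ,
               drop = FALSE]
  tab <- tab[stats::complete.cases(tab[req]), , drop = FALSE]
  for (f in c("material", "tether", "region")) {
    tab[[f]] <- factor(tab[[f]])
  }
  keep <- c("cross_section_um2",
            names(Filter(function(f) nlevels(tab[[f]]) >= 2L,
                         stats::setNames(as.list(c("material", "tether",
                                                   "region")),
                                         c("material", "tether", "region")))))
  fml <- stats::as.formula(paste("idx_tissue_reaction ~",
                                 paste(keep, collapse = " + ")))
  fit <- stats::lm(fml, data = tab)
  sm <- summary(fit)$coefficients
  ali <- is.na(coef(fit))
  if (any(ali)) {
    warning("dropped aliased term(s): ",
            paste(names(coef(fit))[ali], collapse = ", "))
  }
  out <- data.frame(
    comparison = rownames(sm),
    statistic = "t",
    value = sm[, "t value"],
    df = fit$df.residual,
    n = nrow(tab),
    p_raw = sm[, "Pr(>|t|)"],
    p_adj = sm[, "Pr(>|t|)"],
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Trend of the useful-electrode fraction over weeks
#'
#' Per-material ordinary least squares of the percentage of useful
#' electrodes (SNR > 1) on the week index.
#'
#' @param table data frame with columns `material`, `week`, `pct_useful`.
#' @return Data frame with one row per material: slope `estimate` (percent
#'   per week), `se`, t statistic, df, p value.
#' @export
useful_fraction_trend <- function(table) {
  stopifnot(all(c("material", "week", "pct_useful") %in% names(table)))
  rows <- lapply(split(table, table$material), function(d) {
    if (length(unique(d$week)) < 3L) {
      stop("need at least 3 time points per material", call. = FALSE)
    }
    fit <- stats::lm(pct_useful ~ week, data = d)
    sm <- summary(fit)$coefficients
    data.frame(material = d$material[1],
               estimate = sm["week", "Estimate"],
               se = sm["week", "Std. Error"],
               statistic = "t",
               value = sm["week", "t value"],
               df = fit$df.residual,
               n = nrow(d),
               p_raw = sm["week", "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
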