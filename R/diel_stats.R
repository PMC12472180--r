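#' Assumption-guarded group comparison (ANOVA or Kruskal-Wallis)
#'
#' The decision tree used for morning-versus-afternoon contrasts: residual
#' normality is assessed with a Shapiro-Wilk test and homoscedasticity with
#' a median-centred Levene (Brown-Forsythe) test; if both pass at
#' `alpha_assumption`, a one-way ANOVA is run, otherwise a Kruskal-Wallis
#' rank test. Written for two groups; k > 2 groups are accepted.
#'
#' @param values numeric observations.
#' @param groups factor (or coercible) of group labels, >= 2 observations
#'   per group.
#' @param alpha significance level for the group effect (default 0.05).
#' @param alpha_assumption level for the assumption pre-tests (default 0.05).
#' @param variable optional label carried into the result.
#' @param p_adjust optional multiple-testing method applied downstream by
#'   [compare_many()]; kept here for interface symmetry (unused).
#' @return object of class `"group_comparison"`: `variable`, `test_used`
#'   (`"anova"` or `"kruskal_wallis"`), `statistic`, `p_value`, `shapiro_p`,
#'   `levene_p`, `significant`, `flags` (character, e.g. constant-data
#'   fallthrough).
#' @export
compare_groups <- function(values, groups, alpha = 0.05, alpha_assumption = 0.05,
                           variable = NA_character_, p_adjust = NULL) {
  groups <- droplevels(as.factor(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations", call. = FALSE)
  flags <- character(0)

  resid <- values - stats::ave(values, groups)
  shapiro_p <- if (length(unique(round(resid, 12))) < 3 || stats::var(resid) == 0) {
    flags <- c(flags, "constant_data")
    NA_real_
  } else {
    stats::shapiro.test(resid)$p.value
  }
  levene_p <- if (stats::var(values) == 0) NA_real_ else {
    lv <- try(car::leveneTest(values ~ groups, center = stats::median), silent = TRUE)
    if (inherits(lv, "try-error") || is.na(lv[["Pr(>F)"]][1])) NA_real_ else lv[["Pr(>F)"]][1]
  }

  parametric <- !is.na(shapiro_p) && !is.na(levene_p) &&
    shapiro_p >= alpha_assumption && levene_p >= alpha_assumption
  if (is.na(shapiro_p) || is.na(levene_p)) {
    flags <- unique(c(flags, "assumptions_undefined"))
  }

  if (parametric) {
    fit <- stats::aov(values ~ groups)
    tab <- quiet_perfect_fit(summary(fit))[[1]]
    statistic <- tab[["F value"]][1]
    p_value <- tab[["Pr(>F)"]][1]
    test_used <- "anova"
  } else {
    kw <- stats::kruskal.test(values, groups)
    statistic <- unname(kw$statistic)
    p_value <- kw$p.value
    test_used <- "kruskal_wallis"
  }
  out <- list(
    variable = variable,
    test_used = test_used,
    statistic = statistic,
    p_value = p_value,
    shapiro_p = shapiro_p,
    levene_p = levene_p,
    significant = !is.na(p_value) && p_value < alpha,
    flags = flags
  )
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, stat = %.4g, p = %.4g (shapiro p %.3g, levene p %.3g)%s\n",
              if (is.na(x$variable)) "comparison" else x$variable,
              x$test_used, x$statistic, x$p_value, x$shapiro_p, x$levene_p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Run the group comparison across many variables
#'
#' Applies [compare_groups()] to each variable of a tidy table and returns
#' one row per variable; optional Benjamini-Hochberg adjustment of the
#' p-values (off by default, matching single-variable practice).
#'
#' @param data tidy data.frame with columns `variable`, `value` and a group
#'   column (default `session`).
#' @param group_col name of the grouping column.
#' @param alpha,alpha_assumption as in [compare_groups()].
#' @param p_adjust `NULL` (default, no correction) or `"BH"`.
#' @return data.frame with one row per variable: test used, statistic,
#'   p-value (adjusted if requested), assumption p-values, significance.
#' @export
compare_many <- function(data, group_col = "session", alpha = 0.05,
                         alpha_assumption = 0.05, p_adjust = NULL) {
  stopifnot(all(c("variable", "value", group_col) %in% names(data)))
  res <- lapply(split(data, data$variable), function(d) {
    cg <- compare_groups(d$value, d[[group_col]], alpha, alpha_assumption,
                         variable = d$variable[1])
    data.frame(variable = cg$variable, test_used = cg$test_used,
               statistic = cg$statistic, p_value = cg$p_value,
               shapiro_p = cg$shapiro_p, levene_p = cg$levene_p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(p_adjust)) out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  out
}

#' Spearman rank-correlation matrix with significance mask
#'
#' Pairwise-complete Spearman correlations between all columns of a
#' variables-by-observations table, with average ranks for ties, two-sided
#' p-values, and a significance mask at `alpha`. Pairs with fewer than
#' `min_pairs` complete observations are set to `NA` and flagged.
#'
#' @param table data.frame or matrix, one column per variable.
#' @param alpha significance level for the mask (default 0.05).
#' @param min_pairs minimum complete pairs per entry (default 4).
#' @return object of class `"correlation_matrix"`: list with `rho`, `p`,
#'   `n` (complete-pair counts), `significant` (logical mask),
#'   `insufficient` (logical mask of skipped pairs), `alpha`.
#' @export
spearman_matrix <- function(table, alpha = 0.05, min_pairs = 4) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("table must be numeric", call. = FALSE)
  v <- ncol(m)
  vars <- colnames(m)
  if (is.null(vars)) vars <- paste0("V", seq_len(v))
  rho <- p <- matrix(NA_real_, v, v, dimnames = list(vars, vars))
  n <- matrix(0L, v, v, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(v)) {
    n[i, i] <- sum(!is.na(m[, i]))
    for (j in seq_len(v)) {
      if (j <= i) next
      ok <- stats::complete.cases(m[, i], m[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < min_pairs) next
      ct <- suppressWarnings(
        stats::cor.test(m[ok, i], m[ok, j], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  out <- list(rho = rho, p = p, n = n,
              significant = !is.na(p) & p < alpha & row(p) != col(p),
              insufficient = n < min_pairs & row(n) != col(n),
              alpha = alpha)
  class(out) <- "correlation_matrix"
  out
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Spearman correlation matrix, %d variables; %d significant pair(s) at alpha = %g\n",
              ncol(x$rho), sum(x$significant, na.rm = TRUE) / 2, x$alpha))
  print(round(x$rho, 3))
  invisible(x)
}
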