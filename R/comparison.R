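#' Two-tailed paired t-test
#'
#' Thin wrapper with the degenerate cases pinned down: identical vectors
#' return `t = 0, p = 1` (no evidence of a difference), while differences of
#' zero variance around a nonzero mean are an error (the statistic is
#' infinite).
#'
#' @param a,b Paired numeric vectors, equal length >= 3.
#' @return Tibble with columns `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort("a and b must be paired vectors of equal length >= 3")
  }
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(tibble::tibble(t = 0, df = length(d) - 1, p = 1))
    abort("differences have zero variance around a nonzero mean")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th by (m - i + 1), enforces
#' monotonicity, caps at 1 and returns the adjusted values in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F-test across treatment levels with the subject effect
#' removed: `F = MS_treatment / MS_error` with `df1 = k - 1`,
#' `df2 = (k - 1)(n - 1)` for k levels and n subjects. No sphericity
#' correction is applied by default; `gg_correct = TRUE` applies the
#' Greenhouse-Geisser epsilon to the degrees of freedom.
#'
#' @param values Numeric matrix, subjects x levels, complete and balanced
#'   (or a data frame coercible to one).
#' @param gg_correct Apply Greenhouse-Geisser correction.
#' @return Tibble with columns `F`, `df1`, `df2`, `p` (and `epsilon` when
#'   corrected).
#' @export
rm_anova <- function(values, gg_correct = FALSE) {
  m <- as.matrix(values)
  if (any(!is.finite(m))) abort("missing cells: the design must be complete")
  n <- nrow(m); k <- ncol(m)
  if (k < 2 || n < 3) abort("need >= 2 levels and >= 3 subjects")
  df <- data.frame(value = as.vector(m),
                   level = factor(rep(seq_len(k), each = n)),
                   subject = factor(rep(seq_len(n), k)))
  fit <- stats::aov(value ~ level + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  fval <- tab["level", "F value"]
  df1 <- tab["level", "Df"]; df2 <- tab["Residuals", "Df"]
  # identical levels leave zero treatment SS up to rounding; pin F at 0
  ss_tr <- n * sum((colMeans(m) - mean(m))^2)
  if (is.na(fval) || ss_tr <= 1e-12 * (sum(m^2) + 1e-300)) fval <- 0
  if (gg_correct) {
    eps <- gg_epsilon(m)
    p <- stats::pf(fval, df1 * eps, df2 * eps, lower.tail = FALSE)
    return(tibble::tibble(F = fval, df1 = df1, df2 = df2, p = p, epsilon = eps))
  }
  tibble::tibble(F = fval, df1 = df1, df2 = df2,
                 p = stats::pf(fval, df1, df2, lower.tail = FALSE))
}

# Greenhouse-Geisser epsilon from the double-centred covariance of levels.
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  J <- diag(k) - 1 / k
  Sc <- J %*% S %*% J
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Regressor comparison report
#'
#' Runs the within-condition statistics on a tidy per-subject metric table:
#' for every (condition, metric) cell a one-way repeated-measures ANOVA
#' across regressors, followed by all pairwise two-tailed paired t-tests with
#' Holm-Bonferroni correction applied within that cell.
#'
#' @param metric_table Tibble with columns `subject`, `condition`,
#'   `regressor`, `metric`, `value`; one row per combination (balanced).
#' @param alpha Significance level recorded in the report.
#' @return An `abr_comparison` object: list with tibbles `anova` and
#'   `pairwise`, plus `alpha`. `tidy()` returns the pairwise table,
#'   `glance()` the ANOVA table.
#' @export
run_comparison <- function(metric_table, alpha = 0.05) {
  needed <- c("subject", "condition", "regressor", "metric", "value")
  if (!all(needed %in% names(metric_table))) {
    abort(paste0("metric_table needs columns ", paste(needed, collapse = ", ")))
  }
  counts <- metric_table |>
    dplyr::count(.data$condition, .data$metric, .data$regressor, .data$subject)
  if (any(counts$n != 1)) abort("duplicated (subject, condition, regressor, metric) cells")
  full <- tidyr::expand_grid(
    condition = unique(metric_table$condition),
    metric = unique(metric_table$metric),
    regressor = unique(metric_table$regressor),
    subject = unique(metric_table$subject))
  missing <- dplyr::anti_join(
    full, metric_table,
    by = c("condition", "metric", "regressor", "subject"))
  if (nrow(missing) > 0) {
    abort(paste0("unbalanced table; missing cells e.g. ",
                 paste(utils::head(apply(missing, 1, paste, collapse = "/"), 3),
                       collapse = "; ")))
  }

  cells <- metric_table |> dplyr::distinct(.data$condition, .data$metric)
  anova_rows <- list(); pair_rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- metric_table |>
      dplyr::filter(.data$condition == cells$condition[i],
                    .data$metric == cells$metric[i])
    wide <- sub |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "regressor",
                         values_from = "value") |>
      dplyr::arrange(.data$subject)
    regs <- setdiff(names(wide), "subject")
    an <- rm_anova(as.matrix(wide[regs]))
    anova_rows[[i]] <- dplyr::bind_cols(cells[i, ], an)

    prs <- utils::combn(regs, 2, simplify = FALSE)
    pt <- purrr::map(prs, function(pr) {
      res <- paired_t(wide[[pr[1]]], wide[[pr[2]]])
      dplyr::bind_cols(cells[i, ],
                       tibble::tibble(a = pr[1], b = pr[2]), res)
    }) |> dplyr::bind_rows()
    pt$p_adj <- holm_bonferroni(pt$p)
    pair_rows[[i]] <- pt
  }
  structure(list(anova = dplyr::bind_rows(anova_rows),
                 pairwise = dplyr::bind_rows(pair_rows),
                 alpha = alpha),
            class = "abr_comparison")
}

#' @export
print.abr_comparison <- function(x, ...) {
  cat("<abr_comparison> alpha =", x$alpha, "\n\nRepeated-measures ANOVA:\n")
  print(x$anova)
  cat("\nPairwise paired t (Holm-Bonferroni adjusted):\n")
  print(x$pairwise)
  invisible(x)
}

#' Write a comparison report to TSV and JSON
#'
#' @param x An `abr_comparison`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @param settings Named list of run settings (seeds, sizes) logged into the
#'   JSON report.
#' @return `x`, invisibly.
#' @export
write_comparison <- function(x, tsv_path = NULL, json_path = NULL,
                             settings = list()) {
  stopifnot(inherits(x, "abr_comparison"))
  if (!is.null(tsv_path)) {
    utils::write.table(x$pairwise, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(alpha = x$alpha, settings = settings,
                              anova = x$anova, pairwise = x$pairwise),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
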