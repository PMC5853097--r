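#' Correlation of fatty acid composition with seafood intake
#'
#' Per-analyte correlation of relative concentration with reported seafood
#' meals per month, computed within each requested group (cases, controls,
#' and pooled), pairwise-complete. Pearson by default (the analysis frames
#' the association as a regression of composition onto intake); Spearman
#' available for sensitivity.
#'
#' @param tab a [cohort_table()] with `seafood_meals_per_month`.
#' @param groups subset of `c("ASD", "NEU", "pooled")`.
#' @param analytes analyte codes; default all 15.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame with one row per analyte and one correlation column
#'   per group; fewer than 3 complete pairs gives `NA` with a warning.
#' @export
seafood_correlation <- function(tab, groups = c("ASD", "NEU", "pooled"),
                                analytes = fa_all(),
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  groups <- match.arg(groups, several.ok = TRUE)
  assert_analytes(analytes)
  if (!"seafood_meals_per_month" %in% names(tab))
    stop("seafood_meals_per_month column absent", call. = FALSE)
  out <- data.frame(analyte = analytes, stringsAsFactors = FALSE)
  for (g in groups) {
    sel <- if (g == "pooled") rep(TRUE, nrow(tab)) else tab$cohort == g
    s <- tab$seafood_meals_per_month[sel]
    out[[g]] <- vapply(analytes, function(a) {
      v <- tab[[a]][sel]
      ok <- !is.na(v) & !is.na(s)
      if (sum(ok) < 3) {
        warning("fewer than 3 complete pairs for ", a, " in group ", g,
                call. = FALSE)
        return(NA_real_)
      }
      if (stats::sd(v[ok]) == 0 || stats::sd(s[ok]) == 0) {
        warning("zero variance for ", a, " in group ", g,
                "; correlation undefined", call. = FALSE)
        return(NA_real_)
      }
      stats::cor(v[ok], s[ok], method = method)
    }, 0)
  }
  out
}
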