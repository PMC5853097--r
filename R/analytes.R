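#' Analyte registry for the erythrocyte fatty acid panel
#'
#' The panel comprises 11 measured fatty acids, reported as percent of total
#' fatty acids in the sample, plus 4 derived measures (two ratios to AA, the
#' n-3/n-6 ratio, and total PUFA). Canonical short codes are used as column
#' names throughout; display names carry the carbon:double-bond notation.
#'
#' @return `fa_analytes()` returns a data.frame with one row per analyte:
#'   `code`, `display`, `kind` ("measured" or "derived"), and `group`
#'   (PUFA family or saturate/MUFA class).
#' @export
fa_analytes <- function() {
  data.frame(
    code = c("AA", "DGLA", "DHA", "EPA", "elaidic", "LA", "oleic",
             "palmitelaidic", "palmitic", "palmitoleic", "stearic",
             "DHA_AA", "EPA_AA", "n3_n6", "total_PUFA"),
    display = c("AA (20:4n-6)", "DGLA (20:3n-6)", "DHA (22:6n-3)",
                "EPA (20:5n-3)", "Elaidic acid (18:1n-9 trans)",
                "Linoleic acid (18:2n-6)", "Oleic acid (18:1n-9)",
                "Palmitelaidic acid (16:1n-9 trans)", "Palmitic acid (16:0)",
                "Palmitoleic acid (17:1n-7)", "Stearic acid (18:0)",
                "DHA/AA", "EPA/AA", "n-3/n-6", "Total PUFA"),
    kind = c(rep("measured", 11), rep("derived", 4)),
    group = c("n-6", "n-6", "n-3", "n-3", "trans", "n-6", "MUFA",
              "trans", "saturate", "MUFA", "saturate",
              "ratio", "ratio", "ratio", "sum"),
    stringsAsFactors = FALSE
  )
}

#' @rdname fa_analytes
#' @export
fa_measured <- function() fa_analytes()$code[fa_analytes()$kind == "measured"]

#' @rdname fa_analytes
#' @export
fa_derived <- function() fa_analytes()$code[fa_analytes()$kind == "derived"]

# n-3 and n-6 PUFAs among the measured panel; these define the derived sums.
fa_n3 <- function() c("DHA", "EPA")
fa_n6 <- function() c("AA", "DGLA", "LA")

#' @rdname fa_analytes
#' @export
fa_all <- function() fa_analytes()$code

assert_analytes <- function(x) {
  bad <- setdiff(x, fa_all())
  if (length(bad))
    stop("unknown analyte code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(x)
}
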