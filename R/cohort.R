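#' Cohort tables of individual-level fatty acid measurements
#'
#' A cohort table is a data.frame with one row per subject carrying
#' `subject_id` (unique), `cohort` (factor with levels "ASD", "NEU"),
#' optional `diagnosis_subtype` ("autism", "Aspergers", "PDD_NOS", "none"),
#' optional `seafood_meals_per_month`, optional `severity_*` score columns,
#' and one numeric column per analyte code (see [fa_analytes()]).
#' Measured analytes are relative concentrations in percent of total fatty
#' acids; derived measures are dimensionless.
#'
#' @param records data.frame of subject rows.
#' @param provenance free-text source tag.
#' @return An object of class `cohort_table` (a data.frame).
#' @export
cohort_table <- function(records, provenance = "unspecified") {
  stopifnot(is.data.frame(records))
  tab <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"cohort" %in% names(tab))
    stop("cohort column is required", call. = FALSE)
  tab$cohort <- factor(as.character(tab$cohort), levels = c("ASD", "NEU"))
  if (anyNA(tab$cohort))
    stop("cohort labels must be ASD or NEU", call. = FALSE)
  if (!"subject_id" %in% names(tab))
    tab$subject_id <- sprintf("S%03d", seq_len(nrow(tab)))
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id values: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "), call. = FALSE)
  attr(tab, "provenance") <- provenance
  class(tab) <- c("cohort_table", "data.frame")
  validate_cohort(tab)
  tab
}

#' Validate a cohort table
#'
#' Checks the structural invariants: unique subject ids, recognised cohort
#' labels, nonnegative measured concentrations, approximate compositional
#' closure (the 11 measured relative concentrations cannot exceed 100% of
#' total fatty acids; closure violations warn rather than error because the
#' synthetic generator reproduces marginal structure, not exact closure),
#' and consistency of stored derived measures with [compute_derived()].
#'
#' @param tab a `cohort_table`.
#' @param closure_tol rows whose measured sum exceeds `100 + closure_tol`
#'   trigger a warning.
#' @return `tab`, invisibly.
#' @export
validate_cohort <- function(tab, closure_tol = 0) {
  stopifnot(inherits(tab, "data.frame"))
  meas <- intersect(fa_measured(), names(tab))
  for (a in meas) {
    v <- tab[[a]]
    if (!is.numeric(v)) stop("analyte column not numeric: ", a, call. = FALSE)
    if (any(v < 0, na.rm = TRUE))
      warning("negative concentration in analyte ", a,
              " (", sum(v < 0, na.rm = TRUE), " row(s)); relative ",
              "concentrations are nonnegative", call. = FALSE)
  }
  if (length(meas) == 11L) {
    s <- rowSums(tab[meas])
    over <- which(!is.na(s) & s > 100 + closure_tol)
    if (length(over))
      warning(length(over), " row(s) with measured fatty acids summing above ",
              "100% of total (max ", format(max(s[over]), digits = 6),
              "); check units or closure", call. = FALSE)
    der <- intersect(fa_derived(), names(tab))
    if (length(der)) {
      rec <- compute_derived(tab, overwrite = TRUE, quiet = TRUE)
      for (a in der) {
        ok <- is.na(tab[[a]]) | is.na(rec[[a]]) |
          abs(tab[[a]] - rec[[a]]) <= 1e-6 * pmax(1, abs(rec[[a]]))
        if (!all(ok))
          warning("stored derived measure ", a,
                  " inconsistent with recomputation in ",
                  sum(!ok), " row(s)", call. = FALSE)
      }
    }
  }
  invisible(tab)
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- table(x$cohort)
  cat("Cohort table:", nrow(x), "subjects (",
      paste(sprintf("%s n=%d", names(n), n), collapse = ", "), ")\n")
  cat("Provenance:", attr(x, "provenance") %||% "unspecified", "\n")
  cat("Analytes present:",
      paste(intersect(fa_all(), names(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Default CSV dialect: header-to-field mapping
#'
#' The exact column headers of an external individual-level CSV are not
#' standardised, so ingestion is driven by a dialect: a named character
#' vector mapping *file headers* to canonical field/analyte names. The
#' default dialect maps canonical names to themselves plus a few common
#' variants. Override entries or supply a fresh mapping (or a two-column
#' `header=field` key-value file via [read_dialect_file()]).
#'
#' @param ... named overrides, e.g. `c("DHA (22:6n-3)" = "DHA")`.
#' @return named character vector (names = file headers, values = fields).
#' @export
default_dialect <- function(...) {
  base <- c(
    subject_id = "subject_id", id = "subject_id", ID = "subject_id",
    cohort = "cohort", group = "cohort", Group = "cohort",
    diagnosis_subtype = "diagnosis_subtype", subtype = "diagnosis_subtype",
    seafood_meals_per_month = "seafood_meals_per_month",
    seafood = "seafood_meals_per_month",
    stats::setNames(fa_all(), fa_all())
  )
  over <- c(...)
  if (length(over)) base[names(over)] <- over
  base
}

#' @rdname default_dialect
#' @param path flat key-value file, one `header=field` pair per line; `#`
#'   starts a comment.
#' @export
read_dialect_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed dialect line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                  trimws(vapply(kv, `[`, "", 1L)))
}

#' Read an individual-level cohort CSV
#'
#' Reads a header-rowed CSV of per-subject fatty acid measurements, mapping
#' columns to canonical fields through a dialect. Unparseable numeric cells
#' become `NA`, never silent zeros. Columns whose header the dialect does
#' not know are dropped with a warning, except `severity_*` columns which
#' are retained as opaque numeric severity scores.
#'
#' @param path CSV file path.
#' @param dialect named character vector, see [default_dialect()].
#' @param provenance source tag stored on the result.
#' @return a [cohort_table()]; per-cohort row counts are reported via
#'   `message()` and stored in attribute `cohort_counts`.
#' @export
read_cohort_csv <- function(path, dialect = default_dialect(),
                            provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  out <- list()
  for (h in names(raw)) {
    if (h %in% names(dialect)) {
      out[[unname(dialect[h])]] <- raw[[h]]
    } else if (grepl("^severity_", h)) {
      out[[h]] <- raw[[h]]
    } else {
      warning("ignoring unknown column: ", h, call. = FALSE)
    }
  }
  if (!"cohort" %in% names(out))
    stop("no cohort column found (dialect maps none of: ",
         paste(names(raw), collapse = ", "), ")", call. = FALSE)
  tab <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  numcols <- c(intersect(fa_all(), names(tab)), "seafood_meals_per_month",
               grep("^severity_", names(tab), value = TRUE))
  for (cc in intersect(numcols, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    v[!nzchar(trimws(tab[[cc]]))] <- NA
    tab[[cc]] <- v
  }
  tab <- cohort_table(tab, provenance = provenance)
  counts <- table(tab$cohort)
  attr(tab, "cohort_counts") <- counts
  message("read ", nrow(tab), " subjects: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  tab
}

#' Write a cohort table to CSV
#'
#' Writes values at full double precision (`%.15g`) so that a
#' read/write/read cycle is numerically faithful to 1e-12. Optional columns
#' that are entirely absent are omitted from the file.
#'
#' @param tab a `cohort_table`.
#' @param path output file path.
#' @export
write_cohort_csv <- function(tab, path) {
  stopifnot(inherits(tab, "data.frame"))
  out <- as.data.frame(tab)
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) {
      v <- sprintf("%.15g", out[[cc]])
      v[is.na(out[[cc]])] <- ""
      out[[cc]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Compute derived fatty acid measures
#'
#' Fills the four derived measures from the 11 measured analytes:
#' DHA/AA, EPA/AA, the n-3/n-6 ratio (n-3 sum = DHA + EPA; n-6 sum =
#' AA + DGLA + LA, the PUFAs of the measured panel), and total PUFA as the
#' long-chain PUFA sum AA + DGLA + DHA + EPA — the C20+ species, excluding
#' the C18 precursor LA. (The panel's published central values pin these
#' definitions down: the n-3/n-6 centrals are only reproduced with LA in
#' the n-6 denominator, while the total-PUFA centrals of about 26.5% are
#' only reproduced without it.) Ratios with a zero denominator become `NA`
#' with a warning. Idempotent.
#'
#' @param tab a `cohort_table` (or plain data.frame) with the 11 measured
#'   analyte columns.
#' @param overwrite recompute even where derived columns already hold values.
#' @param quiet suppress the zero-denominator warning.
#' @return `tab` with the derived columns filled.
#' @export
compute_derived <- function(tab, overwrite = TRUE, quiet = FALSE) {
  miss <- setdiff(fa_measured(), names(tab))
  if (length(miss))
    stop("measured analytes missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n3 <- rowSums(tab[fa_n3()])
  n6 <- rowSums(tab[fa_n6()])
  zero_aa <- !is.na(tab$AA) & tab$AA == 0
  zero_n6 <- !is.na(n6) & n6 == 0
  if (!quiet && any(zero_aa | zero_n6))
    warning("zero denominator in ", sum(zero_aa | zero_n6),
            " row(s); ratio set to NA", call. = FALSE)
  der <- data.frame(
    DHA_AA = ifelse(zero_aa, NA_real_, tab$DHA / tab$AA),
    EPA_AA = ifelse(zero_aa, NA_real_, tab$EPA / tab$AA),
    n3_n6 = ifelse(zero_n6, NA_real_, n3 / n6),
    total_PUFA = n3 + tab$AA + tab$DGLA
  )
  for (a in names(der)) {
    if (overwrite || !a %in% names(tab)) tab[[a]] <- der[[a]]
    else tab[[a]] <- ifelse(is.na(tab[[a]]), der[[a]], tab[[a]])
  }
  tab
}

#' Exclude diagnosis subtypes from the case cohort
#'
#' Removes ASD records whose `diagnosis_subtype` is in `subtypes`
#' (sensitivity re-analysis, e.g. dropping Asperger's and PDD-NOS
#' participants). Control (NEU) records are never removed.
#'
#' @param tab a `cohort_table` with subtype metadata on ASD rows.
#' @param subtypes character vector of subtype labels to drop.
#' @return filtered `cohort_table`; the number of removed records is
#'   reported via `message()` and attribute `n_removed`.
#' @export
exclude_subtypes <- function(tab, subtypes) {
  stopifnot(inherits(tab, "data.frame"))
  if (length(subtypes) == 0) {
    attr(tab, "n_removed") <- 0L
    return(tab)
  }
  if (!"diagnosis_subtype" %in% names(tab))
    stop("column diagnosis_subtype is absent; subtype exclusion needs it",
         call. = FALSE)
  drop <- tab$cohort == "ASD" &
    !is.na(tab$diagnosis_subtype) & tab$diagnosis_subtype %in% subtypes
  out <- tab[!drop, , drop = FALSE]
  attr(out, "provenance") <- attr(tab, "provenance")
  attr(out, "n_removed") <- sum(drop)
  class(out) <- class(tab)
  message("removed ", sum(drop), " ASD record(s) with subtype in {",
          paste(subtypes, collapse = ", "), "}")
  out
}

# split one analyte into per-cohort vectors, dropping NA pairwise
cohort_split <- function(tab, analyte, min_n = 1L) {
  assert_analytes(analyte)
  if (!analyte %in% names(tab))
    stop("analyte column absent: ", analyte, call. = FALSE)
  x <- tab[[analyte]][tab$cohort == "ASD"]
  y <- tab[[analyte]][tab$cohort == "NEU"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < min_n || length(y) < min_n)
    stop("insufficient records for two-sample analysis of ", analyte,
         " (ASD n=", length(x), ", NEU n=", length(y), ")", call. = FALSE)
  list(asd = x, neu = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
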