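#' Default column mapping for cohort tables
#'
#' Maps the canonical field names used internally to the column names expected
#' in a delimited cohort file. Override any entry to read files with different
#' headers, e.g. `cohort_schema(p_vte = "ccvm_prob")`.
#'
#' @param patient_id,p_vte,p_bleed,padua_score,improve_score,physician_prophylaxis
#'   Column names in the file for each canonical field.
#' @return A named character vector (canonical field -> file column).
#' @export
cohort_schema <- function(patient_id = "patient_id",
                          p_vte = "p_vte",
                          p_bleed = "p_bleed",
                          padua_score = "padua",
                          improve_score = "improve",
                          physician_prophylaxis = "physician_ppx") {
  c(
    patient_id = patient_id,
    p_vte = p_vte,
    p_bleed = p_bleed,
    padua_score = padua_score,
    improve_score = improve_score,
    physician_prophylaxis = physician_prophylaxis
  )
}

#' Construct a validated patient cohort
#'
#' A cohort is a tibble of one row per admission carrying the two model-based
#' risk predictions (14-day VTE probability and in-hospital major-bleeding
#' probability, both as fractions in (0, 1)), the Padua and IMPROVE point
#' scores, and the observed physician prophylaxis flag. Probabilities are
#' always stored as fractions; percentages appear only in rendered output.
#'
#' Score columns may be `NA` throughout (a cohort without scores supports
#' every strategy except `guidelines`).
#'
#' @param records A data frame with columns `patient_id`, `p_vte`, `p_bleed`,
#'   `padua_score`, `improve_score`, `physician_prophylaxis`. Missing score
#'   columns are filled with `NA`.
#' @param metadata Optional named list of provenance tags (source, seed,
#'   generator config digest) stored as an attribute and round-tripped through
#'   [write_cohort()] / [read_cohort()].
#' @return A tibble of class `vte_cohort`.
#' @export
new_cohort <- function(records, metadata = list()) {
  records <- tibble::as_tibble(records)
  for (col in c("padua_score", "improve_score")) {
    if (!col %in% names(records)) records[[col]] <- NA_integer_
  }
  required <- c(
    "patient_id", "p_vte", "p_bleed",
    "padua_score", "improve_score", "physician_prophylaxis"
  )
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(
      paste0("cohort is missing column(s): ", paste(missing, collapse = ", ")),
      class = "vteprophy_schema_error"
    )
  }
  records <- records[required]
  records$patient_id <- as.character(records$patient_id)
  records$physician_prophylaxis <- as.logical(records$physician_prophylaxis)
  records$padua_score <- as.integer(records$padua_score)
  records$improve_score <- as.integer(records$improve_score)
  report <- validate_cohort(records)
  if (nrow(report) > 0) {
    offenders <- unique(report$patient_id)
    abort(
      paste0(
        "invalid cohort: ", nrow(report), " violation(s), e.g. row ",
        report$row[1], " (", report$patient_id[1], "): ", report$field[1],
        " ", report$violation[1], ". Offending patient_ids: ",
        paste(head(offenders, 10), collapse = ", "),
        if (length(offenders) > 10) ", ..." else ""
      ),
      class = "vteprophy_validation_error",
      report = report
    )
  }
  structure(
    records,
    metadata = metadata,
    class = c("vte_cohort", class(tibble::tibble()))
  )
}

#' Validate cohort records
#'
#' Checks the cohort invariants: probabilities strictly inside (0, 1) (a
#' predicted risk of exactly 0 or 1 is treated as a data error), integer
#' scores >= 0 where present, a non-missing logical prophylaxis flag, and
#' unique patient identifiers in a non-empty table.
#'
#' @param records A data frame of cohort records (canonical column names).
#' @return A tibble listing violations with columns `row`, `patient_id`,
#'   `field`, `violation`; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(records) {
  out <- list()
  add <- function(rows, field, violation) {
    if (length(rows) > 0) {
      out[[length(out) + 1]] <<- tibble::tibble(
        row = rows,
        patient_id = as.character(records$patient_id[rows]),
        field = field,
        violation = violation
      )
    }
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(
      row = 0L, patient_id = NA_character_,
      field = "records", violation = "cohort is empty"
    ))
  }
  for (col in c("p_vte", "p_bleed")) {
    p <- records[[col]]
    add(which(is.na(p)), col, "is missing")
    add(which(!is.na(p) & (p <= 0 | p >= 1)), col, "must lie strictly in (0, 1)")
  }
  for (col in c("padua_score", "improve_score")) {
    s <- records[[col]]
    add(which(!is.na(s) & s < 0), col, "must be a non-negative integer")
  }
  add(which(is.na(records$physician_prophylaxis)), "physician_prophylaxis", "is missing")
  dup <- which(duplicated(records$patient_id))
  add(dup, "patient_id", "is duplicated")
  if (length(out) == 0) {
    return(tibble::tibble(
      row = integer(), patient_id = character(),
      field = character(), violation = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row)
}

#' Cohort metadata
#'
#' @param cohort A `vte_cohort`.
#' @return The named list of provenance tags attached to the cohort.
#' @export
cohort_metadata <- function(cohort) {
  attr(cohort, "metadata") %||% list()
}

assert_cohort <- function(cohort) {
  if (!inherits(cohort, "vte_cohort")) {
    abort("expected a `vte_cohort`; see new_cohort()",
      class = "vteprophy_config_error"
    )
  }
  invisible(cohort)
}

#' Read a cohort table from delimited text
#'
#' Reads a UTF-8 delimited file (comma by default; tab detected from the
#' header line) with one row per admission. Leading `#`-prefixed lines are
#' treated as metadata comments of the form `# key: value` and recovered into
#' the cohort metadata. Score columns are optional; all other mapped columns
#' must be present.
#'
#' @param path Path to the file.
#' @param schema Column mapping from [cohort_schema()].
#' @param delim Field delimiter; `NULL` (default) sniffs `,` vs tab.
#' @return A validated [new_cohort()] object, rows in file order.
#' @export
read_cohort <- function(path, schema = cohort_schema(), delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path), class = "vteprophy_io_error")
  }
  lines <- readLines(path, n = 200L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(
    path,
    delim = delim, comment = "#", show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
  optional <- c("padua_score", "improve_score")
  missing <- schema[!schema %in% names(tab)]
  hard_missing <- missing[!names(missing) %in% optional]
  if (length(hard_missing) > 0) {
    abort(
      paste0(
        "cohort file lacks required column(s): ",
        paste(hard_missing, collapse = ", ")
      ),
      class = "vteprophy_schema_error"
    )
  }
  records <- tibble::tibble(.rows = nrow(tab))
  for (field in names(schema)) {
    col <- schema[[field]]
    if (col %in% names(tab)) records[[field]] <- tab[[col]]
  }
  for (field in c("p_vte", "p_bleed")) {
    if (!is.numeric(records[[field]])) {
      val <- suppressWarnings(as.numeric(records[[field]]))
      bad <- which(is.na(val) & !is.na(records[[field]]))
      if (length(bad) > 0) {
        abort(
          paste0(
            field, " does not parse as a number in row(s): ",
            paste(head(bad, 10), collapse = ", ")
          ),
          class = "vteprophy_validation_error"
        )
      }
      records[[field]] <- val
    }
  }
  if (is.numeric(records$physician_prophylaxis)) {
    records$physician_prophylaxis <- records$physician_prophylaxis != 0
  }
  metadata <- parse_metadata_comments(meta_lines)
  new_cohort(records, metadata = metadata)
}

parse_metadata_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' Write a cohort table to delimited text
#'
#' Writes a comma-delimited UTF-8 file with a header row, preceded by
#' `# key: value` comment lines for any cohort metadata. Probabilities are
#' written with 15 significant digits so a write/read round trip reproduces
#' the cohort.
#'
#' @param cohort A `vte_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  assert_cohort(cohort)
  meta <- cohort_metadata(cohort)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"), error = function(e) {
    abort(paste0("cannot open path for writing: ", path),
      class = "vteprophy_io_error"
    )
  })
  on.exit(close(con), add = TRUE)
  for (key in names(meta)) {
    writeLines(paste0("# ", key, ": ", format(meta[[key]])), con)
  }
  out <- as.data.frame(cohort)
  names(out) <- cohort_schema()[names(out)]
  out$p_vte <- formatC(out$p_vte, digits = 15, format = "g")
  out$p_bleed <- formatC(out$p_bleed, digits = 15, format = "g")
  out$physician_ppx <- as.integer(out$physician_ppx)
  writeLines(paste(names(out), collapse = ","), con)
  body <- do.call(paste, c(lapply(out, as.character), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Summarise a cohort
#'
#' Location statistics of the two predicted risks plus the observed
#' prophylaxis rate, mirroring how inpatient cohorts are usually described
#' (mean/median/min/max risk, fraction prescribed).
#'
#' @param cohort A `vte_cohort`.
#' @return A one-row tibble with columns `n`, `vte_mean`, `vte_median`,
#'   `vte_min`, `vte_max`, `bleed_mean`, `bleed_median`, `bleed_min`,
#'   `bleed_max` (all fractions) and `ppx_rate` (fraction prescribed).
#' @export
summarize_cohort <- function(cohort) {
  assert_cohort(cohort)
  tibble::tibble(
    n = nrow(cohort),
    vte_mean = mean(cohort$p_vte),
    vte_median = median(cohort$p_vte),
    vte_min = min(cohort$p_vte),
    vte_max = max(cohort$p_vte),
    bleed_mean = mean(cohort$p_bleed),
    bleed_median = median(cohort$p_bleed),
    bleed_min = min(cohort$p_bleed),
    bleed_max = max(cohort$p_bleed),
    ppx_rate = mean(cohort$physician_prophylaxis)
  )
}

#' @export
print.vte_cohort <- function(x, ...) {
  meta <- cohort_metadata(x)
  cat("<vte_cohort> ", nrow(x), " admissions\n", sep = "")
  if (length(meta) > 0) {
    cat("  metadata: ", paste(names(meta), unlist(meta), sep = "=", collapse = "; "),
      "\n",
      sep = ""
    )
  }
  NextMethod()
}
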