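#' Read rating and pattern-response tables
#'
#' Reads a comma-separated, header-row CSV of per-trial or per-condition
#' records (subject identifiers, ratings, and scalar pattern responses) into
#' a typed tibble. Column names are matched case-insensitively against a
#' small set of synonyms (`subject`/`subject_id`/`subj`, `rating`/`value`,
#' `trial`, `item`/`photo`); matched columns are renamed to the package's
#' canonical names, everything else passes through untouched. Columns whose
#' names start with `C_` are treated as per-cluster pattern responses and
#' kept as numeric.
#'
#' @param path CSV path.
#' @param required canonical column names that must be present after
#'   renaming; missing ones raise an error naming them.
#' @return A tibble with canonical names where recognized.
#' @export
read_response_table <- function(path, required = "subject_id") {
  if (!file.exists(path)) {
    stop(sprintf("response table '%s' does not exist", path), call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop(sprintf("response table '%s' is empty", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || !ncol(df)) {
    stop(sprintf("response table '%s' has no data rows", path), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  canon <- c(
    subject_id = "^(subject(_?id)?|subj(ect)?_?nr?|participant(_?id)?)$",
    rating = "^(rating|ratings|observed_rating)$",
    trial = "^trial(_?id|_?number)?$",
    item = "^(item|photo|picture|image)(_?id)?$",
    condition = "^(condition|level|cond)$",
    modality = "^modality$"
  )
  nm <- names(df)
  for (target in names(canon)) {
    hit <- grep(canon[[target]], nm, ignore.case = TRUE)
    if (length(hit) >= 1 && !target %in% nm) {
      nm[hit[1]] <- target
    }
  }
  names(df) <- nm
  cluster_cols <- grep("^C_", nm, value = TRUE)
  for (cc in cluster_cols) df[[cc]] <- as.numeric(df[[cc]])
  if ("rating" %in% nm) df$rating <- as.numeric(df$rating)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("response table missing required column(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Validate a rating table
#'
#' Checks that ratings lie within the declared scale and that each
#' (subject, trial) pair occurs once.
#'
#' @param tbl data frame with `subject_id`, `rating`, and a `trial` or
#'   `condition` column.
#' @param scale numeric range of admissible ratings.
#' @return The table as a tibble, invisibly checked.
#' @export
validate_rating_table <- function(tbl, scale = c(1, 5)) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("subject_id", "rating") %in% names(tbl)))
  if (any(tbl$rating < scale[1] | tbl$rating > scale[2], na.rm = TRUE)) {
    stop("ratings outside declared scale bounds", call. = FALSE)
  }
  keycol <- intersect(c("trial", "condition"), names(tbl))[1]
  if (!is.na(keycol)) {
    key <- paste(tbl$subject_id, tbl[[keycol]])
    if (anyDuplicated(key)) {
      stop("duplicate (subject, trial) rows in rating table", call. = FALSE)
    }
  }
  tbl
}
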