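#' Feature table schemas
#'
#' Feature tables are plain data.frames with annotation columns followed by
#' numeric feature columns. Three schemas are recognised:
#' \describe{
#'   \item{cohort}{`sample_id` (unique), `group` in \{wildtype, mutant\}.}
#'   \item{retest}{`sample_id` (unique); a second measurement of a cohort
#'     table's features.}
#'   \item{phantom}{`lesion_id` and `condition_id`; the pair is unique.}
#' }
#' @name feature_table
NULL

schema_annotations <- function(schema) {
  switch(schema,
    cohort = c("sample_id", "group"),
    retest = "sample_id",
    phantom = c("lesion_id", "condition_id"),
    stop("unknown schema: ", schema, call. = FALSE)
  )
}

#' Validate a data.frame as a feature table
#'
#' @param x data.frame.
#' @param schema one of `"cohort"`, `"retest"`, `"phantom"`.
#' @return `x` with a `schema` attribute, after validation.
#' @export
as_feature_table <- function(x, schema = c("cohort", "retest", "phantom")) {
  schema <- match.arg(schema)
  ann <- schema_annotations(schema)
  missing <- setdiff(ann, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("schema error: missing column(s) %s for schema '%s'",
                 paste(missing, collapse = ", "), schema), call. = FALSE)
  }
  for (col in ann) {
    if (anyNA(x[[col]]) || any(x[[col]] == "")) {
      stop(sprintf("schema error: incomplete annotation column '%s'", col),
           call. = FALSE)
    }
  }
  if (schema %in% c("cohort", "retest")) {
    if (anyDuplicated(x$sample_id)) {
      dup <- x$sample_id[duplicated(x$sample_id)][1]
      stop(sprintf("schema error: duplicate sample_id '%s'", dup), call. = FALSE)
    }
  } else {
    key <- paste(x$lesion_id, x$condition_id, sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      stop(sprintf("schema error: duplicate (lesion_id, condition_id) = ('%s', '%s')",
                   x$lesion_id[i], x$condition_id[i]), call. = FALSE)
    }
  }
  if (schema == "cohort" && !all(x$group %in% c("wildtype", "mutant"))) {
    bad <- setdiff(unique(x$group), c("wildtype", "mutant"))[1]
    stop(sprintf("schema error: unknown group label '%s'", bad), call. = FALSE)
  }
  feats <- setdiff(names(x), c("sample_id", "group", "lesion_id",
                               "condition_id", "timepoint"))
  for (f in feats) {
    if (!is.numeric(x[[f]]) || any(!is.finite(x[[f]]))) {
      i <- if (is.numeric(x[[f]])) which(!is.finite(x[[f]]))[1] else 1L
      stop(sprintf("schema error: non-numeric or non-finite value in feature '%s' (row %d)",
                   f, i), call. = FALSE)
    }
  }
  attr(x, "schema") <- schema
  x
}

#' Names of the feature (non-annotation) columns
#' @param x a feature table.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(x) {
  setdiff(names(x), c("sample_id", "group", "lesion_id", "condition_id",
                      "timepoint"))
}

#' Read a feature table from CSV
#'
#' Reads an RFC-4180 CSV with header and validates it against the declared
#' schema; errors name the offending column or row.
#'
#' @param path path to a CSV file.
#' @param schema one of `"cohort"`, `"retest"`, `"phantom"`.
#' @return A validated feature table.
#' @export
read_feature_table <- function(path, schema = c("cohort", "retest", "phantom")) {
  schema <- match.arg(schema)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_feature_table(x, schema)
}

#' Write a feature table to CSV
#'
#' @param x a feature table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
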