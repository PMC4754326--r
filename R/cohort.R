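# Cohort table: one row per subject, demographic/clinical metadata plus the
# 55 regional MRI measures named by the manifest.  Implemented as a
# data.frame subclass carrying the manifest as an attribute, so base
# data.frame idioms keep working.

.meta_cols <- c("subject_id", "diagnosis", "age", "sex", "education",
                "mmse", "cdr", "apoe4", "cohort",
                "prog_m12", "prog_m18", "prog_m24", "prog_m36")

.diag_levels  <- c("CTL", "MCI", "AD")
.sex_levels   <- c("M", "F")
.apoe_levels  <- c("negative", "positive", "unknown")
.cohort_levels <- c("ADNI", "ANM")
.prog_levels  <- c("stable", "progressed", "unknown")

#' Progression follow-up months
#'
#' The follow-up months at which MCI progression status is recorded.
#' @return integer vector `c(12, 18, 24, 36)`.
#' @export
progression_months <- function() c(12L, 18L, 24L, 36L)

prog_col <- function(month) paste0("prog_m", month)

#' Construct a cohort table
#'
#' Binds a subject data frame to a feature manifest and validates the result.
#' The data frame must contain the metadata columns
#' `subject_id, diagnosis, age, sex, education, mmse, cdr, apoe4, cohort`,
#' the progression columns `prog_m12 ... prog_m36`, and one numeric column
#' per manifest feature.
#'
#' @param data a data frame as described above.
#' @param manifest a feature manifest (default [default_manifest()]).
#' @return an object of class `cohort_table` (a data.frame).
#' @export
cohort_table <- function(data, manifest = default_manifest()) {
  validate_manifest(manifest)
  missing_cols <- setdiff(c(.meta_cols, manifest$name), names(data))
  if (length(missing_cols))
    stop_schema("cohort is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data <- data[, c(.meta_cols, manifest$name)]
  data$subject_id <- as.character(data$subject_id)
  x <- structure(data,
                 manifest = manifest,
                 class = c("cohort_table", "data.frame"))
  validate_cohort(x)
}

validate_cohort <- function(x) {
  manifest <- attr(x, "manifest")
  chk_levels <- function(col, levels) {
    bad <- !x[[col]] %in% levels
    if (any(bad))
      stop_schema("invalid %s value(s): %s", col,
                  paste(unique(x[[col]][bad]), collapse = ", "))
  }
  if (nrow(x)) {
    chk_levels("diagnosis", .diag_levels)
    chk_levels("sex", .sex_levels)
    chk_levels("apoe4", .apoe_levels)
    chk_levels("cohort", .cohort_levels)
    for (m in progression_months()) chk_levels(prog_col(m), .prog_levels)
    if (any(!is.na(x$age) & x$age <= 0))
      stop_schema("age must be positive")
    if (any(!is.na(x$mmse) & (x$mmse < 0 | x$mmse > 30)))
      stop_schema("MMSE must lie in [0, 30]")
    if (any(!is.na(x$cdr) & x$cdr < 0))
      stop_schema("CDR must be non-negative")
    # progression is defined only for MCI subjects
    non_mci <- x$diagnosis != "MCI"
    for (m in progression_months()) {
      col <- prog_col(m)
      if (any(x[[col]][non_mci] != "unknown"))
        stop_schema("progression status (%s) must be 'unknown' for non-MCI subjects", col)
    }
    for (f in manifest$name) {
      v <- x[[f]]
      if (!is.numeric(v) || anyNA(v))
        stop_schema("feature column '%s' must be numeric with no missing values", f)
    }
  }
  x
}

#' Extract the feature matrix or metadata of a cohort table
#'
#' @param x a `cohort_table`.
#' @param type optionally restrict the feature matrix to `"thickness"` or
#'   `"volume"` columns.
#' @return `cohort_features()` returns a numeric matrix (subjects x
#'   features, manifest order); `cohort_meta()` the metadata data frame;
#'   `cohort_manifest()` the manifest.
#' @export
cohort_features <- function(x, type = NULL) {
  manifest <- attr(x, "manifest")
  keep <- if (is.null(type)) manifest$name else manifest$name[manifest$type == type]
  as.matrix(as.data.frame(unclass(x), stringsAsFactors = FALSE)[, keep, drop = FALSE])
}

#' @rdname cohort_features
#' @export
cohort_meta <- function(x) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)[, .meta_cols]
}

#' @rdname cohort_features
#' @export
cohort_manifest <- function(x) attr(x, "manifest")

#' @export
`[.cohort_table` <- function(x, i, ...) {
  manifest <- attr(x, "manifest")
  out <- as.data.frame(unclass(x), stringsAsFactors = FALSE)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, manifest = manifest,
            class = c("cohort_table", "data.frame"))
}

#' Subset a cohort table by diagnosis
#'
#' @param x a `cohort_table`.
#' @param diagnosis character vector of diagnoses to keep (`CTL`/`MCI`/`AD`).
#' @return a `cohort_table` with only the requested subjects.
#' @export
cohort_subset <- function(x, diagnosis) {
  x[x$diagnosis %in% diagnosis, ]
}

#' @export
print.cohort_table <- function(x, ...) {
  manifest <- attr(x, "manifest")
  cat(sprintf("Cohort table: %d subjects, %d features (%d thickness, %d volume)\n",
              nrow(x), nrow(manifest),
              sum(manifest$type == "thickness"),
              sum(manifest$type == "volume")))
  if (nrow(x)) {
    tab <- table(factor(x$diagnosis, levels = .diag_levels))
    cat("  diagnosis: ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
    cat(sprintf("  age: %.1f +/- %.1f years\n", mean(x$age), stats::sd(x$age)))
  }
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first cohort file.  All metadata
#' columns and all manifest feature columns must be present.  Rows with a
#' missing value in any feature column are rejected (not loaded); their
#' subject ids are reported in a message and returned in the
#' `"rejected_ids"` attribute.  A feature cell that is present but not
#' numeric is a parse error naming the row and column.
#'
#' @param path CSV file path.
#' @param manifest feature manifest the file must conform to.
#' @return a validated `cohort_table`; rejected subject ids (possibly empty)
#'   in `attr(, "rejected_ids")`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, manifest = default_manifest()) {
  if (!file.exists(path)) stop_schema("cohort file not found: %s", path)
  validate_manifest(manifest)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c(.meta_cols, manifest$name), names(raw))
  if (length(missing_cols))
    stop_schema("cohort file is missing column(s): %s",
                paste(missing_cols, collapse = ", "))

  parse_num <- function(col, integer = FALSE) {
    v <- raw[[col]]
    miss <- is.na(v) | v == "" | v == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stop_schema("non-numeric value '%s' in column '%s', data row %d",
                  v[bad[1]], col, bad[1])
    if (integer) num <- as.integer(round(num))
    num
  }

  out <- raw
  for (col in c("age", "education", "cdr")) out[[col]] <- parse_num(col)
  out$mmse <- parse_num("mmse", integer = TRUE)
  feat_missing <- matrix(FALSE, nrow(raw), nrow(manifest))
  for (j in seq_len(nrow(manifest))) {
    col <- manifest$name[j]
    v <- raw[[col]]
    feat_missing[, j] <- is.na(v) | v == "" | v == "NA"
    out[[col]] <- parse_num(col)
  }
  reject <- rowSums(feat_missing) > 0
  rejected_ids <- out$subject_id[reject]
  if (length(rejected_ids))
    message(sprintf("read_cohort: rejected %d row(s) with missing feature values: %s",
                    length(rejected_ids), paste(rejected_ids, collapse = ", ")))
  out <- out[!reject, , drop = FALSE]
  rownames(out) <- NULL
  tab <- cohort_table(out, manifest)
  attr(tab, "rejected_ids") <- rejected_ids
  tab
}

#' Write a cohort table to CSV
#'
#' Serializes floating-point columns with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param x a `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  manifest <- attr(x, "manifest")
  out <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  for (col in c("age", "education", "cdr", manifest$name)) out[[col]] <- fmt(out[[col]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_schema("cannot write cohort file '%s': %s", path,
                               conditionMessage(ok))
  invisible(path)
}
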