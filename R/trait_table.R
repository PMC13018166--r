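#' Default maize trait schema
#'
#' The 26 predictor traits plus the kernel-weight target measured per tagged
#' plant: experimental treatment and plant number, vegetative architecture
#' (plant height, leaf/node/cob/tassel counts, leaf dimensions), ear
#' morphology (ear weight with/without sheath, ear length/width, rows per
#' ear, kernels per row), chlorophyll content at five growth stages (Ch1-Ch5)
#' and canopy temperature at five growth stages (CT1-CT5). Treatment and PN
#' index the field design but are retained as predictors by default, matching
#' the 26-feature input space; use `include_identifiers = FALSE` in
#' [dataset_from_table()] to exclude them.
#'
#' @return A `trait_schema`: data frame with columns `code`, `name`, `unit`,
#'   `role` (one of `"predictor"`, `"target"`).
#' @export
default_trait_schema <- function() {
  entries <- rbind(
    c("Treatment", "Maize variety / treatment level", "level", "predictor"),
    c("PN",    "Tagged plant number",          "count", "predictor"),
    c("PH",    "Plant height",                 "mm",    "predictor"),
    c("NOL",   "Number of leaves",             "count", "predictor"),
    c("NON",   "Number of nodes",              "count", "predictor"),
    c("NOC",   "Number of cobs",               "count", "predictor"),
    c("NOT",   "Number of tassels",            "count", "predictor"),
    c("PHC",   "Plant height at cob",          "mm",    "predictor"),
    c("LL",    "Leaf length",                  "mm",    "predictor"),
    c("LB",    "Leaf breadth",                 "mm",    "predictor"),
    c("EWS",   "Ear weight with sheath",       "g",     "predictor"),
    c("EWOS",  "Ear weight without sheath",    "g",     "predictor"),
    c("EL",    "Ear length",                   "mm",    "predictor"),
    c("EW",    "Ear width",                    "mm",    "predictor"),
    c("RE",    "Rows per ear",                 "count", "predictor"),
    c("KR",    "Kernels per row",              "count", "predictor"),
    c("Ch1",   "Chlorophyll content, stage 1", "CCI",   "predictor"),
    c("Ch2",   "Chlorophyll content, stage 2", "CCI",   "predictor"),
    c("Ch3",   "Chlorophyll content, stage 3", "CCI",   "predictor"),
    c("Ch4",   "Chlorophyll content, stage 4", "CCI",   "predictor"),
    c("Ch5",   "Chlorophyll content, stage 5", "CCI",   "predictor"),
    c("CT1",   "Canopy temperature, stage 1",  "degC",  "predictor"),
    c("CT2",   "Canopy temperature, stage 2",  "degC",  "predictor"),
    c("CT3",   "Canopy temperature, stage 3",  "degC",  "predictor"),
    c("CT4",   "Canopy temperature, stage 4",  "degC",  "predictor"),
    c("CT5",   "Canopy temperature, stage 5",  "degC",  "predictor"),
    c("KW",    "Kernel weight (yield)",        "g",     "target")
  )
  schema <- data.frame(
    code = entries[, 1], name = entries[, 2], unit = entries[, 3],
    role = entries[, 4], stringsAsFactors = FALSE
  )
  trait_schema(schema)
}

#' Construct and validate a trait schema
#'
#' @param entries data frame with columns `code`, `name`, `unit`, `role`.
#' @return validated `trait_schema`.
#' @export
trait_schema <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("code", "name", "unit", "role") %in% names(entries)))
  if (anyDuplicated(entries$code)) {
    stop_hcadbn("trait codes must be unique", "hcadbn_schema_error")
  }
  if (!all(entries$role %in% c("predictor", "target", "identifier"))) {
    stop_hcadbn("role must be predictor, target or identifier",
                "hcadbn_schema_error")
  }
  if (sum(entries$role == "target") != 1L) {
    stop_hcadbn("schema must contain exactly one target trait",
                "hcadbn_schema_error")
  }
  structure(entries, class = c("trait_schema", "data.frame"))
}

#' Read or write a trait schema as a key-value file
#'
#' Schemas serialize to JSON with one record per trait (code, name, unit,
#' role), so alternative trait panels can be described outside R.
#'
#' @param schema a `trait_schema`.
#' @param path file path.
#' @return `read_trait_schema` returns a validated `trait_schema`.
#' @export
write_trait_schema <- function(schema, path) {
  stopifnot(inherits(schema, "trait_schema"))
  jsonlite::write_json(as.data.frame(schema), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trait_schema
#' @export
read_trait_schema <- function(path) {
  trait_schema(jsonlite::read_json(path, simplifyVector = TRUE))
}

schema_codes <- function(schema, role = NULL) {
  if (is.null(role)) return(schema$code)
  schema$code[schema$role %in% role]
}

#' Read a trait table from CSV
#'
#' Expects a header row containing every schema code; unknown extra columns
#' are kept and flagged in the returned object. Cells must parse as numbers.
#'
#' @param path path to a delimited text file.
#' @param schema a `trait_schema`; defaults to [default_trait_schema()].
#' @param delim field delimiter (default comma, `.` decimal mark).
#' @return a `trait_table`: list with `data` (data frame), `schema`, `n`
#'   (row count) and `extra_columns`.
#' @export
load_trait_table <- function(path, schema = default_trait_schema(),
                             delim = ",") {
  if (!file.exists(path)) {
    stop_hcadbn(sprintf("file not found: %s", path), "hcadbn_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim, dec = ".",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character",
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(schema$code, names(raw))
  if (length(missing_cols) > 0) {
    stop_hcadbn(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "hcadbn_schema_error")
  }
  extra <- setdiff(names(raw), schema$code)
  data <- raw
  for (col in names(raw)) {
    vals <- raw[[col]]
    vals[vals %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad) > 0 && col %in% schema$code) {
      stop_hcadbn(sprintf("non-numeric value '%s' at row %d, column %s",
                          vals[bad[1]], bad[1], col),
                  "hcadbn_parse_error")
    }
    data[[col]] <- num
  }
  trait_table(data, schema, extra_columns = extra)
}

#' Construct a trait table from an in-memory data frame
#'
#' @param data data frame with one numeric column per schema code.
#' @param schema a `trait_schema`.
#' @param extra_columns names of retained non-schema columns.
#' @return a `trait_table`.
#' @export
trait_table <- function(data, schema = default_trait_schema(),
                        extra_columns = character()) {
  missing_cols <- setdiff(schema$code, names(data))
  if (length(missing_cols) > 0) {
    stop_hcadbn(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "hcadbn_schema_error")
  }
  structure(
    list(data = as.data.frame(data), schema = schema, n = nrow(data),
         extra_columns = extra_columns),
    class = "trait_table"
  )
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d observations x %d schema columns\n",
              x$n, nrow(x$schema)))
  if (length(x$extra_columns) > 0) {
    cat("  extra (non-schema) columns:",
        paste(x$extra_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a trait table to CSV
#'
#' Values are written at full precision (15 significant digits) so that a
#' write/load round trip reproduces the table exactly.
#'
#' @param table a `trait_table`.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_trait_table <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "trait_table"))
  utils::write.table(format(table$data, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = delim, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop rows containing missing values
#'
#' @param table a `trait_table`.
#' @return list with `table` (complete rows only) and `count_removed`.
#' @export
drop_incomplete_rows <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  keep <- stats::complete.cases(table$data[, table$schema$code, drop = FALSE])
  if (!any(keep)) {
    stop_hcadbn("all rows contain missing values", "hcadbn_empty_data_error")
  }
  cleaned <- trait_table(table$data[keep, , drop = FALSE], table$schema,
                         table$extra_columns)
  list(table = cleaned, count_removed = sum(!keep))
}

#' Binarize kernel weight into low/high yield classes
#'
#' The cut-off is applied on the raw gram scale, before any transform:
#' label 1 (high yield) iff KW >= threshold, else 0 (low yield).
#'
#' @param kw numeric vector of kernel weights in grams.
#' @param threshold class boundary in grams (default 25).
#' @return integer vector of 0/1 labels.
#' @export
binarize_kw <- function(kw, threshold = 25) {
  if (any(!is.finite(kw))) {
    stop_hcadbn("kernel weights must be finite", "hcadbn_validation_error")
  }
  if (any(kw < 0)) {
    stop_hcadbn("kernel weights must be non-negative",
                "hcadbn_validation_error")
  }
  as.integer(kw >= threshold)
}

#' Assemble a labeled dataset from a trait table
#'
#' Binarizes the target on the raw gram scale and collects the predictor
#' matrix. Transformation/scaling of features is a separate, later step
#' (see [fit_minmax()]); the class labels never depend on it.
#'
#' @param table a `trait_table` with no missing values.
#' @param threshold kernel-weight class boundary in grams.
#' @param include_identifiers keep the Treatment and PN design columns as
#'   predictors (default TRUE, matching the 26-feature input space).
#' @return a `labeled_dataset`.
#' @export
dataset_from_table <- function(table, threshold = 25,
                               include_identifiers = TRUE) {
  stopifnot(inherits(table, "trait_table"))
  target_code <- schema_codes(table$schema, "target")
  pred_codes <- schema_codes(table$schema, c("predictor", "identifier"))
  if (!include_identifiers) {
    pred_codes <- setdiff(pred_codes, c("Treatment", "PN"))
  }
  labels <- binarize_kw(table$data[[target_code]], threshold)
  features <- as.matrix(table$data[, pred_codes, drop = FALSE])
  labeled_dataset(features, labels, pred_codes)
}

#' Construct a labeled dataset
#'
#' @param features numeric matrix, one row per observation.
#' @param labels 0/1 integer vector.
#' @param feature_codes column names for `features`.
#' @return a `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels,
                            feature_codes = colnames(features)) {
  features <- as.matrix(features)
  if (is.null(feature_codes)) {
    feature_codes <- paste0("V", seq_len(ncol(features)))
  }
  if (length(feature_codes) != ncol(features)) {
    stop_hcadbn("feature_codes length must match feature count",
                "hcadbn_validation_error")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop_hcadbn("labels must be 0/1", "hcadbn_validation_error")
  }
  if (nrow(features) != length(labels)) {
    stop_hcadbn("features and labels disagree in length",
                "hcadbn_validation_error")
  }
  colnames(features) <- feature_codes
  structure(list(features = features, labels = as.integer(labels),
                 feature_codes = feature_codes),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> n=%d, p=%d, class 1 fraction %.3f\n",
              nrow(x$features), ncol(x$features), mean(x$labels)))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  labeled_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                  ds$feature_codes)
}

#' Stratified train/test split
#'
#' Per-class test counts are `round(class_n * test_fraction)` (half-up);
#' the largest class is then adjusted by +/-1 sample at a time until the
#' global test size `round(n * test_fraction)` is hit, so per-class counts
#' never deviate from exact proportionality by more than one sample.
#' Deterministic given `seed`.
#'
#' @param ds a `labeled_dataset`.
#' @param train_fraction fraction of samples assigned to training, in (0,1).
#' @param seed integer RNG seed.
#' @return list with `train` and `test` datasets plus the index vectors
#'   `train_idx`, `test_idx`.
#' @export
stratified_split <- function(ds, train_fraction, seed) {
  stopifnot(inherits(ds, "labeled_dataset"),
            train_fraction > 0, train_fraction < 1)
  seed <- assert_seed(seed)
  n <- length(ds$labels)
  test_fraction <- 1 - train_fraction
  class_idx <- split(seq_len(n), ds$labels)
  if (length(class_idx) < 2 || any(lengths(class_idx) < 2)) {
    stop_hcadbn("each class needs at least 2 members for stratification",
                "hcadbn_stratification_error")
  }
  target_total <- round_half_up(n * test_fraction, 0)
  per_class <- vapply(class_idx, function(ix) {
    round_half_up(length(ix) * test_fraction, 0)
  }, numeric(1))
  largest <- which.max(lengths(class_idx))
  while (sum(per_class) != target_total) {
    per_class[largest] <- per_class[largest] +
      sign(target_total - sum(per_class))
  }
  per_class <- pmin(pmax(per_class, 1), lengths(class_idx) - 1)
  old <- .Random.seed_exists()
  set.seed(seed)
  test_idx <- sort(unlist(Map(function(ix, k) {
    ix[sample.int(length(ix), k)]
  }, class_idx, per_class), use.names = FALSE))
  .Random.seed_restore(old)
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = subset_dataset(ds, train_idx),
       test = subset_dataset(ds, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

## Save/restore the global RNG stream so seeded helpers do not perturb the
## caller's randomness.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
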