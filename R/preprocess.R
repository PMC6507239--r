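#' Exposure table
#'
#' Container for raw biomonitoring concentrations with per-variable
#' limit-of-detection (LOD) metadata and cell-level bookkeeping: a
#' `missing_mask` for structurally missing cells and a `below_lod_mask` for
#' censored cells. The two masks are disjoint per cell.
#'
#' @param values `n x m` numeric matrix of concentrations (column names are
#'   variable names).
#' @param lod Named numeric vector of detection limits (same units as
#'   `values`); variables without an LOD may be omitted or `NA`.
#' @param missing_mask,below_lod_mask Logical `n x m` matrices; defaults are
#'   derived from `is.na(values)` and all-`FALSE`.
#' @param sample_ids Row labels.
#' @param var_meta Optional data frame of per-variable metadata (e.g.
#'   `variable`, `matrix` with values blood/serum/urine, `display`).
#' @return An object of class `"exposure_table"`.
#' @export
exposure_table <- function(values, lod = NULL, missing_mask = NULL,
                           below_lod_mask = NULL, sample_ids = NULL,
                           var_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  if (is.null(below_lod_mask))
    below_lod_mask <- matrix(FALSE, nrow(values), ncol(values))
  dimnames(missing_mask) <- dimnames(below_lod_mask) <- dimnames(values)
  if (any(missing_mask & below_lod_mask))
    stop("a cell cannot be both missing and below the LOD")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(values)))
  lod_full <- stats::setNames(rep(NA_real_, ncol(values)), colnames(values))
  if (!is.null(lod)) lod_full[names(lod)] <- lod
  structure(list(values = values, lod = lod_full,
                 missing_mask = missing_mask,
                 below_lod_mask = below_lod_mask,
                 sample_ids = sample_ids, var_meta = var_meta),
            class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf("Exposure table: %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing cells: %d; below-LOD cells: %d\n",
              sum(x$missing_mask), sum(x$below_lod_mask)))
  invisible(x)
}

#' @export
dim.exposure_table <- function(x) dim(x$values)

#' Read an exposure table from a delimited file
#'
#' Reads a CSV/TSV with a header row and one row per sample, separating the
#' outcome and any confounder columns from the exposure columns. Missing
#' cells are empty strings or `"NA"`; censored cells are either flagged by a
#' sentinel string (default `"<LOD"`) or detected as numeric values strictly
#' below the variable's limit of detection in `lod_map`.
#'
#' @param path File path (`.tsv`/`.txt` are read tab-separated, otherwise
#'   comma-separated).
#' @param outcome_col Name of the (numeric) outcome column.
#' @param confounder_cols Names of confounder columns.
#' @param lod_map Named numeric vector or list mapping exposure variables to
#'   their LOD, or a path to a two-column CSV (`variable`, `lod`) or a JSON
#'   map.
#' @param id_col Optional sample-id column name.
#' @param sentinel String marking a below-LOD cell with unknown magnitude.
#' @return List with `table` (an [exposure_table()]), `outcome` (numeric
#'   vector), and `confounders` (data frame, possibly 0-column).
#' @export
read_exposure_csv <- function(path, outcome_col, confounder_cols = character(),
                              lod_map = NULL, id_col = NULL,
                              sentinel = "<LOD") {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           stringsAsFactors = FALSE)
  if (!outcome_col %in% names(raw))
    stop("outcome column '", outcome_col, "' not found in ", path)
  missing_conf <- setdiff(confounder_cols, names(raw))
  if (length(missing_conf))
    stop("confounder column(s) not found: ",
         paste(missing_conf, collapse = ", "))
  if (is.character(lod_map) && length(lod_map) == 1 && file.exists(lod_map)) {
    lod_map <- if (grepl("\\.json$", lod_map, ignore.case = TRUE)) {
      unlist(jsonlite::read_json(lod_map))
    } else {
      lt <- utils::read.csv(lod_map, stringsAsFactors = FALSE)
      stats::setNames(as.numeric(lt[[2L]]), lt[[1L]])
    }
  }
  lod_map <- unlist(lod_map)

  sample_ids <- if (!is.null(id_col)) raw[[id_col]] else
    as.character(seq_len(nrow(raw)))
  outcome <- suppressWarnings(as.numeric(raw[[outcome_col]]))
  if (anyNA(outcome))
    stop("outcome column '", outcome_col, "' contains non-numeric entries")
  conf <- raw[, confounder_cols, drop = FALSE]
  conf[] <- lapply(conf, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num) && !all(is.na(num))) v else num
  })

  expo_cols <- setdiff(names(raw), c(outcome_col, confounder_cols, id_col))
  n <- nrow(raw); m <- length(expo_cols)
  values <- matrix(NA_real_, n, m, dimnames = list(NULL, expo_cols))
  missing_mask <- below_mask <- matrix(FALSE, n, m,
                                       dimnames = list(NULL, expo_cols))
  for (j in seq_len(m)) {
    cell <- trimws(raw[[expo_cols[j]]])
    is_missing <- cell == "" | cell == "NA"
    is_sent <- !is_missing & cell == sentinel
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & !is_sent & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                   cell[bad[1L]], bad[1L], expo_cols[j]))
    values[, j] <- num
    missing_mask[, j] <- is_missing
    below_mask[, j] <- is_sent
    lod_j <- lod_map[expo_cols[j]]
    if (!is.na(lod_j))
      below_mask[, j] <- below_mask[, j] |
        (!is_missing & !is_sent & num < lod_j)
  }
  table <- exposure_table(values, lod = lod_map,
                          missing_mask = missing_mask,
                          below_lod_mask = below_mask,
                          sample_ids = sample_ids)
  list(table = table, outcome = outcome, confounders = conf)
}

#' Impute below-LOD cells as LOD/sqrt(2)
#'
#' Replaces every censored cell by its variable's limit of detection divided
#' by the square root of two, the standard single-value imputation for
#' left-censored biomonitoring concentrations. All other cells are
#' unchanged and `below_lod_mask` is preserved for audit.
#'
#' @param table An [exposure_table()].
#' @return The table with censored cells imputed.
#' @export
impute_lod <- function(table) {
  stopifnot(inherits(table, "exposure_table"))
  need <- colSums(table$below_lod_mask) > 0
  no_lod <- need & is.na(table$lod)
  if (any(no_lod))
    stop("below-LOD cells but no LOD metadata for: ",
         paste(names(which(no_lod)), collapse = ", "))
  for (j in which(need))
    table$values[table$below_lod_mask[, j], j] <- table$lod[j] / sqrt(2)
  table
}

#' Drop variables with excessive missingness
#'
#' Removes exposure columns whose combined fraction of structurally missing
#' and (by default) below-LOD cells is strictly greater than
#' `max_missing_frac` -- a column at exactly the threshold is retained.
#'
#' @param table An [exposure_table()].
#' @param max_missing_frac Threshold in `[0, 1)` (default 0.40).
#' @param count_below_lod Whether censored cells count toward missingness
#'   (default `TRUE`).
#' @return List with `table` (retained columns, values untouched) and
#'   `dropped` (data frame of `variable`, `fraction`, `n_missing`,
#'   `n_below_lod`).
#' @export
filter_missing <- function(table, max_missing_frac = 0.40,
                           count_below_lod = TRUE) {
  stopifnot(inherits(table, "exposure_table"),
            max_missing_frac >= 0, max_missing_frac < 1)
  n <- nrow(table$values)
  n_miss <- colSums(table$missing_mask)
  n_blod <- colSums(table$below_lod_mask)
  frac <- (n_miss + if (count_below_lod) n_blod else 0) / n
  drop <- frac > max_missing_frac
  dropped <- data.frame(variable = colnames(table$values)[drop],
                        fraction = unname(frac[drop]),
                        n_missing = unname(n_miss[drop]),
                        n_below_lod = unname(n_blod[drop]))
  if (all(drop))
    stop("all ", length(drop), " variables exceed the missingness threshold")
  keep <- !drop
  out <- exposure_table(table$values[, keep, drop = FALSE],
                        lod = table$lod[keep],
                        missing_mask = table$missing_mask[, keep, drop = FALSE],
                        below_lod_mask = table$below_lod_mask[, keep,
                                                              drop = FALSE],
                        sample_ids = table$sample_ids,
                        var_meta = table$var_meta)
  list(table = out, dropped = dropped)
}

#' Complete-case restriction on remaining missing cells
#'
#' Drops samples with any structurally missing exposure cell (the default
#' handling after [filter_missing()]), or mean-imputes them instead.
#'
#' @param table An [exposure_table()].
#' @param method `"complete_case"` (default) or `"mean_impute"`.
#' @return List with `table` and `kept_rows` (logical index of retained
#'   samples; all `TRUE` under mean imputation).
#' @export
handle_missing <- function(table, method = c("complete_case", "mean_impute")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "exposure_table"))
  if (method == "complete_case") {
    keep <- rowSums(table$missing_mask) == 0
    out <- exposure_table(table$values[keep, , drop = FALSE],
                          lod = table$lod,
                          missing_mask = table$missing_mask[keep, ,
                                                            drop = FALSE],
                          below_lod_mask = table$below_lod_mask[keep, ,
                                                                drop = FALSE],
                          sample_ids = table$sample_ids[keep],
                          var_meta = table$var_meta)
    list(table = out, kept_rows = keep)
  } else {
    for (j in seq_len(ncol(table$values))) {
      miss <- table$missing_mask[, j]
      if (any(miss))
        table$values[miss, j] <- mean(table$values[!miss, j])
    }
    table$missing_mask[] <- FALSE
    list(table = table, kept_rows = rep(TRUE, nrow(table$values)))
  }
}

#' Divide urine analytes by a creatinine column
#'
#' Optional hook for creatinine dilution correction when the upstream data
#' delivery has not already applied it.
#'
#' @param table An [exposure_table()].
#' @param columns Names of columns to correct.
#' @param creatinine Positive numeric vector (one value per sample).
#' @return The corrected table.
#' @export
correct_creatinine <- function(table, columns, creatinine) {
  stopifnot(inherits(table, "exposure_table"),
            length(creatinine) == nrow(table$values), all(creatinine > 0),
            all(columns %in% colnames(table$values)))
  table$values[, columns] <- table$values[, columns] / creatinine
  table
}

#' Log-transform and z-score standardize an exposure table
#'
#' Applies the natural log elementwise (to reduce skewness of concentration
#' distributions), then centers and scales each column to mean 0 and unit
#' sample standard deviation. Run after [impute_lod()] (all cells must be
#' positive) and after resolving structurally missing cells with
#' [handle_missing()].
#'
#' @param table An [exposure_table()] or a positive numeric matrix.
#' @return An object of class `"standardized_matrix"`: list with `values`,
#'   `column_means`, `column_sds` (statistics on the log scale), and
#'   `transform_log = TRUE`.
#' @export
log_zscore <- function(table) {
  values <- if (inherits(table, "exposure_table")) {
    if (any(table$missing_mask))
      stop("structurally missing cells remain; run handle_missing() first")
    table$values
  } else as.matrix(table)
  bad <- which(values <= 0, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)))
    stop(sprintf("non-positive cell at row %d, column '%s': log undefined",
                 bad[1L, 1L], colnames(values)[bad[1L, 2L]]))
  lv <- log(values)
  mu <- colMeans(lv)
  sds <- apply(lv, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  structure(list(values = scale(lv, center = mu, scale = sds)[, ,
                                                              drop = FALSE],
                 column_means = mu, column_sds = sds, transform_log = TRUE),
            class = "standardized_matrix")
}

#' Apply stored standardization parameters to new data
#'
#' @param sm A `"standardized_matrix"` from [log_zscore()].
#' @param newdata Positive matrix with the same columns.
#' @return Standardized matrix of `newdata` using the fitted means/sds.
#' @export
apply_standardization <- function(sm, newdata) {
  stopifnot(inherits(sm, "standardized_matrix"))
  newdata <- as.matrix(newdata)
  lv <- if (sm$transform_log) log(newdata) else newdata
  scale(lv, center = sm$column_means, scale = sm$column_sds)[, ,
                                                             drop = FALSE]
}

#' Invert a standardization back to the concentration scale
#'
#' @param sm A `"standardized_matrix"`.
#' @param values Standardized values (default: the fitted matrix).
#' @return Matrix on the original concentration scale.
#' @export
unstandardize <- function(sm, values = sm$values) {
  stopifnot(inherits(sm, "standardized_matrix"))
  out <- sweep(sweep(as.matrix(values), 2L, sm$column_sds, `*`),
               2L, sm$column_means, `+`)
  if (sm$transform_log) out <- exp(out)
  out
}
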