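#' @title Benchmark tables
#' @description
#' The central data structure of ddgbench is an ordinary tibble, one row per
#' (TKI, mutation) pair, with columns:
#'
#' * `tki` — inhibitor identifier (character).
#' * `mutation` — point mutation in `X###Z` form (wild-type residue letter,
#'   position, mutant letter), e.g. `"T315I"`.
#' * `exp_ddg` — experimental binding free-energy change, kcal/mol.
#' * `exp_sigma` — experimental standard deviation (kcal/mol), 0 if unknown.
#' * `censored` — logical; `TRUE` when the mutant potency exceeded the assay
#'   ceiling so `exp_ddg` is only a lower bound.
#' * `{method}_ddg`, `{method}_sigma` — one pair per predictor. `*_sigma` is
#'   the statistical uncertainty of the reported value (0 for deterministic
#'   predictors).
#' * `{method}_rep1..K` — optional replicate values for stochastic predictors.
#'
#' @name benchmark-table
NULL

mutation_pattern <- "^[A-Z][0-9]+[A-Z]$"

canonical_columns <- c("tki", "mutation", "exp_ddg", "exp_sigma", "censored")

#' List the predictor methods present in a benchmark table
#'
#' Method names are inferred from columns matching `{method}_ddg`, excluding
#' the experimental column.
#'
#' @param data A benchmark tibble (see [benchmark-table]).
#' @return Character vector of method names.
#' @export
benchmark_methods <- function(data) {
  nm <- grep("_ddg$", names(data), value = TRUE)
  setdiff(sub("_ddg$", "", nm), "exp")
}

# Column name helpers
method_col <- function(method) paste0(method, "_ddg")
method_sigma_col <- function(method) paste0(method, "_sigma")

# Ensure the named method's prediction column exists.
check_method <- function(data, method) {
  col <- method_col(method)
  if (!col %in% names(data)) {
    abort(sprintf(
      "Method '%s' not found: column '%s' is missing (available: %s).",
      method, col, paste(benchmark_methods(data), collapse = ", ")
    ))
  }
  invisible(col)
}

# Basic structural validation shared by evaluation functions. Duplicate-key
# checking is opt-in: bootstrap resamples legitimately repeat rows.
validate_benchmark <- function(data, check_duplicates = FALSE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (benchmark table).")
  }
  missing <- setdiff(c("tki", "mutation", "exp_ddg"), names(data))
  if (length(missing) > 0) {
    abort(paste0("Benchmark table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (!"censored" %in% names(data)) data$censored <- FALSE
  if (!"exp_sigma" %in% names(data)) data$exp_sigma <- 0
  data$censored <- as.logical(data$censored)
  if (check_duplicates) {
    key <- paste(data$tki, data$mutation, sep = "/")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      abort(paste0("Duplicate (tki, mutation) keys: ",
                   paste(dup, collapse = ", ")))
    }
  }
  data
}

#' Aggregate replicate predictions into a value and an uncertainty
#'
#' Stochastic predictors (e.g. alchemical free-energy runs repeated with
#' different random seeds) report one value per replicate. The reported
#' estimate is the arithmetic mean; the uncertainty is the sample standard
#' deviation between replicates (divisor n - 1), or the standard error of the
#' mean when `se = TRUE`.
#'
#' @param values Numeric vector of replicate energies (kcal/mol); at least 2
#'   finite values.
#' @param se If `TRUE`, divide the standard deviation by `sqrt(n)` to report
#'   the standard error of the mean instead of the between-replicate standard
#'   deviation.
#' @return A one-row tibble with columns `mean`, `sigma`, `n`.
#' @examples
#' aggregate_replicates(c(1.0, 1.5, 2.0))
#' aggregate_replicates(c(1.0, 1.5, 2.0), se = TRUE)
#' @export
aggregate_replicates <- function(values, se = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values))) {
    abort("At least 2 finite replicate values are required.")
  }
  sigma <- sd(values)
  if (se) sigma <- sigma / sqrt(length(values))
  tibble::tibble(mean = mean(values), sigma = sigma, n = length(values))
}

#' Read a benchmark table from a delimited text file
#'
#' Reads a comma-delimited, UTF-8, header-mandatory table into the benchmark
#' tibble layout (see [benchmark-table]). Columns may be renamed on the way in
#' through `schema`, so files using different headers (or raw potencies
#' instead of pre-converted ddG) can be ingested without editing.
#'
#' If `exp_ddg` is absent but `wt_value` and `mut_value` (potencies in nM,
#' IC50 or Kd) are present, the experimental ddG is computed with
#' [ddg_from_potencies()]. If replicate columns `{method}_rep1..K` are present
#' and `{method}_ddg` is not, replicates are aggregated with
#' [aggregate_replicates()].
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(tki = "drug", exp_ddg = "ddg_experiment")`.
#' @param constants [thermo_constants()] used when converting raw potencies.
#' @param replicate_se Passed to [aggregate_replicates()] as `se` when filling
#'   missing `{method}_ddg`/`{method}_sigma` from replicate columns.
#' @return A benchmark tibble.
#' @export
read_benchmark_table <- function(path, schema = NULL,
                                 constants = thermo_constants(),
                                 replicate_se = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      abort("`schema` must be a fully named character vector.")
    }
    absent <- schema[!schema %in% names(raw)]
    if (length(absent) > 0) {
      abort(paste0(
        "Schema maps missing column(s): ",
        paste(sprintf("%s -> '%s'", names(absent), absent), collapse = ", ")
      ))
    }
    names(raw)[match(schema, names(raw))] <- names(schema)
  }
  for (col in c("tki", "mutation")) {
    if (!col %in% names(raw)) {
      abort(sprintf("Required column '%s' is missing.", col))
    }
  }
  has_ddg <- "exp_ddg" %in% names(raw)
  has_potency <- all(c("wt_value", "mut_value") %in% names(raw))
  if (!has_ddg && !has_potency) {
    abort("Need either an 'exp_ddg' column or 'wt_value' and 'mut_value' columns.")
  }

  bad_mut <- which(!grepl(mutation_pattern, raw$mutation))
  if (length(bad_mut) > 0) {
    abort(paste0(
      "Mutation strings not matching 'X###Z' at row(s): ",
      paste(head(bad_mut, 10), collapse = ", ")
    ))
  }

  character_cols <- c("tki", "mutation", "source", "kind")
  logical_cols <- "censored"
  numeric_cols <- setdiff(names(raw), c(character_cols, logical_cols))
  parsed <- raw
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad) > 0) {
      abort(sprintf(
        "Unparseable numeric value in column '%s' at row(s): %s",
        col, paste(head(bad, 10), collapse = ", ")
      ))
    }
    parsed[[col]] <- vals
  }
  if ("censored" %in% names(parsed)) {
    parsed$censored <- as.logical(parsed$censored)
    parsed$censored[is.na(parsed$censored)] <- FALSE
  } else {
    parsed$censored <- FALSE
  }

  # Required numerics must be present in every row.
  required_numeric <- if (has_ddg) "exp_ddg" else c("wt_value", "mut_value")
  for (col in required_numeric) {
    bad <- which(is.na(parsed[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "Missing or unparseable '%s' at row(s): %s",
        col, paste(head(bad, 10), collapse = ", ")
      ))
    }
  }

  if (!has_ddg) {
    if (any(parsed$wt_value <= 0 | parsed$mut_value <= 0)) {
      abort("Potencies must be positive.")
    }
    parsed$exp_ddg <- ddg_from_potencies(parsed$wt_value, parsed$mut_value,
                                         constants = constants)
  }
  if (!"exp_sigma" %in% names(parsed)) parsed$exp_sigma <- 0
  parsed$exp_sigma[is.na(parsed$exp_sigma)] <- 0

  # Fill method value/sigma from replicate columns when absent.
  rep_cols <- grep("^(.*)_rep[0-9]+$", names(parsed), value = TRUE)
  rep_methods <- unique(sub("_rep[0-9]+$", "", rep_cols))
  for (m in rep_methods) {
    cols <- grep(sprintf("^%s_rep[0-9]+$", m), names(parsed), value = TRUE)
    if (!method_col(m) %in% names(parsed)) {
      agg <- purrr::map(seq_len(nrow(parsed)), function(i) {
        aggregate_replicates(unlist(parsed[i, cols], use.names = FALSE),
                             se = replicate_se)
      })
      parsed[[method_col(m)]] <- purrr::map_dbl(agg, "mean")
      parsed[[method_sigma_col(m)]] <- purrr::map_dbl(agg, "sigma")
    }
  }

  out <- validate_benchmark(parsed, check_duplicates = TRUE)
  front <- intersect(canonical_columns, names(out))
  dplyr::relocate(out, dplyr::all_of(front))
}

#' Write a benchmark table to a delimited text file
#'
#' Writes CSV with a fixed column order (canonical columns first) and full
#' float precision (17 significant digits), so a write/read round trip
#' reproduces the table exactly and a write/read/write cycle is byte-stable.
#'
#' @param data A non-empty benchmark tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_benchmark_table <- function(data, path) {
  data <- validate_benchmark(data, check_duplicates = TRUE)
  if (nrow(data) == 0) {
    abort("Refusing to write an empty benchmark table.")
  }
  front <- intersect(canonical_columns, names(data))
  data <- dplyr::relocate(data, dplyr::all_of(front))
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double),
    ~ sprintf("%.17g", .x)
  ))
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) abort(sprintf("Cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}
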