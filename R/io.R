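#' Read an individual-level analysis table
#'
#' Reads a delimited text table with a header and assembles an `mr_dataset`.
#' Column roles default to the `Z_*` (instruments), `X_*` (auxiliary), `D`
#' (coarsened exposure), `Y` (outcome) naming convention; `column_map`
#' renames foreign headers first (named character vector,
#' `c(file_column = "canonical")`). Rows with missing values in any used
#' column are dropped with a message. The exposure must be integer-coded;
#' non-contiguous category codes are re-mapped onto `0..K` with a warning.
#'
#' @param path file path (TSV/CSV; the delimiter is sniffed).
#' @param instruments,auxiliary,exposure,outcome,covariates column roles.
#' @param column_map optional named character vector renaming file columns
#'   to canonical ones before roles are resolved.
#' @return An `mr_dataset`.
#' @export
read_individual_table <- function(path, instruments = NULL, auxiliary = NULL,
                                  exposure = "D", outcome = "Y",
                                  covariates = NULL, column_map = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!is.null(column_map)) {
    hit <- names(column_map) %in% names(df)
    names(df)[match(names(column_map)[hit], names(df))] <- unname(column_map[hit])
  }
  if (is.null(instruments)) instruments <- grep("^Z_", names(df), value = TRUE)
  if (is.null(auxiliary)) auxiliary <- grep("^X_", names(df), value = TRUE)
  covariates <- covariates %||% character(0)
  used <- c(instruments, auxiliary, exposure, outcome, covariates)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols)) {
    stop("input table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in c(instruments, auxiliary)) {
    if (!is.numeric(df[[cl]])) {
      stop("genotype column '", cl, "' is not numeric", call. = FALSE)
    }
  }
  if (all(is.na(df[[outcome]]))) {
    stop("outcome column '", outcome, "' is entirely missing", call. = FALSE)
  }
  ok <- stats::complete.cases(df[used])
  if (any(!ok)) {
    message("dropping ", sum(!ok), " row(s) with missing values")
    df <- df[ok, , drop = FALSE]
  }
  dvals <- df[[exposure]]
  if (!all(dvals == round(dvals))) {
    stop("exposure column '", exposure, "' must be integer-coded categories",
         call. = FALSE)
  }
  lev <- sort(unique(dvals))
  if (!identical(as.numeric(lev), as.numeric(seq_along(lev) - 1))) {
    warning("exposure categories ", paste(lev, collapse = ","),
            " re-mapped to 0..", length(lev) - 1L)
    df[[exposure]] <- match(dvals, lev) - 1L
  } else {
    df[[exposure]] <- as.integer(dvals)
  }
  structure(
    list(data = df, instruments = instruments, auxiliary = auxiliary,
         exposure = exposure, outcome = outcome, covariates = covariates,
         latent = NULL, params = NULL, n = nrow(df), seed = NA_integer_),
    class = "mr_dataset"
  )
}

#' Write an individual-level dataset to a delimited table
#'
#' Writes the analysis columns (`id`, genotypes, `D`, `Y`, covariates) as a
#' TSV with header; the held-out latent columns are never written.
#'
#' @param dataset an `mr_dataset`.
#' @param path output path.
#' @export
write_individual_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "mr_dataset"))
  data.table::fwrite(dataset$data, path, sep = "\t")
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Reads a delimited table of per-SNP associations with canonical columns
#' `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se` (and
#' optionally `n`). `col_map` renames foreign headers (for example
#' `c(FRQ = "eaf")`). Validation rejects duplicate SNP ids, non-positive
#' standard errors and allele frequencies outside (0, 1); allele strings are
#' upper-cased.
#'
#' @param path file path.
#' @param col_map optional named character vector,
#'   `c(file_column = "canonical")`.
#' @return A validated data frame of summary statistics.
#' @export
read_summary_stats <- function(path, col_map = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!is.null(col_map)) {
    hit <- names(col_map) %in% names(df)
    names(df)[match(names(col_map)[hit], names(df))] <- unname(col_map[hit])
  }
  validate_summary_df(df, basename(path))
}

#' Write GWAS summary statistics
#' @param stats data frame of summary statistics.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.10g", x))
}

#' Write a fit result as a delimited results table
#'
#' Emits a TSV with a deterministic column order and fixed float precision
#' (10 significant digits). Dispatches on the fit class: latent one-sample
#' and two-sample fits produce one row per `theta2` value; naive fits and
#' plain data frames are written as-is.
#'
#' @param result an `mr_latent_fit`, `mr_two_sample_fit`, `mr_naive_fit`,
#'   or data frame.
#' @param path output path.
#' @export
write_results <- function(result, path) {
  tab <- if (inherits(result, "mr_latent_fit")) {
    data.frame(theta2 = result$beta_L$theta2,
               beta_L = result$beta_L$beta_L,
               ci_lo = result$beta_L$ci_lo, ci_hi = result$beta_L$ci_hi,
               beta_G = result$beta_G_hat)
  } else if (inherits(result, "mr_two_sample_fit")) {
    data.frame(theta2 = result$beta_L$theta2,
               beta_L = result$beta_L$beta_L, se = result$beta_L$se,
               ci_lo = result$beta_L$ci_lo, ci_hi = result$beta_L$ci_hi,
               beta_G = result$beta_G_hat, scale_term = result$scale_term,
               ivw_term = result$ivw_term)
  } else if (inherits(result, "mr_naive_fit")) {
    data.frame(beta_D = result$beta_D_hat, se = result$se,
               ci_lo = result$ci[1], ci_hi = result$ci[2], n = result$n)
  } else {
    as.data.frame(result)
  }
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], fmt_num)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a machine-readable provenance record
#'
#' Records the package version, master seed, and the full configuration of
#' a run as JSON next to its results, so any output can be regenerated
#' exactly. No timestamps are included: identical configuration yields
#' byte-identical provenance.
#'
#' @param config named list of run configuration (must include the seed
#'   when the run used randomness).
#' @param path output path (JSON).
#' @export
emit_provenance <- function(config, path) {
  rec <- list(package = "coarseMR",
              version = as.character(utils::packageVersion("coarseMR")),
              config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
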