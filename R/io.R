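# Column schema of the assay-count table. Masses are in ng in the file and
# converted to grams internally; counts are raw per-plate CFUs.
ASSAY_COLUMNS <- c(
  "group", "replicate_id", "method", "label",
  "plasmid_length_bp", "amplicon_length_bp",
  "template_mass_ng", "output_mass_ng",
  "sucrose_cfu", "sucrose_dilution", "sucrose_fraction",
  "plain_cfu", "plain_dilution", "plain_fraction",
  "nc_sucrose_cfu", "nc_plain_cfu")

#' Read an assay-count table
#'
#' Reads and validates a delimited file of per-replicate plate counts. The
#' required header columns are: `group`, `replicate_id`, `method`
#' (`in_vivo`/`pcr`/`rca`), `label`, `plasmid_length_bp`,
#' `amplicon_length_bp`, `template_mass_ng` (blank for in vivo),
#' `output_mass_ng`, `sucrose_cfu`, `sucrose_dilution`, `sucrose_fraction`,
#' `plain_cfu`, `plain_dilution`, `plain_fraction`, `nc_sucrose_cfu`,
#' `nc_plain_cfu`. Negative-control plates are assumed to share the sample
#' plates' dilution and fraction. Masses are in nanograms. Validation
#' failures name the offending row and column.
#'
#' @param path Path to a CSV file.
#' @return A validated data.frame in the assay-count schema.
#' @export
read_assay_counts <- function(path) {
  if (!file.exists(path)) {
    sutox_error(sprintf("file not found: %s", path), "sutox_schema_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_assay_counts(df, context = path)
}

#' Write an assay-count table
#'
#' @param records Data.frame in the assay-count schema (e.g. the `records`
#'   element of [simulate_assay()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_counts <- function(records, path) {
  records <- validate_assay_counts(records, context = "records")
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_assay_counts <- function(df, context = "input") {
  missing_cols <- setdiff(ASSAY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    sutox_error(sprintf("%s: missing column(s): %s", context,
                        paste(missing_cols, collapse = ", ")),
                "sutox_schema_error")
  }
  if (nrow(df) == 0) {
    sutox_error(sprintf("%s: no data rows", context), "sutox_schema_error")
  }
  df <- df[, ASSAY_COLUMNS]
  bad <- function(row, col, why) {
    sutox_error(sprintf("%s row %d, column %s: %s", context, row, col, why),
                "sutox_schema_error")
  }
  num_cols <- setdiff(ASSAY_COLUMNS,
                      c("group", "replicate_id", "method", "label"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    conv_bad <- which(is.na(v) & !is.na(df[[col]]) &
                        trimws(as.character(df[[col]])) != "")
    if (length(conv_bad) > 0) bad(conv_bad[1], col, "not a number")
    df[[col]] <- v
  }
  for (i in seq_len(nrow(df))) {
    if (!df$method[i] %in% c("in_vivo", "pcr", "rca")) {
      bad(i, "method", sprintf("unknown method '%s'", df$method[i]))
    }
    for (col in c("sucrose_cfu", "plain_cfu", "nc_sucrose_cfu",
                  "nc_plain_cfu")) {
      if (is.na(df[[col]][i]) || df[[col]][i] < 0) {
        bad(i, col, "CFU count must be a non-negative number")
      }
    }
    for (col in c("sucrose_dilution", "plain_dilution")) {
      if (is.na(df[[col]][i]) || df[[col]][i] < 1) {
        bad(i, col, "dilution factor must be >= 1")
      }
    }
    for (col in c("sucrose_fraction", "plain_fraction")) {
      if (is.na(df[[col]][i]) || df[[col]][i] <= 0 || df[[col]][i] > 1) {
        bad(i, col, "plated fraction must be in (0, 1]")
      }
    }
    if (is.na(df$plasmid_length_bp[i]) || df$plasmid_length_bp[i] < 1) {
      bad(i, "plasmid_length_bp", "must be a positive length")
    }
    if (is.na(df$amplicon_length_bp[i]) ||
        df$amplicon_length_bp[i] > df$plasmid_length_bp[i]) {
      bad(i, "amplicon_length_bp", "must be <= plasmid_length_bp")
    }
    if (is.na(df$output_mass_ng[i]) || df$output_mass_ng[i] <= 0) {
      bad(i, "output_mass_ng", "must be a positive mass")
    }
    if (df$method[i] != "in_vivo" &&
        (is.na(df$template_mass_ng[i]) || df$template_mass_ng[i] <= 0)) {
      bad(i, "template_mass_ng", "in vitro methods need a template mass")
    }
  }
  df
}

# Turn schema rows into replicate_record objects (ng -> g conversion here).
as_replicate_records <- function(records) {
  if (inherits(records, "simulated_assay")) records <- records$records
  if (!is.data.frame(records)) {
    sutox_error("`records` must be a data.frame in the assay-count schema",
                "sutox_invalid_input")
  }
  df <- validate_assay_counts(records)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    synth <- synthesis_run(
      method = row$method, label = row$label,
      plasmid_length_bp = row$plasmid_length_bp,
      amplicon_length_bp = row$amplicon_length_bp,
      template_mass_g = if (row$method == "in_vivo") NA_real_
                        else row$template_mass_ng * 1e-9,
      output_mass_g = row$output_mass_ng * 1e-9)
    replicate_record(
      group = row$group, replicate_id = row$replicate_id,
      sucrose_plate = plate_count(row$sucrose_cfu, row$sucrose_dilution,
                                  row$sucrose_fraction, "sucrose"),
      plain_plate = plate_count(row$plain_cfu, row$plain_dilution,
                                row$plain_fraction, "plain"),
      nc_sucrose = plate_count(row$nc_sucrose_cfu, row$sucrose_dilution,
                               row$sucrose_fraction, "sucrose"),
      nc_plain = plate_count(row$nc_plain_cfu, row$plain_dilution,
                             row$plain_fraction, "plain"),
      synthesis = synth)
  })
}
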