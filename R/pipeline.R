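#' Round a percentage for human-readable reports
#'
#' One documented precision rule used everywhere a percentage is printed:
#' values at or above 99% keep two decimals (so near-certain intactness like
#' 99.98% is not flattened to 100%), values between 1% and 99% keep one
#' decimal, and values below 1% keep two decimals. Machine-readable outputs
#' always retain full precision.
#'
#' @param x Percentage value(s).
#' @return Rounded value(s).
#' @examples
#' report_percent(c(2.726, 86.544, 99.9817, 6.96, 0.00948))
#' @export
report_percent <- function(x) {
  ifelse(x >= 99, round(x, 2), ifelse(x >= 1, round(x, 1), round(x, 2)))
}

#' Run the estimation pipeline on an assay-count table
#'
#' Loads (or accepts) an assay-count table, estimates per-replicate LOF
#' rates, summarizes per group with fold changes against a reference, runs
#' the ANOVA/Dunnett comparison when the design allows it, and optionally
#' writes the per-replicate and summary tables, a JSON report, and an audit
#' log of every convention applied (background clamps and BDL events), since
#' those conventions silently change values.
#'
#' @param input Path to an assay-count CSV or a data.frame in the schema.
#' @param output_dir Directory for output files; `NULL` (default) writes
#'   nothing and just returns the results.
#' @param region_length_bp Mutational target length (default 1,533).
#' @param reference_group Reference for fold changes and Dunnett contrasts;
#'   defaults to the first group in the table.
#' @param bp_molar_mass Mean molar mass per base pair (g/mol).
#' @return A list: `estimates` (per-replicate data.frame), `summary`
#'   (per-group data.frame), `comparison` ([compare_groups()] result or
#'   `NULL` with single-group input), `log` (character vector of applied
#'   conventions), and, when `output_dir` is given, `files`.
#' @export
run_estimation <- function(input, output_dir = NULL,
                           region_length_bp = SACB_REGION_BP,
                           reference_group = NULL,
                           bp_molar_mass = BP_MOLAR_MASS) {
  records <- if (is.character(input)) read_assay_counts(input)
             else validate_assay_counts(input)
  if (is.null(reference_group)) reference_group <- records$group[1]

  log_lines <- c(
    sprintf("records: %d replicates in %d group(s)", nrow(records),
            length(unique(records$group))),
    sprintf("region_length_bp = %d; reference_group = %s",
            as.integer(region_length_bp), reference_group))
  # audit clamps and BDL events before estimating
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    net_suc <- r$sucrose_cfu * r$sucrose_dilution / r$sucrose_fraction -
      r$nc_sucrose_cfu * r$sucrose_dilution / r$sucrose_fraction
    if (net_suc < 0) {
      log_lines <- c(log_lines, sprintf(
        "row %d (%s/%s): sucrose control exceeds sample; clamped to 0",
        i, r$group, r$replicate_id))
    }
    if (net_suc <= 0) {
      log_lines <- c(log_lines, sprintf(
        "row %d (%s/%s): below detection limit, scored as 0.5 CFU",
        i, r$group, r$replicate_id))
    }
  }

  est <- estimate_rates(records, region_length_bp, bp_molar_mass)
  groups <- unique(est$group)
  summary_df <- summarize_groups(est, reference_group)
  comparison <- NULL
  if (length(groups) >= 2 && all(table(est$group) >= 2)) {
    comparison <- tryCatch(
      compare_groups(est, reference_group),
      sutox_error = function(e) {
        log_lines <<- c(log_lines,
                        paste("group comparison skipped:",
                              conditionMessage(e)))
        NULL
      })
    if (!is.null(comparison)) {
      summary_df$adjusted_p <- NA_real_
      idx <- match(names(comparison$per_group_adjusted_p), summary_df$group)
      summary_df$adjusted_p[idx] <- comparison$per_group_adjusted_p
    }
  } else {
    log_lines <- c(log_lines,
                   "group comparison skipped: need >= 2 groups with >= 2 replicates")
    if (length(groups) < 2) {
      warning("single-group input: fold changes are all 1, comparison skipped")
    }
  }
  log_lines <- c(log_lines,
                 sprintf("BDL replicates: %d of %d", sum(est$bdl_flag),
                         nrow(est)))

  result <- list(estimates = est, summary = summary_df,
                 comparison = comparison, log = log_lines)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      estimates = file.path(output_dir, "rate_estimates.csv"),
      summary = file.path(output_dir, "group_summary.csv"),
      report = file.path(output_dir, "report.json"),
      log = file.path(output_dir, "run.log"))
    utils::write.csv(est, files$estimates, row.names = FALSE)
    utils::write.csv(summary_df, files$summary, row.names = FALSE)
    jsonlite::write_json(
      list(estimates = est, summary = summary_df,
           anova = if (!is.null(comparison))
             list(f = comparison$anova_f, p = comparison$anova_p),
           reference_group = reference_group),
      files$report, auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(log_lines, files$log)
    result$files <- files
  }
  result
}

#' Recompute the published worked examples
#'
#' Re-derives, from the in-package constants alone, the derived quantities
#' reported for this assay: the MBI per-bp rate expressed in percent per kb,
#' the construct-level LOF risks of the rAAV payload and dystrophin
#' examples at the Phi29 and MBI rates, the triple-transfection intactness
#' probabilities, and the Q5-vs-MBI fold change. Each row carries the
#' reported value, the freshly recomputed value rounded under
#' [report_percent()] (fold changes round to the nearest integer), and a
#' pass flag.
#'
#' @param mode Risk-formula mode, `"linear"` (the reported arithmetic) or
#'   `"poisson"`; poisson rows are marked as differing from the reported
#'   convention.
#' @return A data.frame with columns `quantity`, `units`, `reported`,
#'   `recomputed`, `recomputed_rounded`, `pass`, `note`.
#' @examples
#' reproduce_examples()
#' @export
reproduce_examples <- function(mode = c("linear", "poisson")) {
  mode <- match.arg(mode)
  phi29 <- risk_model(sutox_rates[["Phi29"]], mode)
  mbi <- risk_model(sutox_rates[["MBI"]], mode)
  raav <- list(construct_spec("GOI", 4.7), construct_spec("RepCap", 5.5),
               construct_spec("Helper", 13))
  note <- if (mode == "poisson") "mode differs from reported arithmetic"
          else ""
  rows <- list(
    list("MBI rate per kb", "% per kb", 0.00079,
         per_bp_to_percent_per_kb(7.9e-9), signif_round = TRUE),
    list("rAAV GOI (4.7 kb) LOF risk, Phi29", "%", 2.7,
         100 * p_lof(phi29, raav[[1]])),
    list("triple transfection all intact, Phi29", "%", 86.5,
         100 * p_all_intact(phi29, raav)),
    list("triple transfection all intact, MBI", "%", 99.98,
         100 * p_all_intact(mbi, raav)),
    list("dystrophin (12 kb) LOF risk, Phi29", "%", 7,
         100 * p_lof(phi29, construct_spec("dystrophin", 12))),
    list("dystrophin (12 kb) LOF risk, MBI", "%", 0.01,
         100 * p_lof(mbi, construct_spec("dystrophin", 12))),
    list("fold change Q5 vs MBI", "fold", 84,
         sutox_rates[["Q5"]] / sutox_rates[["MBI"]], fold = TRUE))
  out <- do.call(rbind, lapply(rows, function(r) {
    recomputed <- r[[4]]
    rounded <- if (isTRUE(r$fold)) round(recomputed)
               else if (isTRUE(r$signif_round)) signif(recomputed, 2)
               else report_percent(recomputed)
    data.frame(quantity = r[[1]], units = r[[2]], reported = r[[3]],
               recomputed = recomputed, recomputed_rounded = rounded,
               pass = isTRUE(all.equal(rounded, r[[3]])) && mode == "linear",
               note = note, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
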