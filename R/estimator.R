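# Default mutational target: the sacB ORF plus promoter, 1,533 bp.
SACB_REGION_BP <- 1533L

#' Construct a replicate record
#'
#' One biological replicate of the assay: a sucrose plate and a plain plate
#' for the sample, matching negative-control plates (no-insert ligation
#' transformed in parallel), and the synthesis run the DNA came from.
#'
#' @param group Group label (strain or polymerase).
#' @param replicate_id Identifier within the group.
#' @param sucrose_plate,plain_plate Sample [plate_count()]s (media must be
#'   `"sucrose"` and `"plain"` respectively).
#' @param nc_sucrose,nc_plain Negative-control [plate_count()]s on the
#'   matching media.
#' @param synthesis The [synthesis_run()] that produced the DNA.
#' @return An object of class `replicate_record`.
#' @export
replicate_record <- function(group, replicate_id, sucrose_plate, plain_plate,
                             nc_sucrose, nc_plain, synthesis) {
  plates <- list(sucrose_plate = sucrose_plate, plain_plate = plain_plate,
                 nc_sucrose = nc_sucrose, nc_plain = nc_plain)
  for (nm in names(plates)) {
    if (!inherits(plates[[nm]], "plate_count")) {
      sutox_error(sprintf("`%s` must be a plate_count", nm),
                  "sutox_invalid_input")
    }
  }
  if (sucrose_plate$media != "sucrose" || nc_sucrose$media != "sucrose" ||
      plain_plate$media != "plain" || nc_plain$media != "plain") {
    sutox_error("plate media do not match their roles",
                "sutox_invalid_input")
  }
  if (!inherits(synthesis, "synthesis_run")) {
    sutox_error("`synthesis` must be a synthesis_run", "sutox_invalid_input")
  }
  structure(
    list(group = as.character(group),
         replicate_id = as.character(replicate_id),
         sucrose_plate = sucrose_plate, plain_plate = plain_plate,
         nc_sucrose = nc_sucrose, nc_plain = nc_plain,
         synthesis = synthesis),
    class = "replicate_record")
}

#' Convert a per-bp rate to percent per kilobase
#'
#' Multiplies by 1,000 bp/kb and by 100 to express the rate as a percentage:
#' e.g. 7.9e-9 per bp becomes 0.00079 % per kb.
#'
#' @param rate_per_bp LOF rate per base pair per doubling.
#' @return Rate in percent per kb per doubling.
#' @export
per_bp_to_percent_per_kb <- function(rate_per_bp) {
  rate_per_bp * 1000 * 100
}

#' Convert percent per kilobase back to a per-bp rate
#'
#' Inverse of [per_bp_to_percent_per_kb()].
#'
#' @param percent_per_kb Rate in percent per kb per doubling.
#' @return Rate per base pair per doubling.
#' @export
percent_per_kb_to_per_bp <- function(percent_per_kb) {
  percent_per_kb / 1000 / 100
}

#' Estimate the LOF mutation rate for one replicate
#'
#' Composes the full per-replicate calculation: normalize and background-
#' subtract both plates, apply the 0.5-CFU below-detection-limit convention
#' to the sucrose count, derive DNA doublings from the synthesis masses, and
#' compute
#' \deqn{rate = \frac{mutant\ CFU}{transformant\ CFU \times doublings}}
#' i.e. the fraction of molecules carrying a LOF mutation, normalized by how
#' many times the template was replicated. The per-bp rate divides by the
#' mutational target length; percent per kb multiplies that by 1,000 x 100.
#'
#' @param record A [replicate_record()].
#' @param region_length_bp Mutational target length in bp (default 1,533,
#'   the sacB ORF plus promoter).
#' @param bp_molar_mass Mean molar mass per base pair (g/mol), used for the
#'   single-molecule input mass of in vivo runs.
#' @return A `rate_estimate` list with fields `group`, `replicate_id`,
#'   `mutant_cfu_net`, `transformant_cfu_net`, `doublings`,
#'   `rate_per_doubling`, `rate_per_bp`, `rate_percent_per_kb`, `bdl_flag`
#'   and `region_length_bp`.
#' @export
lof_rate <- function(record, region_length_bp = SACB_REGION_BP,
                     bp_molar_mass = BP_MOLAR_MASS) {
  if (!inherits(record, "replicate_record")) {
    sutox_error("`record` must be a replicate_record", "sutox_invalid_input")
  }
  check_scalar(region_length_bp, "region_length_bp", lower = 1)

  mutant_net <- net_cfu(record$sucrose_plate, record$nc_sucrose)
  transformant_net <- net_cfu(record$plain_plate, record$nc_plain)
  if (transformant_net <= 0) {
    sutox_error(sprintf(
      "replicate %s/%s has zero net transformants; rate undefined",
      record$group, record$replicate_id), "sutox_degenerate_replicate")
  }
  bdl <- apply_bdl(mutant_net)
  doublings <- dna_doublings(
    dna_input_mass(record$synthesis, bp_molar_mass),
    record$synthesis$output_mass_g)
  if (doublings <= 0) {
    sutox_error(sprintf(
      "replicate %s/%s has zero doublings; rate undefined",
      record$group, record$replicate_id), "sutox_degenerate_replicate")
  }
  rate <- bdl$cfu / transformant_net / doublings
  rate_bp <- rate / region_length_bp
  structure(
    list(group = record$group, replicate_id = record$replicate_id,
         mutant_cfu_net = bdl$cfu, transformant_cfu_net = transformant_net,
         doublings = doublings, rate_per_doubling = rate,
         rate_per_bp = rate_bp,
         rate_percent_per_kb = per_bp_to_percent_per_kb(rate_bp),
         bdl_flag = bdl$bdl,
         region_length_bp = as.integer(region_length_bp)),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %s/%s: %.3g mutants / %.3g transformants / %.3g doublings\n",
    x$group, x$replicate_id, x$mutant_cfu_net, x$transformant_cfu_net,
    x$doublings))
  cat(sprintf("  rate %.3g per doubling = %.2g %%/kb%s\n",
              x$rate_per_doubling, signif(x$rate_percent_per_kb, 2),
              if (x$bdl_flag) " [BDL]" else ""))
  invisible(x)
}

#' Estimate LOF rates for a table of replicates
#'
#' Runs [lof_rate()] on every row of a validated assay-count table (see
#' [read_assay_counts()] for the column schema) and returns one row per
#' replicate with the full set of rate fields.
#'
#' @param records A data.frame in the assay-count schema, as returned by
#'   [read_assay_counts()] or [simulate_assay()].
#' @param region_length_bp Mutational target length in bp (default 1,533).
#' @param bp_molar_mass Mean molar mass per base pair (g/mol).
#' @return A data.frame with columns `group`, `replicate_id`,
#'   `mutant_cfu_net`, `transformant_cfu_net`, `doublings`,
#'   `rate_per_doubling`, `rate_per_bp`, `rate_percent_per_kb`, `bdl_flag`.
#' @export
estimate_rates <- function(records, region_length_bp = SACB_REGION_BP,
                           bp_molar_mass = BP_MOLAR_MASS) {
  recs <- as_replicate_records(records)
  out <- lapply(recs, function(r) {
    est <- lof_rate(r, region_length_bp, bp_molar_mass)
    data.frame(group = est$group, replicate_id = est$replicate_id,
               mutant_cfu_net = est$mutant_cfu_net,
               transformant_cfu_net = est$transformant_cfu_net,
               doublings = est$doublings,
               rate_per_doubling = est$rate_per_doubling,
               rate_per_bp = est$rate_per_bp,
               rate_percent_per_kb = est$rate_percent_per_kb,
               bdl_flag = est$bdl_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fold changes of group mean rates against a reference group
#'
#' Divides each group's mean per-doubling rate by the reference group's
#' mean; the reference group maps to exactly 1. The per-doubling and
#' percent-per-kb scales give identical fold changes since the conversion is
#' a shared constant.
#'
#' @param estimates Output of [estimate_rates()] (needs `group` and
#'   `rate_per_doubling` columns).
#' @param reference_group Group used as the denominator.
#' @return Named numeric vector of fold changes, one per group.
#' @export
fold_changes <- function(estimates, reference_group) {
  if (!all(c("group", "rate_per_doubling") %in% names(estimates))) {
    sutox_error("`estimates` needs group and rate_per_doubling columns",
                "sutox_invalid_input")
  }
  means <- tapply(estimates$rate_per_doubling, estimates$group, mean)
  if (!reference_group %in% names(means)) {
    sutox_error(sprintf("reference group '%s' not present", reference_group),
                "sutox_invalid_input")
  }
  if (means[[reference_group]] <= 0) {
    sutox_error("reference group mean rate must be positive",
                "sutox_invalid_input")
  }
  fc <- means / means[[reference_group]]
  fc[reference_group] <- 1
  c(fc)
}

#' Compare group rates by one-way ANOVA with Dunnett contrasts
#'
#' Fits a one-way analysis of variance on the untransformed per-replicate
#' per-doubling rates and tests each group against the reference with
#' Dunnett's many-to-one procedure (two-sided, single-step adjusted
#' p-values, via \pkg{multcomp}).
#'
#' @param estimates Output of [estimate_rates()]; at least 2 groups with
#'   at least 2 replicates each.
#' @param reference_group Group every other group is compared to.
#' @return A `comparison_result` list: `group_means`, `fold_changes`,
#'   `anova_f`, `anova_p`, `per_group_adjusted_p` (named by non-reference
#'   group), and `reference_group`.
#' @export
compare_groups <- function(estimates, reference_group) {
  fc <- fold_changes(estimates, reference_group)   # validates columns/ref
  groups <- unique(estimates$group)
  if (length(groups) < 2) {
    sutox_error("need at least 2 groups to compare", "sutox_invalid_input")
  }
  n_per <- table(estimates$group)
  if (any(n_per < 2)) {
    sutox_error(sprintf(
      "groups with fewer than 2 replicates: %s",
      paste(names(n_per)[n_per < 2], collapse = ", ")),
      "sutox_insufficient_replicates")
  }
  dat <- data.frame(
    rate = estimates$rate_per_doubling,
    group = factor(estimates$group,
                   levels = c(reference_group,
                              setdiff(sort(groups), reference_group))))
  if (stats::var(dat$rate) == 0 ||
      all(tapply(dat$rate, dat$group, stats::var) == 0)) {
    sutox_error("zero within-group variance: F statistic undefined",
                "sutox_degenerate_input")
  }
  fit <- stats::aov(rate ~ group, data = dat)
  tab <- stats::anova(fit)
  dunnett <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  ps <- summary(dunnett)$test$pvalues
  names(ps) <- levels(dat$group)[-1]
  structure(
    list(group_means = c(tapply(dat$rate, dat$group, mean)),
         fold_changes = fc,
         anova_f = tab[["F value"]][1],
         anova_p = tab[["Pr(>F)"]][1],
         per_group_adjusted_p = c(ps),
         reference_group = reference_group),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> one-way ANOVA F = %.3g, p = %.3g\n",
              x$anova_f, x$anova_p))
  cat(sprintf("Dunnett contrasts vs %s (two-sided, adjusted):\n",
              x$reference_group))
  for (g in names(x$per_group_adjusted_p)) {
    cat(sprintf("  %-12s fold %8.3g   p = %.3g\n", g,
                x$fold_changes[[g]], x$per_group_adjusted_p[[g]]))
  }
  invisible(x)
}

#' Per-group summary of rate estimates
#'
#' @param estimates Output of [estimate_rates()].
#' @param reference_group Optional; adds a fold-change column when given.
#' @return A data.frame with one row per group: n, mean and SD of the
#'   per-doubling rate, mean percent-per-kb rate, BDL count, and (when a
#'   reference is given) fold change.
#' @export
summarize_groups <- function(estimates, reference_group = NULL) {
  split_by <- split(estimates, estimates$group)
  out <- do.call(rbind, lapply(names(split_by), function(g) {
    e <- split_by[[g]]
    data.frame(group = g, n = nrow(e),
               mean_rate_per_doubling = mean(e$rate_per_doubling),
               sd_rate_per_doubling = stats::sd(e$rate_per_doubling),
               mean_rate_percent_per_kb = mean(e$rate_percent_per_kb),
               n_bdl = sum(e$bdl_flag), stringsAsFactors = FALSE)
  }))
  if (!is.null(reference_group)) {
    fc <- fold_changes(estimates, reference_group)
    out$fold_change <- unname(fc[out$group])
  }
  rownames(out) <- NULL
  out
}
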