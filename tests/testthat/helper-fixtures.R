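# Builders for in-code fixtures shared across test files.

make_plate <- function(cfu, media, dil = 1, frac = 1) {
  plate_count(cfu, dilution_factor = dil, plated_fraction = frac,
              media = media)
}

# A replicate_record with a synthesis run engineered to give exactly
# `doublings` doublings (template 1 ng, output 2^d ng).
make_record <- function(sucrose, plain, nc_sucrose = 0, nc_plain = 0,
                        doublings = 20, group = "g", rep = "r1",
                        method = "pcr", dil = 1, frac = 1) {
  synth <- synthesis_run(method, label = "test",
                         plasmid_length_bp = 5000,
                         amplicon_length_bp = 5000,
                         template_mass_g = 1e-9,
                         output_mass_g = 1e-9 * 2^doublings)
  replicate_record(
    group = group, replicate_id = rep,
    sucrose_plate = make_plate(sucrose, "sucrose", dil, frac),
    plain_plate = make_plate(plain, "plain", dil, frac),
    nc_sucrose = make_plate(nc_sucrose, "sucrose", dil, frac),
    nc_plain = make_plate(nc_plain, "plain", dil, frac),
    synthesis = synth)
}

# One row of the assay-count CSV schema.
make_assay_row <- function(group = "g", rep = "r1", method = "pcr",
                           sucrose = 10, plain = 1000, nc_sucrose = 0,
                           nc_plain = 0, doublings = 20, dil = 1,
                           frac = 1) {
  data.frame(
    group = group, replicate_id = rep, method = method, label = method,
    plasmid_length_bp = 5000, amplicon_length_bp = 5000,
    template_mass_ng = if (method == "in_vivo") NA_real_ else 1,
    output_mass_ng = if (method == "in_vivo")
      plasmid_molecule_mass(5000) * 1e9 * 2^doublings else 2^doublings,
    sucrose_cfu = sucrose, sucrose_dilution = dil, sucrose_fraction = frac,
    plain_cfu = plain, plain_dilution = dil, plain_fraction = frac,
    nc_sucrose_cfu = nc_sucrose, nc_plain_cfu = nc_plain,
    stringsAsFactors = FALSE)
}

# A grouped rate-estimate table built from chosen per-replicate rates, for
# fold-change / comparison tests (doublings = 1, transformants = 1, so the
# per-doubling rate equals the mutant count).
make_rate_table <- function(rates_by_group) {
  do.call(rbind, lapply(names(rates_by_group), function(g) {
    r <- rates_by_group[[g]]
    data.frame(group = g, replicate_id = paste0("r", seq_along(r)),
               mutant_cfu_net = r, transformant_cfu_net = 1, doublings = 1,
               rate_per_doubling = r, rate_per_bp = r / 1533,
               rate_percent_per_kb = r / 1533 * 1e5, bdl_flag = FALSE,
               stringsAsFactors = FALSE)
  }))
}

# Write a table then read it back, so validation happens through the
# public reader (errors carry file row numbers).
validate_and_read <- function(df) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  read_assay_counts(path)
}

# Permutation oracle for the many-to-one comparison: max-|t| permutation
# distribution over group-label shuffles, pooled-variance t statistics of
# each non-reference group against the reference.
perm_maxt_p <- function(est, reference, B = 1000) {
  groups <- setdiff(unique(est$group), reference)
  tstat <- function(rate, grp) {
    s2 <- sum(tapply(rate, grp, function(x) sum((x - mean(x))^2))) /
      (length(rate) - length(unique(grp)))
    vapply(groups, function(g) {
      a <- rate[grp == g]; b <- rate[grp == reference]
      (mean(a) - mean(b)) / sqrt(s2 * (1 / length(a) + 1 / length(b)))
    }, numeric(1))
  }
  obs <- abs(tstat(est$rate_per_doubling, est$group))
  maxt <- replicate(B, {
    shuffled <- sample(est$group)
    max(abs(tstat(est$rate_per_doubling, shuffled)))
  })
  vapply(obs, function(t0) mean(maxt >= t0), numeric(1))
}
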