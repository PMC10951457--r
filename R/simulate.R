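#' Configure the forward assay simulator
#'
#' Parameterizes a forward simulation of the whole assay: branching DNA
#' replication with absorbing LOF mutation, transformation sampling, plating
#' with dilution, and Poisson background colonies. The defaults describe a
#' Phi29-like RCA run assayed in triplicate against the 1,533 bp sacB
#' target.
#'
#' @param method `"in_vivo"`, `"pcr"` or `"rca"`. In vivo replication starts
#'   from the single plasmid molecule that transformed the founder cell, so
#'   `initial_molecules` is forced to 1.
#' @param true_rate_per_bp True LOF rate per bp per copy event (mu). The
#'   per-copy LOF probability is `q = 1 - (1 - mu)^L` over the
#'   `region_length_bp` target.
#' @param region_length_bp Mutational target length L in bp (default 1,533).
#' @param n_cycles Number of replication cycles (doublings at efficiency 1).
#' @param per_cycle_efficiency Probability that a molecule replicates in a
#'   cycle, in (0, 1]; 1 for in vivo exponential growth.
#' @param initial_molecules Starting population size (1 for in vivo).
#' @param transformants_mean Expected total transformants per replicate.
#' @param background_mean_sucrose,background_mean_plain Poisson means of
#'   background colonies per plate (vector re-ligation carry-over).
#' @param dilution_factor,plated_fraction Plating geometry applied to every
#'   plate (see [plate_count()]).
#' @param n_replicates Biological replicates (independent syntheses).
#' @param seed Integer master seed; replicate `r` reseeds the generator with
#'   `(seed + 7919 * r) mod (2^31 - 1)` so replicates are reproducible
#'   independently.
#' @param population_cap Error threshold for the simulated population; runs
#'   that would exceed it abort with advice to scale parameters down.
#' @param plasmid_length_bp Plasmid length used to back-compute synthesis
#'   masses for the emitted records.
#' @param template_mass_g Nominal in vitro template mass used in the
#'   back-computed records.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(method = c("rca", "pcr", "in_vivo"),
                       true_rate_per_bp = 5.8e-6,
                       region_length_bp = SACB_REGION_BP,
                       n_cycles = 20,
                       per_cycle_efficiency = 1,
                       initial_molecules = if (method[1] == "in_vivo") 1 else 500,
                       transformants_mean = 1e5,
                       background_mean_sucrose = 1,
                       background_mean_plain = 1,
                       dilution_factor = 1,
                       plated_fraction = 1,
                       n_replicates = 3,
                       seed = 1,
                       population_cap = 1e9,
                       plasmid_length_bp = 5000,
                       template_mass_g = 1e-8) {
  method <- match.arg(method)
  check_scalar(true_rate_per_bp, "true_rate_per_bp", lower = 0)
  check_scalar(region_length_bp, "region_length_bp", lower = 1)
  check_scalar(n_cycles, "n_cycles", lower = 1)
  check_scalar(per_cycle_efficiency, "per_cycle_efficiency", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_scalar(initial_molecules, "initial_molecules", lower = 1)
  check_scalar(transformants_mean, "transformants_mean", lower = 0,
               strict_lower = TRUE)
  check_scalar(background_mean_sucrose, "background_mean_sucrose", lower = 0)
  check_scalar(background_mean_plain, "background_mean_plain", lower = 0)
  check_scalar(dilution_factor, "dilution_factor", lower = 1)
  check_scalar(plated_fraction, "plated_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(n_replicates, "n_replicates", lower = 1)
  check_scalar(seed, "seed")
  if (method == "in_vivo" && initial_molecules != 1) {
    sutox_error("in vivo replication starts from a single molecule",
                "sutox_invalid_input")
  }
  if (true_rate_per_bp * region_length_bp > 1) {
    sutox_error("true_rate_per_bp x region_length_bp exceeds 1",
                "sutox_invalid_input")
  }
  structure(
    list(method = method, true_rate_per_bp = true_rate_per_bp,
         region_length_bp = as.integer(region_length_bp),
         n_cycles = as.integer(n_cycles),
         per_cycle_efficiency = per_cycle_efficiency,
         initial_molecules = initial_molecules,
         transformants_mean = transformants_mean,
         background_mean_sucrose = background_mean_sucrose,
         background_mean_plain = background_mean_plain,
         dilution_factor = dilution_factor,
         plated_fraction = plated_fraction,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed),
         population_cap = population_cap,
         plasmid_length_bp = as.integer(plasmid_length_bp),
         template_mass_g = template_mass_g),
    class = "sim_config")
}

# Per-copy LOF probability over the whole target region.
per_copy_lof_prob <- function(cfg) {
  1 - (1 - cfg$true_rate_per_bp)^cfg$region_length_bp
}

#' Simulate branching DNA replication with absorbing LOF mutation
#'
#' Population-count simulation of semiconservative replication: in each
#' cycle every molecule replicates with probability
#' `per_cycle_efficiency`, and a replicating molecule is replaced by two
#' daughters, each carrying one newly synthesized strand and therefore each
#' independently acquiring at least one LOF mutation with probability
#' `q = 1 - (1 - mu)^L`. Daughters of a mutant molecule are always mutant
#' (LOF is absorbing; reversion is negligible at these rates). Tracking
#' population counts per generation rather than lineage trees preserves
#' Luria-Delbruck jackpot variance without storing trees. Uses the current
#' RNG state; seed management is done by [simulate_assay()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `wildtype` and `mutant` final molecule counts and
#'   `realized_doublings = log2(total / initial)`.
#' @export
simulate_replication <- function(cfg) {
  if (!inherits(cfg, "sim_config")) {
    sutox_error("`cfg` must be a sim_config", "sutox_invalid_input")
  }
  q <- per_copy_lof_prob(cfg)
  eff <- cfg$per_cycle_efficiency
  wt <- cfg$initial_molecules
  mut <- 0
  for (cycle in seq_len(cfg$n_cycles)) {
    if ((wt + mut) * (1 + eff) > cfg$population_cap) {
      sutox_error(paste0(
        "population would exceed the cap (", format(cfg$population_cap),
        "); rescale initial_molecules or n_cycles"),
        "sutox_resolution_limit")
    }
    rep_wt <- stats::rbinom(1, wt, eff)
    rep_mut <- stats::rbinom(1, mut, eff)
    new_mutants <- stats::rbinom(1, 2 * rep_wt, q)
    # replicating parents are replaced by their two daughters
    wt <- (wt - rep_wt) + (2 * rep_wt - new_mutants)
    mut <- (mut - rep_mut) + 2 * rep_mut + new_mutants
  }
  list(wildtype = wt, mutant = mut,
       realized_doublings = log2((wt + mut) / cfg$initial_molecules))
}

#' Simulate plating of a replicated population
#'
#' Transformation and plating are modelled with standard plating statistics:
#' the number of transformants reaching each plate is Poisson with mean
#' `transformants_mean * plated_fraction / dilution_factor`; on sucrose,
#' each sampled transformant survives only if its molecule was a LOF mutant
#' (binomial thinning at the population mutant fraction); independent
#' Poisson background colonies are added to every plate, and matching
#' negative-control plates receive background draws only. Sampling is
#' effectively with replacement, valid while transformants are a small
#' fraction of the population; a guard errors when the expected
#' transformants exceed 1% of the final molecule count.
#'
#' @param wildtype,mutant Final molecule counts from
#'   [simulate_replication()].
#' @param cfg A [sim_config()].
#' @return A list of four raw plate counts: `sucrose_cfu`, `plain_cfu`,
#'   `nc_sucrose_cfu`, `nc_plain_cfu`.
#' @export
simulate_plating <- function(wildtype, mutant, cfg) {
  if (!inherits(cfg, "sim_config")) {
    sutox_error("`cfg` must be a sim_config", "sutox_invalid_input")
  }
  total <- wildtype + mutant
  if (total <= 0) {
    sutox_error("cannot plate an empty population", "sutox_invalid_input")
  }
  if (cfg$transformants_mean > 0.01 * total) {
    sutox_error(paste0(
      "transformants_mean exceeds 1% of the final population (",
      format(total), "); with-replacement sampling invalid"),
      "sutox_sampling_guard")
  }
  plate_mean <- cfg$transformants_mean * cfg$plated_fraction /
    cfg$dilution_factor
  p_mut <- mutant / total
  plain <- stats::rpois(1, plate_mean)
  sucrose_sampled <- stats::rpois(1, plate_mean)
  sucrose <- stats::rbinom(1, sucrose_sampled, p_mut)
  list(
    sucrose_cfu = sucrose + stats::rpois(1, cfg$background_mean_sucrose),
    plain_cfu = plain + stats::rpois(1, cfg$background_mean_plain),
    nc_sucrose_cfu = stats::rpois(1, cfg$background_mean_sucrose),
    nc_plain_cfu = stats::rpois(1, cfg$background_mean_plain))
}

replicate_seed <- function(seed, r) {
  as.integer((as.double(seed) + 7919 * r) %% (2^31 - 1))
}

#' Simulate a complete assay
#'
#' Runs [simulate_replication()] and [simulate_plating()] for each of
#' `n_replicates` independent syntheses and packages the results as an
#' assay-count table directly consumable by [estimate_rates()]. Synthesis
#' masses are back-computed so that [dna_doublings()] reproduces each
#' replicate's realized doublings exactly: in vivo records carry the
#' single-molecule input implied by `plasmid_length_bp`, in vitro records
#' the nominal `template_mass_g` over the full plasmid. Deterministic given
#' the config: replicate `r` reseeds with `(seed + 7919 r) mod (2^31 - 1)`.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `simulated_assay`: `records` (assay-count
#'   data.frame, see [read_assay_counts()]), `truth` (the config plus the
#'   per-copy LOF probability `q` and the expected per-doubling /
#'   percent-per-kb rates), `final_wildtype_molecules`,
#'   `final_mutant_molecules` and `realized_doublings` (per replicate).
#' @examples
#' sim <- simulate_assay(sim_config(n_replicates = 2, n_cycles = 10,
#'                                  transformants_mean = 1e3, seed = 7))
#' estimate_rates(sim$records)
#' @export
simulate_assay <- function(cfg) {
  if (!inherits(cfg, "sim_config")) {
    sutox_error("`cfg` must be a sim_config", "sutox_invalid_input")
  }
  n <- cfg$n_replicates
  wt <- mut <- dbl <- numeric(n)
  rows <- vector("list", n)
  label <- switch(cfg$method, in_vivo = "in_vivo_strain",
                  pcr = "pcr_polymerase", rca = "phi29")
  for (r in seq_len(n)) {
    set.seed(replicate_seed(cfg$seed, r))
    pop <- simulate_replication(cfg)
    plates <- simulate_plating(pop$wildtype, pop$mutant, cfg)
    wt[r] <- pop$wildtype; mut[r] <- pop$mutant
    dbl[r] <- pop$realized_doublings
    if (cfg$method == "in_vivo") {
      input_g <- plasmid_molecule_mass(cfg$plasmid_length_bp)
      template_ng <- NA_real_
    } else {
      input_g <- cfg$template_mass_g
      template_ng <- cfg$template_mass_g * 1e9
    }
    rows[[r]] <- data.frame(
      group = cfg$method, replicate_id = sprintf("rep%d", r),
      method = cfg$method, label = label,
      plasmid_length_bp = cfg$plasmid_length_bp,
      amplicon_length_bp = cfg$plasmid_length_bp,
      template_mass_ng = template_ng,
      output_mass_ng = input_g * 2^pop$realized_doublings * 1e9,
      sucrose_cfu = plates$sucrose_cfu,
      sucrose_dilution = cfg$dilution_factor,
      sucrose_fraction = cfg$plated_fraction,
      plain_cfu = plates$plain_cfu,
      plain_dilution = cfg$dilution_factor,
      plain_fraction = cfg$plated_fraction,
      nc_sucrose_cfu = plates$nc_sucrose_cfu,
      nc_plain_cfu = plates$nc_plain_cfu,
      stringsAsFactors = FALSE)
  }
  q <- per_copy_lof_prob(cfg)
  structure(
    list(records = do.call(rbind, rows),
         truth = c(unclass(cfg), list(
           per_copy_lof_prob = q,
           expected_rate_per_doubling = q,
           expected_rate_percent_per_kb = per_bp_to_percent_per_kb(
             q / cfg$region_length_bp))),
         final_wildtype_molecules = wt,
         final_mutant_molecules = mut,
         realized_doublings = dbl),
    class = "simulated_assay")
}

#' @export
print.simulated_assay <- function(x, ...) {
  n <- length(x$realized_doublings)
  cat(sprintf(
    "<simulated_assay> %d replicate(s), method %s, q = %.3g, %0.4g doublings\n",
    n, x$truth$method, x$truth$per_copy_lof_prob,
    mean(x$realized_doublings)))
  invisible(x)
}

#' Closed-form expected mutant fraction
#'
#' Under the absorbing-mutation doubling model at efficiency 1, the expected
#' mutant fraction after `d` doublings is `1 - (1 - q)^d` with
#' `q = 1 - (1 - mu)^L`: each doubling leaves a surviving wild-type lineage
#' intact with probability `1 - q`. Serves as the analytic oracle for the
#' simulator; restricted to `q <= 0.01`, where the expectation over the
#' branching population coincides with the per-lineage form.
#'
#' @param cfg A [sim_config()] with `per_cycle_efficiency = 1`.
#' @return Expected mutant fraction in \[0, 1\].
#' @export
expected_mutant_fraction <- function(cfg) {
  if (!inherits(cfg, "sim_config")) {
    sutox_error("`cfg` must be a sim_config", "sutox_invalid_input")
  }
  if (cfg$per_cycle_efficiency != 1) {
    sutox_error("closed form requires per_cycle_efficiency = 1",
                "sutox_unsupported_configuration")
  }
  q <- per_copy_lof_prob(cfg)
  if (q > 0.01) {
    sutox_error("closed form restricted to per-copy LOF probability <= 0.01",
                "sutox_unsupported_configuration")
  }
  1 - (1 - q)^cfg$n_cycles
}
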