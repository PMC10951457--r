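#' Construct a plate count
#'
#' One plate from one transformation: the raw colony count together with the
#' dilution applied before plating and the fraction of the transformation
#' volume that was spread on the plate. The media distinguishes the sucrose
#' (counterselective) plate, on which only LOF sacB mutants grow, from the
#' plain plate that counts total transformants.
#'
#' @param raw_cfu Non-negative integer; colonies counted on the plate.
#' @param dilution_factor Total fold-dilution applied before plating
#'   (>= 1; 1 means undiluted).
#' @param plated_fraction Fraction of the transformation volume plated,
#'   in (0, 1] (e.g. 0.25 when a quarter of the volume is spread).
#' @param media `"sucrose"` or `"plain"`.
#' @return An object of class `plate_count`.
#' @examples
#' plate_count(12, dilution_factor = 10, plated_fraction = 0.25,
#'             media = "sucrose")
#' @export
plate_count <- function(raw_cfu, dilution_factor = 1, plated_fraction = 1,
                        media = c("sucrose", "plain")) {
  media <- match.arg(media)
  check_scalar(raw_cfu, "raw_cfu", lower = 0)
  check_scalar(dilution_factor, "dilution_factor", lower = 1)
  check_scalar(plated_fraction, "plated_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  structure(
    list(raw_cfu = raw_cfu, dilution_factor = dilution_factor,
         plated_fraction = plated_fraction, media = media),
    class = "plate_count")
}

#' @export
print.plate_count <- function(x, ...) {
  cat(sprintf("<plate_count> %s: %g CFU (dilution %g, fraction %g) -> %g\n",
              x$media, x$raw_cfu, x$dilution_factor, x$plated_fraction,
              normalize_plate(x)))
  invisible(x)
}

#' Normalize a plate count to the whole transformation
#'
#' Scales the raw colony count by the dilution factor and the plated
#' fraction, estimating the CFU that the entire undiluted transformation
#' would have yielded: `raw_cfu * dilution_factor / plated_fraction`.
#'
#' @param p A [plate_count()].
#' @return Estimated CFU in the whole transformation (non-negative real).
#' @examples
#' normalize_plate(plate_count(10, 1, 0.25, media = "plain"))  # 40
#' @export
normalize_plate <- function(p) {
  if (!inherits(p, "plate_count")) {
    sutox_error("`p` must be a plate_count", "sutox_invalid_input")
  }
  p$raw_cfu * p$dilution_factor / p$plated_fraction
}

#' Background-subtracted normalized CFU
#'
#' Normalizes the sample and negative-control plates (same media) and
#' subtracts the control as background. Colonies on the no-insert control
#' arise from vector re-ligation or carry-over and are present in every
#' sample; a control exceeding the sample is clamped to zero rather than
#' producing a negative count.
#'
#' @param sample,control [plate_count()] objects on the same media.
#' @return `max(0, normalize_plate(sample) - normalize_plate(control))`.
#' @examples
#' net_cfu(plate_count(100, media = "plain"), plate_count(7, media = "plain"))
#' @export
net_cfu <- function(sample, control) {
  if (!inherits(sample, "plate_count") || !inherits(control, "plate_count")) {
    sutox_error("both arguments must be plate_count objects",
                "sutox_invalid_input")
  }
  if (!identical(sample$media, control$media)) {
    sutox_error(sprintf(
      "media mismatch: sample is %s but control is %s",
      sample$media, control$media), "sutox_invalid_input")
  }
  max(0, normalize_plate(sample) - normalize_plate(control))
}

#' Apply the below-detection-limit half-count convention
#'
#' A replicate with zero net sucrose colonies after background subtraction
#' carries no information about the mutant count other than an upper bound;
#' it is scored as if 0.5 CFU had been observed, giving a strictly positive
#' floor rate, and flagged as below the detection limit (BDL). Only an exact
#' zero triggers the rule: fractional positive net counts, which can arise
#' after dilution scaling, pass through untouched.
#'
#' @param net_mutant_cfu Non-negative net sucrose CFU.
#' @return A list with `cfu` (the possibly-substituted count) and
#'   `bdl` (logical flag).
#' @examples
#' apply_bdl(0)    # 0.5, BDL
#' apply_bdl(12)   # unchanged
#' @export
apply_bdl <- function(net_mutant_cfu) {
  check_scalar(net_mutant_cfu, "net_mutant_cfu", lower = 0)
  if (net_mutant_cfu == 0) {
    list(cfu = 0.5, bdl = TRUE)
  } else {
    list(cfu = net_mutant_cfu, bdl = FALSE)
  }
}
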