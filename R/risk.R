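#' Default per-kb LOF rates by synthesis method
#'
#' Per-doubling LOF mutation rates in percent per kb for common synthesis
#' methods, as measured by the sucrose counterselection assay: two in vivo
#' E. coli strains (DH5a, MBI) and three in vitro polymerases (Taq, Q5,
#' Phi29/RCA). Used as the default rate table by [risk_report()].
#'
#' @format Named numeric vector (percent per kb per doubling).
#' @export
sutox_rates <- c(DH5a = 0.0012, MBI = 0.00079, Taq = 2.3, Q5 = 0.066,
                 Phi29 = 0.58)

#' Construct a risk model
#'
#' Carries a per-kb LOF rate and the formula used to turn it into a
#' per-construct defect probability. `"linear"` multiplies rate by length
#' (a first-order approximation, valid while rate x length is well below
#' 100%); `"poisson"` treats LOF hits as a Poisson process along the
#' construct, `1 - exp(-rate x length)`, which is a proper probability for
#' any rate.
#'
#' @param rate_percent_per_kb LOF rate in percent per kb (>= 0).
#' @param mode `"linear"` (default) or `"poisson"`.
#' @return An object of class `risk_model`.
#' @examples
#' risk_model(0.58)                    # Phi29-like, linear
#' risk_model(0.58, mode = "poisson")
#' @export
risk_model <- function(rate_percent_per_kb, mode = c("linear", "poisson")) {
  mode <- match.arg(mode)
  check_scalar(rate_percent_per_kb, "rate_percent_per_kb", lower = 0)
  structure(list(mode = mode, rate_percent_per_kb = rate_percent_per_kb),
            class = "risk_model")
}

#' Construct a construct specification
#'
#' @param name Construct name (e.g. `"GOI"`, `"RepCap"`, `"Helper"`).
#' @param length_kb Construct length in kilobases (> 0).
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(name, length_kb) {
  check_scalar(length_kb, "length_kb", lower = 0, strict_lower = TRUE)
  structure(list(name = as.character(name), length_kb = length_kb),
            class = "construct_spec")
}

as_construct <- function(x) {
  if (inherits(x, "construct_spec")) return(x)
  if (is_scalar_number(x)) return(construct_spec(sprintf("%g kb", x), x))
  sutox_error("constructs must be construct_spec objects or lengths in kb",
              "sutox_invalid_input")
}

#' Probability that one construct carries a LOF mutation
#'
#' Linear mode: `(rate/100) * length_kb`; errors if that reaches 1, since
#' the linear form is only a small-rate approximation. Poisson mode:
#' `1 - exp(-(rate/100) * length_kb)`.
#'
#' @param model A [risk_model()].
#' @param construct A [construct_spec()] or a bare length in kb.
#' @return Probability in \[0, 1).
#' @examples
#' p_lof(risk_model(0.58), 4.7)   # ~0.027: a 4.7 kb payload at 0.58 %/kb
#' @export
p_lof <- function(model, construct) {
  if (!inherits(model, "risk_model")) {
    sutox_error("`model` must be a risk_model", "sutox_invalid_input")
  }
  construct <- as_construct(construct)
  x <- model$rate_percent_per_kb / 100 * construct$length_kb
  if (model$mode == "linear") {
    if (x >= 1) {
      sutox_error(paste0(
        "linear-mode LOF probability >= 1 for construct '",
        construct$name, "'; use mode = \"poisson\""),
        "sutox_invalid_parameter")
    }
    x
  } else {
    1 - exp(-x)
  }
}

#' Probability that every co-transfected construct is intact
#'
#' For a cell transfected with several constructs (e.g. the rAAV GOI,
#' RepCap and Helper plasmids), the chance that none carries a LOF
#' mutation. Linear mode uses the first-order one-minus-sum form
#' `1 - sum(p_lof)`; poisson mode uses the exact independent product
#' `prod(1 - p_lof)`.
#'
#' @param model A [risk_model()].
#' @param constructs List of [construct_spec()]s or numeric lengths in kb.
#' @return Probability in \[0, 1\].
#' @examples
#' p_all_intact(risk_model(0.58), c(4.7, 5.5, 13))  # ~0.865
#' @export
p_all_intact <- function(model, constructs) {
  if (!inherits(model, "risk_model")) {
    sutox_error("`model` must be a risk_model", "sutox_invalid_input")
  }
  if (length(constructs) == 0) {
    sutox_error("need at least one construct", "sutox_invalid_input")
  }
  if (is.numeric(constructs)) constructs <- as.list(constructs)
  ps <- vapply(constructs, function(cc) p_lof(model, cc), numeric(1))
  if (model$mode == "linear") {
    s <- sum(ps)
    if (s >= 1) {
      sutox_error(
        "linear-mode summed LOF probability >= 1; use mode = \"poisson\"",
        "sutox_invalid_parameter")
    }
    min(max(1 - s, 0), 1)
  } else {
    min(max(prod(1 - ps), 0), 1)
  }
}

#' Construct-risk report across synthesis methods
#'
#' For each method's per-kb rate, tabulates the per-construct LOF
#' probability, the probability that all constructs are intact, and the
#' fold ratio of each method's per-construct risk to the lowest-rate
#' method.
#'
#' @param rates Named numeric vector of percent-per-kb rates (default
#'   [sutox_rates]).
#' @param constructs List of [construct_spec()]s or numeric lengths in kb.
#' @param mode `"linear"` or `"poisson"`.
#' @return A data.frame with one row per method: the rate, one
#'   `p_lof_<name>` column per construct (percent), `p_all_intact`
#'   (percent), and `risk_ratio_vs_best`.
#' @examples
#' risk_report(constructs = c(4.7, 5.5, 13))
#' @export
risk_report <- function(rates = sutox_rates, constructs,
                        mode = c("linear", "poisson")) {
  mode <- match.arg(mode)
  if (length(rates) == 0 || is.null(names(rates)) || any(rates <= 0)) {
    sutox_error("`rates` must be a non-empty named vector of positive rates",
                "sutox_invalid_input")
  }
  if (length(constructs) == 0) {
    sutox_error("need at least one construct", "sutox_invalid_input")
  }
  if (is.numeric(constructs)) constructs <- as.list(constructs)
  constructs <- lapply(constructs, as_construct)
  rows <- lapply(names(rates), function(m) {
    model <- risk_model(rates[[m]], mode)
    ps <- vapply(constructs, function(cc) p_lof(model, cc), numeric(1))
    row <- data.frame(method = m, rate_percent_per_kb = rates[[m]],
                      stringsAsFactors = FALSE)
    for (i in seq_along(constructs)) {
      row[[paste0("p_lof_", gsub("[^A-Za-z0-9]+", "_",
                                 constructs[[i]]$name))]] <- 100 * ps[i]
    }
    row$p_all_intact <- 100 * p_all_intact(model, constructs)
    row
  })
  out <- do.call(rbind, rows)
  out$risk_ratio_vs_best <- out$rate_percent_per_kb / min(out$rate_percent_per_kb)
  rownames(out) <- NULL
  out
}
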