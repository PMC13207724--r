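# Typed condition helpers: every validation failure carries a class so
# callers (and tests) can distinguish schema, validation, domain and
# degenerate-input errors without string matching.

abort_schema <- function(msg, ...) {
  abort(msg, class = "hasindex_schema_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "hasindex_validation_error", ...)
}

abort_domain <- function(msg, ...) {
  abort(msg, class = "hasindex_domain_error", ...)
}

abort_degenerate <- function(msg, ...) {
  abort(msg, class = "hasindex_degenerate_error", ...)
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic operations in the package draw from sub-streams derived
#' deterministically from one master seed and a character label, so that
#' independent blocks (per group, per variable) do not perturb each other
#' when the simulation is extended.
#'
#' @param master Integer master seed.
#' @param label Character label naming the sub-stream.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
stream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  h <- 0
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647 * 2654435 + h) %% 2147483647)
}

# quantile with the documented linear-interpolation convention (type 7)
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
}

fmt_num <- function(x) format(x, digits = 4)
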