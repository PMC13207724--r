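# The targeted amino-acid panel: 23 serum analytes quantified by LC-MS/MS,
# grouped by functional role. Several analytes carry more than one pathway
# tag (glycine, serine and methionine sit in both the proteinogenic and
# one-carbon families; glutamine is also a muscle-catabolism marker), but
# each analyte appears exactly once in the panel.

PANEL_METABOLITES <- c(
  # proteinogenic, essential
  "histidine", "isoleucine", "leucine", "lysine", "phenylalanine",
  "methionine", "threonine", "tryptophan", "valine",
  # proteinogenic, non-essential / conditionally essential
  "alanine", "arginine", "asparagine", "aspartic-acid", "cystine",
  "glutamine", "glycine", "proline", "tyrosine",
  # one-carbon metabolism / methylation flux
  "sarcosine", "serine", "taurine",
  # muscle catabolism
  "3-methylhistidine", "beta-alanine"
)

PANEL_PATHWAYS <- list(
  `proteinogenic-essential` = c(
    "histidine", "isoleucine", "leucine", "lysine", "phenylalanine",
    "methionine", "threonine", "tryptophan", "valine"
  ),
  `proteinogenic-nonessential` = c(
    "alanine", "arginine", "asparagine", "aspartic-acid", "cystine",
    "glutamine", "glycine", "proline", "serine", "tyrosine"
  ),
  `one-carbon` = c("sarcosine", "glycine", "serine", "methionine", "taurine"),
  `muscle-catabolism` = c("3-methylhistidine", "beta-alanine", "alanine",
                          "glutamine")
)

METABOLITE_ALIASES <- c(
  "3-mh"              = "3-methylhistidine",
  "3 methylhistidine" = "3-methylhistidine",
  "aspartate"         = "aspartic-acid",
  "aspartic acid"     = "aspartic-acid",
  "beta alanine"      = "beta-alanine",
  "b-alanine"         = "beta-alanine"
)

#' Canonicalize metabolite names
#'
#' Lower-cases, trims, converts internal whitespace and underscores to
#' hyphen-free tokens, and resolves common aliases (for example `"3-MH"`
#' to `"3-methylhistidine"`).
#'
#' @param x Character vector of metabolite names.
#' @return Character vector of canonical names.
#' @export
canonical_metabolite <- function(x) {
  out <- tolower(trimws(x))
  out <- gsub("_", " ", out)
  hit <- out %in% names(METABOLITE_ALIASES)
  out[hit] <- METABOLITE_ALIASES[out[hit]]
  out <- gsub(" ", "-", out)
  out
}

#' The 23-analyte amino-acid panel
#'
#' Returns the targeted panel of 23 serum amino-acid analytes with their
#' functional-pathway tags. A metabolite may carry several tags; names are
#' unique.
#'
#' @return A tibble with columns `metabolite` (canonical name) and
#'   `pathways` (list-column of character tags).
#' @export
#' @examples
#' aa_panel()
aa_panel <- function() {
  tags <- lapply(PANEL_METABOLITES, function(m) {
    names(PANEL_PATHWAYS)[vapply(PANEL_PATHWAYS, function(g) m %in% g,
                                 logical(1))]
  })
  tibble(metabolite = PANEL_METABOLITES, pathways = tags)
}

#' Construct an index specification
#'
#' An index specification is an ordered list of (metabolite, sign) terms
#' with equal weighting: every term contributes its z-score with magnitude
#' one and sign +1 or -1.
#'
#' @param metabolites Character vector of metabolite names.
#' @param signs Numeric vector of +1 / -1, one per metabolite.
#' @param name Name of the index.
#' @return A tibble of class `index_spec` with columns `metabolite`, `sign`.
#' @export
index_spec <- function(metabolites, signs, name = "index") {
  metabolites <- canonical_metabolite(metabolites)
  if (length(metabolites) < 1) {
    abort_validation("an index specification needs at least one term")
  }
  if (anyDuplicated(metabolites)) {
    abort_validation("index specification lists a metabolite twice")
  }
  if (length(signs) != length(metabolites) || !all(signs %in% c(-1, 1))) {
    abort_validation("signs must be +1 or -1, one per metabolite")
  }
  out <- tibble(metabolite = metabolites, sign = as.numeric(signs))
  attr(out, "index_name") <- name
  class(out) <- c("index_spec", class(out))
  out
}

#' The HASI-40 index specification
#'
#' The built-in composite index: `z(3-methylhistidine) - z(sarcosine) -
#' z(taurine) - z(serine)`. The proteolysis marker 3-methylhistidine
#' contributes positively; the one-carbon and cytoprotective metabolites
#' (sarcosine, serine, taurine) contribute negatively, so higher values
#' indicate proteolytic dominance with reduced metabolic resilience.
#'
#' @return An [index_spec()] with four terms.
#' @export
#' @examples
#' hasi40_spec()
hasi40_spec <- function() {
  index_spec(
    metabolites = c("3-methylhistidine", "sarcosine", "taurine", "serine"),
    signs = c(1, -1, -1, -1),
    name = "HASI-40"
  )
}

#' Validate an index specification against a panel
#'
#' @param spec An [index_spec()].
#' @param panel A panel tibble as returned by [aa_panel()].
#' @return `spec`, invisibly, if valid; otherwise a validation error.
#' @export
validate_index_spec <- function(spec, panel = aa_panel()) {
  missing <- setdiff(spec$metabolite, panel$metabolite)
  if (length(missing) > 0) {
    abort_validation(paste0(
      "index metabolite(s) not in panel: ", paste(missing, collapse = ", ")
    ))
  }
  invisible(spec)
}
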