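#' Bundled defense-system lookup tables
#'
#' The package ships three small plain-text lookup tables under
#' `inst/extdata/`:
#'
#' * `defense_system_catalog.csv` — canonical system names with their
#'   class (`validated`, `PDC`, `DMS-other`, `HEC`) and mechanism
#'   category, transcribed from the published mechanism table for the
#'   100-strain *P. aeruginosa* diversity panel, with grouped rows
#'   (PD systems, Abi systems) expanded to individual names.
#' * `system_aliases.csv` — lower-cased annotator stems mapped to
#'   canonical display names (PADLOC-DB labels drift between releases,
#'   so this file is meant to be edited).
#' * `subtype_suffix_rules.csv` — regular expressions stripped from the
#'   end of raw names so that subtypes (e.g. CBASS type I/II/III) are
#'   grouped under one canonical system.
#'
#' @param which One of `"catalog"`, `"aliases"`, `"suffix_rules"`.
#' @return A tibble with the requested lookup table.
#' @export
#' @examples
#' head(defense_lookup("catalog"))
defense_lookup <- function(which = c("catalog", "aliases", "suffix_rules")) {
  which <- match.arg(which)
  file <- switch(which,
    catalog      = "defense_system_catalog.csv",
    aliases      = "system_aliases.csv",
    suffix_rules = "subtype_suffix_rules.csv"
  )
  path <- system.file("extdata", file, package = "phagedefense", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# memoised copies; lookups are hit once per call to canonicalize_system()
the <- new.env(parent = emptyenv())

lookup_cached <- function(which) {
  if (is.null(the[[which]])) the[[which]] <- defense_lookup(which)
  the[[which]]
}

norm_stem <- function(x) {
  gsub("[-. ]+", "_", tolower(trimws(x)))
}

strip_subtype_suffix <- function(stem, rules = lookup_cached("suffix_rules")) {
  for (pat in rules$pattern) {
    stem <- sub(paste0("(?i)", pat), "", stem, perl = TRUE)
  }
  stem
}

#' Canonicalize an annotator system name
#'
#' Maps a raw system label as emitted by a defense-system annotator
#' (e.g. `"cbass_type_II"`) to its canonical grouped name (`"CBASS"`) and
#' system class. The mapping is total and deterministic: subtype
#' suffixes are stripped (rules in the bundled suffix table), matching
#' is case-insensitive, names with the PDC prefix are classed `PDC` and
#' HEC candidates `HEC`, the `DMS-other` catch-all is preserved, and
#' unknown names pass through unchanged with class `validated` (a notice
#' is emitted once per unknown name unless `quiet = TRUE`).
#'
#' @param raw_system Character vector of raw system labels.
#' @param quiet Suppress the notice for names absent from the bundled
#'   alias table.
#' @return A tibble with columns `raw_system`, `system`, `system_class`.
#' @export
#' @examples
#' canonicalize_system(c("cbass_type_II", "zorya_type_I", "PDC-S06", "DMS_other"))
canonicalize_system <- function(raw_system, quiet = FALSE) {
  stopifnot(is.character(raw_system), all(nzchar(trimws(raw_system))))
  stem <- norm_stem(raw_system)

  system <- character(length(stem))
  class <- character(length(stem))

  is_pdc <- startsWith(stem, "pdc_") | startsWith(stem, "pdcs") | stem == "pdc"
  is_hec <- startsWith(stem, "hec_") | stem == "hec"
  is_dms <- stem %in% c("dms_other", "dms")

  # PDC / HEC identifiers keep their own name, upper-cased with hyphens
  system[is_pdc] <- toupper(gsub("_", "-", stem[is_pdc]))
  class[is_pdc] <- "PDC"
  system[is_hec] <- toupper(gsub("_", "-", stem[is_hec]))
  class[is_hec] <- "HEC"
  system[is_dms] <- "DMS-other"
  class[is_dms] <- "DMS-other"

  rest <- !(is_pdc | is_hec | is_dms)
  if (any(rest)) {
    aliases <- lookup_cached("aliases")
    stripped <- strip_subtype_suffix(stem[rest])
    hit <- match(stripped, aliases$stem)
    canon <- aliases$canonical[hit]
    unknown <- is.na(hit)
    if (any(unknown)) {
      # pass the suffix-stripped original through, preserving its case
      raw_stripped <- strip_subtype_suffix(trimws(raw_system[rest])[unknown],
        rules = lookup_cached("suffix_rules")
      )
      canon[unknown] <- raw_stripped
      if (!quiet) {
        rlang::inform(paste0(
          "System name(s) not in the bundled catalog, passed through: ",
          paste(unique(raw_stripped), collapse = ", ")
        ))
      }
    }
    system[rest] <- canon
    class[rest] <- "validated"
  }

  tibble::tibble(raw_system = raw_system, system = system, system_class = class)
}

#' Mechanism category of a canonical defense system
#'
#' Looks the canonical system name up in the bundled mechanism table.
#' Categories are `nuclease_degradation`, `abortive_infection`,
#' `nucleic_acid_modification`, `protein_modification`, `other`, and
#' `unknown` for systems (including all PDCs) without a validated or
#' predicted mechanism.
#'
#' @param system Character vector of canonical system names (as returned
#'   by [canonicalize_system()]).
#' @return Character vector of mechanism categories.
#' @export
#' @examples
#' mechanism_category(c("Gabija", "CBASS", "PDC-S02"))
mechanism_category <- function(system) {
  stopifnot(is.character(system))
  catalog <- lookup_cached("catalog")
  out <- catalog$mechanism_category[match(system, catalog$system)]
  out[startsWith(system, "HEC-")] <- "unknown"
  out[is.na(out)] <- "unknown"
  out
}

#' @rdname mechanism_category
#' @export
mechanism_categories <- function() {
  c(
    "nuclease_degradation", "abortive_infection",
    "nucleic_acid_modification", "protein_modification",
    "other", "unknown"
  )
}
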