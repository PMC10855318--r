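#' Read a PADLOC-dialect defense-system annotation table
#'
#' Parses a tabular annotation file with one row per detected system
#' locus per genome into a canonical defense-call table. The default
#' column mapping follows the PADLOC CSV dialect (`system` for the
#' system label, `seqid` for the genome/strain identifier) but both can
#' be remapped for other dialects or web-server exports.
#'
#' Each row becomes one call; `locus_index` numbers multiple loci of the
#' same canonical system within a strain in input row order, starting
#' at 0.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the
#'   header line unless `delim` is given).
#' @param column_map Named character vector mapping the roles `strain`
#'   and `system` to column names in the file.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @param quiet Passed to [canonicalize_system()].
#' @return A tibble of defense calls with columns `strain_id`,
#'   `raw_system`, `system`, `system_class`, `mechanism_category`,
#'   `locus_index`.
#' @export
parse_padloc_table <- function(path,
                               column_map = c(strain = "seqid", system = "system"),
                               delim = NULL,
                               quiet = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Annotation file not found: ", path), class = "phagedefense_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (length(header) && grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0L) {
    rlang::warn(paste0("Annotation file has no rows: ", path))
    return(empty_calls())
  }
  for (role in c("strain", "system")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      rlang::abort(
        paste0(
          "Mapped column for role '", role, "' (", col %||% "<unset>",
          ") not present in ", path
        ),
        class = "phagedefense_config_error"
      )
    }
  }
  as_defense_calls(
    strain_id = raw[[column_map[["strain"]]]],
    raw_system = raw[[column_map[["system"]]]],
    quiet = quiet
  )
}

empty_calls <- function() {
  tibble::tibble(
    strain_id = character(), raw_system = character(),
    system = character(), system_class = character(),
    mechanism_category = character(), locus_index = integer()
  )
}

#' Build a canonical defense-call table from strain and system labels
#'
#' Lower-level constructor behind [parse_padloc_table()]: canonicalizes
#' raw system names, attaches mechanism categories and assigns
#' `locus_index` in input order within each (strain, system) pair.
#'
#' @param strain_id,raw_system Equal-length character vectors.
#' @inheritParams parse_padloc_table
#' @return A defense-call tibble (see [parse_padloc_table()]).
#' @export
as_defense_calls <- function(strain_id, raw_system, quiet = FALSE) {
  stopifnot(length(strain_id) == length(raw_system))
  if (length(strain_id) == 0L) return(empty_calls())
  strain_id <- as.character(strain_id)
  if (any(is.na(strain_id) | !nzchar(trimws(strain_id)))) {
    rlang::abort("strain_id must be non-empty", class = "phagedefense_input_error")
  }
  canon <- canonicalize_system(as.character(raw_system), quiet = quiet)
  calls <- tibble::tibble(
    strain_id = trimws(strain_id),
    raw_system = canon$raw_system,
    system = canon$system,
    system_class = canon$system_class,
    mechanism_category = mechanism_category(canon$system)
  )
  calls |>
    dplyr::group_by(.data$strain_id, .data$system) |>
    dplyr::mutate(locus_index = seq_len(dplyr::n()) - 1L) |>
    dplyr::ungroup()
}

#' Tally defense calls per strain and per system
#'
#' Aggregates a canonical defense-call table into per-strain profiles
#' and per-system occupancy counts (the numbers of strains encoding at
#' least one locus of each system).
#'
#' The per-strain `system_count` honours the active counting policy:
#' `count = "loci"` counts every annotated locus (the default — the
#' annotator reports per-locus hits and per-strain totals above any
#' plausible number of distinct types occur in real panels), while
#' `count = "distinct"` counts distinct canonical systems.
#' `include_classes` controls which system classes enter the per-strain
#' counts; by default validated systems, phage-defense candidates (PDC),
#' the DMS-other catch-all and HEC candidates are all included.
#' `distinct_system_count` is always the number of distinct canonical
#' names among the included classes.
#'
#' @param calls A defense-call tibble from [parse_padloc_table()] or
#'   [as_defense_calls()].
#' @param count Counting policy, `"loci"` or `"distinct"`.
#' @param include_classes System classes included in per-strain counts.
#' @param strains Optional character vector of strain identifiers that
#'   must appear in the per-strain output even with zero calls (strains
#'   in which no system was detected).
#' @return A list with elements `per_strain` (tibble: `strain_id`,
#'   `system_count`, `distinct_system_count`) and `per_system` (tibble:
#'   `system`, `system_class`, `mechanism_category`, `n_strains`),
#'   sorted descending by `n_strains` with ties by name.
#' @export
tally_defense <- function(calls,
                          count = c("loci", "distinct"),
                          include_classes = c("validated", "PDC", "DMS-other", "HEC"),
                          strains = NULL) {
  count <- match.arg(count)
  counted <- calls[calls$system_class %in% include_classes, , drop = FALSE]

  per_strain <- counted |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      distinct_system_count = dplyr::n_distinct(.data$system),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      system_count = if (count == "loci") .data$n_loci else .data$distinct_system_count
    ) |>
    dplyr::select("strain_id", "system_count", "distinct_system_count")

  if (!is.null(strains)) {
    missing <- setdiff(strains, per_strain$strain_id)
    if (length(missing)) {
      per_strain <- dplyr::bind_rows(
        per_strain,
        tibble::tibble(
          strain_id = missing,
          system_count = 0L, distinct_system_count = 0L
        )
      )
    }
  }
  per_strain <- dplyr::arrange(per_strain, .data$strain_id)

  per_system <- calls |>
    dplyr::distinct(.data$strain_id, .data$system, .data$system_class, .data$mechanism_category) |>
    dplyr::count(.data$system, .data$system_class, .data$mechanism_category, name = "n_strains") |>
    dplyr::arrange(dplyr::desc(.data$n_strains), .data$system)

  list(per_strain = per_strain, per_system = per_system)
}
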