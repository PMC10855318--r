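#' Construct a strains-by-phages interaction matrix
#'
#' The interaction matrix is the package's container for plaque-assay
#' host-range data: one cell per (strain, phage) pair with an explicit
#' tested/untested state, a binary plaque call for tested cells, and an
#' optional titer in PFU/mL. "Lysis from without" (adsorption-driven
#' lysis with no productive replication) is scored negative.
#'
#' Invariants enforced: at most one cell per pair; `plaque` defined iff
#' `tested`; a positive titer implies a positive plaque call; negative
#' cells carry titer 0; every strain has at least one tested cell.
#'
#' @param cells Tibble with columns `strain_id`, `phage_id`, `tested`
#'   (logical), `plaque` (`"positive"`/`"negative"`/`NA`), `titer`
#'   (PFU/mL, `NA` when unknown or untested).
#' @param strains,phages Optional metadata tibbles keyed by `strain_id`
#'   / `phage_id`; minimal ones are derived from `cells` when omitted.
#'   Strain metadata may carry `sequence_type`, `serotype` and
#'   `prophage_region_count`; phage metadata `genus` and `morphotype`.
#' @return An object of class `interaction_matrix`: a list with tibbles
#'   `cells`, `strains`, `phages`.
#' @export
interaction_matrix <- function(cells, strains = NULL, phages = NULL) {
  req <- c("strain_id", "phage_id", "tested", "plaque", "titer")
  if (!all(req %in% names(cells))) {
    rlang::abort(
      paste0("cells must have columns: ", paste(req, collapse = ", ")),
      class = "phagedefense_input_error"
    )
  }
  cells <- tibble::as_tibble(cells)
  cells$strain_id <- as.character(cells$strain_id)
  cells$phage_id <- as.character(cells$phage_id)
  cells$tested <- as.logical(cells$tested)
  cells$titer <- as.numeric(cells$titer)

  if (anyDuplicated(cells[c("strain_id", "phage_id")])) {
    rlang::abort("duplicate (strain, phage) cells", class = "phagedefense_input_error")
  }
  bad_plaque <- xor(cells$tested, !is.na(cells$plaque))
  if (any(bad_plaque)) {
    rlang::abort("plaque call must be present exactly for tested cells",
      class = "phagedefense_input_error"
    )
  }
  if (any(!is.na(cells$titer) & cells$titer < 0)) {
    rlang::abort("titers must be non-negative", class = "phagedefense_input_error")
  }
  pos_titer <- !is.na(cells$titer) & cells$titer > 0
  if (any(pos_titer & cells$plaque != "positive")) {
    rlang::abort("a positive titer implies a positive plaque call",
      class = "phagedefense_input_error"
    )
  }
  cells$titer[which(cells$plaque == "negative")] <- 0

  if (is.null(strains)) {
    strains <- tibble::tibble(strain_id = sort(unique(cells$strain_id)))
  }
  if (is.null(phages)) {
    phages <- tibble::tibble(phage_id = sort(unique(cells$phage_id)))
  }
  strains <- tibble::as_tibble(strains)
  phages <- tibble::as_tibble(phages)
  if (anyDuplicated(strains$strain_id) || anyDuplicated(phages$phage_id)) {
    rlang::abort("strain_id / phage_id metadata keys must be unique",
      class = "phagedefense_input_error"
    )
  }
  tested_per_strain <- tapply(cells$tested, cells$strain_id, any)
  untested <- setdiff(strains$strain_id, names(tested_per_strain)[tested_per_strain %in% TRUE])
  if (length(untested)) {
    rlang::abort(
      paste0(
        "every strain needs at least one tested cell; missing: ",
        paste(head(untested, 5), collapse = ", ")
      ),
      class = "phagedefense_input_error"
    )
  }
  structure(
    list(cells = cells, strains = strains, phages = phages),
    class = "interaction_matrix"
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  n_tested <- sum(x$cells$tested)
  n_pos <- sum(x$cells$plaque == "positive", na.rm = TRUE)
  cat(sprintf(
    "<interaction_matrix> %d strains x %d phages; %d tested cells (%.1f%% plaque-positive)\n",
    nrow(x$strains), nrow(x$phages), n_tested,
    if (n_tested) 100 * n_pos / n_tested else NA_real_
  ))
  invisible(x)
}

#' Read a host-range matrix from CSV
#'
#' Two dialects are accepted. The wide (canonical) layout has one row
#' per strain, a `strain_id` first column and one column per phage,
#' values being titers in PFU/mL: blank cells are untested, `0` is a
#' negative call, and the token `LFW` marks lysis from without (scored
#' negative with titer 0). The long layout has columns `strain_id`,
#' `phage_id`, `plaque` (`positive`/`negative`/`LFW`, blank or `NT` for
#' untested) and optional `titer`.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param strains,phages Optional metadata passed to
#'   [interaction_matrix()].
#' @return An [interaction_matrix()].
#' @export
read_hostrange <- function(path, layout = c("wide", "long"),
                           strains = NULL, phages = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    rlang::abort(paste0("Host-range file not found: ", path), class = "phagedefense_io_error")
  }
  raw <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    rlang::abort(paste0("Host-range file is empty: ", path), class = "phagedefense_io_error")
  }
  if (layout == "wide") {
    names(raw)[1] <- "strain_id"
    long <- tidyr::pivot_longer(raw, -"strain_id",
      names_to = "phage_id", values_to = "value"
    )
    value <- trimws(long$value %||% "")
    is_lfw <- !is.na(value) & toupper(value) == "LFW"
    titer <- suppressWarnings(as.numeric(value))
    titer[is_lfw] <- 0
    tested <- !is.na(value) & nzchar(value)
    bad <- tested & !is_lfw & is.na(titer)
    if (any(bad)) {
      rlang::abort(
        paste0(
          "non-numeric titer values: ",
          paste(head(unique(value[bad]), 5), collapse = ", ")
        ),
        class = "phagedefense_io_error"
      )
    }
    cells <- tibble::tibble(
      strain_id = long$strain_id,
      phage_id = long$phage_id,
      tested = tested,
      plaque = dplyr::case_when(
        !tested ~ NA_character_,
        titer > 0 ~ "positive",
        TRUE ~ "negative"
      ),
      titer = ifelse(tested, titer, NA_real_)
    )
  } else {
    need <- c("strain_id", "phage_id", "plaque")
    if (!all(need %in% names(raw))) {
      rlang::abort(paste0(
        "long layout needs columns: ", paste(need, collapse = ", ")
      ), class = "phagedefense_io_error")
    }
    call <- toupper(trimws(raw$plaque %||% ""))
    tested <- !is.na(call) & nzchar(call) & call != "NT"
    plaque <- dplyr::case_when(
      !tested ~ NA_character_,
      call %in% c("POSITIVE", "POS", "+", "1") ~ "positive",
      call %in% c("NEGATIVE", "NEG", "-", "0", "LFW") ~ "negative",
      TRUE ~ "bad"
    )
    if (any(plaque == "bad", na.rm = TRUE)) {
      rlang::abort(
        paste0(
          "unrecognized plaque calls: ",
          paste(head(unique(call[which(plaque == "bad")]), 5), collapse = ", ")
        ),
        class = "phagedefense_io_error"
      )
    }
    titer <- if ("titer" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$titer))
    } else {
      NA_real_
    }
    titer <- ifelse(tested & plaque == "negative", 0, titer)
    titer[!tested] <- NA_real_
    cells <- tibble::tibble(
      strain_id = raw$strain_id, phage_id = raw$phage_id,
      tested = tested, plaque = plaque, titer = titer
    )
  }
  interaction_matrix(cells, strains = strains, phages = phages)
}

tested_cells <- function(matrix, strain_id = NULL) {
  cells <- matrix$cells[matrix$cells$tested, , drop = FALSE]
  if (!is.null(strain_id)) {
    if (!strain_id %in% matrix$strains$strain_id &&
      !strain_id %in% matrix$cells$strain_id) {
      rlang::abort(paste0("unknown strain: ", strain_id), class = "phagedefense_lookup_error")
    }
    cells <- cells[cells$strain_id == strain_id, , drop = FALSE]
    if (nrow(cells) == 0L) {
      rlang::abort(paste0("no tested cells for strain ", strain_id),
        class = "phagedefense_domain_error"
      )
    }
  }
  cells
}

#' Per-strain phage susceptibility percentage
#'
#' The fraction (x100) of tested phages that form plaques on a strain.
#' Untested cells are excluded from numerator and denominator, so a
#' strain assayed against a reduced phage subset is scored over the
#' phages it was actually tested against.
#'
#' @param matrix An [interaction_matrix()].
#' @param strain_id Single strain identifier.
#' @return Susceptibility percentage in \[0, 100\].
#' @export
susceptibility_percent <- function(matrix, strain_id) {
  cells <- tested_cells(matrix, strain_id)
  100 * sum(cells$plaque == "positive") / nrow(cells)
}

#' Per-strain susceptibility summary table
#'
#' @param matrix An [interaction_matrix()].
#' @return Tibble with `strain_id`, `n_tested`, `n_positive`,
#'   `susceptibility_pct`, one row per strain, sorted by `strain_id`.
#' @export
susceptibility_table <- function(matrix) {
  tested_cells(matrix) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_positive = sum(.data$plaque == "positive"),
      .groups = "drop"
    ) |>
    dplyr::mutate(susceptibility_pct = 100 * .data$n_positive / .data$n_tested) |>
    dplyr::arrange(.data$strain_id)
}

#' Efficiency of plating (EOP) for every tested cell
#'
#' Each phage's titer is normalized to the highest titer that phage
#' attains on any strain in the panel; plaque-negative or nonproductive
#' cells have an EOP of 0. A phage with no positive cell anywhere has
#' all EOPs 0 (a warning is emitted; no division by zero occurs).
#' Untested cells carry no EOP.
#'
#' @param matrix An [interaction_matrix()].
#' @return Tibble `strain_id`, `phage_id`, `eop` over tested cells.
#' @export
eop_matrix <- function(matrix) {
  cells <- tested_cells(matrix)
  if (any(cells$plaque == "positive" & is.na(cells$titer))) {
    rlang::abort("positive cells need titers to compute EOP",
      class = "phagedefense_domain_error"
    )
  }
  by_phage <- cells |>
    dplyr::group_by(.data$phage_id) |>
    dplyr::mutate(max_titer = max(.data$titer, na.rm = TRUE)) |>
    dplyr::ungroup()
  dead <- unique(by_phage$phage_id[by_phage$max_titer <= 0])
  if (length(dead)) {
    rlang::warn(paste0(
      "phage(s) with no positive titer on any strain, EOP set to 0: ",
      paste(head(dead, 5), collapse = ", ")
    ))
  }
  by_phage |>
    dplyr::mutate(
      eop = ifelse(.data$max_titer > 0, .data$titer / .data$max_titer, 0)
    ) |>
    dplyr::select("strain_id", "phage_id", "eop")
}

#' Per-strain average efficiency of plating
#'
#' Mean EOP over the cells tested for each strain (the denominator is
#' the number of phages tested on that strain, not the panel size).
#'
#' @param matrix An [interaction_matrix()].
#' @param strain_id Optional single strain; when omitted a per-strain
#'   table is returned.
#' @return A single value in \[0, 1\], or a tibble `strain_id`,
#'   `n_tested`, `avg_eop`.
#' @export
average_eop <- function(matrix, strain_id = NULL) {
  eop <- eop_matrix(matrix)
  if (!is.null(strain_id)) {
    tested_cells(matrix, strain_id) # validates the strain
    return(mean(eop$eop[eop$strain_id == strain_id]))
  }
  eop |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      avg_eop = mean(.data$eop),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$strain_id)
}
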