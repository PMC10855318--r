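#' End-to-end analysis pipeline
#'
#' Runs the full analysis on a defense-call annotation table plus a
#' host-range matrix (and optional strain metadata): canonical calls,
#' per-system and per-strain tallies, susceptibility, EOP, the
#' count-susceptibility and count-EOP correlations, the rank-based
#' susceptibility groups, per-system prevalence, group means and
#' metadata summaries. All tables are written as CSV with fixed decimal
#' formatting and stable sort orders, so identical inputs yield
#' byte-identical outputs, together with a machine-readable run
#' manifest (configuration echo, package version, input checksums).
#'
#' @param calls_path PADLOC-dialect annotation table (see
#'   [parse_padloc_table()]).
#' @param hostrange_path Host-range CSV (see [read_hostrange()]).
#' @param outdir Output directory, created if needed.
#' @param metadata_path Optional strain-metadata TSV/CSV with
#'   `strain_id` and any of `sequence_type`, `serotype`,
#'   `prophage_region_count`.
#' @param layout Host-range layout, `"wide"` or `"long"`.
#' @param column_map Column mapping for the annotation table.
#' @param count,include_classes Counting policy for [tally_defense()].
#' @param k_fraction Extreme-group fraction for [assign_groups()].
#' @param threshold,min_encoding Prevalence parameters for
#'   [prevalence()].
#' @param all_systems Keep systems below `min_encoding` in the
#'   prevalence table (they are always flagged `low_n`); by default the
#'   emitted table is restricted to systems at or above `min_encoding`.
#' @param quiet Suppress canonicalization notices.
#' @return Invisibly, a list with every computed table and the manifest.
#' @export
run_pipeline <- function(calls_path, hostrange_path, outdir,
                         metadata_path = NULL,
                         layout = c("wide", "long"),
                         column_map = c(strain = "seqid", system = "system"),
                         count = c("loci", "distinct"),
                         include_classes = c("validated", "PDC", "DMS-other", "HEC"),
                         k_fraction = 0.10,
                         threshold = 52.5,
                         min_encoding = 15,
                         all_systems = FALSE,
                         quiet = TRUE) {
  layout <- match.arg(layout)
  count <- match.arg(count)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("[", name, "] ", conditionMessage(e)),
        class = "phagedefense_stage_error", parent = e
      )
    })
  }

  calls <- stage("ingest", parse_padloc_table(calls_path, column_map = column_map, quiet = quiet))
  strains_meta <- NULL
  if (!is.null(metadata_path)) {
    strains_meta <- stage("ingest", read_metadata(metadata_path))
  }
  matrix <- stage("ingest", read_hostrange(hostrange_path, layout = layout, strains = strains_meta))

  panel_strains <- matrix$strains$strain_id
  tallies <- stage("tally", tally_defense(calls,
    count = count,
    include_classes = include_classes, strains = panel_strains
  ))
  susc <- stage("score", susceptibility_table(matrix))
  avg_eop <- stage("score", average_eop(matrix))
  eop <- stage("score", eop_matrix(matrix))

  joined <- dplyr::inner_join(tallies$per_strain, susc, by = "strain_id") |>
    dplyr::inner_join(avg_eop[c("strain_id", "avg_eop")], by = "strain_id")
  cor_susc <- stage("associate", pearson_cor(joined$system_count, joined$susceptibility_pct))
  cor_eop <- stage("associate", pearson_cor(joined$system_count, joined$avg_eop))
  groups <- stage("associate", assign_groups(susc, k_fraction = k_fraction))
  prev <- stage("associate", prevalence(calls, groups,
    threshold = threshold,
    min_encoding = min_encoding
  ))
  gmeans <- stage("associate", group_means(tallies$per_strain, groups))

  meta_serotype <- NULL
  meta_prophage <- NULL
  if (!is.null(strains_meta) && "serotype" %in% names(strains_meta)) {
    meta_serotype <- stage(
      "associate",
      metadata_summary(strains_meta, susc, tallies$per_strain, by = "serotype")
    )
  }
  if (!is.null(strains_meta) && "prophage_region_count" %in% names(strains_meta)) {
    meta_prophage <- stage(
      "associate",
      metadata_summary(strains_meta, susc, tallies$per_strain, by = "prophage")
    )
  }

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, file) {
    readr::write_csv(x, file.path(outdir, file), progress = FALSE)
  }
  stage("report", {
    w(calls, "canonical_calls.csv")
    w(tallies$per_system, "system_tally.csv")
    w(tallies$per_strain, "strain_counts.csv")
    w(fmt_cols(susc, susceptibility_pct = 1), "susceptibility.csv")
    w(fmt_cols(eop, eop = 4), "eop_matrix.csv")
    w(fmt_cols(avg_eop, avg_eop = 4), "average_eop.csv")
    w(
      dplyr::mutate(groups$assignment,
        susceptibility_pct = fmt_num(.data$susceptibility_pct, 1)
      ),
      "groups.csv"
    )
    prev_out <- if (all_systems) prev else prev[!prev$low_n, , drop = FALSE]
    w(fmt_cols(prev_out, percent_resistant = 1), "prevalence.csv")
    w(fmt_cols(gmeans, mean_system_count = 1), "group_means.csv")
    if (!is.null(meta_serotype)) {
      w(
        fmt_cols(meta_serotype, mean_susceptibility_pct = 1, mean_system_count = 1),
        "metadata_serotype.csv"
      )
    }
    if (!is.null(meta_prophage)) w(meta_prophage, "metadata_prophage.csv")
    jsonlite::write_json(
      list(
        count_vs_susceptibility = unclass(cor_susc),
        count_vs_avg_eop = unclass(cor_eop)
      ),
      file.path(outdir, "correlation.json"),
      auto_unbox = TRUE, digits = NA
    )
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("phagedefense")),
    config = list(
      calls_path = calls_path, hostrange_path = hostrange_path,
      metadata_path = metadata_path, layout = layout, count = count,
      include_classes = include_classes, k_fraction = k_fraction,
      threshold = threshold, min_encoding = min_encoding,
      all_systems = all_systems
    ),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(
      calls_path, hostrange_path, metadata_path
    ))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    calls = calls, tallies = tallies, susceptibility = susc,
    eop = eop, average_eop = avg_eop,
    correlation = list(count_vs_susceptibility = cor_susc, count_vs_avg_eop = cor_eop),
    groups = groups, prevalence = prev, group_means = gmeans,
    metadata_serotype = meta_serotype, metadata_prophage = meta_prophage,
    manifest = manifest
  ))
}

read_metadata <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Metadata file not found: ", path), class = "phagedefense_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (length(header) && grepl("\t", header)) "\t" else ","
  meta <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  if (!"strain_id" %in% names(meta)) {
    rlang::abort(paste0("metadata needs a strain_id column: ", path),
      class = "phagedefense_config_error"
    )
  }
  meta
}

fmt_num <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), x)
}

fmt_cols <- function(df, ...) {
  digits <- list(...)
  for (col in names(digits)) {
    df[[col]] <- fmt_num(df[[col]], digits[[col]])
  }
  df
}
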