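#' Pearson correlation with least-squares line
#'
#' Product-moment correlation between two numeric vectors with a
#' two-sided p-value from the t-distribution on n - 2 degrees of
#' freedom (t = r * sqrt((n - 2) / (1 - r^2))), plus the ordinary
#' least-squares slope and intercept of y on x for plotting. This is
#' the "XY correlation" reported by common desktop statistics tools.
#'
#' @param x,y Numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @return A list of class `correlation_result` with elements `n`, `r`,
#'   `r_squared`, `p_value`, `slope`, `intercept`.
#' @export
#' @examples
#' pearson_cor(1:10, (1:10) + rnorm(10))
pearson_cor <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    rlang::abort("x and y must have equal length", class = "phagedefense_input_error")
  }
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    rlang::abort("need at least 3 paired observations", class = "phagedefense_domain_error")
  }
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  dy <- y - my
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    rlang::abort("zero variance in x or y; correlation undefined",
      class = "phagedefense_degenerate_error"
    )
  }
  sxy <- sum(dx * dy)
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(
    list(
      n = n, r = r, r_squared = r^2, p_value = p,
      slope = sxy / sxx, intercept = my - (sxy / sxx) * mx
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> n = %d, r = %.4f, r^2 = %.4f, p = %.4g\n  y = %.4g + %.4g x\n",
    x$n, x$r, x$r_squared, x$p_value, x$intercept, x$slope
  ))
  invisible(x)
}

#' Rank-based susceptibility grouping of strains
#'
#' Partitions strains into four susceptibility groups by rank: the
#' panel is split at the median into a resistant half (lower
#' susceptibility) and a susceptible half, and within each half the
#' `k = round(k_fraction * n)` most extreme strains form the
#' "most resistant" / "most susceptible" groups; the remainder are the
#' intermediate groups. For n = 100 and the default `k_fraction = 0.10`
#' the group sizes are 10/40/40/10. Ties in susceptibility are broken
#' by strain identifier (lexicographic), making the partition
#' deterministic; with odd n the resistant half receives the extra
#' strain (a notice is emitted).
#'
#' @param susceptibility Named numeric vector (names are strain
#'   identifiers) of susceptibility percentages, or a tibble with
#'   columns `strain_id` and `susceptibility_pct`.
#' @param k_fraction Fraction of the panel in each extreme group.
#' @return A list of class `susceptibility_groups`: `assignment`
#'   (tibble `strain_id`, `susceptibility_pct`, `group`), `k_extreme`,
#'   and `implied_thresholds` (the realized susceptibility cut points
#'   between consecutive groups, for comparison with published
#'   threshold descriptions).
#' @export
assign_groups <- function(susceptibility, k_fraction = 0.10) {
  if (is.data.frame(susceptibility)) {
    stopifnot(all(c("strain_id", "susceptibility_pct") %in% names(susceptibility)))
    s <- susceptibility$susceptibility_pct
    names(s) <- susceptibility$strain_id
    susceptibility <- s
  }
  n <- length(susceptibility)
  if (n < 4) {
    rlang::abort("need at least 4 strains to form groups", class = "phagedefense_domain_error")
  }
  if (is.null(names(susceptibility)) || anyDuplicated(names(susceptibility))) {
    rlang::abort("susceptibility must be uniquely named by strain",
      class = "phagedefense_input_error"
    )
  }
  ord <- order(susceptibility, names(susceptibility), method = "radix")
  s <- susceptibility[ord]
  n_resistant <- ceiling(n / 2)
  if (n %% 2 == 1) {
    rlang::inform("odd number of strains: resistant half receives the extra strain")
  }
  k <- round(k_fraction * n)
  if (k < 1 || 2 * k > n) {
    rlang::abort("k_fraction yields an impossible extreme-group size",
      class = "phagedefense_domain_error"
    )
  }
  group <- character(n)
  group[seq_len(k)] <- "most_resistant"
  group[(k + 1):n_resistant] <- "intermediate_resistant"
  group[(n_resistant + 1):(n - k)] <- "intermediate_susceptible"
  group[(n - k + 1):n] <- "most_susceptible"

  assignment <- tibble::tibble(
    strain_id = names(s),
    susceptibility_pct = unname(s),
    group = factor(group, levels = susceptibility_group_levels())
  )
  structure(
    list(
      assignment = assignment,
      k_extreme = k,
      implied_thresholds = c(
        most_resistant_max = unname(s[k]),
        median_split = unname(s[n_resistant]),
        intermediate_susceptible_max = unname(s[n - k])
      )
    ),
    class = "susceptibility_groups"
  )
}

#' @rdname assign_groups
#' @export
susceptibility_group_levels <- function() {
  c(
    "most_resistant", "intermediate_resistant",
    "intermediate_susceptible", "most_susceptible"
  )
}

#' @export
print.susceptibility_groups <- function(x, ...) {
  sizes <- table(x$assignment$group)
  cat(
    "<susceptibility_groups> sizes:",
    paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n"
  )
  invisible(x)
}

resistant_half <- function(groups) {
  a <- groups$assignment
  a$strain_id[a$group %in% c("most_resistant", "intermediate_resistant")]
}

#' Prevalence of a defense system in the resistant half of the panel
#'
#' For each system, the share of its carrier strains that fall in the
#' resistant half (most resistant + intermediate resistant groups). A
#' system is classified `resistant_prevalent` when that share is at
#' least `threshold` percent, `susceptible_prevalent` when the
#' complementary share is, and `neither` otherwise. Systems carried by
#' fewer than `min_encoding` strains are still classified but flagged
#' `low_n`.
#'
#' @param calls Defense-call tibble (see [parse_padloc_table()]).
#' @param groups A [assign_groups()] result covering the carrier strains.
#' @param system Optional single canonical system name; when omitted all
#'   systems in `calls` are classified.
#' @param threshold Prevalence threshold in percent (default 52.5).
#' @param min_encoding Minimum carrier count below which results are
#'   flagged `low_n` (default 15).
#' @return Tibble `system`, `system_class`, `n_encoding`,
#'   `n_resistant_half`, `percent_resistant`, `classification`, `low_n`,
#'   sorted descending by `n_encoding` then by name.
#' @export
prevalence <- function(calls, groups, system = NULL,
                       threshold = 52.5, min_encoding = 15) {
  stopifnot(inherits(groups, "susceptibility_groups"))
  if (!is.null(system)) {
    calls <- calls[calls$system %in% system, , drop = FALSE]
    if (nrow(calls) == 0L) {
      rlang::abort(paste0("system not encoded by any strain: ", system),
        class = "phagedefense_domain_error"
      )
    }
  }
  res_half <- resistant_half(groups)
  known <- groups$assignment$strain_id
  carriers <- dplyr::distinct(calls, .data$system, .data$system_class, .data$strain_id)
  missing <- setdiff(carriers$strain_id, known)
  if (length(missing)) {
    rlang::abort(
      paste0(
        "carrier strain(s) missing from the group assignment: ",
        paste(head(missing, 5), collapse = ", ")
      ),
      class = "phagedefense_input_error"
    )
  }
  carriers |>
    dplyr::group_by(.data$system, .data$system_class) |>
    dplyr::summarise(
      n_encoding = dplyr::n(),
      n_resistant_half = sum(.data$strain_id %in% res_half),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent_resistant = 100 * .data$n_resistant_half / .data$n_encoding,
      classification = dplyr::case_when(
        .data$percent_resistant >= threshold ~ "resistant_prevalent",
        100 - .data$percent_resistant >= threshold ~ "susceptible_prevalent",
        TRUE ~ "neither"
      ),
      low_n = .data$n_encoding < min_encoding
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_encoding), .data$system)
}

#' Mean defense-system count per susceptibility group
#'
#' @param per_strain Per-strain profile tibble (`strain_id`,
#'   `system_count`) from [tally_defense()].
#' @param groups A [assign_groups()] result.
#' @return Tibble `group`, `n_strains`, `mean_system_count` with one row
#'   per group in resistance order. Empty groups yield `NaN` with a
#'   warning.
#' @export
group_means <- function(per_strain, groups) {
  stopifnot(inherits(groups, "susceptibility_groups"))
  a <- groups$assignment
  missing <- setdiff(a$strain_id, per_strain$strain_id)
  if (length(missing)) {
    rlang::abort(
      paste0(
        "profiles missing for strain(s): ",
        paste(head(missing, 5), collapse = ", ")
      ),
      class = "phagedefense_input_error"
    )
  }
  out <- a |>
    dplyr::left_join(per_strain, by = "strain_id") |>
    dplyr::group_by(.data$group, .drop = FALSE) |>
    dplyr::summarise(
      n_strains = dplyr::n(),
      mean_system_count = mean(.data$system_count),
      .groups = "drop"
    )
  if (any(out$n_strains == 0L)) {
    rlang::warn("empty susceptibility group; its mean is undefined")
  }
  out
}

#' Metadata summaries: serotype breakdown or prophage correlations
#'
#' With `by = "serotype"`, groups strains by O-antigen serotype and
#' reports per-serotype size, mean susceptibility and mean system
#' count. With `by = "prophage"`, correlates the prophage region count
#' with susceptibility and with system count via [pearson_cor()];
#' degenerate inputs (e.g. identical prophage counts) are surfaced as
#' not-computable rows rather than errors.
#'
#' @param strains Strain metadata tibble with `strain_id` and the
#'   requested column (`serotype` or `prophage_region_count`).
#' @param susceptibility Tibble `strain_id`, `susceptibility_pct` (from
#'   [susceptibility_table()]).
#' @param per_strain Per-strain profiles (`strain_id`, `system_count`).
#' @param by `"serotype"` or `"prophage"`.
#' @return For serotype: a tibble `serotype`, `n`,
#'   `mean_susceptibility_pct`, `mean_system_count`. For prophage: a
#'   tibble `response`, `n`, `r`, `r_squared`, `p_value`, `computable`.
#' @export
metadata_summary <- function(strains, susceptibility, per_strain,
                             by = c("serotype", "prophage")) {
  by <- match.arg(by)
  col <- if (by == "serotype") "serotype" else "prophage_region_count"
  if (!col %in% names(strains)) {
    rlang::abort(paste0("metadata column missing: ", col),
      class = "phagedefense_config_error"
    )
  }
  merged <- strains |>
    dplyr::inner_join(susceptibility, by = "strain_id") |>
    dplyr::inner_join(per_strain, by = "strain_id")
  present <- merged[!is.na(merged[[col]]), , drop = FALSE]
  if (nrow(present) < 3) {
    rlang::abort(paste0("metadata column '", col, "' present for fewer than 3 strains"),
      class = "phagedefense_domain_error"
    )
  }
  if (by == "serotype") {
    return(
      present |>
        dplyr::group_by(serotype = .data$serotype) |>
        dplyr::summarise(
          n = dplyr::n(),
          mean_susceptibility_pct = mean(.data$susceptibility_pct),
          mean_system_count = mean(.data$system_count),
          .groups = "drop"
        ) |>
        dplyr::arrange(dplyr::desc(.data$n), .data$serotype)
    )
  }
  one <- function(response, y) {
    res <- tryCatch(
      pearson_cor(present$prophage_region_count, y),
      phagedefense_degenerate_error = function(e) NULL,
      phagedefense_domain_error = function(e) NULL
    )
    if (is.null(res)) {
      rlang::warn(paste0("prophage correlation with ", response, " not computable"))
      tibble::tibble(
        response = response, n = nrow(present),
        r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
        computable = FALSE
      )
    } else {
      tibble::tibble(
        response = response, n = res$n,
        r = res$r, r_squared = res$r_squared, p_value = res$p_value,
        computable = TRUE
      )
    }
  }
  dplyr::bind_rows(
    one("susceptibility_pct", present$susceptibility_pct),
    one("system_count", present$system_count)
  )
}
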