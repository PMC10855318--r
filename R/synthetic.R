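#' Default synthetic defense-system catalog
#'
#' The bundled synthetic catalog (`inst/extdata/synthetic_system_catalog.csv`)
#' lists the systems a simulated panel draws from: canonical name,
#' class, per-strain carriage probability and effect size on the
#' log-odds of phage susceptibility. Carriage probabilities follow the
#' published per-system occupancy of the 100-strain diversity panel
#' where a count was printed (a few near-universal systems, a long tail
#' of singletons) and small invented values elsewhere, scaled so the
#' expected number of systems per strain is 14.2. The file is a plain
#' CSV and is meant to be edited for custom scenarios.
#'
#' @return Tibble `system`, `system_class`, `carriage_prob`,
#'   `effect_size`.
#' @export
synthetic_system_catalog <- function() {
  path <- system.file("extdata", "synthetic_system_catalog.csv",
    package = "phagedefense", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Configuration for the synthetic panel generator
#'
#' Collects the generative-model parameters with validation. The
#' defaults emulate the structure of a real clinical diversity panel:
#' 100 strains, 70 phages, a system catalog whose carriage sums to
#' ~14.2 expected systems per strain, a mean susceptibility of ~38.7%
#' and a weak negative count-susceptibility association (realized
#' R-squared around 0.2-0.3), plus two strains assayed against a
#' reduced 44-phage subset.
#'
#' The model: strain i carries system s independently with probability
#' `carriage_prob[s]`; its susceptibility log-odds are
#' `alpha - sum(effect_size[carried]) + N(0, strain_noise_sd)`; cell
#' (i, j) is plaque-positive with probability
#' `plogis(logit_i + offset_j)` where `offset_j ~ N(0,
#' per_phage_offset_sd)`; positive cells receive titers
#' `10^N(titer_log10_mean, titer_log10_sd)` PFU/mL.
#'
#' @param n_strains,n_phages Panel dimensions.
#' @param seed Integer seed; the generator is bit-for-bit reproducible
#'   for a given configuration.
#' @param system_catalog Tibble with `system`, `system_class`,
#'   `carriage_prob`, `effect_size` (defaults to
#'   [synthetic_system_catalog()]).
#' @param baseline_logit Susceptibility log-odds of a strain carrying
#'   no systems (`alpha` above).
#' @param per_phage_offset_sd,strain_noise_sd Standard deviations of
#'   the phage host-range offsets and the unexplained strain-level
#'   noise, on the log-odds scale.
#' @param titer_log10_mean,titer_log10_sd Lognormal titer parameters
#'   for plaque-positive cells (log10 PFU/mL).
#' @param effect_multiplier Scales every effect size (0 switches the
#'   count-susceptibility association off; used by
#'   [recovery_experiment()]).
#' @param reduced_panel `NULL`, or `list(n_strains, n_phages)`: the last
#'   `n_strains` strains are tested against only the first `n_phages`
#'   phages, emulating panel members swapped in after host-range data
#'   collection.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 100,
                             n_phages = 70,
                             seed = 1L,
                             system_catalog = synthetic_system_catalog(),
                             baseline_logit = 2.02,
                             per_phage_offset_sd = 1.3,
                             strain_noise_sd = 0.95,
                             titer_log10_mean = 8,
                             titer_log10_sd = 1,
                             effect_multiplier = 1,
                             reduced_panel = list(n_strains = 2, n_phages = 44)) {
  stopifnot(
    n_strains >= 4, n_phages >= 1,
    is.numeric(seed), length(seed) == 1,
    per_phage_offset_sd >= 0, strain_noise_sd >= 0,
    titer_log10_sd >= 0, effect_multiplier >= 0
  )
  req <- c("system", "system_class", "carriage_prob", "effect_size")
  if (!all(req %in% names(system_catalog))) {
    rlang::abort(paste0("system_catalog needs columns: ", paste(req, collapse = ", ")),
      class = "phagedefense_config_error"
    )
  }
  if (anyDuplicated(system_catalog$system)) {
    rlang::abort("system_catalog names must be unique", class = "phagedefense_config_error")
  }
  if (any(system_catalog$carriage_prob < 0 | system_catalog$carriage_prob > 1)) {
    rlang::abort("carriage probabilities must lie in [0, 1]", class = "phagedefense_config_error")
  }
  if (any(system_catalog$effect_size < 0)) {
    rlang::abort("effect sizes must be >= 0 (effects reduce susceptibility)",
      class = "phagedefense_config_error"
    )
  }
  if (!is.null(reduced_panel)) {
    stopifnot(
      reduced_panel$n_strains >= 0, reduced_panel$n_strains < n_strains,
      reduced_panel$n_phages >= 1, reduced_panel$n_phages <= n_phages
    )
  }
  structure(
    list(
      n_strains = as.integer(n_strains), n_phages = as.integer(n_phages),
      seed = as.integer(seed),
      system_catalog = tibble::as_tibble(system_catalog),
      baseline_logit = baseline_logit,
      per_phage_offset_sd = per_phage_offset_sd,
      strain_noise_sd = strain_noise_sd,
      titer_log10_mean = titer_log10_mean,
      titer_log10_sd = titer_log10_sd,
      effect_multiplier = effect_multiplier,
      reduced_panel = reduced_panel
    ),
    class = "synthetic_config"
  )
}

phage_genera <- function() {
  c(
    "Pbunavirus", "Nankokuvirus", "Pakpunavirus", "Phikzvirus", "Yuavirus",
    "Septimatrevirus", "Epaquintavirus", "Phikmvvirus", "Pifdecavirus",
    "Bruynoghevirus", "Kochitakasuvirus", "Litunavirus", "Warsawvirus",
    "Hollowayvirus"
  )
}

# matrix-level generative core shared by simulate_panel() and
# recovery_experiment(); assumes the RNG state is already set
sim_core <- function(config) {
  n <- config$n_strains
  p <- config$n_phages
  cat_tbl <- config$system_catalog
  n_sys <- nrow(cat_tbl)

  carriage <- matrix(
    runif(n * n_sys) < rep(cat_tbl$carriage_prob, each = n),
    nrow = n, ncol = n_sys
  )
  counts <- rowSums(carriage)
  beta <- cat_tbl$effect_size * config$effect_multiplier
  burden <- as.vector(carriage %*% beta)
  logit <- config$baseline_logit - burden + rnorm(n, 0, config$strain_noise_sd)
  offsets <- rnorm(p, 0, config$per_phage_offset_sd)
  prob <- stats::plogis(outer(logit, offsets, "+"))
  positive <- matrix(runif(n * p) < prob, nrow = n, ncol = p)

  tested <- matrix(TRUE, nrow = n, ncol = p)
  rp <- config$reduced_panel
  if (!is.null(rp) && rp$n_strains > 0 && rp$n_phages < p) {
    rows <- (n - rp$n_strains + 1):n
    tested[rows, (rp$n_phages + 1):p] <- FALSE
  }
  list(
    carriage = carriage, counts = counts, logit = logit,
    offsets = offsets, prob = prob, positive = positive, tested = tested
  )
}

sim_susceptibility_pct <- function(core) {
  100 * rowSums(core$positive & core$tested) / rowSums(core$tested)
}

#' Generate a synthetic strain-phage panel with known ground truth
#'
#' Draws one panel from the generative model described in
#' [synthetic_config()] and assembles it into the same containers the
#' ingestion functions produce: a canonical defense-call table and an
#' [interaction_matrix()] with titers, plus a ground-truth record. The
#' same configuration (including seed) always regenerates the identical
#' panel.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `calls` (defense-call tibble),
#'   `matrix` (an [interaction_matrix()]), and `truth` (list:
#'   `carriage` strain-by-system logical matrix, `system_count`,
#'   `latent_logit`, `latent_susceptibility` expected per-strain
#'   positive fraction, `phage_offsets`, `config`).
#' @export
simulate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::local_seed(config$seed)

  core <- sim_core(config)
  n <- config$n_strains
  p <- config$n_phages
  strain_ids <- sprintf("SYN-%03d", seq_len(n))
  phage_ids <- sprintf("PHI-%02d", seq_len(p))

  # defense-call table in the canonical dialect
  idx <- which(core$carriage, arr.ind = TRUE)
  sys_names <- config$system_catalog$system[idx[, 2]]
  ord <- order(idx[, 1], idx[, 2])
  calls <- as_defense_calls(
    strain_id = strain_ids[idx[ord, 1]],
    raw_system = sys_names[ord],
    quiet = TRUE
  )

  # interaction matrix with lognormal titers on positive tested cells
  tested <- as.vector(core$tested)
  positive <- as.vector(core$positive) & tested
  titer <- rep(NA_real_, n * p)
  n_pos <- sum(positive)
  titer[positive] <- 10^rnorm(n_pos, config$titer_log10_mean, config$titer_log10_sd)
  titer[tested & !positive] <- 0
  cells <- tibble::tibble(
    strain_id = rep(strain_ids, times = p),
    phage_id = rep(phage_ids, each = n),
    tested = tested,
    plaque = ifelse(!tested, NA_character_, ifelse(positive, "positive", "negative")),
    titer = titer
  )

  # light strain/phage metadata: serotype, sequence type, prophage load
  serotypes <- sprintf("O%d", 1:12)
  sero_w <- 0.75^(0:11)
  prophage_p <- stats::plogis(-1.2 + 0.08 * (core$counts - mean(core$counts)))
  strains <- tibble::tibble(
    strain_id = strain_ids,
    sequence_type = sprintf("ST%d", sample(100:4000, n, replace = TRUE)),
    serotype = sample(serotypes, n, replace = TRUE, prob = sero_w / sum(sero_w)),
    prophage_region_count = 1L + rbinom(n, 13L, prophage_p)
  )
  phages <- tibble::tibble(
    phage_id = phage_ids,
    genus = sample(phage_genera(), p, replace = TRUE),
    morphotype = sample(c("myo", "sipho", "podo"), p, replace = TRUE)
  )

  truth <- list(
    carriage = {
      m <- core$carriage
      dimnames(m) <- list(strain_ids, config$system_catalog$system)
      m
    },
    system_count = stats::setNames(core$counts, strain_ids),
    latent_logit = stats::setNames(core$logit, strain_ids),
    latent_susceptibility = stats::setNames(
      rowSums(core$prob * core$tested) / rowSums(core$tested), strain_ids
    ),
    phage_offsets = stats::setNames(core$offsets, phage_ids),
    config = config
  )
  list(
    calls = calls,
    matrix = interaction_matrix(cells, strains = strains, phages = phages),
    truth = truth
  )
}

#' Write a synthetic panel in the dialects the ingestion functions read
#'
#' Emits `calls.csv` (PADLOC dialect: `seqid`, `system`),
#' `hostrange.csv` (wide titer matrix; blank = untested, 0 = negative),
#' `strains.tsv`, `phages.tsv` and `truth.json` into `dir`.
#'
#' @param panel Result of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    tibble::tibble(seqid = panel$calls$strain_id, system = panel$calls$raw_system),
    file.path(dir, "calls.csv")
  )
  wide <- panel$matrix$cells |>
    dplyr::mutate(value = ifelse(.data$tested, format_titer(.data$titer), "")) |>
    dplyr::select("strain_id", "phage_id", "value") |>
    tidyr::pivot_wider(names_from = "phage_id", values_from = "value") |>
    dplyr::arrange(.data$strain_id)
  readr::write_csv(wide, file.path(dir, "hostrange.csv"))
  readr::write_tsv(panel$matrix$strains, file.path(dir, "strains.tsv"))
  readr::write_tsv(panel$matrix$phages, file.path(dir, "phages.tsv"))
  truth <- panel$truth
  jsonlite::write_json(
    list(
      system_count = as.list(truth$system_count),
      latent_susceptibility = as.list(truth$latent_susceptibility),
      seed = truth$config$seed
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

format_titer <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.6g", x))
  out[which(x == 0)] <- "0"
  out
}

#' Power and type-I-error experiment for the burden-susceptibility test
#'
#' Repeatedly simulates panels at scaled effect sizes and records how
#' often the Pearson test of per-strain system count against
#' susceptibility rejects at level `alpha` with a negative slope. At
#' multiplier 0 the rejection fraction is the empirical type-I error
#' (the test should reject at about the nominal level); at positive
#' multipliers it is power. The mean realized R-squared per multiplier
#' is also reported.
#'
#' Two rejection rates are reported: `rejection_rate` counts two-sided
#' rejections (p < alpha), whose value at multiplier 0 is the empirical
#' type-I error and should sit near the nominal level, and
#' `directional_rejection_rate` additionally requires a negative slope
#' (the scientifically meaningful direction), which is the relevant
#' power quantity at positive multipliers.
#'
#' @param config A [synthetic_config()]; its `effect_multiplier` is
#'   overridden by `at_effect`.
#' @param n_replicates Replicates per multiplier.
#' @param at_effect Numeric vector of effect-size multipliers.
#' @param alpha Test level.
#' @param detail Attach the per-replicate results (`p_value`, `slope`,
#'   `r_squared`) as attribute `"replicates"`.
#' @return Tibble `effect_multiplier`, `n_replicates`,
#'   `rejection_rate`, `directional_rejection_rate`, `mean_r_squared`,
#'   `mean_susceptibility_pct`.
#' @export
recovery_experiment <- function(config = synthetic_config(),
                                n_replicates = 200,
                                at_effect = c(0, 1),
                                alpha = 0.05,
                                detail = FALSE) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1)
  withr::local_seed(config$seed)
  reps <- vector("list", length(at_effect))
  rows <- vector("list", length(at_effect))
  for (k in seq_along(at_effect)) {
    m <- at_effect[k]
    cfg <- config
    cfg$effect_multiplier <- m
    p_value <- slope <- r2 <- msusc <- numeric(n_replicates)
    for (i in seq_len(n_replicates)) {
      core <- sim_core(cfg)
      susc <- sim_susceptibility_pct(core)
      res <- tryCatch(
        pearson_cor(core$counts, susc),
        phagedefense_degenerate_error = function(e) NULL
      )
      if (is.null(res)) {
        p_value[i] <- NA_real_
        slope[i] <- NA_real_
        r2[i] <- NA_real_
      } else {
        p_value[i] <- res$p_value
        slope[i] <- res$slope
        r2[i] <- res$r_squared
      }
      msusc[i] <- mean(susc)
    }
    reps[[k]] <- tibble::tibble(
      effect_multiplier = m, replicate = seq_len(n_replicates),
      p_value = p_value, slope = slope, r_squared = r2
    )
    rows[[k]] <- tibble::tibble(
      effect_multiplier = m,
      n_replicates = n_replicates,
      rejection_rate = mean(p_value < alpha, na.rm = TRUE),
      directional_rejection_rate = mean(p_value < alpha & slope < 0, na.rm = TRUE),
      mean_r_squared = mean(r2, na.rm = TRUE),
      mean_susceptibility_pct = mean(msusc)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (detail) attr(out, "replicates") <- dplyr::bind_rows(reps)
  out
}
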