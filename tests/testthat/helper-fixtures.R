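# fixture builders shared across test files; everything built in code

# interaction matrix from a titer matrix: rows strains, cols phages;
# NA = untested, 0 = negative
im_from_titers <- function(titers) {
  strains <- rownames(titers) %||% sprintf("S%02d", seq_len(nrow(titers)))
  phages <- colnames(titers) %||% sprintf("P%02d", seq_len(ncol(titers)))
  cells <- tibble::tibble(
    strain_id = rep(strains, times = ncol(titers)),
    phage_id = rep(phages, each = nrow(titers)),
    titer = as.vector(titers)
  )
  cells$tested <- !is.na(cells$titer)
  cells$plaque <- ifelse(!cells$tested, NA_character_,
    ifelse(cells$titer > 0, "positive", "negative")
  )
  interaction_matrix(cells)
}

# random titer matrix with controllable positivity; guarantees every
# strain has >= 1 tested cell
random_titer_matrix <- function(n_strains, n_phages, p_untested = 0.1, p_negative = 0.4) {
  m <- matrix(10^stats::runif(n_strains * n_phages, 2, 10),
    nrow = n_strains, ncol = n_phages
  )
  m[stats::runif(length(m)) < p_negative] <- 0
  m[stats::runif(length(m)) < p_untested] <- NA
  blank <- rowSums(!is.na(m)) == 0
  m[blank, 1] <- 0
  rownames(m) <- sprintf("S%02d", seq_len(n_strains))
  colnames(m) <- sprintf("P%02d", seq_len(n_phages))
  m
}

# defense-call fixture from a named list strain -> character vector of
# raw system labels
calls_from_list <- function(x) {
  as_defense_calls(
    strain_id = rep(names(x), lengths(x)),
    raw_system = unlist(x, use.names = FALSE),
    quiet = TRUE
  )
}

# susceptibility groups from an explicit named susceptibility vector
groups_from <- function(susc, k_fraction = 0.25) {
  assign_groups(susc, k_fraction = k_fraction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
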