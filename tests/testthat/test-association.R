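# independent two-pass product-moment oracle used throughout
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

test_that("pearson_cor reproduces closed-form values", {
  res <- pearson_cor(1:10, 1:10)
  expect_equal(res$r, 1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 1)
  expect_equal(res$intercept, 0)

  res <- pearson_cor(c(1, 2, 3), c(2, 1, 3))
  expect_equal(res$r, oracle_pearson(c(1, 2, 3), c(2, 1, 3)))
  expect_equal(res$r, 0.5)
})

test_that("pearson_cor agrees with stats::cor.test and lm", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- sample(3:200, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    res <- pearson_cor(x, y)
    ct <- stats::cor.test(x, y, method = "pearson")
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
    fit <- stats::lm(y ~ x)
    expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(res$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("pearson_cor rejects degenerate input", {
  expect_error(pearson_cor(1:2, 1:2), class = "phagedefense_domain_error")
  expect_error(pearson_cor(rep(1, 5), 1:5), class = "phagedefense_degenerate_error")
  expect_error(pearson_cor(1:5, rep(2, 5)), class = "phagedefense_degenerate_error")
  expect_error(pearson_cor(1:4, 1:5), class = "phagedefense_input_error")
})

test_that("group sizes follow the rank rule", {
  withr::local_seed(12)
  s100 <- stats::setNames(runif(100, 0, 100), sprintf("M%03d", 1:100))
  g <- assign_groups(s100)
  expect_equal(as.vector(table(g$assignment$group)), c(10, 40, 40, 10))
  expect_equal(g$k_extreme, 10)

  s10 <- stats::setNames(sample(1:100, 10), sprintf("M%02d", 1:10))
  g10 <- assign_groups(s10)
  expect_equal(as.vector(table(g10$assignment$group)), c(1, 4, 4, 1))
})

test_that("groups are a monotone partition of all strains", {
  withr::local_seed(13)
  for (rep in 1:10) {
    n <- sample(4:60, 1)
    s <- stats::setNames(round(runif(n, 0, 100)), sprintf("M%03d", seq_len(n)))
    g <- suppressMessages(assign_groups(s, k_fraction = 0.1 + runif(1, 0, 0.2)))
    a <- g$assignment
    expect_setequal(a$strain_id, names(s))
    expect_equal(nrow(a), n)
    # group index never decreases as susceptibility increases
    ord <- order(a$susceptibility_pct, a$strain_id)
    expect_true(all(diff(as.integer(a$group[ord])) >= 0))
    # size pattern (k, nr - k, ns - k, k)
    sizes <- as.vector(table(a$group))
    expect_equal(sizes[1], sizes[4])
    expect_equal(sum(sizes), n)
    expect_equal(sizes[2], ceiling(n / 2) - sizes[1])
  }
})

test_that("ties at boundaries are broken by strain id, deterministically", {
  s <- c(A = 10, B = 20, C = 20, D = 20, E = 30, F = 40, G = 50, H = 60)
  g1 <- assign_groups(s, k_fraction = 0.25)
  g2 <- assign_groups(s[sample(names(s))], k_fraction = 0.25)
  o1 <- g1$assignment[order(g1$assignment$strain_id), ]
  o2 <- g2$assignment[order(g2$assignment$strain_id), ]
  expect_equal(o1, o2)
  # brute force: sort by (value, id) gives A,B,C,D,E,F,G,H; k = 2, halves of 4
  expect_equal(
    as.character(o1$group),
    c(
      "most_resistant", "most_resistant", "intermediate_resistant",
      "intermediate_resistant", "intermediate_susceptible",
      "intermediate_susceptible", "most_susceptible", "most_susceptible"
    )
  )
})

test_that("odd panels put the extra strain in the resistant half", {
  s <- stats::setNames(1:9, paste0("M", 1:9))
  expect_message(g <- assign_groups(s, k_fraction = 0.12), "odd")
  sizes <- table(g$assignment$group)
  expect_equal(sum(sizes[c("most_resistant", "intermediate_resistant")]), 5)
})

test_that("implied thresholds are the realized cut points", {
  s <- stats::setNames(c(1, 2, 10, 20, 40, 60, 80, 90), paste0("M", 1:8))
  g <- assign_groups(s, k_fraction = 0.25)
  expect_equal(unname(g$implied_thresholds["most_resistant_max"]), 2)
  expect_equal(unname(g$implied_thresholds["median_split"]), 20)
  expect_equal(unname(g$implied_thresholds["intermediate_susceptible_max"]), 60)
})

# builds calls + groups where `k` of `n` carriers sit in the resistant half
prevalence_fixture <- function(k, n, system = "zorya", n_extra = 10) {
  total <- n + n_extra
  ids <- sprintf("M%03d", seq_len(total))
  # lowest-susceptibility half = resistant; carriers: k resistant, n - k susceptible
  susc <- stats::setNames(seq(0, 100, length.out = total), ids)
  carriers <- c(ids[seq_len(k)], rev(ids)[seq_len(n - k)])
  calls <- as_defense_calls(carriers, rep(system, n), quiet = TRUE)
  groups <- suppressMessages(assign_groups(susc, k_fraction = 0.2))
  list(calls = calls, groups = groups)
}

test_that("prevalence classification matches reconstructed published splits", {
  f <- prevalence_fixture(13, 15)
  res <- prevalence(f$calls, f$groups)
  expect_equal(res$n_encoding, 15L)
  expect_equal(round(res$percent_resistant, 1), 86.7)
  expect_equal(res$classification, "resistant_prevalent")

  f <- prevalence_fixture(7, 14, system = "brex")
  res <- prevalence(f$calls, f$groups)
  expect_equal(res$percent_resistant, 50)
  expect_equal(res$classification, "neither")
  expect_true(res$low_n)

  f <- prevalence_fixture(11, 25, system = "drt")
  res <- prevalence(f$calls, f$groups)
  expect_equal(100 - res$percent_resistant, 56)
  expect_equal(res$classification, "susceptible_prevalent")
})

test_that("mirroring the halves flips the prevalence classification", {
  withr::local_seed(21)
  for (k in c(2, 5, 9, 13)) {
    f <- prevalence_fixture(k, 15)
    res <- prevalence(f$calls, f$groups)
    mirrored <- f$groups
    flip <- c(
      most_resistant = "most_susceptible",
      intermediate_resistant = "intermediate_susceptible",
      intermediate_susceptible = "intermediate_resistant",
      most_susceptible = "most_resistant"
    )
    mirrored$assignment$group <- factor(
      flip[as.character(f$groups$assignment$group)],
      levels = susceptibility_group_levels()
    )
    res_m <- prevalence(f$calls, mirrored)
    expect_equal(res_m$percent_resistant, 100 - res$percent_resistant)
    swap <- c(
      resistant_prevalent = "susceptible_prevalent",
      susceptible_prevalent = "resistant_prevalent",
      neither = "neither"
    )
    expect_equal(res_m$classification, unname(swap[res$classification]))
  }
})

test_that("no system is prevalent on both sides for thresholds above 50", {
  withr::local_seed(22)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    k <- sample(0:n, 1)
    f <- prevalence_fixture(k, n)
    res <- prevalence(f$calls, f$groups, threshold = runif(1, 50.01, 80))
    expect_true(res$classification %in% c("resistant_prevalent", "susceptible_prevalent", "neither"))
    expect_false(
      res$percent_resistant >= 52.5 && (100 - res$percent_resistant) >= 52.5
    )
  }
})

test_that("prevalence errors on systems no strain encodes", {
  f <- prevalence_fixture(3, 5)
  expect_error(
    prevalence(f$calls, f$groups, system = "Thoeris"),
    class = "phagedefense_domain_error"
  )
})

test_that("group means average system counts within groups", {
  susc <- stats::setNames(c(10, 20, 30, 40), c("A", "B", "C", "D"))
  g <- assign_groups(susc, k_fraction = 0.25)
  per_strain <- tibble::tibble(
    strain_id = c("A", "B", "C", "D"),
    system_count = c(1L, 2L, 3L, 4L)
  )
  gm <- group_means(per_strain, g)
  expect_equal(gm$mean_system_count, c(1, 2, 3, 4))

  per_strain$system_count <- 7L
  expect_equal(group_means(per_strain, g)$mean_system_count, rep(7, 4))
})

test_that("group means under distinct counting never exceed loci counting", {
  withr::local_seed(23)
  ids <- sprintf("M%02d", 1:12)
  labels <- c("gabija", "gabija", "cbass", "zorya", "brex", "septu")
  calls <- as_defense_calls(
    rep(ids, each = 6),
    unlist(lapply(ids, function(i) sample(labels, 6, replace = TRUE))),
    quiet = TRUE
  )
  g <- assign_groups(stats::setNames(runif(12, 0, 100), ids), k_fraction = 0.25)
  loci <- group_means(tally_defense(calls, count = "loci")$per_strain, g)
  dist <- group_means(tally_defense(calls, count = "distinct")$per_strain, g)
  expect_true(all(dist$mean_system_count <= loci$mean_system_count))
})

test_that("serotype summary reduces to panel means for a single serotype", {
  strains <- tibble::tibble(strain_id = c("A", "B", "C"), serotype = "O6")
  susc <- tibble::tibble(strain_id = c("A", "B", "C"), susceptibility_pct = c(10, 50, 90))
  per_strain <- tibble::tibble(strain_id = c("A", "B", "C"), system_count = c(5L, 10L, 15L))
  out <- metadata_summary(strains, susc, per_strain, by = "serotype")
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_susceptibility_pct, 50)
  expect_equal(out$mean_system_count, 10)
})

test_that("prophage correlations carry the expected sign and degenerate safely", {
  strains <- tibble::tibble(
    strain_id = sprintf("M%02d", 1:10),
    prophage_region_count = 10:1
  )
  susc <- tibble::tibble(
    strain_id = sprintf("M%02d", 1:10),
    susceptibility_pct = seq(5, 95, length.out = 10)
  )
  per_strain <- tibble::tibble(
    strain_id = sprintf("M%02d", 1:10),
    system_count = sample(5:20, 10)
  )
  out <- metadata_summary(strains, susc, per_strain, by = "prophage")
  r_susc <- out$r[out$response == "susceptibility_pct"]
  expect_lt(r_susc, 0)
  expect_equal(
    r_susc,
    oracle_pearson(strains$prophage_region_count, susc$susceptibility_pct)
  )

  strains$prophage_region_count <- 4L
  warns <- testthat::capture_warnings(
    out <- metadata_summary(strains, susc, per_strain, by = "prophage")
  )
  expect_true(all(grepl("not computable", warns)))
  expect_length(warns, 2)
  expect_false(any(out$computable))

  expect_error(
    metadata_summary(strains[, "strain_id"], susc, per_strain, by = "prophage"),
    class = "phagedefense_config_error"
  )
})
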