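test_that("a clean sample has zero aberrant ground truth and tabulation", {
  sim <- simulate_sample(n_events = 20000, seed = 701)
  expect_true(all(sim$truth$subpop_counts == 0))
  tab <- tabulate_sample(sim$events)
  expect_true(all(tab$subpops$count == 0))
  expect_equal(tab$n_cd45, sim$truth$n_cd45)
})

test_that("simulation is deterministic under its seed", {
  a <- simulate_sample(n_events = 8000, seed = 702,
                       background = lfc_background_params("BMD"))
  b <- simulate_sample(n_events = 8000, seed = 702,
                       background = lfc_background_params("BMD"))
  expect_identical(a$events$values, b$events$values)
  expect_identical(a$truth$subpop_counts, b$truth$subpop_counts)
  c <- simulate_sample(n_events = 8000, seed = 703,
                       background = lfc_background_params("BMD"))
  expect_false(identical(a$events$values, c$events$values))
})

test_that("rare clone fractions are reproduced within binomial tolerance", {
  frac <- 3e-5   # 0.003% of CD45+
  sim <- simulate_sample(n_events = 400000, seed = 704,
                         clones = list(clone_spec(TRUE, TRUE, TRUE,
                                                  "CD56pos", frac)))
  tab <- tabulate_sample(sim$events)
  pct <- tab$subpops$pct[tab$subpops$id == "CD34+CD117+HLA-DR+ CD56pos"]
  n <- tab$n_cd45
  se <- 100 * sqrt(frac * (1 - frac) / n)
  expect_lt(abs(pct - 100 * frac), 4 * se + 100 / n)  # + rounding of the count
})

test_that("infeasible clones are rejected at specification time", {
  expect_error(clone_spec(TRUE, TRUE, TRUE, c("CD13neg", "CD33neg"), 0.1),
               "myP/M")
  expect_error(clone_spec(TRUE, TRUE, TRUE, "CD56pos", 1.0), "fraction")
  expect_error(simulate_sample(n_events = 100, seed = 1, clones = list(1)),
               "clone_spec")
  expect_error(simulate_sample(n_events = 100), "seed")
})

test_that("LFC cohort generation respects the cohort mix and reproduces", {
  co <- generate_lfc_cohort(n_samples = 12,
                            cohort_mix = c(BMD = 4, ALL_molCR = 3,
                                           hip_surgery = 4, PCNSL = 1),
                            n_events = 8000, seed = 705)
  expect_length(co$tables, 12)
  expect_equal(table(co$cohorts)[c("BMD", "ALL_molCR", "hip_surgery", "PCNSL")],
               table(rep(c("BMD", "ALL_molCR", "hip_surgery", "PCNSL"),
                         c(4, 3, 4, 1)))[c("BMD", "ALL_molCR",
                                           "hip_surgery", "PCNSL")])
  labels <- vapply(co$tables, function(t) t$cohort_label, "")
  expect_equal(sort(unique(labels)),
               c("ALL_molCR", "BMD", "PCNSL", "hip_surgery"))
  # cohort-level reference panels are identical across runs with one seed
  co2 <- generate_lfc_cohort(n_samples = 12,
                             cohort_mix = c(BMD = 4, ALL_molCR = 3,
                                            hip_surgery = 4, PCNSL = 1),
                             n_events = 8000, seed = 705)
  expect_identical(estimate_reference(co$tables)$values,
                   estimate_reference(co2$tables)$values)
  expect_warning(generate_lfc_cohort(n_samples = 2,
                                     cohort_mix = c(BMD = 1, ALL_molCR = 1),
                                     n_events = 5000, seed = 706),
                 "minimal")
  expect_error(generate_lfc_cohort(n_samples = 5, cohort_mix = c(BMD = 4),
                                   seed = 1), "sum")
})

test_that("a planted heavy-tail cohort is recovered by attribution", {
  planted <- function(cohort) {
    bg <- lfc_background_params(cohort)
    if (cohort == "PCNSL") {    # plant an extreme CD7pos tail in PCNSL
      sel <- grepl("CD7pos", bg$id)
      bg$p_present[sel] <- 1
      bg$meanlog[sel] <- log(0.8)
      bg$sdlog[sel] <- 0.3
    }
    bg
  }
  co <- generate_lfc_cohort(n_samples = 24,
                            cohort_mix = c(BMD = 8, ALL_molCR = 5,
                                           hip_surgery = 6, PCNSL = 5),
                            n_events = 10000, seed = 707,
                            background_fn = planted)
  panel <- estimate_reference(co$tables)
  v <- panel$values
  expect_true(all(v$driving_cohort[v$category == "CD7pos"] == "PCNSL"))
})

test_that("patient pairs carry the clone at the requested fractions", {
  clone <- clone_spec(TRUE, TRUE, FALSE, c("CD13neg", "CD56pos"), 0.3)
  pair <- generate_patient_pair(clone, residual_fraction = 0.002, seed = 708,
                                n_events = 60000)
  dx <- tabulate_sample(pair$diagnosis$events)
  fu <- tabulate_sample(pair$followup$events)
  # diagnosis clone qualifies as aLAIP in both its categories
  prof <- detect_alaip(dx)
  expect_setequal(prof$alaip_set, c("CD13neg", "CD56pos"))
  # the myeloid share of the P/M gate sits near its 94% target
  expect_lt(abs(dx$n_mypm / dx$n_pm - 0.94), 0.02)
  # follow-up clone is scaled to the residual fraction
  fu_pct <- fu$subpops$pct[fu$subpops$id == "CD34+CD117+HLA-DR- CD56pos"]
  expect_lt(abs(fu_pct - 0.2), 0.05)
  # residual_fraction = 0 leaves no trace of the clone
  pair0 <- generate_patient_pair(clone, residual_fraction = 0, seed = 709,
                                 n_events = 30000)
  expect_true(all(pair0$followup$truth$subpop_counts == 0))
})

test_that("phenotype shift changes the follow-up clone's category set", {
  clone <- clone_spec(TRUE, TRUE, FALSE, "CD13neg", 0.3)
  pair <- generate_patient_pair(clone, residual_fraction = 0.01,
                                phenotype_shift = "CD56pos", seed = 710,
                                n_events = 40000)
  counts <- pair$followup$truth$subpop_counts
  expect_gt(counts["CD34+CD117+HLA-DR- CD56pos"], 0)
  expect_equal(unname(counts["CD34+CD117+HLA-DR- CD13neg"]), 0L)
})
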