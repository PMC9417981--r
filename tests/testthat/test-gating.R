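cfg <- gate_config()

test_that("doublet exclusion works on the FSC-A/FSC-H ratio", {
  ev <- make_events(4, `FSC-A` = c(400, 800, 400, 400),
                    `FSC-H` = c(400, 400, 310, 0))
  expect_equal(exclude_doublets(ev, cfg), c(TRUE, FALSE, TRUE, FALSE))
  strict <- gate_config(doublet_ratio = 0)
  expect_equal(exclude_doublets(ev, strict), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("debris exclusion thresholds FSC-A and SSC-A", {
  ev <- make_events(3, `FSC-A` = c(400, 50, 400), `SSC-A` = c(150, 150, 5))
  expect_equal(exclude_debris(ev, cfg), c(TRUE, FALSE, FALSE))
  none <- gate_config(fsc_min = 0, ssc_min = 0)
  expect_true(all(exclude_debris(ev, none)))
})

test_that("CD45+ gate counts the denominator and flags empty samples", {
  set.seed(201)
  ev <- make_events(1000, CD45 = c(rep(5, 900), rep(0, 100)))
  g <- gate_cd45_leukocytes(ev, cfg)
  expect_equal(g$n_cd45, 900)
  expect_true(g$evaluable)
  low <- gate_config(cd45_threshold = -Inf)
  expect_equal(gate_cd45_leukocytes(ev, low)$n_cd45, 1000)
  # all events debris -> empty downstream, non-evaluable
  deb <- make_events(10, `FSC-A` = 1)
  g0 <- gate_cd45_leukocytes(deb, cfg)
  expect_equal(g0$n_cd45, 0)
  expect_false(g0$evaluable)
})

test_that("P/M and lymphocyte polygons include interiors and boundaries", {
  pmc <- colMeans(cfg$pm_polygon)
  ev <- make_events(4,
                    CD45 = c(pmc[1], 6.5, 2.0, 1.2),
                    `SSC-A` = c(pmc[2], 100, 350, 700))
  g <- gate_pm_lymph(ev, cfg)
  expect_equal(g$pm, c(TRUE, FALSE, TRUE, FALSE))     # centroid; boundary vertex
  expect_equal(g$lymph, c(FALSE, TRUE, FALSE, FALSE)) # outside both for 4th
  expect_error(gate_config(pm_polygon = cbind(c(0, 1), c(0, 1))), "3")
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(gate_config(pm_polygon = bowtie), "simple")
  expect_error(gate_config(lymph_polygon = cbind(CD45 = c(2, 4, 4, 2),
                                                 `SSC-A` = c(0, 0, 300, 300))),
               "disjoint")
})

test_that("myP/M requires at least one myeloid marker (OR semantics)", {
  ev <- make_events(3, CD13 = c(3, 0.5, 0.5), CD33 = c(0.5, 3, 0.5))
  pm <- rep(TRUE, 3)
  expect_equal(gate_mypm(ev, cfg, pm), c(TRUE, TRUE, FALSE))
})

test_that("backbone thresholding covers all 8 combinations exactly once", {
  grid <- expand.grid(CD34 = c(0.5, 3.5), CD117 = c(0.5, 3.5),
                      `HLA-DR` = c(0.5, 3.5), check.names = FALSE)
  ev <- make_events(8, CD34 = grid$CD34, CD117 = grid$CD117,
                    `HLA-DR` = grid[["HLA-DR"]])
  bb <- assign_backbone(ev, cfg, rep(TRUE, 8))
  expect_setequal(bb, dfnmrd:::backbone_levels())
  expect_equal(anyDuplicated(bb), 0L)
  # outside myP/M the backbone is undefined
  expect_true(all(is.na(assign_backbone(ev, cfg, rep(FALSE, 8)))))
})

test_that("category assignment flags deficiency and strong cross-lineage", {
  ev <- make_events(3,
                    CD13 = c(0.5, 3.5, 3.5), CD33 = c(3.5, 3.5, 3.5),
                    CD7 = c(0.5, 0.5, 2.5),   # 2.5 < strong cutoff 3
                    CD56 = c(4.0, 0.5, 0.5))
  cats <- assign_categories(ev, cfg, rep(TRUE, 3))
  expect_equal(unname(cats[1, ]), c(TRUE, FALSE, FALSE, TRUE))  # CD13neg+CD56pos
  expect_equal(sum(cats[2, ]), 0)                               # normal
  expect_equal(sum(cats[3, ]), 0)                               # weak CD7 ignored
})

test_that("gating invariants hold on simulated marrow", {
  for (seed in c(301, 302, 303)) {
    sim <- simulate_sample(n_events = 15000, seed = seed,
                           background = lfc_background_params("ALL_molCR"),
                           clones = list(clone_spec(FALSE, FALSE, FALSE,
                                                    "CD56pos", 0.01)))
    lab <- gate_events(sim$events, cfg)
    # hierarchy containment
    expect_true(all(!lab$in_mypm | lab$in_pm))
    expect_true(all(!lab$in_pm | lab$is_cd45pos))
    expect_true(all(!lab$is_cd45pos | (!lab$is_debris & !lab$is_doublet)))
    expect_false(any(lab$in_pm & lab$in_lymph))
    # backbone labels partition myP/M
    expect_true(all(!is.na(lab$backbone[lab$in_mypm])))
    expect_true(all(is.na(lab$backbone[!lab$in_mypm])))
    # CD13neg & CD33neg jointly unreachable for myP/M
    expect_false(any(lab$categories[, "CD13neg"] & lab$categories[, "CD33neg"]))
  }
})

test_that("gating is deterministic and independent of event order", {
  sim <- simulate_sample(n_events = 5000, seed = 304,
                         background = lfc_background_params("BMD"))
  ev <- sim$events
  lab1 <- gate_events(ev, cfg)
  set.seed(99)
  perm <- sample.int(ev$n_events)
  ev2 <- ev
  ev2$values <- ev$values[perm, ]
  lab2 <- gate_events(ev2, cfg)
  expect_identical(lab1$in_mypm[perm], lab2$in_mypm)
  expect_identical(lab1$backbone[perm], lab2$backbone)
  expect_identical(gate_events(ev, cfg)$categories, lab1$categories)
})

test_that("raising a fixed threshold is monotone in the gated counts", {
  sim <- simulate_sample(n_events = 10000, seed = 305,
                         background = lfc_background_params("ALL_molCR"))
  counts <- sapply(c(2.5, 3.0, 3.5, 4.0), function(cut) {
    lab <- gate_events(sim$events, gate_config(cd56_strong = cut))
    sum(lab$categories[, "CD56pos"])
  })
  expect_true(all(diff(counts) <= 0))
  mypm <- sapply(c(1.5, 2.0, 2.5), function(cut) {
    sum(gate_events(sim$events, gate_config(cd13_pos = cut,
                                            cd33_pos = cut))$in_mypm)
  })
  expect_true(all(diff(mypm) <= 0))
})
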