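test_that("aLAIP detection thresholds the per-category myP/M share", {
  # 150 CD56pos and 90 CD7pos events among 1000 myP/M
  tab <- make_table(c(`CD34+CD117+HLA-DR+ CD56pos` = 150,
                      `CD34-CD117-HLA-DR+ CD7pos` = 90),
                    n_cd45 = 1e5, n_mypm = 1000)
  prof <- detect_alaip(tab, threshold_pct = 10)
  expect_equal(unname(prof$pct_of_mypm["CD56pos"]), 15)
  expect_equal(prof$alaip_set, "CD56pos")
  expect_equal(prof$minor_clones, "CD7pos")       # 9% < 10%
  prof5 <- detect_alaip(tab, threshold_pct = 5)
  expect_setequal(prof5$alaip_set, c("CD56pos", "CD7pos"))
  empty <- detect_alaip(make_table(n_cd45 = 1e5, n_mypm = 500))
  expect_length(empty$alaip_set, 0)
  expect_warning(detect_alaip(make_table(n_cd45 = 10, n_mypm = 0)), "myP/M")
})

test_that("MRD calling applies burden arithmetic and the max-category rule", {
  panel <- make_panel(default = 5, `CD34+CD117+HLA-DR+ CD56pos` = 0.001)
  fu <- make_table(c(`CD34+CD117+HLA-DR+ CD56pos` = 30), n_cd45 = 1e6)
  res <- call_mrd(fu, panel)
  expect_equal(res$status, "pos")
  expect_equal(res$positive_subpops$pct, 0.003)
  expect_equal(res$positive_subpops$burden, 0.002)
  expect_equal(res$mrd_load, 0.002)
  expect_equal(res$load_category, "CD56pos")
  expect_equal(res$origin, "no_diagnosis")
  expect_equal(res$load_class, "Lo")

  # burdens with identical category are summed; max category wins
  panel2 <- make_panel(default = 0.01)
  fu2 <- make_table(c(`CD34+CD117+HLA-DR+ CD56pos` = 300,
                      `CD34+CD117-HLA-DR+ CD56pos` = 400,
                      `CD34-CD117-HLA-DR+ CD13neg` = 300),
                    n_cd45 = 1e6)
  res2 <- call_mrd(fu2, panel2)
  expect_equal(unname(res2$category_sums["CD56pos"]),
               (0.03 - 0.01) + (0.04 - 0.01))
  expect_equal(unname(res2$category_sums["CD13neg"]), 0.02)
  expect_equal(res2$mrd_load, 0.05)
  expect_equal(res2$load_category, "CD56pos")
  expect_false(res2$load_tie)
})

test_that("the >= 20 event minimum filters subpopulations before calling", {
  panel <- make_panel(default = 1e-4)
  fu <- make_table(c(`CD34+CD117+HLA-DR+ CD7pos` = 19), n_cd45 = 1e6)
  res <- call_mrd(fu, panel)         # far above reference but only 19 events
  expect_equal(res$status, "neg")
  expect_equal(res$mrd_load, 0)
  expect_true("CD34+CD117+HLA-DR+ CD7pos" %in% res$non_evaluable_subpops)
  res20 <- call_mrd(make_table(c(`CD34+CD117+HLA-DR+ CD7pos` = 20),
                               n_cd45 = 1e6), panel)
  expect_equal(res20$status, "pos")
  # raising min_events can only flip pos -> neg, never neg -> pos
  for (me in c(20, 25, 50, 200)) {
    r <- call_mrd(make_table(c(`CD34+CD117+HLA-DR+ CD7pos` = 40),
                             n_cd45 = 1e6), panel, min_events = me)
    expect_equal(r$status, if (me <= 40) "pos" else "neg")
  }
})

test_that("positivity requires strictly exceeding the reference", {
  panel <- make_panel(default = 0.003)
  fu <- make_table(c(`CD34+CD117+HLA-DR+ CD56pos` = 30), n_cd45 = 1e6)
  expect_equal(call_mrd(fu, panel)$status, "neg")   # pct == ref, not above
})

test_that("origin distinguishes aLAIP reoccurrence from post-treatment DfN", {
  panel <- make_panel(default = 0.001)
  fu <- make_table(c(`CD34+CD117+HLA-DR+ CD13neg` = 100), n_cd45 = 1e6)
  dx_alaip <- detect_alaip(make_table(c(`CD34+CD117+HLA-DR+ CD13neg` = 200),
                                      n_cd45 = 1e4, n_mypm = 1000))
  expect_equal(call_mrd(fu, panel, dx_alaip)$origin, "aLAIP_only")
  dx_none <- detect_alaip(make_table(n_cd45 = 1e4, n_mypm = 1000))
  expect_equal(call_mrd(fu, panel, dx_none)$origin, "ptDfN_only")
  both <- make_table(c(`CD34+CD117+HLA-DR+ CD13neg` = 100,
                       `CD34+CD117+HLA-DR+ CD56pos` = 100), n_cd45 = 1e6)
  expect_equal(call_mrd(both, panel, dx_alaip)$origin, "aLAIP_and_ptDfN")
  expect_true(is.na(call_mrd(make_table(n_cd45 = 1e6), panel, dx_alaip)$origin))
})

test_that("ELN scheme restricts to immature subpopulations at a flat 0.1%", {
  fu <- make_table(c(`CD34+CD117+HLA-DR+ CD56pos` = 1500), n_cd45 = 1e6)
  expect_equal(call_mrd_eln(fu), "pos")                       # 0.15% >= 0.1%
  low <- make_table(c(`CD34+CD117+HLA-DR+ CD56pos` = 900), n_cd45 = 1e6)
  expect_equal(call_mrd_eln(low), "neg")                      # 0.09%
  # the CD34-CD117- compartment is excluded no matter how large
  mono <- make_table(c(`CD34-CD117-HLA-DR+ CD56pos` = 50000), n_cd45 = 1e6)
  expect_equal(call_mrd_eln(mono), "neg")
  # 0.09% can still be positive under the reference scheme
  panel <- make_panel(default = 0.05)
  expect_equal(call_mrd(low, panel)$status, "pos")
  expect_equal(call_mrd(low, panel)$eln_status, "neg")
})

test_that("immature-only calls nest inside the full scheme", {
  panel <- make_panel(default = 0.001)
  mono_only <- make_table(c(`CD34-CD117-HLA-DR+ CD56pos` = 5000), n_cd45 = 1e6)
  res <- call_mrd(mono_only, panel)
  expect_equal(res$status, "pos")
  expect_equal(res$immonly_status, "neg")   # positivity outside immature only
  imm <- make_table(c(`CD34+CD117-HLA-DR+ CD56pos` = 5000), n_cd45 = 1e6)
  res2 <- call_mrd(imm, panel)
  expect_equal(res2$immonly_status, "pos")
  expect_equal(res2$status, "pos")
  # property: ImmOnly-pos implies full-pos on random tables
  set.seed(501)
  ids <- enumerate_subpopulations()$id
  for (i in 1:20) {
    counts <- setNames(rpois(32, 30), ids)
    tab <- make_table(counts, n_cd45 = 1e6)
    if (call_mrd_immonly(tab, panel) == "pos")
      expect_equal(call_mrd(tab, panel)$status, "pos")
  }
})

test_that("load splits into Lo and Hi at an excess of 0.1 (>= convention)", {
  panel <- make_panel(default = 0.01)
  mk <- function(count) call_mrd(make_table(
    c(`CD34+CD117+HLA-DR+ CD56pos` = count), n_cd45 = 1e6), panel)
  expect_equal(mk(600)$load_class, "Lo")    # excess 0.05
  expect_equal(mk(1100)$load_class, "Hi")   # excess 0.1 exactly
  expect_equal(mk(20100)$load_class, "Hi")  # excess 2.0
  neg <- call_mrd(make_table(n_cd45 = 1e6), panel)
  expect_error(classify_load(neg), "positive")
})

test_that("ties between categories use the canonical order and are flagged", {
  panel <- make_panel(default = 0.01)
  fu <- make_table(c(`CD34+CD117+HLA-DR+ CD7pos` = 300,
                     `CD34+CD117+HLA-DR+ CD56pos` = 300), n_cd45 = 1e6)
  res <- call_mrd(fu, panel)
  expect_equal(res$load_category, "CD7pos")  # CD7pos precedes CD56pos
  expect_true(res$load_tie)
})

test_that("calling validates its inputs", {
  panel <- make_panel(default = 0.01)
  expect_error(call_mrd(make_table(n_cd45 = 0), panel), "non-evaluable")
  bad_panel <- panel
  bad_panel$values <- bad_panel$values[-1, ]
  expect_error(call_mrd(make_table(n_cd45 = 100), bad_panel), "missing")
  expect_error(call_mrd(make_table(n_cd45 = 100), panel, diagnosis = 1),
               "alaip_profile")
})
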