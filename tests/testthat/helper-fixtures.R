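# Shared fixtures: hand-built event matrices, minimal subpopulation
# tables and reference panels, and an independent brute-force pairwise
# Krippendorff's-alpha oracle.

# event matrix with sensible defaults, overridable per marker
make_events <- function(n, ..., sample_id = "fix", sample_kind = "followup") {
  defaults <- c(`FSC-A` = 400, `FSC-H` = 400, `SSC-A` = 150,
                CD7 = 0.5, CD13 = 3.5, CD33 = 3.5, CD34 = 0.5,
                CD45 = 4.0, CD56 = 0.5, CD117 = 0.5, `HLA-DR` = 0.5)
  m <- matrix(rep(defaults, each = n), nrow = n,
              dimnames = list(NULL, names(defaults)))
  over <- list(...)
  for (nm in names(over)) m[, nm] <- over[[nm]]
  event_matrix(m, sample_id = sample_id, sample_kind = sample_kind)
}

# minimal subpop_table from named per-subpopulation counts
make_table <- function(counts = integer(0), n_cd45 = 1e6, n_mypm = NULL,
                       cohort = NULL, sample_id = "tab") {
  subs <- enumerate_subpopulations()
  subs$count <- 0L
  if (length(counts)) {
    stopifnot(all(names(counts) %in% subs$id))
    subs$count[match(names(counts), subs$id)] <- as.integer(counts)
  }
  subs$pct <- 100 * subs$count / n_cd45
  bb <- unique(subs$backbone)
  main <- data.frame(backbone = bb, count = 0L, pct = 0, stringsAsFactors = FALSE)
  if (is.null(n_mypm)) n_mypm <- sum(subs$count)
  structure(list(main = main, subpops = subs, n_cd45 = n_cd45,
                 n_mypm = n_mypm, n_events = n_cd45, n_singlet = n_cd45,
                 n_pm = n_mypm, evaluable = n_cd45 >= 1,
                 sample_id = sample_id, cohort_label = cohort),
            class = "subpop_table")
}

# reference panel with a flat default and named overrides
make_panel <- function(default = 1, ...) {
  subs <- enumerate_subpopulations()
  ref <- stats::setNames(rep(default, nrow(subs)), subs$id)
  over <- unlist(list(...))
  ref[names(over)] <- over
  v <- subs[, c("id", "backbone", "category", "immature")]
  v$ref_pct <- unname(ref[v$id])
  v$driving_cohort <- "BMD"
  v$tie <- FALSE
  structure(list(values = v, n_controls = 90, prob = 0.975,
                 quantile_type = 7, method = "fixture",
                 cohort_sizes = table(c("BMD"))),
            class = "mrd_reference")
}

# Brute-force pairwise Krippendorff's alpha, written independently of
# the coincidence-matrix implementation: explicit loops over all ordered
# within-unit pairs (observed disagreement, each unit's pairs weighted
# by 1/(m_u - 1)) and over all ordered pairs of pooled values (expected
# disagreement).
oracle_kripp <- function(ratings, metric = "nominal") {
  d <- switch(metric,
              nominal = function(a, b) as.numeric(a != b),
              interval = function(a, b) (a - b)^2,
              ratio = function(a, b) if (a + b == 0) 0 else ((a - b) / (a + b))^2)
  pooled <- c()
  d_obs_num <- 0
  for (u in seq_len(nrow(ratings))) {
    x <- ratings[u, ]
    x <- x[!is.na(x)]
    if (length(x) < 2) next
    pooled <- c(pooled, x)
    for (i in seq_along(x)) for (j in seq_along(x)) {
      if (i == j) next
      d_obs_num <- d_obs_num + d(x[i], x[j]) / (length(x) - 1)
    }
  }
  n <- length(pooled)
  d_obs <- d_obs_num / n
  d_exp_num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d_exp_num <- d_exp_num + d(pooled[i], pooled[j])
  }
  d_exp <- d_exp_num / (n * (n - 1))
  if (d_exp == 0) return(1)
  1 - d_obs / d_exp
}
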