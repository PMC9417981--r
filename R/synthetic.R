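# Synthetic bone-marrow simulator: leukemia-free marrow (lymphocytes,
# monocytes, granulocytes, CD34+ progenitors, erythroid/CD45- cells,
# debris, doublets, low-frequency background aberrancies) and AML
# samples with leukemic clones carrying configurable aberrant categories
# at configurable residual fractions. Events are generated directly on
# the transformed scale; every event is kept outside a guard band around
# each fixed threshold so that ground-truth labels are exact.

#' Specify a leukemic clone
#'
#' @param backbone Target backbone: logical `cd34`, `cd117`, `hladr`.
#' @param categories Subset of [aberrant_categories()]; `CD13neg` and
#'   `CD33neg` are mutually exclusive because a clone deficient in both
#'   myeloid markers could not pass the myP/M gate.
#' @param fraction Clone size as a fraction of CD45+ events.
#' @return An object of class `clone_spec`.
#' @examples
#' clone_spec(cd34 = TRUE, cd117 = TRUE, hladr = FALSE,
#'            categories = c("CD13neg", "CD56pos"), fraction = 0.3)
#' @export
clone_spec <- function(cd34, cd117, hladr, categories, fraction) {
  categories <- match.arg(categories, aberrant_categories(),
                          several.ok = TRUE)
  if (all(c("CD13neg", "CD33neg") %in% categories))
    stop("a clone deficient in both CD13 and CD33 cannot pass the myP/M gate")
  if (fraction < 0 || fraction >= 1)
    stop("clone fraction must be in [0, 1)")
  structure(list(cd34 = cd34, cd117 = cd117, hladr = hladr,
                 categories = categories, fraction = fraction,
                 backbone = backbone_label(cd34, cd117, hladr)),
            class = "clone_spec")
}

# Normal marrow constituents. Fractions are of singlet, non-debris
# events and sum to 1; boxes are placed strictly inside/outside the
# default gate regions. Marker locations are on the transformed (asinh)
# display scale where negatives sit near 0.5 and positives near 3.5-4.5.
default_marrow_populations <- function() {
  pop <- function(name, fraction, cd45, ssc, fluor = list(), side = character()) {
    list(name = name, fraction = fraction, cd45 = cd45, ssc = ssc,
         fluor = fluor, side = side)
  }
  list(
    pop("t_lymphocytes", 0.16, cd45 = c(5.7, 7.3), ssc = c(20, 230),
        fluor = list(CD7 = c(4.5, 0.35)), side = c(CD7 = "above")),
    pop("b_lymphocytes", 0.05, cd45 = c(5.7, 7.3), ssc = c(20, 230),
        fluor = list(`HLA-DR` = c(3.6, 0.4)), side = c(`HLA-DR` = "above")),
    pop("nk_cells", 0.03, cd45 = c(5.7, 7.3), ssc = c(20, 230),
        fluor = list(CD56 = c(4.2, 0.4)), side = c(CD56 = "above")),
    pop("monocytes", 0.09, cd45 = c(3.8, 4.9), ssc = c(150, 340),
        fluor = list(CD13 = c(3.2, 0.4), CD33 = c(4.2, 0.4),
                     `HLA-DR` = c(3.4, 0.4)),
        side = c(CD13 = "above", CD33 = "above", `HLA-DR` = "above")),
    pop("progenitors", 0.02, cd45 = c(2.4, 3.4), ssc = c(30, 200),
        fluor = list(CD13 = c(3.0, 0.4), CD33 = c(3.3, 0.4),
                     CD34 = c(3.6, 0.4), CD117 = c(3.4, 0.4),
                     `HLA-DR` = c(3.3, 0.4)),
        side = c(CD13 = "above", CD33 = "above", CD34 = "above",
                 CD117 = "above", `HLA-DR` = "above")),
    pop("granulocytes", 0.59, cd45 = c(2.6, 4.6), ssc = c(420, 900),
        fluor = list(CD13 = c(3.4, 0.5), CD33 = c(3.1, 0.5)),
        side = c(CD13 = "above", CD33 = "above")),
    pop("erythroid", 0.06, cd45 = c(0.05, NA), ssc = c(20, 120))
  )
}

# threshold governing each fluorescence marker
marker_threshold <- function(marker, config) {
  switch(marker,
         CD13 = config$thresholds$cd13_pos,
         CD33 = config$thresholds$cd33_pos,
         CD34 = config$thresholds$cd34_pos,
         CD117 = config$thresholds$cd117_pos,
         `HLA-DR` = config$thresholds$hladr_pos,
         CD7 = config$thresholds$cd7_strong,
         CD56 = config$thresholds$cd56_strong)
}

clamp_side <- function(x, thr, side, guard) {
  switch(side,
         above = pmax(x, thr + guard),
         below = pmin(x, thr - guard),
         free = x)
}

# Draw n events for one population spec; erythroid CD45 is clamped below
# the CD45 cutoff instead of into a box.
draw_population <- function(n, spec, config, guard) {
  if (n == 0L) return(NULL)
  m <- matrix(0, n, length(mrd_markers()),
              dimnames = list(NULL, mrd_markers()))
  fsca <- pmin(pmax(stats::rnorm(n, 420, 60), config$fsc_min + 4 * guard), 1000)
  ratio <- stats::runif(n, 0.95, 1.05)
  m[, "FSC-A"] <- fsca
  m[, "FSC-H"] <- fsca / ratio
  lo <- spec$ssc[1]; hi <- spec$ssc[2]
  m[, "SSC-A"] <- pmin(pmax(stats::rnorm(n, (lo + hi) / 2, (hi - lo) / 5), lo), hi)
  c45 <- spec$cd45
  if (is.na(c45[2])) {      # CD45-negative population
    m[, "CD45"] <- pmin(pmax(stats::rnorm(n, 0.4, 0.25), c45[1]),
                        config$cd45_threshold - guard)
  } else {
    m[, "CD45"] <- pmin(pmax(stats::rnorm(n, (c45[1] + c45[2]) / 2,
                                          (c45[2] - c45[1]) / 5), c45[1]), c45[2])
  }
  for (mk in fluor_markers()) {
    if (mk == "CD45") next
    par <- spec$fluor[[mk]]
    side <- if (mk %in% names(spec$side)) spec$side[[mk]] else "below"
    if (is.null(par)) par <- c(0.5, 0.3)
    x <- stats::rnorm(n, par[1], par[2])
    m[, mk] <- clamp_side(x, marker_threshold(mk, config), side, guard)
  }
  m
}

# Aberrant (clone or background) events: myP/M box with backbone and
# category markers forced to their intended sides.
draw_aberrant <- function(n, cd34, cd117, hladr, categories, config, guard) {
  pos <- c(3.6, 0.4); neg <- c(0.5, 0.3); strong <- c(4.3, 0.4)
  fluor <- list(CD34 = if (cd34) pos else neg,
                CD117 = if (cd117) pos else neg,
                `HLA-DR` = if (hladr) pos else neg,
                CD13 = if ("CD13neg" %in% categories) neg else pos,
                CD33 = if ("CD33neg" %in% categories) neg else pos,
                CD7 = if ("CD7pos" %in% categories) strong else neg,
                CD56 = if ("CD56pos" %in% categories) strong else neg)
  side <- c(CD34 = if (cd34) "above" else "below",
            CD117 = if (cd117) "above" else "below",
            `HLA-DR` = if (hladr) "above" else "below",
            CD13 = if ("CD13neg" %in% categories) "below" else "above",
            CD33 = if ("CD33neg" %in% categories) "below" else "above",
            CD7 = if ("CD7pos" %in% categories) "above" else "below",
            CD56 = if ("CD56pos" %in% categories) "above" else "below")
  spec <- list(name = "aberrant", cd45 = c(2.3, 4.8), ssc = c(30, 330),
               fluor = fluor, side = side)
  draw_population(n, spec, config, guard)
}

# P/M blasts lacking both myeloid markers; enter the P/M gate but not
# myP/M. Used to emulate the non-myeloid share of the P/M gate.
draw_nonmyeloid_blasts <- function(n, config, guard) {
  spec <- list(name = "nonmyeloid_blasts", cd45 = c(2.3, 4.8), ssc = c(30, 330),
               fluor = list(CD34 = c(3.6, 0.4), CD117 = c(3.4, 0.4),
                            `HLA-DR` = c(3.4, 0.4)),
               side = c(CD34 = "above", CD117 = "above", `HLA-DR` = "above",
                        CD13 = "below", CD33 = "below"))
  draw_population(n, spec, config, guard)
}

#' Per-cohort background-aberrancy parameters for leukemia-free marrow
#'
#' Background frequencies of the 32 aberrant subpopulations are modeled
#' as zero-inflated lognormal percentages of CD45+ events: with
#' probability `p_present` a subpopulation is present at a
#' `rlnorm(meanlog, sdlog)` percentage (capped at `cap_pct`). Cohorts
#' differ in their tails, mirroring leukemia-free marrow: prior
#' chemotherapy exposure (ALL in molecular remission) inflates
#' cross-lineage CD56 and CD13 deficiency, older hip-surgery patients
#' show more CD33 deficiency, bone-marrow donors carry mild CD7
#' cross-lineage signal, and untreated PCNSL marrow is quietest.
#' Subpopulations without markers of immaturity get a higher baseline.
#'
#' @param cohort One of `"BMD"`, `"ALL_molCR"`, `"hip_surgery"`,
#'   `"PCNSL"`.
#' @return Data frame with one row per subpopulation: `id`, `p_present`,
#'   `meanlog`, `sdlog`, `cap_pct`.
#' @export
lfc_background_params <- function(cohort = c("BMD", "ALL_molCR",
                                             "hip_surgery", "PCNSL")) {
  cohort <- match.arg(cohort)
  subs <- enumerate_subpopulations()
  out <- data.frame(id = subs$id, p_present = 0.35,
                    meanlog = log(0.004), sdlog = 0.7, cap_pct = 2.5,
                    stringsAsFactors = FALSE)
  out$meanlog[!subs$immature] <- out$meanlog[!subs$immature] + log(4)
  boost <- function(sel, p, mu, sd) {
    out$p_present[sel] <<- p
    out$meanlog[sel] <<- mu
    out$sdlog[sel] <<- sd
  }
  if (cohort == "ALL_molCR")
    boost(subs$category %in% c("CD56pos", "CD13neg"), 0.75, log(0.06), 1.1)
  if (cohort == "hip_surgery")
    boost(subs$category == "CD33neg", 0.6, log(0.04), 0.9)
  if (cohort == "BMD")
    boost(subs$category == "CD7pos", 0.55, log(0.025), 0.8)
  if (cohort == "PCNSL")
    out$p_present <- out$p_present * 0.5
  out
}

#' Simulate one bone-marrow sample with exact ground truth
#'
#' Draws `n_events` events from Gaussian population components on the
#' transformed scale: normal marrow constituents, optional leukemic
#' clones (fractions of CD45+ events), optional zero-inflated lognormal
#' background aberrancies, doublets and debris. No event is generated
#' within `guard` of a fixed threshold (nor inside a margin of the gate
#' polygons), so the returned ground truth matches the gating pipeline
#' exactly; set `guard = 0` for robustness testing of borderline events.
#'
#' @param n_events Total events (default 500,000, the targeted
#'   acquisition per tube).
#' @param clones List of [clone_spec()] objects.
#' @param background `NULL`, or a data frame as returned by
#'   [lfc_background_params()].
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param sample_id,sample_kind,cohort_label Sample metadata, see
#'   [event_matrix()].
#' @param config The [gate_config()] the generator is calibrated against.
#' @param guard Guard band around fixed thresholds, transformed units.
#' @param doublet_rate,debris_rate Fractions of total events.
#' @param pm_nonmyeloid_fraction Fraction of CD45+ events drawn as P/M
#'   blasts lacking both CD13 and CD33 (default 0: in leukemia-free
#'   marrow essentially all P/M events are myeloid).
#' @return An object of class `mrd_simulation`: `events` (an
#'   [event_matrix()]) and `truth` (per-event `origin`, exact
#'   subpopulation and main-population counts, `n_cd45`, clone
#'   bookkeeping).
#' @export
simulate_sample <- function(n_events = 500000, clones = list(),
                            background = NULL, seed,
                            sample_id = "synthetic", sample_kind = "lfc",
                            cohort_label = NULL,
                            config = gate_config(), guard = 0.2,
                            doublet_rate = 0.02, debris_rate = 0.03,
                            pm_nonmyeloid_fraction = 0) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  if (n_events < 1) stop("n_events must be >= 1")
  if (length(clones) && !all(vapply(clones, inherits, TRUE, "clone_spec")))
    stop("clones must be a list of clone_spec objects")
  set.seed(seed)
  pops <- default_marrow_populations()
  n_doublet <- round(doublet_rate * n_events)
  n_debris <- round(debris_rate * n_events)
  n_rest <- n_events - n_doublet - n_debris
  f_ery <- pops[[which(vapply(pops, `[[`, "", "name") == "erythroid")]]$fraction
  n_cd45 <- round(n_rest * (1 - f_ery))
  n_ery <- n_rest - n_cd45

  # CD45+ budget: clones and extra P/M blasts (deterministic counts),
  # background aberrancies (Poisson), remainder to normal populations.
  n_clone <- vapply(clones, function(cl) round(cl$fraction * n_cd45), 0)
  n_nm <- round(pm_nonmyeloid_fraction * n_cd45)
  bg_counts <- integer(0)
  bg_ids <- character(0)
  if (!is.null(background)) {
    present <- stats::rbinom(nrow(background), 1L, background$p_present) == 1L
    pct <- ifelse(present,
                  pmin(stats::rlnorm(nrow(background), background$meanlog,
                                     background$sdlog), background$cap_pct), 0)
    bg_counts <- stats::rpois(nrow(background), pct / 100 * n_cd45)
    bg_ids <- background$id
  }
  n_aberrant <- sum(n_clone) + sum(bg_counts) + n_nm
  if (n_aberrant > n_cd45)
    stop("clone/background fractions exceed the CD45+ budget")
  n_norm <- n_cd45 - n_aberrant
  norm_pops <- Filter(function(p) p$name != "erythroid", pops)
  w <- vapply(norm_pops, `[[`, 0, "fraction")
  n_per_pop <- as.integer(stats::rmultinom(1L, n_norm, w / sum(w)))

  subs <- enumerate_subpopulations()
  chunks <- list(); origin <- list()
  for (i in seq_along(norm_pops)) {
    chunks[[length(chunks) + 1L]] <-
      draw_population(n_per_pop[i], norm_pops[[i]], config, guard)
    origin[[length(origin) + 1L]] <- rep(norm_pops[[i]]$name, n_per_pop[i])
  }
  ery_spec <- pops[[which(vapply(pops, `[[`, "", "name") == "erythroid")]]
  chunks[[length(chunks) + 1L]] <- draw_population(n_ery, ery_spec, config, guard)
  origin[[length(origin) + 1L]] <- rep("erythroid", n_ery)
  if (n_nm > 0) {
    chunks[[length(chunks) + 1L]] <- draw_nonmyeloid_blasts(n_nm, config, guard)
    origin[[length(origin) + 1L]] <- rep("nonmyeloid_blasts", n_nm)
  }
  for (i in seq_along(clones)) {
    cl <- clones[[i]]
    chunks[[length(chunks) + 1L]] <-
      draw_aberrant(n_clone[i], cl$cd34, cl$cd117, cl$hladr,
                    cl$categories, config, guard)
    origin[[length(origin) + 1L]] <- rep(paste0("clone", i), n_clone[i])
  }
  for (i in seq_along(bg_counts)) {
    if (bg_counts[i] == 0L) next
    row <- subs[subs$id == bg_ids[i], ]
    chunks[[length(chunks) + 1L]] <-
      draw_aberrant(bg_counts[i], row$cd34, row$cd117, row$hladr,
                    row$category, config, guard)
    origin[[length(origin) + 1L]] <- rep(paste0("bg:", bg_ids[i]), bg_counts[i])
  }
  if (n_debris > 0) {
    debris_spec <- list(name = "debris", cd45 = c(0.05, NA), ssc = c(1, 60),
                        fluor = list(), side = character())
    deb <- draw_population(n_debris, debris_spec, config, guard)
    deb[, "FSC-A"] <- stats::runif(n_debris, 5, config$fsc_min - 2 * guard - 10)
    deb[, "FSC-H"] <- deb[, "FSC-A"] / stats::runif(n_debris, 0.95, 1.05)
    chunks[[length(chunks) + 1L]] <- deb
    origin[[length(origin) + 1L]] <- rep("debris", n_debris)
  }
  if (n_doublet > 0) {
    dbl <- draw_population(n_doublet, norm_pops[[1L]], config, guard)
    dbl[, "FSC-A"] <- 2 * dbl[, "FSC-H"]
    chunks[[length(chunks) + 1L]] <- dbl
    origin[[length(origin) + 1L]] <- rep("doublet", n_doublet)
  }
  values <- do.call(rbind, chunks)
  origin <- unlist(origin)
  perm <- sample.int(nrow(values))
  values <- values[perm, , drop = FALSE]
  origin <- origin[perm]

  # exact ground truth from the generator's bookkeeping
  true_counts <- stats::setNames(integer(nrow(subs)), subs$id)
  for (i in seq_along(clones)) {
    cl <- clones[[i]]
    for (cc in cl$categories) {
      id <- paste(cl$backbone, cc)
      true_counts[id] <- true_counts[id] + n_clone[i]
    }
  }
  if (length(bg_counts))
    for (i in seq_along(bg_counts))
      true_counts[bg_ids[i]] <- true_counts[bg_ids[i]] + bg_counts[i]
  main_true <- stats::setNames(integer(8L), backbone_levels())
  main_true["CD34-CD117-HLA-DR+"] <-
    n_per_pop[which(vapply(norm_pops, `[[`, "", "name") == "monocytes")]
  main_true["CD34+CD117+HLA-DR+"] <- main_true["CD34+CD117+HLA-DR+"] +
    n_per_pop[which(vapply(norm_pops, `[[`, "", "name") == "progenitors")]
  for (i in seq_along(clones))
    main_true[clones[[i]]$backbone] <- main_true[clones[[i]]$backbone] + n_clone[i]
  if (length(bg_counts))
    for (i in seq_along(bg_counts)) {
      bb <- subs$backbone[subs$id == bg_ids[i]]
      main_true[bb] <- main_true[bb] + bg_counts[i]
    }

  events <- event_matrix(values, sample_id = sample_id,
                         sample_kind = sample_kind,
                         cohort_label = cohort_label)
  structure(list(events = events,
                 truth = list(origin = origin,
                              subpop_counts = true_counts,
                              main_counts = main_true,
                              n_cd45 = n_cd45,
                              n_mypm = sum(main_true),
                              clone_counts = n_clone,
                              seed = seed)),
            class = "mrd_simulation")
}

#' @export
print.mrd_simulation <- function(x, ...) {
  cat(sprintf("<mrd_simulation> %s: %d events, %d CD45+ (truth), %d myP/M (truth), seed %d\n",
              x$events$sample_id, x$events$n_events, x$truth$n_cd45,
              x$truth$n_mypm, x$truth$seed))
  invisible(x)
}

#' Simulate a leukemia-free control cohort
#'
#' Generates `n_samples` control samples split across the four control
#' subcohorts (defaults 30 bone-marrow donors, 19 ALL in molecular
#' remission, 32 hip-surgery patients, 9 untreated PCNSL), each with
#' cohort-specific background-aberrancy tails
#' ([lfc_background_params()]), then gates and tabulates them.
#'
#' @param n_samples Number of control samples (default 90).
#' @param cohort_mix Named integer vector of per-cohort sample counts;
#'   must sum to `n_samples`.
#' @param n_events Events per sample.
#' @param seed Integer seed.
#' @param config A [gate_config()].
#' @param keep_events If `TRUE`, also return the simulations.
#' @param background_fn Function `cohort -> background data frame`.
#' @return List with `tables` (list of `subpop_table` with cohort
#'   labels) and, when requested, `simulations`.
#' @export
generate_lfc_cohort <- function(n_samples = 90,
                                cohort_mix = c(BMD = 30, ALL_molCR = 19,
                                               hip_surgery = 32, PCNSL = 9),
                                n_events = 500000, seed,
                                config = gate_config(),
                                keep_events = FALSE,
                                background_fn = lfc_background_params) {
  if (missing(seed)) stop("seed is mandatory")
  if (sum(cohort_mix) != n_samples)
    stop("cohort_mix must sum to n_samples")
  if (n_samples < 2) stop("need at least 2 control samples")
  if (n_samples < 10)
    warning("minimal control cohort (n = ", n_samples,
            "); reference values will be unstable")
  labels <- rep(names(cohort_mix), cohort_mix)
  tables <- vector("list", n_samples)
  sims <- if (keep_events) vector("list", n_samples) else NULL
  for (i in seq_len(n_samples)) {
    sim <- simulate_sample(n_events = n_events,
                           background = background_fn(labels[i]),
                           seed = (seed + 7919L * i) %% .Machine$integer.max,
                           sample_id = sprintf("lfc_%02d_%s", i, labels[i]),
                           sample_kind = "lfc", cohort_label = labels[i],
                           config = config)
    tables[[i]] <- tabulate_sample(sim$events, config)
    if (keep_events) sims[[i]] <- sim
  }
  out <- list(tables = tables, cohorts = labels, seed = seed)
  if (keep_events) out$simulations <- sims
  out
}

#' Simulate a paired diagnosis / follow-up AML patient
#'
#' The diagnosis sample carries the leukemic clone at `diagnosis_fraction`
#' of CD45+ events (large enough to qualify its categories as aLAIP); the
#' follow-up sample carries the same clone scaled down to
#' `residual_fraction`, optionally with a shifted category set to
#' exercise post-treatment DfN calls. The non-myeloid share of the P/M
#' gate defaults to 6% at diagnosis and 16% at follow-up, matching the
#' observed medians (94% and 84% myeloid).
#'
#' @param diagnosis_clone A [clone_spec()]; its `fraction` field is
#'   ignored in favour of `diagnosis_fraction`.
#' @param residual_fraction Residual clone size at follow-up, fraction of
#'   CD45+ events in `[0, 1)`.
#' @param phenotype_shift Optional character vector: the clone's category
#'   set at follow-up (e.g. shift `CD13neg` to `CD56pos`).
#' @param seed Integer seed.
#' @param n_events Events per sample.
#' @param diagnosis_fraction Clone fraction of CD45+ at diagnosis
#'   (default 0.3).
#' @param pm_myeloid_diag,pm_myeloid_fu Target myeloid share of the P/M
#'   gate at diagnosis and follow-up.
#' @param config A [gate_config()].
#' @return List with `diagnosis` and `followup` (both `mrd_simulation`).
#' @export
generate_patient_pair <- function(diagnosis_clone, residual_fraction,
                                  phenotype_shift = NULL, seed,
                                  n_events = 500000,
                                  diagnosis_fraction = 0.3,
                                  pm_myeloid_diag = 0.94,
                                  pm_myeloid_fu = 0.84,
                                  config = gate_config()) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(diagnosis_clone, "clone_spec"))
  if (residual_fraction < 0 || residual_fraction >= 1)
    stop("residual_fraction must be in [0, 1)")
  # non-myeloid P/M fraction solving for the target myeloid share, given
  # the normal monocyte+progenitor share of CD45+ normals (0.11/0.94)
  nm_fraction <- function(f_clone, target) {
    a <- 0.11 / 0.94
    (1 - target) * (a + f_clone * (1 - a)) / (target + (1 - target) * a)
  }
  diag_clone <- diagnosis_clone
  diag_clone$fraction <- diagnosis_fraction
  dx <- simulate_sample(n_events = n_events, clones = list(diag_clone),
                        seed = seed %% .Machine$integer.max,
                        sample_id = "diagnosis", sample_kind = "diagnosis",
                        config = config,
                        pm_nonmyeloid_fraction = nm_fraction(diagnosis_fraction,
                                                             pm_myeloid_diag))
  fu_clone <- diagnosis_clone
  fu_clone$fraction <- residual_fraction
  if (!is.null(phenotype_shift)) {
    fu_clone$categories <- match.arg(phenotype_shift, aberrant_categories(),
                                     several.ok = TRUE)
    if (all(c("CD13neg", "CD33neg") %in% fu_clone$categories))
      stop("shifted clone cannot be deficient in both CD13 and CD33")
  }
  clones_fu <- if (residual_fraction > 0) list(fu_clone) else list()
  fu <- simulate_sample(n_events = n_events, clones = clones_fu,
                        seed = (seed + 104729L) %% .Machine$integer.max,
                        sample_id = "followup", sample_kind = "followup",
                        config = config,
                        pm_nonmyeloid_fraction = nm_fraction(residual_fraction,
                                                             pm_myeloid_fu))
  list(diagnosis = dx, followup = fu)
}
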