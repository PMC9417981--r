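# Diagnosis LAIP detection and follow-up MRD calling: >=20-event filter,
# per-subpopulation reference excess, category aggregation, max-category
# MRD load, aLAIP vs post-treatment-DfN origin, and the alternative
# calling schemes (ELN 0.1%, Lo/Hi load split, immature-only).

#' Detect aberrant LAIP categories in a diagnosis sample
#'
#' An aberrant category qualifies as LAIP (aLAIP) when at least
#' `threshold_pct` percent of myP/M events carry it (default 10; the
#' alternative thresholds 5, 2.5 and 1 are supported). Categories present
#' below the threshold are recorded as minor clones.
#'
#' @param diagnosis A `subpop_table` of the diagnosis sample (bone marrow
#'   or peripheral blood).
#' @param threshold_pct aLAIP threshold in percent of myP/M (default 10).
#' @return An object of class `alaip_profile` with `pct_of_mypm` per
#'   category, `alaip_set` and `minor_clones`.
#' @export
detect_alaip <- function(diagnosis, threshold_pct = 10) {
  stopifnot(inherits(diagnosis, "subpop_table"))
  if (!threshold_pct %in% c(10, 5, 2.5, 1))
    warning("non-standard aLAIP threshold: ", threshold_pct,
            "% (supported defaults are 10, 5, 2.5, 1)")
  cats <- aberrant_categories()
  if (diagnosis$n_mypm < 1) {
    warning("diagnosis sample has no myP/M events; empty LAIP profile")
    pct <- stats::setNames(rep(NA_real_, length(cats)), cats)
    return(structure(list(pct_of_mypm = pct, alaip_threshold = threshold_pct,
                          alaip_set = character(0), minor_clones = character(0),
                          sample_id = diagnosis$sample_id),
                     class = "alaip_profile"))
  }
  # category counts are % of CD45+; rescale to % of myP/M via event counts
  counts <- vapply(cats, function(cc)
    sum(diagnosis$subpops$count[diagnosis$subpops$category == cc]), 0)
  pct <- 100 * counts / diagnosis$n_mypm
  structure(list(pct_of_mypm = pct, alaip_threshold = threshold_pct,
                 alaip_set = cats[pct >= threshold_pct],
                 minor_clones = cats[pct > 0 & pct < threshold_pct],
                 sample_id = diagnosis$sample_id),
            class = "alaip_profile")
}

#' @export
print.alaip_profile <- function(x, ...) {
  cat(sprintf("<alaip_profile> %s (threshold %g%% of myP/M)\n",
              x$sample_id, x$alaip_threshold))
  for (cc in names(x$pct_of_mypm))
    cat(sprintf("  %s: %.2f%% of myP/M%s\n", cc, x$pct_of_mypm[[cc]],
                if (cc %in% x$alaip_set) "  [aLAIP]"
                else if (cc %in% x$minor_clones) "  [minor clone]" else ""))
  if (!length(x$alaip_set)) cat("  no aLAIP at this threshold\n")
  invisible(x)
}

#' Call MRD on a follow-up sample
#'
#' Applies the different-from-normal calling rules: (i) only
#' subpopulations with at least `min_events` events are analyzed
#' (default 20); (ii) a sample is MRD positive when at least one analyzed
#' aberrant subpopulation strictly exceeds its reference value; (iii) the
#' excess over the reference (disease burden, in % of CD45+ cells) is
#' summed per aberrant category, and only the category with the highest
#' sum quantifies the MRD load; (iv) a positive category already
#' qualifying as aLAIP at diagnosis marks reoccurrence (origin aLAIP),
#' otherwise its de-novo appearance is post-treatment DfN (ptDfN).
#'
#' The alternative schemes are evaluated alongside: the ELN-style call
#' ([call_mrd_eln()]), the immature-only call ([call_mrd_immonly()]) and
#' the Lo/Hi load split ([classify_load()]).
#'
#' @param followup A `subpop_table` of the follow-up sample.
#' @param panel An `mrd_reference`.
#' @param diagnosis Optional `alaip_profile`; when absent, origin is
#'   `no_diagnosis`.
#' @param min_events Minimum events per subpopulation (default 20).
#' @param load_split Lo/Hi split on the per-subpopulation excess
#'   (default 0.1, in percentage points of CD45+).
#' @return An object of class `mrd_result`.
#' @export
call_mrd <- function(followup, panel, diagnosis = NULL, min_events = 20,
                     load_split = 0.1) {
  stopifnot(inherits(followup, "subpop_table"), inherits(panel, "mrd_reference"))
  if (!followup$evaluable || followup$n_cd45 < 1)
    stop("follow-up sample is non-evaluable (no CD45+ events)")
  if (!is.null(diagnosis) && !inherits(diagnosis, "alaip_profile"))
    stop("diagnosis must be an alaip_profile (see detect_alaip())")
  sp <- followup$subpops
  ref <- panel$values$ref_pct[match(sp$id, panel$values$id)]
  if (anyNA(ref))
    stop("reference panel is missing subpopulation(s): ",
         paste(sp$id[is.na(ref)], collapse = ", "))
  analyzed <- sp$count >= min_events
  positive <- analyzed & sp$pct > ref
  pos <- data.frame(id = sp$id[positive], backbone = sp$backbone[positive],
                    category = sp$category[positive],
                    count = sp$count[positive], pct = sp$pct[positive],
                    ref_pct = ref[positive],
                    burden = sp$pct[positive] - ref[positive],
                    stringsAsFactors = FALSE)
  cats <- aberrant_categories()
  category_sums <- vapply(cats, function(cc)
    sum(pos$burden[pos$category == cc]), 0)
  status <- if (nrow(pos)) "pos" else "neg"
  if (status == "pos") {
    mrd_load <- max(category_sums)
    winners <- cats[category_sums == mrd_load]
    load_category <- winners[1L]          # canonical category order
    load_tie <- length(winners) > 1L
  } else {
    mrd_load <- 0
    load_category <- NA_character_
    load_tie <- FALSE
  }
  pos_cats <- cats[category_sums > 0]
  origin <- if (status == "neg") NA_character_
  else if (is.null(diagnosis)) "no_diagnosis"
  else {
    in_alaip <- pos_cats %in% diagnosis$alaip_set
    if (all(in_alaip)) "aLAIP_only"
    else if (!any(in_alaip)) "ptDfN_only"
    else "aLAIP_and_ptDfN"
  }
  result <- structure(list(status = status,
                           positive_subpops = pos,
                           category_sums = category_sums,
                           mrd_load = mrd_load,
                           load_category = load_category,
                           load_tie = load_tie,
                           origin = origin,
                           load_class = NA_character_,
                           eln_status = call_mrd_eln(followup,
                                                     min_events = min_events),
                           immonly_status = call_mrd_immonly(followup, panel,
                                                             min_events = min_events),
                           non_evaluable_subpops = sp$id[!analyzed],
                           min_events = min_events,
                           n_cd45 = followup$n_cd45,
                           sample_id = followup$sample_id),
                      class = "mrd_result")
  if (status == "pos")
    result$load_class <- classify_load(result, split = load_split)
  result
}

#' ELN-style uniform 0.1% MRD call
#'
#' Restricts the analysis to the 24 aberrant subpopulations expressing at
#' least one marker of immaturity (CD34 and/or CD117) and replaces the
#' individual reference values by a uniform cutoff of 0.1% of CD45+
#' events. The minimum-event filter is kept (configurable).
#'
#' @inheritParams call_mrd
#' @param cutoff Uniform positivity cutoff in % of CD45+ (default 0.1,
#'   reached with `>=`).
#' @return `"pos"` or `"neg"`.
#' @export
call_mrd_eln <- function(followup, min_events = 20, cutoff = 0.1) {
  stopifnot(inherits(followup, "subpop_table"))
  if (!followup$evaluable) stop("follow-up sample is non-evaluable")
  sp <- followup$subpops
  imm <- enumerate_subpopulations(immature_only = TRUE)$id
  hit <- sp$id %in% imm & sp$count >= min_events & sp$pct >= cutoff
  if (any(hit)) "pos" else "neg"
}

#' Immature-only MRD call
#'
#' The full calling rules of [call_mrd()] restricted to the 24
#' subpopulations with at least one marker of immaturity; reference
#' values are unchanged. Positivity under this scheme implies positivity
#' under the full scheme.
#'
#' @inheritParams call_mrd
#' @return `"pos"` or `"neg"`.
#' @export
call_mrd_immonly <- function(followup, panel, min_events = 20) {
  stopifnot(inherits(followup, "subpop_table"), inherits(panel, "mrd_reference"))
  if (!followup$evaluable) stop("follow-up sample is non-evaluable")
  sp <- followup$subpops
  ref <- panel$values$ref_pct[match(sp$id, panel$values$id)]
  if (anyNA(ref)) stop("reference panel is missing subpopulations")
  imm <- enumerate_subpopulations(immature_only = TRUE)$id
  hit <- sp$id %in% imm & sp$count >= min_events & sp$pct > ref
  if (any(hit)) "pos" else "neg"
}

#' Split a positive MRD result into low and high load
#'
#' `Hi` when any positive subpopulation exceeds its reference value by at
#' least `split` (default 0.1 percentage points of CD45+), else `Lo`.
#'
#' @param result A positive `mrd_result`.
#' @param split Excess split point (default 0.1; `>=` counts as `Hi`).
#' @return `"Lo"` or `"Hi"`.
#' @export
classify_load <- function(result, split = 0.1) {
  stopifnot(inherits(result, "mrd_result"))
  if (result$status != "pos")
    stop("load classification is defined for MRD-positive results only")
  if (any(result$positive_subpops$burden >= split)) "Hi" else "Lo"
}

#' @export
print.mrd_result <- function(x, digits = 4, ...) {
  cat(sprintf("MRD call for %s (N_CD45 = %d, min %d events/subpopulation)\n",
              x$sample_id, x$n_cd45, x$min_events))
  cat(sprintf("  status: MRD-%s", x$status))
  if (x$status == "pos")
    cat(sprintf(" (%s)  load %.4g%% of CD45+ [%s%s]  origin: %s",
                x$load_class, x$mrd_load, x$load_category,
                if (x$load_tie) ", tie" else "", x$origin))
  cat("\n")
  cat(sprintf("  alternative schemes: ELN 0.1%% = %s, immature-only = %s\n",
              x$eln_status, x$immonly_status))
  if (nrow(x$positive_subpops)) {
    p <- x$positive_subpops
    p$pct <- round(p$pct, digits); p$ref_pct <- round(p$ref_pct, digits)
    p$burden <- round(p$burden, digits)
    cat("  positive subpopulations:\n")
    print(p[, c("id", "count", "pct", "ref_pct", "burden")], row.names = FALSE)
  }
  n_ne <- length(x$non_evaluable_subpops)
  cat(sprintf("  %d/32 subpopulations below the %d-event minimum\n",
              n_ne, x$min_events))
  invisible(x)
}
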