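# Reference-value estimation from leukemia-free controls: upper limit of
# the one-sided 97.5% reference range per aberrant subpopulation, with
# attribution of each reference value to the control subcohort that
# drives it.

#' Estimate subpopulation reference values from leukemia-free controls
#'
#' For each of the 32 aberrant subpopulations, the reference value is the
#' upper limit of the one-sided 97.5% reference range of its %CD45+
#' frequency across the control samples. The estimator is nonparametric
#' (order statistics with linear interpolation, `stats::quantile`
#' type 7); control frequencies are zero-inflated, so a parametric
#' (Gaussian) limit would be indefensible. Each reference value is
#' attributed to the cohort of the control sample whose frequency
#' determines the quantile (the smallest sample value at or above it);
#' exact ties between cohorts are broken lexicographically and flagged.
#'
#' @param controls List of `subpop_table` objects (see
#'   [tabulate_sample()]), each carrying a `cohort_label`.
#' @param prob Reference-range probability (default 0.975).
#' @param min_samples Minimum number of evaluable controls (default 2).
#' @param quantile_type Quantile algorithm type passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @return An object of class `mrd_reference` with one row per
#'   subpopulation: `ref_pct`, `driving_cohort`, `tie`.
#' @seealso [predict.mrd_reference()] to call MRD on a follow-up sample,
#'   [detectability()] for minimum acquisition requirements.
#' @export
estimate_reference <- function(controls, prob = 0.975, min_samples = 2,
                               quantile_type = 7) {
  if (!length(controls) || !all(vapply(controls, inherits, TRUE, "subpop_table")))
    stop("controls must be a list of subpop_table objects")
  evaluable <- vapply(controls, function(x) isTRUE(x$evaluable), TRUE)
  if (any(!evaluable)) {
    warning(sum(!evaluable), " non-evaluable control sample(s) excluded")
    controls <- controls[evaluable]
  }
  n <- length(controls)
  if (n < min_samples)
    stop("need at least ", min_samples, " evaluable control samples, got ", n)
  cohorts <- vapply(controls, function(x)
    if (is.null(x$cohort_label)) "unlabeled" else x$cohort_label, "")
  subs <- enumerate_subpopulations()
  pct <- vapply(controls, function(x) {
    x$subpops$pct[match(subs$id, x$subpops$id)]
  }, numeric(nrow(subs)))           # 32 x n
  ref <- apply(pct, 1L, stats::quantile, probs = prob, type = quantile_type,
               names = FALSE)
  attr_res <- t(vapply(seq_len(nrow(subs)), function(i) {
    attribute_cohort(pct[i, ], cohorts, ref[i])
  }, c(cohort = "", tie = "")))
  out <- subs[, c("id", "backbone", "category", "immature")]
  out$ref_pct <- ref
  out$driving_cohort <- attr_res[, "cohort"]
  out$tie <- attr_res[, "tie"] == "TRUE"
  structure(list(values = out, n_controls = n, prob = prob,
                 quantile_type = quantile_type,
                 method = sprintf("nonparametric type-%d quantile, p = %g",
                                  quantile_type, prob),
                 cohort_sizes = table(cohorts)),
            class = "mrd_reference")
}

# The determining order statistic: the smallest control value at or above
# the estimated quantile (for the maximum-interpolation edge case where no
# value lies above, the largest value). Ties across cohorts at that value
# are flagged and resolved lexicographically.
attribute_cohort <- function(values, cohorts, ref) {
  at_or_above <- values >= ref
  det_value <- if (any(at_or_above)) min(values[at_or_above]) else max(values)
  det_cohorts <- sort(unique(cohorts[values == det_value]))
  c(cohort = det_cohorts[1L], tie = as.character(length(det_cohorts) > 1L))
}

#' Attribute each reference value to its driving control cohort
#'
#' Standalone form of the attribution performed by [estimate_reference()]:
#' the cohort of the quantile-determining control sample.
#'
#' @inheritParams estimate_reference
#' @param panel An `mrd_reference` estimated from `controls`.
#' @return Data frame with `id`, `driving_cohort`, `tie`.
#' @export
attribute_cohorts <- function(controls, panel) {
  stopifnot(inherits(panel, "mrd_reference"))
  cohorts <- vapply(controls, function(x)
    if (is.null(x$cohort_label)) "unlabeled" else x$cohort_label, "")
  subs <- panel$values
  res <- t(vapply(seq_len(nrow(subs)), function(i) {
    v <- vapply(controls, function(x)
      x$subpops$pct[match(subs$id[i], x$subpops$id)], 0)
    attribute_cohort(v, cohorts, subs$ref_pct[i])
  }, c(cohort = "", tie = "")))
  data.frame(id = subs$id, driving_cohort = res[, "cohort"],
             tie = res[, "tie"] == "TRUE", stringsAsFactors = FALSE)
}

#' Minimum acquisition needed to evaluate each subpopulation
#'
#' With a minimum population size of `min_events` (default 20) at
#' follow-up, a subpopulation with reference value `r` (% of CD45+) can
#' only turn MRD positive when at least `ceil(min_events / (r/100))`
#' CD45+ events are acquired: e.g. a reference value of 0.001% requires
#' 2,000,000 CD45+ events for 20 relevant events. Subpopulations whose
#' requirement exceeds the acquired count are not reliably evaluable.
#'
#' @param panel An `mrd_reference`.
#' @param n_acquired Number of CD45+ events acquired.
#' @param min_events Minimum relevant events (default 20).
#' @return Data frame with `id`, `ref_pct`, `min_required`, `evaluable`.
#' @export
detectability <- function(panel, n_acquired, min_events = 20) {
  stopifnot(inherits(panel, "mrd_reference"), min_events >= 1)
  r <- panel$values$ref_pct
  min_required <- ifelse(r > 0, ceiling(min_events / (r / 100)), min_events)
  data.frame(id = panel$values$id, ref_pct = r,
             min_required = min_required,
             evaluable = n_acquired >= min_required,
             stringsAsFactors = FALSE)
}

#' @export
print.mrd_reference <- function(x, digits = 4, ...) {
  cat(sprintf("MRD reference panel: %d subpopulations, %d controls, %s\n",
              nrow(x$values), x$n_controls, x$method))
  cat(sprintf("Reference values span %.4g%% to %.4g%% of CD45+\n",
              min(x$values$ref_pct), max(x$values$ref_pct)))
  invisible(x)
}

#' @export
summary.mrd_reference <- function(object, ...) {
  v <- object$values
  cat(sprintf("MRD reference panel (%s) from %d leukemia-free controls\n",
              object$method, object$n_controls))
  cat("Cohorts: ", paste(sprintf("%s (n=%d)", names(object$cohort_sizes),
                                 as.integer(object$cohort_sizes)),
                         collapse = ", "), "\n", sep = "")
  cat(sprintf("Reference range: %.4g%% - %.4g%% of CD45+ events\n",
              min(v$ref_pct), max(v$ref_pct)))
  attribution <- sort(table(v$driving_cohort), decreasing = TRUE)
  cat("Reference values mainly influenced by:\n")
  for (i in seq_along(attribution))
    cat(sprintf("  %s: %d/%d (%.0f%%)\n", names(attribution)[i],
                attribution[i], nrow(v), 100 * attribution[i] / nrow(v)))
  invisible(object)
}

#' @export
coef.mrd_reference <- function(object, ...) {
  stats::setNames(object$values$ref_pct, object$values$id)
}

#' Call MRD on a new follow-up tabulation against a reference panel
#'
#' `predict` on an `mrd_reference` is the deployment step: given the
#' subpopulation tabulation of a follow-up sample, it applies the full
#' different-from-normal calling rules of [call_mrd()].
#'
#' @param object An `mrd_reference`.
#' @param newdata A `subpop_table` for the follow-up sample.
#' @param diagnosis Optional `alaip_profile` from [detect_alaip()].
#' @param ... Passed to [call_mrd()] (e.g. `min_events`).
#' @return An `mrd_result`.
#' @export
predict.mrd_reference <- function(object, newdata, diagnosis = NULL, ...) {
  call_mrd(newdata, object, diagnosis = diagnosis, ...)
}

#' Serialize or restore a reference panel as JSON
#'
#' Reference values are exchanged as a standalone JSON artifact so that
#' clinical calling never silently recomputes them.
#'
#' @param panel An `mrd_reference`.
#' @param path File path.
#' @return `read_reference_json` returns an `mrd_reference`;
#'   `write_reference_json` returns `path` invisibly.
#' @export
write_reference_json <- function(panel, path) {
  stopifnot(inherits(panel, "mrd_reference"))
  out <- list(schema_version = "1.0",
              method = panel$method, prob = panel$prob,
              quantile_type = panel$quantile_type,
              n_controls = panel$n_controls,
              cohort_sizes = as.list(panel$cohort_sizes),
              values = panel$values)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_json
#' @export
read_reference_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- as.data.frame(j$values, stringsAsFactors = FALSE)
  structure(list(values = v, n_controls = j$n_controls, prob = j$prob,
                 quantile_type = j$quantile_type, method = j$method,
                 cohort_sizes = unlist(j$cohort_sizes)),
            class = "mrd_reference")
}
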