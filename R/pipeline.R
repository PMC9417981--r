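# End-to-end composition: gating -> tabulation -> MRD calling, emitted
# as a versioned, hash-stamped report (JSON canonical form plus a
# human-readable rendering).

REPORT_SCHEMA_VERSION <- "1.0"

# 32-bit FNV-1a over a character scalar; avoids a hashing dependency.
# The multiply is split into 16-bit halves to stay exact in doubles.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

hash_gate_config <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

hash_reference <- function(panel) {
  fnv1a_hash(jsonlite::toJSON(list(method = panel$method,
                                   values = panel$values),
                              auto_unbox = TRUE, digits = NA))
}

#' Run the full MRD pipeline on one sample
#'
#' Deterministic composition of the hierarchical gating cascade,
#' subpopulation tabulation and the different-from-normal MRD calling
#' rules, returning a versioned report. The gate configuration and
#' reference panel are content-hashed into the report so that the
#' fixed-gate premise is auditable.
#'
#' @param events An [event_matrix()] (follow-up sample).
#' @param config A [gate_config()].
#' @param panel An `mrd_reference`.
#' @param diagnosis Optional diagnosis [event_matrix()] or a precomputed
#'   `alaip_profile`.
#' @param transform Optional [transform_spec()] applied to `events` (and
#'   a diagnosis event matrix) before gating.
#' @param min_events Minimum events per subpopulation (default 20).
#' @param alaip_threshold aLAIP threshold in % of myP/M (default 10).
#' @return An object of class `mrd_report`.
#' @export
run_pipeline <- function(events, config, panel, diagnosis = NULL,
                         transform = NULL, min_events = 20,
                         alaip_threshold = 10) {
  stopifnot(inherits(events, "event_matrix"), inherits(config, "gate_config"),
            inherits(panel, "mrd_reference"))
  if (!is.null(transform)) events <- transform_events(events, transform)
  profile <- NULL
  if (!is.null(diagnosis)) {
    profile <- if (inherits(diagnosis, "alaip_profile")) diagnosis
    else {
      if (!inherits(diagnosis, "event_matrix"))
        stop("stage diagnosis: expected event_matrix or alaip_profile")
      dxe <- if (is.null(transform)) diagnosis
      else transform_events(diagnosis, transform)
      detect_alaip(tabulate_sample(dxe, config),
                   threshold_pct = alaip_threshold)
    }
  }
  labels <- tryCatch(gate_events(events, config),
                     error = function(e) stop("stage gating: ",
                                              conditionMessage(e)))
  tab <- tabulate_subpopulations(labels)
  tab$sample_kind <- events$sample_kind
  tab$cohort_label <- events$cohort_label
  if (!tab$evaluable)
    stop("stage tabulation: sample non-evaluable (no CD45+ events)")
  result <- tryCatch(call_mrd(tab, panel, diagnosis = profile,
                              min_events = min_events),
                     error = function(e) stop("stage calling: ",
                                              conditionMessage(e)))
  sp <- tab$subpops
  sp$ref_pct <- panel$values$ref_pct[match(sp$id, panel$values$id)]
  sp$burden <- pmax(sp$pct - sp$ref_pct, 0)
  sp$analyzed <- sp$count >= min_events
  structure(list(schema_version = REPORT_SCHEMA_VERSION,
                 sample_id = events$sample_id,
                 sample_kind = events$sample_kind,
                 gating = list(n_events = labels$n_events,
                               n_singlet = labels$n_singlet,
                               n_cd45 = labels$n_cd45,
                               n_pm = labels$n_pm,
                               n_mypm = labels$n_mypm),
                 main_populations = tab$main,
                 subpopulations = sp,
                 mrd = result,
                 alaip = profile,
                 config_hash = hash_gate_config(config),
                 reference_hash = hash_reference(panel)),
            class = "mrd_report")
}

#' @export
print.mrd_report <- function(x, digits = 4, ...) {
  cat(sprintf("=== MRD report (schema %s) ===\n", x$schema_version))
  cat(sprintf("Sample: %s (%s)\n", x$sample_id, x$sample_kind))
  g <- x$gating
  cat(sprintf("Gating: %d events -> %d singlet non-debris -> %d CD45+ -> %d P/M -> %d myP/M\n",
              g$n_events, g$n_singlet, g$n_cd45, g$n_pm, g$n_mypm))
  cat("Main populations (% of CD45+): ",
      paste(sprintf("%s %.2f", x$main_populations$backbone,
                    x$main_populations$pct), collapse = "; "), "\n", sep = "")
  print(x$mrd, digits = digits)
  cat(sprintf("Hashes: gates %s, reference %s\n",
              x$config_hash, x$reference_hash))
  invisible(x)
}

#' Serialize an MRD report to canonical JSON
#'
#' The serialization is deterministic (fixed key order, full precision),
#' so identical inputs yield byte-identical reports.
#'
#' @param report An `mrd_report`.
#' @param path Output path; when `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mrd_report"))
  mrd <- report$mrd
  out <- list(schema_version = report$schema_version,
              sample_id = report$sample_id,
              sample_kind = report$sample_kind,
              gating = report$gating,
              main_populations = report$main_populations,
              subpopulations = report$subpopulations,
              mrd = list(status = mrd$status,
                         mrd_load = mrd$mrd_load,
                         load_category = mrd$load_category,
                         load_class = mrd$load_class,
                         origin = mrd$origin,
                         eln_status = mrd$eln_status,
                         immonly_status = mrd$immonly_status,
                         category_sums = as.list(mrd$category_sums),
                         positive_subpops = mrd$positive_subpops,
                         non_evaluable_subpops = mrd$non_evaluable_subpops,
                         min_events = mrd$min_events),
              config_hash = report$config_hash,
              reference_hash = report$reference_hash)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
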