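# Aggregation of per-event labels into the 8 main myP/M populations and
# the 32 aberrant subpopulations, as percentages of CD45+ events.

backbone_levels <- function() {
  g <- expand.grid(hladr = c(TRUE, FALSE), cd117 = c(TRUE, FALSE),
                   cd34 = c(TRUE, FALSE))
  g <- g[order(-g$cd34, -g$cd117, -g$hladr), ]
  backbone_label(g$cd34, g$cd117, g$hladr)
}

#' Enumerate the aberrant subpopulations
#'
#' The 8 backbone combinations (CD34/CD117/HLA-DR each +/-) crossed with
#' the 4 aberrant categories give 32 subpopulations. A subpopulation is
#' immature when its backbone expresses CD34 and/or CD117 (24 of 32).
#'
#' @param immature_only If `TRUE`, return only the 24 immature
#'   subpopulations.
#' @return Data frame with columns `id`, `backbone`, `cd34`, `cd117`,
#'   `hladr` (logical), `category`, `immature`.
#' @export
enumerate_subpopulations <- function(immature_only = FALSE) {
  bb <- backbone_levels()
  g <- expand.grid(category = aberrant_categories(), backbone = bb,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("backbone", "category")]
  g$cd34 <- grepl("CD34+", g$backbone, fixed = TRUE)
  g$cd117 <- grepl("CD117+", g$backbone, fixed = TRUE)
  g$hladr <- grepl("HLA-DR+", g$backbone, fixed = TRUE)
  g$immature <- g$cd34 | g$cd117
  g$id <- paste(g$backbone, g$category)
  rownames(g) <- NULL
  g <- g[, c("id", "backbone", "cd34", "cd117", "hladr", "category", "immature")]
  if (immature_only) g <- g[g$immature, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Tabulate subpopulation counts and percentages
#'
#' Counts myP/M events per backbone (8 main populations) and per
#' (backbone, category) pair (32 aberrant subpopulations), expressed as
#' percentages of CD45+ events. An event carrying several categories
#' contributes to each of its category subpopulations; the main
#' populations partition myP/M. Percentages are kept at full precision;
#' rounding happens only at report time.
#'
#' @param labels An [gate_events()] result (`event_labels`).
#' @param n_cd45 CD45+ denominator; defaults to the one recorded in
#'   `labels`.
#' @return An object of class `subpop_table`: `main` (8 rows), `subpops`
#'   (32 rows), `n_cd45`, `n_mypm`, `evaluable`, plus sample metadata.
#' @export
tabulate_subpopulations <- function(labels, n_cd45 = labels$n_cd45) {
  stopifnot(inherits(labels, "event_labels"))
  bb <- backbone_levels()
  subs <- enumerate_subpopulations()
  evaluable <- n_cd45 >= 1
  mypm <- labels$in_mypm
  bfac <- factor(labels$backbone[mypm], levels = bb)
  main_counts <- as.integer(table(bfac))
  cat_counts <- matrix(0L, nrow = length(bb), ncol = 4L,
                       dimnames = list(bb, aberrant_categories()))
  if (any(mypm)) {
    cats <- labels$categories[mypm, , drop = FALSE]
    for (cc in aberrant_categories()) {
      cat_counts[, cc] <- as.integer(table(bfac[cats[, cc]]))
    }
  }
  denom <- if (evaluable) n_cd45 else NA_real_
  main <- data.frame(backbone = bb, count = main_counts,
                     pct = if (evaluable) 100 * main_counts / denom else NA_real_,
                     stringsAsFactors = FALSE)
  subs$count <- cat_counts[cbind(match(subs$backbone, bb),
                                 match(subs$category, aberrant_categories()))]
  subs$pct <- if (evaluable) 100 * subs$count / denom else NA_real_
  structure(list(main = main, subpops = subs,
                 n_cd45 = n_cd45, n_mypm = sum(mypm),
                 n_events = labels$n_events, n_singlet = labels$n_singlet,
                 n_pm = labels$n_pm,
                 evaluable = evaluable,
                 sample_id = labels$sample_id),
            class = "subpop_table")
}

#' Gate and tabulate a sample in one step
#'
#' @param events An [event_matrix()].
#' @param config A [gate_config()].
#' @return A `subpop_table`; carries the sample's `cohort_label` when set.
#' @export
tabulate_sample <- function(events, config = gate_config()) {
  tab <- tabulate_subpopulations(gate_events(events, config))
  tab$sample_kind <- events$sample_kind
  tab$cohort_label <- events$cohort_label
  tab
}

#' @export
print.subpop_table <- function(x, digits = 4, ...) {
  cat(sprintf("<subpop_table> %s: N_CD45 = %d, myP/M = %d (%s)\n",
              x$sample_id, x$n_cd45, x$n_mypm,
              if (x$evaluable) "evaluable" else "NON-EVALUABLE"))
  m <- x$main
  m$pct <- round(m$pct, digits)
  cat("Main populations (% of CD45+):\n")
  print(m, row.names = FALSE)
  nz <- x$subpops[x$subpops$count > 0, c("id", "count", "pct")]
  if (nrow(nz)) {
    nz$pct <- round(nz$pct, digits)
    cat("Non-empty aberrant subpopulations:\n")
    print(nz, row.names = FALSE)
  } else cat("No aberrant subpopulation events\n")
  invisible(x)
}

#' @export
as.data.frame.subpop_table <- function(x, ...) {
  out <- x$subpops
  out$sample_id <- x$sample_id
  out$n_cd45 <- x$n_cd45
  out$evaluable <- x$evaluable
  out
}
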