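# Hierarchical fixed-gate cascade: doublet/debris exclusion, CD45+
# leukocytes, P/M and lymphocyte regions on CD45/SSC, myeloid assignment
# (CD13 and/or CD33), backbone combinations and aberrant categories.

#' Aberrant category names
#'
#' Deficiency of a myeloid marker (true absence of CD13 or CD33) or
#' cross-lineage (strong) expression of a lymphoid marker (CD7 or CD56).
#' The order is the canonical tie-break order used throughout.
#'
#' @return Character vector of the four category names.
#' @export
aberrant_categories <- function() c("CD13neg", "CD33neg", "CD7pos", "CD56pos")

#' Construct a gate configuration
#'
#' Only the progenitor/monocyte (P/M) and lymphocyte regions on CD45 vs
#' side scatter are individually adjustable gates; the seven marker
#' thresholds (myeloid positivity for CD13/CD33, backbone positivity for
#' CD34/CD117/HLA-DR, and strong cross-lineage expression for CD7/CD56)
#' are fixed cutoffs on the transformed scale. Events on a gate boundary
#' are inside (closed-boundary convention).
#'
#' The published strategy positions the fixed gates from leukemia-free
#' reference measurements and internal controls (in particular
#' lymphocytes); the defaults here are calibrated the same way against
#' the synthetic marrow of [simulate_sample()], whose lymphocytes are
#' CD45-bright/SSC-low and whose T cells are CD7-strong.
#'
#' @param doublet_ratio Maximum allowed `|FSC-A/FSC-H - 1|` for singlets.
#' @param fsc_min,ssc_min Debris exclusion minima on FSC-A and SSC-A.
#' @param cd45_threshold CD45 positivity cutoff (transformed units).
#' @param pm_polygon,lymph_polygon Two-column matrices of vertices in
#'   (CD45, SSC-A) space; must be simple and mutually disjoint.
#' @param cd13_pos,cd33_pos,cd34_pos,cd117_pos,hladr_pos Positivity
#'   cutoffs; values below `cd13_pos`/`cd33_pos` count as deficiency.
#' @param cd7_strong,cd56_strong Strong-expression cutoffs for the
#'   cross-lineage markers (deliberately above ordinary positivity).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(doublet_ratio = 0.3,
                        fsc_min = 100, ssc_min = 10,
                        cd45_threshold = 1.0,
                        pm_polygon = default_pm_polygon(),
                        lymph_polygon = default_lymph_polygon(),
                        cd13_pos = 2.0, cd33_pos = 2.0,
                        cd34_pos = 2.0, cd117_pos = 2.0, hladr_pos = 2.0,
                        cd7_strong = 3.0, cd56_strong = 3.0) {
  thr <- c(cd13_pos = cd13_pos, cd33_pos = cd33_pos, cd34_pos = cd34_pos,
           cd117_pos = cd117_pos, hladr_pos = hladr_pos,
           cd7_strong = cd7_strong, cd56_strong = cd56_strong)
  if (any(!is.finite(thr))) stop("all fixed thresholds must be finite")
  if (doublet_ratio < 0) stop("doublet_ratio must be >= 0")
  pm_polygon <- as_polygon(pm_polygon, "pm_polygon")
  lymph_polygon <- as_polygon(lymph_polygon, "lymph_polygon")
  if (polygons_overlap(pm_polygon, lymph_polygon))
    stop("pm_polygon and lymph_polygon must be disjoint")
  structure(list(doublet_ratio = doublet_ratio,
                 fsc_min = fsc_min, ssc_min = ssc_min,
                 cd45_threshold = cd45_threshold,
                 pm_polygon = pm_polygon, lymph_polygon = lymph_polygon,
                 thresholds = as.list(thr),
                 schema_version = "1.0"),
            class = "gate_config")
}

default_pm_polygon <- function() {
  cbind(CD45 = c(2.0, 5.0, 5.0, 2.0), `SSC-A` = c(0, 0, 350, 350))
}

default_lymph_polygon <- function() {
  cbind(CD45 = c(5.5, 7.5, 7.5, 5.5), `SSC-A` = c(0, 0, 250, 250))
}

#' @export
print.gate_config <- function(x, ...) {
  cat("MRD gate configuration (schema", x$schema_version, ")\n")
  cat(sprintf("  doublets: |FSC-A/FSC-H - 1| <= %.3g; debris: FSC-A >= %g, SSC-A >= %g\n",
              x$doublet_ratio, x$fsc_min, x$ssc_min))
  cat(sprintf("  CD45+ cutoff: %.3g; P/M polygon: %d vertices; lymph polygon: %d vertices\n",
              x$cd45_threshold, nrow(x$pm_polygon), nrow(x$lymph_polygon)))
  cat("  fixed thresholds:",
      paste(sprintf("%s=%.3g", names(x$thresholds), unlist(x$thresholds)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a gate configuration as JSON
#'
#' @param x A [gate_config()].
#' @param path File path.
#' @return `read_gate_config` returns a `gate_config`; `write_gate_config`
#'   returns `path` invisibly.
#' @export
write_gate_config <- function(x, path) {
  stopifnot(inherits(x, "gate_config"))
  out <- list(schema_version = x$schema_version,
              doublet_ratio = x$doublet_ratio,
              fsc_min = x$fsc_min, ssc_min = x$ssc_min,
              cd45_threshold = x$cd45_threshold,
              pm_polygon = unclass(x$pm_polygon),
              lymph_polygon = unclass(x$lymph_polygon),
              thresholds = x$thresholds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gate_config
#' @export
read_gate_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  poly <- function(p) {
    m <- as.matrix(p); colnames(m) <- c("CD45", "SSC-A"); m
  }
  do.call(gate_config,
          c(list(doublet_ratio = j$doublet_ratio, fsc_min = j$fsc_min,
                 ssc_min = j$ssc_min, cd45_threshold = j$cd45_threshold,
                 pm_polygon = poly(j$pm_polygon),
                 lymph_polygon = poly(j$lymph_polygon)),
            j$thresholds))
}

# --- polygon helpers --------------------------------------------------------

as_polygon <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop(what, " must be a matrix of >= 3 (CD45, SSC-A) vertices")
  if (any(!is.finite(p))) stop(what, " vertices must be finite")
  if (!polygon_is_simple(p)) stop(what, " must be a simple (non-self-intersecting) polygon")
  p
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (they share a vertex by construction)
      if (j == i || idx(j) == idx(i + 1L) || idx(i) == idx(j + 1L)) next
      if (segments_intersect(p[i, ], p[idx(i + 1L), ],
                             p[j, ], p[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

polygons_overlap <- function(a, b) {
  if (any(point_in_polygon(a[, 1], a[, 2], b))) return(TRUE)
  if (any(point_in_polygon(b[, 1], b[, 2], a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (segments_intersect(a[i, ], a[(i %% na) + 1L, ],
                           b[j, ], b[(j %% nb) + 1L, ])) return(TRUE)
  }
  FALSE
}

# Vectorised even-odd point-in-polygon with closed boundaries: points on an
# edge or vertex are inside.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on_this <- abs(cross) <= 1e-9 * pmax(1, abs(xj - xi) + abs(yj - yi)) &
      x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
      y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_this
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# --- gating operations ------------------------------------------------------

#' Doublet exclusion
#'
#' Singlets satisfy `|FSC-A/FSC-H - 1| <= doublet_ratio`; events with
#' `FSC-H = 0` are excluded.
#'
#' @param events An [event_matrix()].
#' @param config A [gate_config()].
#' @return Logical singlet mask over all events.
#' @export
exclude_doublets <- function(events, config) {
  fsca <- events$values[, "FSC-A"]; fsch <- events$values[, "FSC-H"]
  ok <- fsch != 0
  ratio <- ifelse(ok, fsca / fsch, Inf)
  ok & abs(ratio - 1) <= config$doublet_ratio
}

#' Debris exclusion
#'
#' @inheritParams exclude_doublets
#' @return Logical mask, true for retained (non-debris) events with
#'   `FSC-A >= fsc_min` and `SSC-A >= ssc_min`.
#' @export
exclude_debris <- function(events, config) {
  events$values[, "FSC-A"] >= config$fsc_min &
    events$values[, "SSC-A"] >= config$ssc_min
}

#' CD45+ leukocyte gate
#'
#' Applied to singlet, non-debris events; the resulting count is the
#' denominator for all subpopulation percentages (% of CD45+ events).
#'
#' @inheritParams exclude_doublets
#' @param base Optional logical mask of singlet non-debris events; computed
#'   from `config` when omitted.
#' @return List with `mask` (logical over all events), `n_cd45` and
#'   `evaluable` (`FALSE` when no CD45+ event remains).
#' @export
gate_cd45_leukocytes <- function(events, config, base = NULL) {
  if (is.null(base))
    base <- exclude_doublets(events, config) & exclude_debris(events, config)
  mask <- base & events$values[, "CD45"] >= config$cd45_threshold
  list(mask = mask, n_cd45 = sum(mask), evaluable = any(mask))
}

#' P/M and lymphocyte gates on CD45 vs side scatter
#'
#' The progenitor/monocyte (P/M) region holds blasts and monocytes; the
#' lymphocyte region is the CD45-bright, SSC-low internal control. Both
#' are evaluated only on CD45+ events and are disjoint by configuration.
#'
#' @inheritParams exclude_doublets
#' @param cd45_mask Logical CD45+ mask; computed when omitted.
#' @return List of logical masks `pm` and `lymph`.
#' @export
gate_pm_lymph <- function(events, config, cd45_mask = NULL) {
  if (is.null(cd45_mask)) cd45_mask <- gate_cd45_leukocytes(events, config)$mask
  cd45 <- events$values[, "CD45"]; ssc <- events$values[, "SSC-A"]
  pm <- cd45_mask & point_in_polygon(cd45, ssc, config$pm_polygon)
  lymph <- cd45_mask & point_in_polygon(cd45, ssc, config$lymph_polygon)
  list(pm = pm, lymph = lymph)
}

#' Myeloid P/M gate
#'
#' P/M events must express at least one of the myeloid markers CD13 or
#' CD33 (`myP/M`) to enter the subpopulation analysis.
#'
#' @inheritParams exclude_doublets
#' @param pm_mask Logical P/M mask.
#' @return Logical myP/M mask.
#' @export
gate_mypm <- function(events, config, pm_mask) {
  thr <- config$thresholds
  pm_mask & (events$values[, "CD13"] >= thr$cd13_pos |
               events$values[, "CD33"] >= thr$cd33_pos)
}

#' Backbone assignment (CD34, CD117, HLA-DR)
#'
#' Each myP/M event is assigned exactly one of the eight +/- combinations
#' of the backbone markers by thresholding.
#'
#' @inheritParams exclude_doublets
#' @param mypm_mask Logical myP/M mask.
#' @return Character vector over all events: backbone label for myP/M
#'   events, `NA` elsewhere.
#' @export
assign_backbone <- function(events, config, mypm_mask) {
  thr <- config$thresholds
  lab <- rep(NA_character_, events$n_events)
  v <- events$values
  lab[mypm_mask] <- backbone_label(v[mypm_mask, "CD34"] >= thr$cd34_pos,
                                   v[mypm_mask, "CD117"] >= thr$cd117_pos,
                                   v[mypm_mask, "HLA-DR"] >= thr$hladr_pos)
  lab
}

backbone_label <- function(cd34, cd117, hladr) {
  sprintf("CD34%sCD117%sHLA-DR%s",
          ifelse(cd34, "+", "-"), ifelse(cd117, "+", "-"),
          ifelse(hladr, "+", "-"))
}

#' Aberrant-category assignment
#'
#' On myP/M events, deficiency means true absence (below the positivity
#' cutoff) of CD13 or CD33, and cross-lineage expression means strong
#' expression (at or above the dedicated strong cutoff) of CD7 or CD56.
#' An event may carry none, one, or several categories; `{CD13neg,
#' CD33neg}` is unreachable for myP/M events because the myeloid gate
#' requires at least one of the two markers.
#'
#' @inheritParams assign_backbone
#' @return Logical matrix (events x 4) with columns
#'   [aberrant_categories()]; rows are `FALSE` outside myP/M.
#' @export
assign_categories <- function(events, config, mypm_mask) {
  thr <- config$thresholds
  v <- events$values
  m <- cbind(CD13neg = v[, "CD13"] < thr$cd13_pos,
             CD33neg = v[, "CD33"] < thr$cd33_pos,
             CD7pos = v[, "CD7"] >= thr$cd7_strong,
             CD56pos = v[, "CD56"] >= thr$cd56_strong)
  m & mypm_mask
}

#' Run the full hierarchical gating cascade
#'
#' Composes doublet and debris exclusion, the CD45+ leukocyte gate, the
#' P/M and lymphocyte regions, the myeloid (CD13 and/or CD33) gate, and
#' the fixed backbone and category gates into per-event labels.
#'
#' @inheritParams exclude_doublets
#' @return An object of class `event_labels`: logical masks `is_doublet`,
#'   `is_debris`, `is_cd45pos`, `in_pm`, `in_lymph`, `in_mypm`; `backbone`
#'   (character, `NA` outside myP/M); `categories` (logical matrix);
#'   counts `n_events`, `n_singlet`, `n_cd45`, `n_pm`, `n_mypm`; and
#'   `evaluable`.
#' @export
gate_events <- function(events, config = gate_config()) {
  stopifnot(inherits(events, "event_matrix"), inherits(config, "gate_config"))
  singlet <- exclude_doublets(events, config)
  keep <- exclude_debris(events, config)
  base <- singlet & keep
  cd45 <- gate_cd45_leukocytes(events, config, base = base)
  pml <- gate_pm_lymph(events, config, cd45_mask = cd45$mask)
  mypm <- gate_mypm(events, config, pml$pm)
  structure(list(is_doublet = !singlet, is_debris = !keep,
                 is_cd45pos = cd45$mask,
                 in_pm = pml$pm, in_lymph = pml$lymph, in_mypm = mypm,
                 backbone = assign_backbone(events, config, mypm),
                 categories = assign_categories(events, config, mypm),
                 n_events = events$n_events,
                 n_singlet = sum(base),
                 n_cd45 = cd45$n_cd45, n_pm = sum(pml$pm),
                 n_mypm = sum(mypm),
                 evaluable = cd45$evaluable,
                 sample_id = events$sample_id),
            class = "event_labels")
}

#' @export
print.event_labels <- function(x, ...) {
  cat(sprintf("<event_labels> %s: %d events -> %d singlet non-debris -> %d CD45+ -> %d P/M -> %d myP/M%s\n",
              x$sample_id, x$n_events, x$n_singlet, x$n_cd45, x$n_pm, x$n_mypm,
              if (x$evaluable) "" else " [NON-EVALUABLE: no CD45+ events]"))
  invisible(x)
}
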