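# Marker panel, event-matrix container and file I/O (CSV and FCS 3.0/3.1).

#' Logical marker names of the one-tube MRD panel
#'
#' The panel consists of three scatter parameters and eight monoclonal
#' antibodies: CD7, CD13, CD33, CD34, CD45, CD56, CD117 and HLA-DR.
#' The order below is the canonical column order of an [event_matrix()].
#'
#' @return Character vector of the 11 logical marker names.
#' @export
mrd_markers <- function() {
  c("FSC-A", "FSC-H", "SSC-A",
    "CD7", "CD13", "CD33", "CD34", "CD45", "CD56", "CD117", "HLA-DR")
}

scatter_markers <- function() c("FSC-A", "FSC-H", "SSC-A")

fluor_markers <- function() setdiff(mrd_markers(), scatter_markers())

#' Construct a marker panel
#'
#' A panel binds the fixed set of logical markers to instrument channel
#' names. The exact fluorochrome-to-antibody assignment is
#' instrument-specific, so the channel map is user supplied; by default
#' channels are assumed to already carry the logical marker names.
#'
#' @param channel_map Named character vector mapping instrument channel
#'   names (names) to logical marker names (values). Defaults to the
#'   identity map over [mrd_markers()].
#' @return An object of class `marker_panel`.
#' @examples
#' p <- marker_panel(c("FL1-A" = "CD7", "FL2-A" = "CD13"))
#' @export
marker_panel <- function(channel_map = NULL) {
  markers <- mrd_markers()
  if (is.null(channel_map)) {
    channel_map <- stats::setNames(markers, markers)
  }
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stop("channel_map must be a named character vector (instrument -> logical)")
  extra <- setdiff(unname(channel_map), markers)
  if (length(extra))
    stop("unknown logical marker(s) in channel_map: ", paste(extra, collapse = ", "))
  if (anyDuplicated(unname(channel_map)))
    stop("each logical marker may map from exactly one channel")
  # unmapped channels default to identity where the channel name is itself
  # a logical marker
  unmapped <- setdiff(markers, unname(channel_map))
  channel_map <- c(channel_map, stats::setNames(unmapped, unmapped))
  structure(list(markers = markers, channel_map = channel_map),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("One-tube MRD marker panel:", length(x$markers), "parameters\n")
  nontrivial <- x$channel_map[names(x$channel_map) != unname(x$channel_map)]
  if (length(nontrivial)) {
    cat("Channel mapping:\n")
    for (i in seq_along(nontrivial))
      cat(sprintf("  %s -> %s\n", names(nontrivial)[i], nontrivial[i]))
  } else cat("Channels carry logical marker names directly\n")
  invisible(x)
}

#' Construct an event matrix
#'
#' @param values Numeric matrix, one row per event, columns named by the
#'   logical markers of [mrd_markers()]. Values are assumed compensated.
#' @param sample_id Sample identifier.
#' @param sample_kind One of `"diagnosis"`, `"followup"`, `"lfc"`.
#' @param cohort_label Optional control-cohort label (e.g. `"BMD"`,
#'   `"ALL_molCR"`, `"hip_surgery"`, `"PCNSL"`); only meaningful for
#'   leukemia-free control samples.
#' @return An object of class `event_matrix`.
#' @export
event_matrix <- function(values, sample_id = "sample",
                         sample_kind = c("followup", "diagnosis", "lfc"),
                         cohort_label = NULL) {
  sample_kind <- match.arg(sample_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  missing <- setdiff(mrd_markers(), colnames(values))
  if (length(missing))
    stop("missing channel ", paste(missing, collapse = ", "))
  values <- values[, mrd_markers(), drop = FALSE]
  if (nrow(values) < 1L) stop("event matrix must contain at least one event")
  if (!all(is.finite(values)))
    stop("event intensities must be finite and non-missing")
  structure(list(values = values, n_events = nrow(values),
                 sample_id = sample_id, sample_kind = sample_kind,
                 cohort_label = cohort_label),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %s (%s%s): %d events x %d markers\n",
              x$sample_id, x$sample_kind,
              if (is.null(x$cohort_label)) "" else paste0("/", x$cohort_label),
              x$n_events, ncol(x$values)))
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$values)

#' Read cytometry events from an FCS or CSV file
#'
#' FCS 3.0/3.1 files are detected by their magic bytes; anything else is
#' read as a delimited table with a header row naming the channels.
#' Channel names (for FCS, `$PnS` when present, else `$PnN`) are mapped
#' to logical markers through the panel's channel map.
#'
#' @param path Path to an FCS 3.0/3.1 file or a CSV event table.
#' @param panel A [marker_panel()].
#' @inheritParams event_matrix
#' @return An [event_matrix()].
#' @export
read_events <- function(path, panel = marker_panel(), sample_id = NULL,
                        sample_kind = "followup", cohort_label = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  magic <- readBin(path, "raw", n = 6L)
  is_fcs <- length(magic) == 6L && rawToChar(magic[1:3]) == "FCS"
  raw_mat <- if (is_fcs) read_fcs(path) else {
    df <- utils::read.csv(path, check.names = FALSE)
    as.matrix(df)
  }
  cn <- colnames(raw_mat)
  mapped <- ifelse(cn %in% names(panel$channel_map),
                   unname(panel$channel_map[cn]), cn)
  colnames(raw_mat) <- mapped
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  event_matrix(raw_mat, sample_id = sample_id, sample_kind = sample_kind,
               cohort_label = cohort_label)
}

#' Write cytometry events to CSV or FCS
#'
#' @param events An [event_matrix()].
#' @param path Output path.
#' @param format `"csv"` (default) or `"fcs"` (FCS 3.1, 32-bit float).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(events, "event_matrix"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(events$values, check.names = FALSE),
                     path, row.names = FALSE)
  } else {
    write_fcs(events$values, path)
  }
  invisible(path)
}

# --- minimal FCS 3.0/3.1 support -------------------------------------------
# No FCS package is available in this stack, so the subset of the standard
# needed here is implemented directly: list-mode data, $DATATYPE F/D/I,
# common byte orders, keywords $PAR/$TOT/$PnB/$PnN/$PnS.

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1L])
  body <- rawToChar(raw_text[-1L])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(vals, keys)
}

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  seek(con, text_start)
  kw <- parse_fcs_text(readBin(con, "raw", n = text_end - text_start + 1L))
  if (data_start == 0 || data_end == 0) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1") || identical(byteord, "2,1"))
    "big" else "little"
  if (!is.null(kw[["$MODE"]]) && toupper(kw[["$MODE"]]) != "L")
    stop("only list-mode ($MODE L) FCS data is supported")
  bits <- as.integer(vapply(seq_len(npar),
                            function(i) kw[[sprintf("$P%dB", i)]], ""))
  seek(con, data_start)
  n_values <- npar * ntot
  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    vals <- readBin(con, "double", n = n_values, size = size, endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L)
      stop("integer FCS data with mixed $PnB widths is not supported")
    size <- bits[1L] %/% 8L
    vals <- readBin(con, "integer", n = n_values, size = size,
                    signed = size > 2L, endian = endian)
    vals <- as.double(vals)
    if (size <= 2L) vals[vals < 0] <- vals[vals < 0] + 2^bits[1L]
  } else stop("unsupported $DATATYPE: ", dtype)
  if (length(vals) != n_values)
    stop("truncated FCS data segment in ", path)
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  nm <- vapply(seq_len(npar), function(i) {
    s <- kw[[sprintf("$P%dS", i)]]
    if (is.null(s) || !nzchar(trimws(s))) kw[[sprintf("$P%dN", i)]] else s
  }, "")
  colnames(mat) <- trimws(nm)
  mat
}

write_fcs <- function(values, path) {
  npar <- ncol(values); ntot <- nrow(values)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0",
          "$PAR" = as.character(npar), "$TOT" = as.character(ntot))
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "262144"
    kw[sprintf("$P%dN", i)] <- colnames(values)[i]
    kw[sprintf("$P%dS", i)] <- colnames(values)[i]
  }
  # fixed-width BEGINDATA/ENDDATA so the TEXT length does not depend on them
  kw["$BEGINDATA"] <- "000000000000"
  kw["$ENDDATA"] <- "000000000000"
  build_text <- function(kw) paste0("|", paste0(names(kw), "|", kw, "|",
                                                collapse = ""))
  text_start <- 58L
  text_len <- nchar(build_text(kw))
  data_start <- text_start + text_len
  data_end <- data_start + 4L * npar * ntot - 1L
  kw["$BEGINDATA"] <- sprintf("%012d", data_start)
  kw["$ENDDATA"] <- sprintf("%012d", data_end)
  text <- build_text(kw)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + text_len - 1L,
                    data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}

# --- transforms -------------------------------------------------------------

#' Specify a per-marker intensity transform
#'
#' Fluorescence channels are mapped onto a stable display scale before the
#' fixed gates are applied; scatter channels are never transformed. The
#' default is the inverse hyperbolic sine `asinh(x / cofactor)`, the
#' standard variance-stabilising transform for compensated cytometry data.
#' `identity` is intended for data already generated on the transformed
#' scale (e.g. by [simulate_sample()]).
#'
#' @param kind `"asinh"` or `"identity"`.
#' @param cofactor Single positive cofactor, or a named vector with one
#'   entry per fluorescence marker.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(kind = c("asinh", "identity"), cofactor = 150) {
  kind <- match.arg(kind)
  fl <- fluor_markers()
  if (kind == "asinh") {
    if (length(cofactor) == 1L && is.null(names(cofactor)))
      cofactor <- stats::setNames(rep(cofactor, length(fl)), fl)
    missing <- setdiff(fl, names(cofactor))
    if (length(missing))
      stop("cofactor missing for marker(s): ", paste(missing, collapse = ", "))
    if (any(!is.finite(cofactor)) || any(cofactor <= 0))
      stop("cofactors must be finite and positive (monotone transform)")
  }
  structure(list(kind = kind, cofactor = cofactor), class = "transform_spec")
}

#' Apply an intensity transform to an event matrix
#'
#' @param events An [event_matrix()].
#' @param spec A [transform_spec()].
#' @return A transformed [event_matrix()]; scatter channels untouched.
#' @export
transform_events <- function(events, spec = transform_spec()) {
  stopifnot(inherits(events, "event_matrix"), inherits(spec, "transform_spec"))
  if (spec$kind == "identity") return(events)
  v <- events$values
  for (m in fluor_markers())
    v[, m] <- asinh(v[, m] / spec$cofactor[[m]])
  events$values <- v
  events
}
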