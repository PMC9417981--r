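# Krippendorff's alpha via the coincidence-matrix formulation, for
# nominal (MRD status), interval and ratio (%CD45+ frequencies) data.

#' Krippendorff's alpha inter-rater reliability
#'
#' Chance-corrected agreement between multiple raters,
#' `alpha = 1 - D_observed / D_expected`, computed from the coincidence
#' matrix of within-unit value pairs. Missing ratings are allowed; units
#' with fewer than two non-missing ratings are excluded. Difference
#' functions: nominal `0/1`, interval `(c - k)^2`, ratio
#' `((c - k)/(c + k))^2`. Percentages of CD45+ events are ratio-scale
#' quantities, hence the ratio metric is the default for subpopulation
#' frequencies; MRD status uses the nominal metric.
#'
#' @param ratings Units x raters matrix (`NA` = missing), or a long-format
#'   data frame with columns `unit`, `rater`, `value`.
#' @param metric `"nominal"`, `"interval"` or `"ratio"`.
#' @return An object of class `kripp_alpha`: `alpha`, `metric`,
#'   `n_units`, `n_raters`, `n_pairable`, and `perfect` (`TRUE` when
#'   expected disagreement is zero, in which case `alpha` is defined
#'   as 1).
#' @examples
#' m <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2))
#' krippendorff_alpha(m, metric = "nominal")
#' @export
krippendorff_alpha <- function(ratings, metric = c("ratio", "interval", "nominal")) {
  metric <- match.arg(metric)
  if (is.data.frame(ratings)) {
    need <- c("unit", "rater", "value")
    if (!all(need %in% names(ratings)))
      stop("long-format ratings need columns unit, rater, value")
    ratings <- long_to_wide_ratings(ratings)
  }
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("at least 2 raters are required")
  if (is.character(ratings)) {
    if (metric != "nominal")
      stop("character ratings require the nominal metric")
    ratings <- matrix(as.integer(factor(ratings)), nrow = nrow(ratings))
  }
  keep <- rowSums(!is.na(ratings)) >= 2L
  if (!any(keep))
    stop("no unit with at least 2 non-missing ratings")
  r <- ratings[keep, , drop = FALSE]
  vals <- sort(unique(stats::na.omit(as.vector(r))))
  if (metric == "ratio" && any(vals < 0))
    stop("ratio metric requires non-negative ratings")
  K <- length(vals)
  # coincidence matrix: o[c,k] = sum_u n_uc (n_uk - [c==k]) / (m_u - 1)
  o <- matrix(0, K, K)
  for (u in seq_len(nrow(r))) {
    x <- r[u, ]; x <- x[!is.na(x)]
    m_u <- length(x)
    n_uc <- tabulate(match(x, vals), nbins = K)
    o <- o + (outer(n_uc, n_uc) - diag(n_uc, nrow = K)) / (m_u - 1)
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  d <- switch(metric,
              nominal = 1 - diag(K),
              interval = outer(vals, vals, function(a, b) (a - b)^2),
              ratio = outer(vals, vals, function(a, b) {
                s <- a + b
                ifelse(s == 0, 0, ((a - b) / s)^2)
              }))
  d_obs <- sum(o * d) / n
  d_exp <- sum(outer(n_c, n_c) * d) / (n * (n - 1))
  perfect <- d_exp == 0
  alpha <- if (perfect) 1 else 1 - d_obs / d_exp
  structure(list(alpha = alpha, metric = metric,
                 n_units = sum(keep), n_raters = ncol(ratings),
                 n_pairable = n, perfect = perfect),
            class = "kripp_alpha")
}

long_to_wide_ratings <- function(df) {
  units <- unique(df$unit); raters <- unique(df$rater)
  m <- matrix(NA_real_, length(units), length(raters),
              dimnames = list(as.character(units), as.character(raters)))
  if (is.character(df$value) || is.factor(df$value))
    m <- matrix(NA_character_, length(units), length(raters),
                dimnames = dimnames(m))
  m[cbind(match(df$unit, units), match(df$rater, raters))] <- df$value
  m
}

#' @export
print.kripp_alpha <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (%s metric): %.3f\n", x$metric, x$alpha))
  cat(sprintf("  %d units, %d raters, %g pairable ratings%s\n",
              x$n_units, x$n_raters, x$n_pairable,
              if (x$perfect) "  [zero expected disagreement]" else ""))
  invisible(x)
}
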