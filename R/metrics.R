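# Small, exactly-specified preclinical computations: xenograft tumour
# volume, randomisation validity, and the beta-catenin TOP/FOP reporter
# ratio.

#' Tumour volume from caliper axes
#'
#' `V = d^2 * D / 2` with `d` the minor and `D` the major tumour axis
#' (millimetres); volume in cubic millimetres.
#'
#' @param d Minor axis, mm.
#' @param D Major axis, mm.
#' @param lenient Swap the axes (with a warning) instead of failing when
#'   `d > D`.
#' @return Volume in mm^3 (vectorised).
#' @export
tumour_volume <- function(d, D, lenient = FALSE) {
  if (any(d <= 0) || any(D <= 0))
    stop_data("tumour axes must be positive", class = "cs_parse_error")
  bad <- d > D
  if (any(bad)) {
    if (!lenient)
      stop_data("minor axis exceeds major axis; pass lenient = TRUE to auto-swap",
                class = "cs_parse_error")
    warning(sprintf("%d measurement(s) had d > D; axes swapped", sum(bad)),
            call. = FALSE)
    tmp <- d[bad]; d[bad] <- D[bad]; D[bad] <- tmp
  }
  d^2 * D / 2
}

#' Validate a randomisation into two treatment arms
#'
#' Randomisation is valid when the relative difference between the two
#' group mean volumes is below 10%. The denominator is configurable (the
#' published rule does not state it): the midpoint of the two means
#' (default), the first group's mean, or the larger mean.
#'
#' @param group_a,group_b Numeric vectors of tumour volumes (mm^3).
#' @param threshold Maximum allowed relative difference (default 0.10).
#' @param denominator `"midpoint"`, `"first"` or `"max"`.
#' @return List `valid` (logical), `relative_difference`, `mean_a`,
#'   `mean_b`.
#' @export
randomisation_valid <- function(group_a, group_b, threshold = 0.10,
                                denominator = c("midpoint", "first", "max")) {
  if (!length(group_a) || !length(group_b))
    stop_config("both groups must be non-empty", field = "group")
  denominator <- match.arg(denominator)
  ma <- mean(group_a); mb <- mean(group_b)
  den <- switch(denominator,
                midpoint = mean(c(ma, mb)),
                first = ma,
                max = max(ma, mb))
  rel <- abs(ma - mb) / den
  list(valid = rel < threshold, relative_difference = rel,
       mean_a = ma, mean_b = mb)
}

#' TOP/FOP luciferase reporter ratio
#'
#' Ratio of TOP (TCF/LEF-responsive) to FOP (mutated control) luminescence,
#' a measure of beta-catenin-driven transcription.
#'
#' @param top,fop Luminescence readings; `fop` must be positive.
#' @return `top / fop` (vectorised).
#' @export
top_fop_ratio <- function(top, fop) {
  if (any(fop <= 0))
    stop_data("FOP luminescence must be positive", class = "cs_parse_error")
  if (any(top < 0))
    stop_data("TOP luminescence must be non-negative", class = "cs_parse_error")
  top / fop
}

#' Summarise tumour growth curves
#'
#' Per day and group: mean volume and the half-width of the t-based 95%
#' confidence interval of the mean.
#'
#' @param df Data frame with columns `day`, `group`, `volume`.
#' @return Data frame `day`, `group`, `n`, `mean_volume`, `ci_half_width`.
#' @export
summarise_growth <- function(df) {
  need <- c("day", "group", "volume")
  if (!all(need %in% names(df)))
    stop_data("growth table needs columns day, group, volume",
              class = "cs_parse_error")
  parts <- split(df, list(df$day, df$group), drop = TRUE)
  out <- lapply(parts, function(p) {
    n <- nrow(p)
    m <- mean(p$volume)
    hw <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(p$volume) / sqrt(n) else NA_real_
    data.frame(day = p$day[1], group = p$group[1], n = n,
               mean_volume = m, ci_half_width = hw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$group, out$day), ]
  rownames(out) <- NULL
  out
}
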