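#' Construct a depth profile
#'
#' Per-target-region median read depths from an exome capture, used for
#' depth-ratio gene copy number. Regions are 0-based half-open intervals.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `gene`,
#'   `median_depth`.
#' @return A `depth_profile` data frame.
#' @export
depth_profile <- function(df) {
  need <- c("chrom", "start", "end", "gene", "median_depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data(sprintf("depth profile missing column(s): %s",
                      paste(miss, collapse = ", ")), class = "cs_parse_error")
  df <- df[, need]
  if (any(df$end <= df$start))
    stop_data("depth profile regions must satisfy end > start",
              class = "cs_parse_error")
  if (any(!is.finite(df$median_depth)) || any(df$median_depth < 0))
    stop_data("median depths must be finite and non-negative",
              class = "cs_parse_error")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("depth_profile", "data.frame"))
}

#' Gene copy number from target-region depth ratios
#'
#' First the median read depth over all target regions is computed; next,
#' for each gene, the median depth of that gene's regions is obtained and
#' divided by the global value. Median here is the midpoint convention for
#' even counts, taken over region-level median depths.
#'
#' @param profile A [depth_profile()].
#' @return Named numeric vector of per-gene GCN ratios (unitless; 1 means
#'   depth at the sample-wide level, i.e. the baseline ploidy).
#' @export
compute_gcn <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile) < 1)
    stop_data("depth profile has no regions", class = "cs_parse_error")
  global <- stats::median(profile$median_depth)
  if (global <= 0)
    stop_data("global median depth is zero; cannot form depth ratios")
  gcn <- tapply(profile$median_depth, profile$gene, stats::median) / global
  out <- as.numeric(gcn)
  names(out) <- names(gcn)
  out[order(names(out))]
}

#' Absolute copies from GCN ratios
#'
#' Copies = GCN x baseline ploidy. By default the result is rounded to the
#' nearest integer copy number (minimum 1): genomic DNA comes in whole
#' copies, and rounding keeps the depth-ratio sampling noise of diploid
#' genes out of downstream cellular-prevalence estimates. Pass
#' `round = FALSE` for the raw ratio scale.
#'
#' @param gcn Named GCN vector from [compute_gcn()].
#' @param baseline_ploidy Copies corresponding to GCN 1 (default 2).
#' @param round Round to the nearest integer copy number.
#' @return Named numeric vector of absolute copy numbers.
#' @export
absolute_copies <- function(gcn, baseline_ploidy = 2, round = TRUE) {
  if (!is.numeric(baseline_ploidy) || baseline_ploidy <= 0)
    stop_config("baseline_ploidy must be positive", field = "baseline_ploidy")
  copies <- gcn * baseline_ploidy
  if (round) {
    copies <- base::round(copies)
    copies[copies < 1] <- 1
  }
  copies
}

#' Read a depth profile from BED + depth TSV
#'
#' @param bed_path BED file (`chrom start end gene`, 0-based half-open).
#' @param depth_path TSV with header `region median_depth`, region ids of
#'   the form `chrom:start-end`.
#' @return A `depth_profile`.
#' @export
read_depth_profile <- function(bed_path, depth_path) {
  bed <- tryCatch(utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                                    col.names = c("chrom", "start", "end", "gene")),
                  error = function(e) stop_data(
                    sprintf("malformed BED '%s': %s", bed_path, conditionMessage(e)),
                    class = "cs_parse_error"))
  dep <- tryCatch(utils::read.delim(depth_path, stringsAsFactors = FALSE),
                  error = function(e) stop_data(
                    sprintf("malformed depth TSV '%s': %s", depth_path, conditionMessage(e)),
                    class = "cs_parse_error"))
  region <- sprintf("%s:%d-%d", bed$chrom, bed$start, bed$end)
  m <- match(region, dep$region)
  if (anyNA(m))
    stop_data("depth TSV is missing one or more BED regions",
              class = "cs_parse_error")
  depth_profile(data.frame(bed, median_depth = dep$median_depth[m],
                           stringsAsFactors = FALSE))
}

#' Write a depth profile as BED + depth TSV
#'
#' @param profile A `depth_profile`.
#' @param bed_path,depth_path Output paths.
#' @export
write_depth_profile <- function(profile, bed_path, depth_path) {
  stopifnot(inherits(profile, "depth_profile"))
  utils::write.table(profile[, c("chrom", "start", "end", "gene")],
                     bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dep <- data.frame(region = sprintf("%s:%d-%d", profile$chrom,
                                     profile$start, profile$end),
                    median_depth = profile$median_depth)
  utils::write.table(dep, depth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed_path, depth_path))
}

#' Write per-gene copy number as TSV
#' @param gcn Named vector from [compute_gcn()].
#' @param path Output path.
#' @export
write_gcn <- function(gcn, path) {
  utils::write.table(data.frame(gene = names(gcn), gcn = as.numeric(gcn)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
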