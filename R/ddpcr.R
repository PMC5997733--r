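#' Construct a ddPCR well record
#'
#' Positive/negative droplet counts for the mutant and wild-type channels
#' of one droplet digital PCR well.
#'
#' @param well_id Well label.
#' @param n_droplets Total droplets analysed.
#' @param pos_mut,neg_mut Mutant-channel positive/negative droplets.
#' @param pos_wt,neg_wt Wild-type-channel positive/negative droplets.
#' @param droplet_volume Droplet volume in nanolitres.
#' @return A one-row `ddpcr_well` data frame.
#' @export
ddpcr_well <- function(well_id, n_droplets, pos_mut, neg_mut, pos_wt, neg_wt,
                       droplet_volume = 0.85) {
  if (any(c(pos_mut, neg_mut, pos_wt, neg_wt) < 0))
    stop_data("droplet counts must be non-negative", class = "cs_parse_error")
  if (pos_mut + neg_mut != n_droplets || pos_wt + neg_wt != n_droplets)
    stop_data("positives + negatives must equal total droplets on each channel",
              class = "cs_parse_error")
  if (droplet_volume <= 0)
    stop_config("droplet_volume must be positive (nanolitres)",
                field = "droplet_volume")
  structure(data.frame(well_id = well_id, n_droplets = as.integer(n_droplets),
                       pos_mut = as.integer(pos_mut), neg_mut = as.integer(neg_mut),
                       pos_wt = as.integer(pos_wt), neg_wt = as.integer(neg_wt),
                       droplet_volume = droplet_volume,
                       stringsAsFactors = FALSE),
            class = c("ddpcr_well", "data.frame"))
}

#' Fractional abundance of mutant events
#'
#' `F.A.% = Nmut / (Nmut + Nwt) * 100`, the percentage of mutant DNA
#' alleles in the wild-type background.
#'
#' @param nmut,nwt Mutant and wild-type event counts (non-negative; not
#'   both zero).
#' @return Fractional abundance in percent.
#' @export
fractional_abundance <- function(nmut, nwt) {
  if (any(nmut < 0) || any(nwt < 0))
    stop_data("event counts must be non-negative", class = "cs_parse_error")
  if (any(nmut + nwt == 0))
    stop_data("fractional abundance undefined when both event counts are zero")
  nmut / (nmut + nwt) * 100
}

#' Poisson occupancy estimate of template copies per droplet
#'
#' With `n` droplets of which `npos` are positive, the mean copies per
#' droplet is `lambda = -ln((n - npos)/n)`. The 95% confidence interval is
#' delta-method based: `lambda +/- 1.96 * sqrt((1 - p) / (n * p))` with
#' `p = (n - npos)/n` the negative fraction, floored at 0. Saturated wells
#' (no negative droplets) carry no information about lambda and raise an
#' error advising dilution.
#'
#' @param npos Positive droplets.
#' @param ntotal Total droplets (>= 1).
#' @return List `lambda`, `ci95` (length-2 vector).
#' @export
poisson_lambda <- function(npos, ntotal) {
  if (ntotal < 1 || npos < 0 || npos > ntotal)
    stop_data("need 0 <= npos <= ntotal and ntotal >= 1", class = "cs_parse_error")
  if (npos == ntotal)
    stop_data("all droplets positive: channel saturated, dilute the template and repeat",
              class = "cs_saturation_error")
  p_neg <- (ntotal - npos) / ntotal
  lambda <- -log(p_neg)
  half <- 1.96 * sqrt((1 - p_neg) / (ntotal * p_neg))
  list(lambda = lambda,
       ci95 = c(max(0, lambda - half), max(0, lambda + half)))
}

#' Quantify a ddPCR well
#'
#' Per channel: Poisson-corrected copies per droplet and concentration in
#' copies per microlitre (`lambda / droplet volume`). Fractional abundance
#' is reported twice: `fa_raw` from positive-droplet counts directly, and
#' `fa_corrected` from the Poisson-corrected copy estimates,
#' `lambda_mut / (lambda_mut + lambda_wt) * 100`, matching instrument
#' software behaviour (the default to report). The FA confidence interval
#' propagates the per-channel lambda uncertainties through the ratio.
#'
#' @param well A `ddpcr_well`.
#' @return A `ddpcr_quant` list: `lambda_mut`, `lambda_wt`, `conc_mut`,
#'   `conc_wt` (copies/uL), per-channel `ci95`, `fa_raw`, `fa_corrected`,
#'   `fa_ci95` (percent).
#' @export
quantify_well <- function(well) {
  stopifnot(inherits(well, "ddpcr_well"))
  lm_ <- poisson_lambda(well$pos_mut, well$n_droplets)
  lw_ <- poisson_lambda(well$pos_wt, well$n_droplets)
  vol_ul <- well$droplet_volume / 1000      # nL -> uL
  tot <- lm_$lambda + lw_$lambda
  if (tot == 0)
    stop_data("no template detected on either channel")
  fa_corr <- lm_$lambda / tot * 100
  fa_raw <- fractional_abundance(well$pos_mut, well$pos_wt)
  # delta-method propagation of the channel CIs through m/(m+w)
  se_m <- (lm_$ci95[2] - lm_$lambda) / 1.96
  se_w <- (lw_$ci95[2] - lw_$lambda) / 1.96
  dm <- lw_$lambda / tot^2
  dw <- -lm_$lambda / tot^2
  se_fa <- 100 * sqrt((dm * se_m)^2 + (dw * se_w)^2)
  fa_ci <- c(max(0, fa_corr - 1.96 * se_fa), min(100, fa_corr + 1.96 * se_fa))
  structure(list(well_id = well$well_id,
                 lambda_mut = lm_$lambda, lambda_wt = lw_$lambda,
                 ci95_mut = lm_$ci95, ci95_wt = lw_$ci95,
                 conc_mut = lm_$lambda / vol_ul, conc_wt = lw_$lambda / vol_ul,
                 conc_ci95_mut = lm_$ci95 / vol_ul,
                 conc_ci95_wt = lw_$ci95 / vol_ul,
                 fa_raw = fa_raw, fa_corrected = fa_corr, fa_ci95 = fa_ci),
            class = "ddpcr_quant")
}

#' @export
print.ddpcr_quant <- function(x, ...) {
  cat(sprintf("ddPCR well %s: lambda mut %.4f, wt %.4f; F.A. %.2f%% (95%% CI %.2f-%.2f)\n",
              x$well_id, x$lambda_mut, x$lambda_wt,
              x$fa_corrected, x$fa_ci95[1], x$fa_ci95[2]))
  invisible(x)
}

#' Detect mixed populations in single-cell dilution wells
#'
#' Single-cell-derived clones carry their marker mutations heterozygously,
#' so every detected marker should sit near the expected heterozygous
#' fractional abundance (50% at diploid loci). A well containing a marker
#' clearly below that level must hold a mixture of cells — imperfect single
#' cloning. Classification per well: `mixed` when any detected marker has
#' FA below `expected_het_fa - tolerance`; `pure` when all detected markers
#' lie within `tolerance` of `expected_het_fa`; otherwise `ambiguous`
#' (including wells with no detected marker).
#'
#' @param fa_table Data frame `well_id`, `target`, `fa` (percent), e.g.
#'   built from [quantify_well()] results or
#'   [simulate_single_cell_ddpcr()].
#' @param expected_het_fa Expected FA of a clonal heterozygous marker
#'   (percent).
#' @param tolerance Percent tolerance around the expected value.
#' @param detect_limit Minimum FA (percent) for a marker to count as
#'   detected.
#' @return Data frame `well_id`, `call`, `n_detected`, `min_detected_fa`.
#' @export
detect_mixed_clone <- function(fa_table, expected_het_fa = 50,
                               tolerance = 15, detect_limit = 5) {
  need <- c("well_id", "target", "fa")
  if (!all(need %in% names(fa_table)))
    stop_data("fa_table needs columns well_id, target, fa", class = "cs_parse_error")
  if (nrow(fa_table) < 1)
    stop_config("need at least one well", field = "fa_table")
  wells <- unique(fa_table$well_id)
  res <- lapply(wells, function(w) {
    fa <- fa_table$fa[fa_table$well_id == w]
    det <- fa[fa >= detect_limit]
    call <- if (!length(det)) "ambiguous"
    else if (any(det < expected_het_fa - tolerance)) "mixed"
    else if (all(abs(det - expected_het_fa) <= tolerance)) "pure"
    else "ambiguous"
    data.frame(well_id = w, call = call, n_detected = length(det),
               min_detected_fa = if (length(det)) min(det) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read ddPCR wells from CSV
#'
#' Expects columns `well_id,channel,positives,negatives` with channels
#' `mut` and `wt` per well (the written form of [write_ddpcr_wells()]).
#'
#' @param path CSV path.
#' @param droplet_volume Droplet volume in nanolitres.
#' @return List of `ddpcr_well` objects.
#' @export
read_ddpcr_wells <- function(path, droplet_volume = 0.85) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_data(
                   sprintf("malformed ddPCR CSV '%s': %s", path, conditionMessage(e)),
                   class = "cs_parse_error"))
  need <- c("well_id", "channel", "positives", "negatives")
  if (!all(need %in% names(df)))
    stop_data("ddPCR CSV needs columns well_id, channel, positives, negatives",
              class = "cs_parse_error")
  lapply(unique(df$well_id), function(w) {
    sub <- df[df$well_id == w, ]
    m <- sub[sub$channel == "mut", ]
    wt <- sub[sub$channel == "wt", ]
    if (nrow(m) != 1 || nrow(wt) != 1)
      stop_data(sprintf("well %s must have one 'mut' and one 'wt' channel row", w),
                class = "cs_parse_error")
    ddpcr_well(well_id = w, n_droplets = m$positives + m$negatives,
               pos_mut = m$positives, neg_mut = m$negatives,
               pos_wt = wt$positives, neg_wt = wt$negatives,
               droplet_volume = droplet_volume)
  })
}

#' Write ddPCR wells to CSV
#' @param wells List of `ddpcr_well` objects (or a single one).
#' @param path CSV path.
#' @export
write_ddpcr_wells <- function(wells, path) {
  if (inherits(wells, "ddpcr_well")) wells <- list(wells)
  rows <- do.call(rbind, lapply(wells, function(w) {
    data.frame(well_id = rep(w$well_id, 2), channel = c("mut", "wt"),
               positives = c(w$pos_mut, w$pos_wt),
               negatives = c(w$neg_mut, w$neg_wt),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
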