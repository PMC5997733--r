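#' Simulation configuration for synthetic clonal structures
#'
#' Parameterises the synthetic-data generator that emulates a drug-resistance
#' evolution experiment: a parental (drug-sensitive) cell population gives
#' rise to a resistant population whose cells belong to a rooted tree of
#' subclones. Trunk variants are somatic mutations already present in the
#' parental line (and therefore removed by parental subtraction); acquired
#' variants arise on the resistant clone tree; germline variants are shared
#' heterozygous background.
#'
#' @param n_clones Number of subclonal populations in the resistant line
#'   (including the founder clone at the root).
#' @param n_trunk_variants Somatic variants shared by parental and resistant
#'   samples (subtracted out during somatic calling).
#' @param mean_novel_variants_per_clone Poisson mean of the number of novel
#'   variants each clone acquires (minimum 1 enforced).
#' @param nonsynonymous_fraction Probability that a simulated variant is
#'   non-synonymous.
#' @param mean_depth Mean sequencing depth (reads) per variant site and per
#'   capture target region.
#' @param depth_dispersion Negative-binomial size parameter of the depth
#'   distribution; `Inf` degenerates to Poisson depths.
#' @param sequencing_error_rate Per-read probability of observing the
#'   alternate allele at a site not carried by the sample.
#' @param n_germline_variants Heterozygous germline variants present in both
#'   samples at expected VAF 0.5.
#' @param cn_events Named list or vector mapping gene id to integer total
#'   copy number (genes absent from it are diploid).
#' @param droplet_count Droplets generated per ddPCR well.
#' @param droplet_volume Droplet volume in nanolitres.
#' @param regions_per_gene Capture target regions simulated per gene.
#' @param n_genes Number of genes in the simulated capture design; default
#'   scales with the number of variants.
#' @param min_prevalence_gap Optional lower bound on the pairwise separation
#'   of clone cellular prevalences (and on the smallest prevalence). Drawn
#'   prevalence vectors are rejected until the bound holds; 0 disables the
#'   constraint.
#' @param seed Integer seed; identical configurations yield identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clones = 5L,
                       n_trunk_variants = 40L,
                       mean_novel_variants_per_clone = 20,
                       nonsynonymous_fraction = 0.7,
                       mean_depth = 150,
                       depth_dispersion = 100,
                       sequencing_error_rate = 0,
                       n_germline_variants = 100L,
                       cn_events = list(),
                       droplet_count = 15000L,
                       droplet_volume = 0.85,
                       regions_per_gene = 16L,
                       n_genes = NULL,
                       min_prevalence_gap = 0,
                       seed = 1L) {
  cfg <- list(n_clones = as.integer(n_clones),
              n_trunk_variants = as.integer(n_trunk_variants),
              mean_novel_variants_per_clone = mean_novel_variants_per_clone,
              nonsynonymous_fraction = nonsynonymous_fraction,
              mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              sequencing_error_rate = sequencing_error_rate,
              n_germline_variants = as.integer(n_germline_variants),
              cn_events = cn_events,
              droplet_count = as.integer(droplet_count),
              droplet_volume = droplet_volume,
              regions_per_gene = as.integer(regions_per_gene),
              n_genes = if (is.null(n_genes)) NULL else as.integer(n_genes),
              min_prevalence_gap = min_prevalence_gap,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop_config(sprintf("invalid simulation configuration: %s", what),
                                 field = field)
  }
  chk(length(cfg$n_clones) == 1 && !is.na(cfg$n_clones) && cfg$n_clones >= 1L,
      "n_clones", "must be an integer >= 1")
  chk(cfg$n_trunk_variants >= 0L, "n_trunk_variants", "must be >= 0")
  chk(is.numeric(cfg$mean_novel_variants_per_clone) &&
        cfg$mean_novel_variants_per_clone > 0,
      "mean_novel_variants_per_clone", "must be a positive real")
  chk(cfg$nonsynonymous_fraction >= 0 && cfg$nonsynonymous_fraction <= 1,
      "nonsynonymous_fraction", "must lie in [0,1]")
  chk(is.numeric(cfg$mean_depth) && cfg$mean_depth > 0,
      "mean_depth", "must be positive")
  chk(is.numeric(cfg$depth_dispersion) && cfg$depth_dispersion > 0,
      "depth_dispersion", "must be positive (Inf allowed)")
  chk(cfg$sequencing_error_rate >= 0 && cfg$sequencing_error_rate < 1,
      "sequencing_error_rate", "must lie in [0,1)")
  chk(cfg$n_germline_variants >= 0L, "n_germline_variants", "must be >= 0")
  if (length(cfg$cn_events)) {
    chk(!is.null(names(cfg$cn_events)) && all(nzchar(names(cfg$cn_events))),
        "cn_events", "must be named by gene id")
    chk(all(unlist(cfg$cn_events) >= 0), "cn_events", "copy numbers must be >= 0")
  }
  chk(cfg$droplet_count >= 1L, "droplet_count", "must be >= 1")
  chk(cfg$droplet_volume > 0, "droplet_volume", "must be positive (nanolitres)")
  chk(cfg$regions_per_gene >= 1L, "regions_per_gene", "must be >= 1")
  chk(cfg$min_prevalence_gap >= 0 && cfg$min_prevalence_gap < 1,
      "min_prevalence_gap", "must lie in [0,1)")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed", "must be a single integer")
  invisible(cfg)
}

#' Simulate a ground-truth clone tree
#'
#' Draws a rooted tree of subclonal populations: the root is the founder of
#' the resistant population; every other clone attaches uniformly at random
#' to an earlier clone. Each clone acquires a Poisson number of novel
#' variants (minimum 1); subtree-exclusive subpopulation fractions are drawn
#' by symmetric stick-breaking and normalised to sum to 1. The cumulative
#' mutation set of a clone is the union of the novel sets on its path from
#' the root, so cumulative sets always form a laminar family.
#'
#' @param config A [sim_config()].
#' @return A `clone_truth` object: parent vector, per-clone novel mutation
#'   sets, exclusive fractions and cumulative cellular prevalences, the full
#'   simulated variant catalogue (germline / trunk / acquired), per-gene copy
#'   number, the implied clones-by-mutations incidence matrix, and the true
#'   fractional abundance of every acquired variant.
#' @export
simulate_clone_tree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  K <- config$n_clones

  draw_tree <- function() {
    p <- rep(NA_integer_, K)
    if (K > 1L) for (i in 2:K) p[i] <- sample.int(i - 1L, 1L)
    p
  }
  draw_fractions <- function() {
    v <- stats::runif(K)
    w <- v * cumprod(c(1, 1 - v[-K]))
    w / sum(w)
  }
  cum_from <- function(p, frac) {
    cum <- frac
    if (K > 1L) for (i in K:2) cum[p[i]] <- cum[p[i]] + cum[i]
    cum
  }

  parent <- draw_tree()
  fractions <- draw_fractions()
  cum_prev <- cum_from(parent, fractions)
  gap <- config$min_prevalence_gap
  if (gap > 0 && K > 1L) {
    # topology and fractions are rejected jointly: star-like trees cannot
    # satisfy a pairwise gap on cumulative prevalences, whatever the
    # fractions, so redrawing fractions alone could loop forever
    ok <- function(cp) min(cp) >= gap && min(diff(sort(cp))) >= gap
    attempts <- 1L
    while (!ok(cum_prev)) {
      attempts <- attempts + 1L
      if (attempts > 1000000L)
        stop_config("could not satisfy min_prevalence_gap after 1e6 draws",
                    field = "min_prevalence_gap")
      parent <- draw_tree()
      fractions <- draw_fractions()
      cum_prev <- cum_from(parent, fractions)
    }
  }

  n_novel <- pmax(1L, stats::rpois(K, config$mean_novel_variants_per_clone))

  n_acq <- sum(n_novel)
  n_tot <- config$n_germline_variants + config$n_trunk_variants + n_acq

  n_genes <- if (is.null(config$n_genes)) max(20L, ceiling(n_tot / 3)) else config$n_genes
  cn_genes <- names(config$cn_events)
  gene_ids <- unique(c(cn_genes, sprintf("GENE%04d", seq_len(n_genes))))[seq_len(max(n_genes, length(cn_genes)))]
  gene_chrom <- sample(paste0("chr", 1:22), length(gene_ids), replace = TRUE)
  # lay genes out on disjoint megabase slots so coordinates never collide
  gene_start <- integer(length(gene_ids))
  for (ch in unique(gene_chrom)) {
    idx <- which(gene_chrom == ch)
    gene_start[idx] <- 100000L + (seq_along(idx) - 1L) * 1000000L
  }
  span <- config$regions_per_gene * 2000L
  genes <- data.frame(gene = gene_ids, chrom = gene_chrom,
                      start = gene_start, end = gene_start + span,
                      stringsAsFactors = FALSE)

  gene_cn <- stats::setNames(rep(2, length(gene_ids)), gene_ids)
  if (length(config$cn_events))
    gene_cn[names(config$cn_events)] <- as.numeric(unlist(config$cn_events))

  vclass <- c(rep("germline", config$n_germline_variants),
              rep("trunk", config$n_trunk_variants),
              rep("acquired", n_acq))
  vclone <- c(rep(NA_character_, n_tot - n_acq),
              rep(sprintf("clone%d", seq_len(K)), times = n_novel))
  vgene <- sample(gene_ids, n_tot, replace = TRUE)
  pos <- integer(n_tot)
  for (g in unique(vgene)) {
    idx <- which(vgene == g)
    gi <- match(g, gene_ids)
    pos[idx] <- gene_start[gi] + sample.int(span, length(idx))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_tot, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  effect <- ifelse(stats::runif(n_tot) < config$nonsynonymous_fraction,
                   "nonsynonymous", "synonymous")
  variants <- data.frame(
    chrom = gene_chrom[match(vgene, gene_ids)],
    pos = pos, ref = ref, alt = alt,
    gene = vgene, effect = effect,
    class = vclass, clone = vclone,
    multiplicity = 1L,
    stringsAsFactors = FALSE)
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  stopifnot(!anyDuplicated(variants$key))

  clone_ids <- sprintf("clone%d", seq_len(K))
  novel <- lapply(clone_ids, function(cl) sort(variants$key[!is.na(variants$clone) & variants$clone == cl]))
  names(novel) <- clone_ids

  ancestors <- function(i) {           # root-to-i path, indices
    path <- i
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  }
  acq_keys <- sort(variants$key[variants$class == "acquired"])
  incidence <- matrix(FALSE, nrow = K, ncol = length(acq_keys),
                      dimnames = list(clone_ids, acq_keys))
  for (i in seq_len(K)) {
    carried <- sort(unlist(novel[ancestors(i)], use.names = FALSE))
    incidence[i, carried] <- TRUE
  }
  cmatrix <- new_clone_matrix(
    clones = data.frame(clone = clone_ids, prevalence = cum_prev,
                        stringsAsFactors = FALSE),
    mutations = acq_keys, incidence = incidence)

  acq <- variants[variants$class == "acquired", ]
  carrier <- cum_prev[match(acq$clone, clone_ids)]
  truth_fa <- stats::setNames(
    carrier * acq$multiplicity / gene_cn[acq$gene], acq$key)

  structure(list(clones = clone_ids, parent = parent,
                 fractions = fractions, cum_prev = cum_prev,
                 n_novel = n_novel, novel = novel,
                 variants = variants, genes = genes, gene_cn = gene_cn,
                 matrix = cmatrix, truth_fa = truth_fa,
                 config = config),
            class = "clone_truth")
}

#' @export
print.clone_truth <- function(x, ...) {
  cat(sprintf("Ground-truth clone tree: %d clones, %d acquired / %d trunk / %d germline variants\n",
              length(x$clones), sum(x$n_novel),
              x$config$n_trunk_variants, x$config$n_germline_variants))
  cat("cellular prevalences:",
      paste(sprintf("%s=%.3f", x$clones, x$cum_prev), collapse = ", "), "\n")
  invisible(x)
}

r_depth <- function(n, mean_depth, dispersion) {
  d <- if (is.infinite(dispersion)) stats::rpois(n, mean_depth)
       else stats::rnbinom(n, size = dispersion, mu = mean_depth)
  pmax(d, 1L)
}

#' Simulate paired read-count tables and a depth profile
#'
#' Produces the raw inputs of the analysis pipeline from a ground truth:
#' a parental variant table (germline + trunk variants), a resistant table
#' (germline + trunk + acquired variants) and a per-target-region depth
#' profile reflecting the configured copy-number events multiplicatively.
#'
#' Per variant, depth is negative-binomial (mean `mean_depth`, size
#' `depth_dispersion`) and alternate reads are binomial with success
#' probability equal to the expected VAF: (cell fraction carrying the
#' variant x multiplicity) / local total copy number. Germline variants are
#' heterozygous at expected VAF 0.5 in both samples. When the sequencing
#' error rate is positive, sites not carried by the parental sample can
#' appear in its table with alternate reads drawn at the error rate.
#'
#' @param truth A `clone_truth` from [simulate_clone_tree()].
#' @param config The same [sim_config()] used to build `truth`.
#' @return A `clone_sim` list: `parental` and `resistant` variant tables,
#'   `depth_profile`, plus the `truth` and `config` used.
#' @export
simulate_read_counts <- function(truth, config) {
  stopifnot(inherits(truth, "clone_truth"))
  validate_sim_config(config)
  set.seed(config$seed + 1000L)

  v <- truth$variants
  copies <- truth$gene_cn[v$gene]
  carrier <- ifelse(v$class == "acquired",
                    truth$cum_prev[match(v$clone, truth$clones)],
                    1)
  exp_vaf <- ifelse(v$class == "germline", 0.5,
                    pmin(1, carrier * v$multiplicity / copies))

  sample_counts <- function(idx, p) {
    depth <- r_depth(length(idx), config$mean_depth, config$depth_dispersion)
    alt <- stats::rbinom(length(idx), depth, p)
    data.frame(chrom = v$chrom[idx], pos = v$pos[idx],
               ref = v$ref[idx], alt = v$alt[idx],
               gene = v$gene[idx], effect = v$effect[idx],
               alt_reads = alt, ref_reads = depth - alt,
               stringsAsFactors = FALSE)
  }

  par_idx <- which(v$class %in% c("germline", "trunk"))
  par_df <- sample_counts(par_idx, exp_vaf[par_idx])
  err <- config$sequencing_error_rate
  if (err > 0) {
    acq_idx <- which(v$class == "acquired")
    noise <- sample_counts(acq_idx, rep(err, length(acq_idx)))
    par_df <- rbind(par_df, noise[noise$alt_reads > 0, ])
  }
  res_idx <- seq_len(nrow(v))
  res_df <- sample_counts(res_idx, exp_vaf)

  prof_gene <- rep(truth$genes$gene, each = config$regions_per_gene)
  reg_off <- (seq_len(config$regions_per_gene) - 1L) * 2000L
  reg_start <- rep(truth$genes$start, each = config$regions_per_gene) +
    rep(reg_off, times = nrow(truth$genes))
  cn <- truth$gene_cn[prof_gene]
  reg_depth <- if (is.infinite(config$depth_dispersion))
    stats::rpois(length(prof_gene), config$mean_depth * cn / 2)
  else
    stats::rnbinom(length(prof_gene), size = config$depth_dispersion,
                   mu = config$mean_depth * cn / 2)
  profile <- depth_profile(data.frame(
    chrom = rep(truth$genes$chrom, each = config$regions_per_gene),
    start = reg_start, end = reg_start + 150L,
    gene = prof_gene, median_depth = as.numeric(reg_depth),
    stringsAsFactors = FALSE))

  structure(list(parental = variant_table(par_df, sample_id = "parental"),
                 resistant = variant_table(res_df, sample_id = "resistant"),
                 depth_profile = profile,
                 truth = truth, config = config),
            class = "clone_sim")
}

#' Simulate a droplet digital PCR well
#'
#' Mutant and wild-type template copies are loaded into droplets under
#' independent Poisson partitioning: with `D` droplets and `M` copies of a
#' template, each droplet holds Poisson(`M/D`) copies and is channel-positive
#' when it holds at least one.
#'
#' @param true_fa True fractional abundance of the mutant allele, in [0,1].
#' @param total_copies Total template copies loaded into the well.
#' @param config A [sim_config()] supplying `droplet_count`, `droplet_volume`
#'   and `seed`.
#' @param well_id Well label.
#' @return A one-row `ddpcr_well` data frame (positive/negative droplet
#'   counts per channel).
#' @export
simulate_ddpcr_well <- function(true_fa, total_copies, config, well_id = "A01") {
  if (!is.numeric(true_fa) || length(true_fa) != 1 || is.na(true_fa) ||
      true_fa < 0 || true_fa > 1)
    stop_config("true_fa must lie in [0,1]", field = "true_fa")
  validate_sim_config(config)
  set.seed(config$seed + 2000L)
  D <- config$droplet_count
  pos_mut <- stats::rbinom(1L, D, 1 - exp(-total_copies * true_fa / D))
  pos_wt <- stats::rbinom(1L, D, 1 - exp(-total_copies * (1 - true_fa) / D))
  ddpcr_well(well_id = well_id, n_droplets = D,
             pos_mut = pos_mut, neg_mut = D - pos_mut,
             pos_wt = pos_wt, neg_wt = D - pos_wt,
             droplet_volume = config$droplet_volume)
}

#' Simulate single-cell dilution wells
#'
#' Each well receives one clone sampled by its subtree-exclusive population
#' fraction; with probability `mixing_rate` a second, distinct clone is added
#' (imperfect single cloning). The genotype of a well is the union of the
#' cumulative mutation sets of its clones.
#'
#' @param truth A `clone_truth`.
#' @param n_wells Number of wells.
#' @param mixing_rate Probability that a well receives two clones.
#' @param seed Integer seed.
#' @return An `sc_wells` list; each element has `well_id`, `clones`
#'   (character vector of 1 or 2 clone ids) and `genotype` (variant keys).
#' @export
simulate_single_cell_wells <- function(truth, n_wells, mixing_rate, seed) {
  stopifnot(inherits(truth, "clone_truth"))
  if (n_wells < 1) stop_config("n_wells must be >= 1", field = "n_wells")
  if (mixing_rate < 0 || mixing_rate > 1)
    stop_config("mixing_rate must lie in [0,1]", field = "mixing_rate")
  set.seed(seed)
  K <- length(truth$clones)
  cum_sets <- lapply(seq_len(K), function(i) colnames(truth$matrix$incidence)[truth$matrix$incidence[i, ]])
  first <- sample.int(K, n_wells, replace = TRUE, prob = truth$fractions)
  mixed <- stats::runif(n_wells) < mixing_rate & K > 1L
  wells <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    cl <- first[w]
    if (mixed[w]) {
      others <- setdiff(seq_len(K), cl)
      p <- truth$fractions[others]
      cl <- c(cl, others[sample.int(length(others), 1L, prob = p / sum(p))])
    }
    wells[[w]] <- list(well_id = sprintf("W%03d", w),
                       clones = truth$clones[cl],
                       genotype = sort(unique(unlist(cum_sets[cl]))))
  }
  structure(wells, class = "sc_wells")
}

#' Simulate a clone-marker ddPCR panel over single-cell wells
#'
#' Assays one marker variant per clone (its first novel variant) on every
#' well, assuming clones contribute equal cell numbers to a well. The true
#' fractional abundance of a marker is (fraction of cells carrying it x
#' multiplicity) / local copy number; droplet counts are then generated as in
#' [simulate_ddpcr_well()] and quantified with [quantify_well()].
#'
#' @param truth A `clone_truth`.
#' @param wells An `sc_wells` object.
#' @param config A [sim_config()].
#' @param total_copies Template copies loaded per well and assay.
#' @return Data frame `well_id`, `target` (marker key), `marker_clone`,
#'   `true_fa` (percent) and `fa` (Poisson-corrected percent estimate).
#' @export
simulate_single_cell_ddpcr <- function(truth, wells, config, total_copies = 3000) {
  stopifnot(inherits(truth, "clone_truth"), inherits(wells, "sc_wells"))
  validate_sim_config(config)
  set.seed(config$seed + 3000L)
  markers <- vapply(truth$novel, function(k) k[1L], character(1))
  mgene <- truth$variants$gene[match(markers, truth$variants$key)]
  copies <- truth$gene_cn[mgene]
  D <- config$droplet_count
  # cumulative carrier sets per clone
  carries <- lapply(seq_along(truth$clones),
                    function(i) colnames(truth$matrix$incidence)[truth$matrix$incidence[i, ]])
  names(carries) <- truth$clones
  out <- list()
  for (w in wells) {
    cell_frac <- vapply(seq_along(markers), function(m) {
      mean(vapply(w$clones, function(cl) markers[m] %in% carries[[cl]], logical(1)))
    }, numeric(1))
    fa_true <- cell_frac * 1 / copies
    for (m in seq_along(markers)) {
      pos_mut <- stats::rbinom(1L, D, 1 - exp(-total_copies * fa_true[m] / D))
      pos_wt <- stats::rbinom(1L, D, 1 - exp(-total_copies * (1 - fa_true[m]) / D))
      well <- ddpcr_well(well_id = w$well_id, n_droplets = D,
                         pos_mut = pos_mut, neg_mut = D - pos_mut,
                         pos_wt = pos_wt, neg_wt = D - pos_wt,
                         droplet_volume = config$droplet_volume)
      q <- quantify_well(well)
      out[[length(out) + 1L]] <- data.frame(
        well_id = w$well_id, target = markers[m],
        marker_clone = truth$clones[m],
        true_fa = 100 * fa_true[m], fa = q$fa_corrected,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `parental.vcf`/`.tsv`, `resistant.vcf`/`.tsv`, `targets.bed`,
#' `depth_profile.tsv` and `truth.json` under `dir`.
#'
#' @param sim A `clone_sim` from [simulate_read_counts()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "clone_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    parental_vcf = file.path(dir, "parental.vcf"),
    parental_tsv = file.path(dir, "parental.tsv"),
    resistant_vcf = file.path(dir, "resistant.vcf"),
    resistant_tsv = file.path(dir, "resistant.tsv"),
    bed = file.path(dir, "targets.bed"),
    depth = file.path(dir, "depth_profile.tsv"),
    truth = file.path(dir, "truth.json"))
  write_variants(sim$parental, paths["parental_vcf"], format = "vcf")
  write_variants(sim$parental, paths["parental_tsv"], format = "tsv")
  write_variants(sim$resistant, paths["resistant_vcf"], format = "vcf")
  write_variants(sim$resistant, paths["resistant_tsv"], format = "tsv")
  write_depth_profile(sim$depth_profile, bed_path = paths["bed"],
                      depth_path = paths["depth"])
  write_ground_truth(sim$truth, paths["truth"])
  invisible(paths)
}

#' Serialise a ground truth to JSON
#' @param truth A `clone_truth`.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "clone_truth"))
  obj <- list(clones = truth$clones,
              parent = ifelse(is.na(truth$parent), -1L, truth$parent),
              fractions = truth$fractions,
              cum_prev = truth$cum_prev,
              novel = truth$novel,
              gene_cn = as.list(truth$gene_cn),
              truth_fa = as.list(truth$truth_fa),
              variants = truth$variants)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
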