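# Fixtures are built in code; nothing binary is stored on disk.

# clone-mutation matrix from a named list of cumulative mutation sets
matrix_from_sets <- function(sets, prevalence = NULL) {
  ids <- names(sets)
  keys <- sort(unique(unlist(sets)))
  inc <- matrix(FALSE, length(ids), length(keys), dimnames = list(ids, keys))
  for (i in seq_along(ids)) inc[i, sets[[i]]] <- TRUE
  if (is.null(prevalence)) prevalence <- seq(1, 0.1, length.out = length(ids))
  new_clone_matrix(data.frame(clone = ids, prevalence = prevalence,
                              stringsAsFactors = FALSE),
                   keys, inc)
}

# subclone_clusters object straight from prevalences + member sets
clusters_from <- function(prevalence, members) {
  ids <- sprintf("C%d", seq_along(prevalence))
  names(members) <- ids
  structure(list(clusters = data.frame(
    cluster = ids, prevalence = prevalence,
    n_total = lengths(members),
    n_nonsynonymous = 0L, stringsAsFactors = FALSE),
    members = members, n_filtered = 0L),
    class = "subclone_clusters")
}

# small variant table from keys "chrom:pos:ref:alt"
table_from_keys <- function(keys, sample_id = "s", alt = 10L, ref = 10L) {
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  variant_table(data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                           ref = parts[, 3], alt = parts[, 4],
                           alt_reads = alt, ref_reads = ref,
                           stringsAsFactors = FALSE),
                sample_id = sample_id)
}

# binomial prevalence estimates around given true cluster prevalences
estimates_from <- function(prev, n, depth, copies = 2, seed = 1) {
  set.seed(seed)
  rows <- list()
  idx <- 0
  for (g in seq_along(prev)) {
    for (i in seq_len(n[g])) {
      idx <- idx + 1
      d <- depth
      a <- rbinom(1, d, prev[g] / copies)
      rows[[idx]] <- data.frame(key = sprintf("chr1:%d:A:T", idx),
                                alt_reads = a, ref_reads = d - a,
                                stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  est <- cellular_prevalence(df$alt_reads, df$ref_reads,
                             local_copies = copies, key = df$key)
  est$depth <- df$alt_reads + df$ref_reads
  est$alt_reads <- df$alt_reads
  est$effect <- "other"
  est
}

# random ground-truth laminar system (small novel sets, no background)
random_laminar_truth <- function(K, seed) {
  simulate_clone_tree(sim_config(n_clones = K, mean_novel_variants_per_clone = 3,
                                 n_trunk_variants = 0, n_germline_variants = 0,
                                 seed = seed))
}

easy_regime_config <- function(seed, outdir = tempfile()) {
  list(seed = seed, outdir = outdir,
       simulate = list(n_clones = 5, mean_depth = 300,
                       min_prevalence_gap = 0.15, sequencing_error_rate = 0))
}

is_chain <- function(truth) {
  sum(table(truth$parent[!is.na(truth$parent)]) > 1) == 0
}
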