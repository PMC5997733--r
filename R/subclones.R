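# Desk-scale subclone inference: VAF + copy number -> cellular prevalence,
# 1-D kernel-density clustering into subclonal populations, and greedy
# sum-rule nesting into a clones x mutations incidence matrix. This stage is
# a deliberately simple stand-in for heavyweight subclonal-deconvolution
# tools: its contract is the interface (per-cluster prevalences plus the
# mutation matrix the tree builder consumes), not any particular algorithm.

#' Clustering and nesting parameters for subclone inference
#'
#' @param method Clustering engine: `"gmm"` (default) fits 1-D Gaussian
#'   mixtures whose per-variant standard deviations are fixed at the known
#'   binomial counting error of the prevalence estimate and selects the
#'   number of subclones by BIC; `"kde"` finds local maxima of a
#'   fixed-bandwidth kernel density over the prevalence values.
#' @param min_depth Minimum read depth for a variant to enter clustering.
#' @param min_alt Minimum alternate reads.
#' @param bandwidth Gaussian kernel bandwidth on the cellular prevalence
#'   axis (`"kde"` method only).
#' @param max_clusters Largest number of mixture components considered
#'   (`"gmm"` method only).
#' @param min_separation Cluster centres closer than this are merged
#'   (weighted mean).
#' @param min_cluster_size Clusters below this size are dissolved into the
#'   nearest surviving centre.
#' @param nesting_tolerance Slack allowed when testing the pigeonhole sum
#'   rule during greedy nesting.
#' @param baseline_ploidy Copies corresponding to GCN 1.
#' @return A `subclone_params` list.
#' @export
subclone_params <- function(method = c("gmm", "kde"),
                            min_depth = 20L, min_alt = 3L,
                            bandwidth = 0.05, max_clusters = 8L,
                            min_separation = 0.05,
                            min_cluster_size = 3L, nesting_tolerance = 0.05,
                            baseline_ploidy = 2) {
  p <- list(method = match.arg(method),
            min_depth = as.integer(min_depth), min_alt = as.integer(min_alt),
            bandwidth = bandwidth, max_clusters = as.integer(max_clusters),
            min_separation = min_separation,
            min_cluster_size = as.integer(min_cluster_size),
            nesting_tolerance = nesting_tolerance,
            baseline_ploidy = baseline_ploidy)
  if (p$bandwidth <= 0 || p$min_separation < 0 || p$nesting_tolerance < 0 ||
      p$min_cluster_size < 1L || p$min_depth < 0L || p$min_alt < 0L ||
      p$max_clusters < 1L)
    stop_config("invalid subclone parameters", field = "subclone_params")
  class(p) <- "subclone_params"
  p
}

#' Cellular prevalence of a single variant
#'
#' Converts a variant allele fraction into the fraction of cells carrying
#' the variant: `cp = vaf * local_copies / multiplicity`, capped at 1.
#' These are pure cell populations (no stromal admixture), so no purity
#' term appears.
#'
#' @param alt_reads,ref_reads Read counts (alt + ref must be positive).
#' @param local_copies Local total copy number at the variant site.
#' @param multiplicity Copies of the variant allele per carrying cell.
#' @param key Variant key used in error messages and output.
#' @return One-row data frame: `key`, `vaf`, `local_copies`, `multiplicity`,
#'   `cp`, `capped`.
#' @export
cellular_prevalence <- function(alt_reads, ref_reads, local_copies,
                                multiplicity = 1L, key = NA_character_) {
  depth <- alt_reads + ref_reads
  if (any(is.na(depth)) || any(depth <= 0))
    stop_data(sprintf("zero depth for variant %s: cannot estimate prevalence",
                      paste(key[is.na(depth) | depth <= 0], collapse = ", ")))
  if (any(local_copies <= 0))
    stop_config("local_copies must be positive", field = "local_copies")
  if (any(multiplicity < 1))
    stop_config("multiplicity must be a positive integer", field = "multiplicity")
  vaf <- alt_reads / depth
  raw <- vaf * local_copies / multiplicity
  data.frame(key = key, vaf = vaf, local_copies = local_copies,
             multiplicity = as.integer(multiplicity),
             cp = pmin(1, raw), cp_raw = raw, capped = raw > 1,
             stringsAsFactors = FALSE)
}

#' Cellular prevalence estimates for an acquired-variant table
#'
#' Vectorised convenience wrapper: looks up each variant's local copy
#' number by gene (genes absent from `copies` are taken at baseline
#' ploidy) and returns the per-variant prevalence estimates together with
#' depth, alternate reads and effect, ready for [cluster_prevalences()].
#'
#' @param table A `variant_table` of acquired variants.
#' @param copies Named vector of absolute copies per gene
#'   (see [absolute_copies()]).
#' @param params A [subclone_params()].
#' @return Data frame of prevalence estimates.
#' @export
prevalence_table <- function(table, copies = numeric(),
                             params = subclone_params()) {
  stopifnot(inherits(table, "variant_table"))
  key <- variant_keys(table)
  local <- rep(params$baseline_ploidy, nrow(table))
  hit <- !is.na(table$gene) & table$gene %in% names(copies)
  local[hit] <- copies[table$gene[hit]]
  est <- cellular_prevalence(table$alt_reads, table$ref_reads,
                             local_copies = local, key = key)
  est$depth <- table$alt_reads + table$ref_reads
  est$alt_reads <- table$alt_reads
  est$effect <- table$effect
  est
}

# nearest-centre assignment; ties broken toward the higher prevalence
assign_nearest <- function(values, centres) {
  vapply(values, function(v) {
    d <- abs(v - centres)
    cand <- which(d == min(d))
    cand[which.max(centres[cand])]
  }, integer(1))
}

# candidate centres from local maxima of a fixed-bandwidth Gaussian KDE
cluster_centres_kde <- function(cp, params) {
  bw <- params$bandwidth
  dens <- stats::density(cp, bw = bw, from = min(cp) - 3 * bw,
                         to = max(cp) + 3 * bw, n = 1024)
  y <- dens$y
  is_max <- c(FALSE, diff(y) > 0) & c(diff(y) <= 0, FALSE)
  peaks <- dens$x[is_max]
  if (!length(peaks)) peaks <- dens$x[which.max(y)]
  sort(peaks)
}

# 1-D Gaussian mixture with KNOWN per-point standard deviations (the
# binomial counting error of each prevalence estimate); only the component
# means and weights are free, and the number of components is chosen by
# BIC. Deterministic: means are initialised at quantiles.
cluster_centres_gmm <- function(cp, sigma, params) {
  n <- length(cp)
  g_max <- max(1L, min(params$max_clusters, n %/% params$min_cluster_size))
  fit_g <- function(G) {
    mu <- as.numeric(stats::quantile(cp, probs = (2 * seq_len(G) - 1) / (2 * G),
                                     type = 8))
    pi_k <- rep(1 / G, G)
    w <- 1 / sigma^2
    ll_old <- -Inf
    ll <- -Inf
    for (it in seq_len(500L)) {
      dens <- vapply(seq_len(G), function(k)
        pi_k[k] * stats::dnorm(cp, mu[k], sigma), numeric(n))
      dens <- matrix(dens, nrow = n)
      tot <- pmax(rowSums(dens), .Machine$double.xmin)
      ll <- sum(log(tot))
      r <- dens / tot
      denom <- colSums(r * w)
      mu <- ifelse(denom > 0, colSums(r * w * cp) / denom, mu)
      pi_k <- colMeans(r)
      if (abs(ll - ll_old) < 1e-9) break
      ll_old <- ll
    }
    list(mu = mu, ll = ll, bic = -2 * ll + (2 * G - 1) * log(n))
  }
  fits <- lapply(seq_len(g_max), fit_g)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  sort(unique(best$mu))
}

#' Cluster cellular prevalences into subclonal populations
#'
#' After depth/alt-read filtering, candidate subclone prevalences are found
#' on the uncapped prevalence scale (truncating at 1 first would pile
#' clonal variants into an atom at 1.0): by default a 1-D Gaussian mixture
#' with the per-variant standard deviation fixed at its known binomial
#' counting error, the number of subclones selected by BIC
#' (`method = "gmm"`); alternatively the local maxima of a fixed-bandwidth
#' kernel density (`method = "kde"`). Each variant is then assigned to the
#' nearest centre (ties toward the higher prevalence), centres closer than
#' `min_separation` are merged by member-weighted mean, and clusters below
#' `min_cluster_size` are dissolved into the nearest surviving centre.
#' Cluster prevalence is the mean prevalence of its members, capped at 1.
#'
#' @param estimates Data frame from [prevalence_table()] (needs `key`,
#'   `cp`, `cp_raw`, `vaf`, `local_copies`, `multiplicity`, `depth`,
#'   `alt_reads`, optionally `effect`).
#' @param params A [subclone_params()].
#' @return A `subclone_clusters` object: `clusters` data frame (id,
#'   prevalence, n_total, n_nonsynonymous) sorted by descending prevalence,
#'   and `members`, a named list of variant keys.
#' @export
cluster_prevalences <- function(estimates, params = subclone_params()) {
  if (is.null(estimates$effect)) estimates$effect <- "other"
  keep <- estimates$depth >= params$min_depth & estimates$alt_reads >= params$min_alt
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est) < params$min_cluster_size)
    stop_inference(sprintf(
      "only %d variants pass filtering (min_cluster_size = %d); cannot cluster",
      nrow(est), params$min_cluster_size))

  cp <- if (!is.null(est$cp_raw)) est$cp_raw else est$cp
  peaks <- if (params$method == "gmm") {
    mult <- if (is.null(est$multiplicity)) 1 else est$multiplicity
    sigma <- est$local_copies / mult *
      sqrt(pmax(est$vaf * (1 - est$vaf), 0.25 / est$depth) / est$depth)
    cluster_centres_gmm(cp, pmax(sigma, 1e-4), params)
  } else {
    cluster_centres_kde(cp, params)
  }

  member_of <- assign_nearest(cp, peaks)
  # merge centres closer than min_separation, member-count-weighted
  repeat {
    if (length(peaks) < 2) break
    gaps <- diff(peaks)
    if (min(gaps) >= params$min_separation) break
    i <- which.min(gaps)
    w1 <- sum(member_of == i); w2 <- sum(member_of == i + 1L)
    merged <- if (w1 + w2 > 0) (peaks[i] * w1 + peaks[i + 1L] * w2) / (w1 + w2)
              else mean(peaks[i + 0:1])
    peaks <- c(peaks[seq_len(i - 1L)], merged,
               peaks[setdiff(seq_along(peaks), seq_len(i + 1L))])
    member_of <- assign_nearest(cp, peaks)
  }
  # dissolve undersized clusters into the nearest surviving centre
  repeat {
    sizes <- tabulate(member_of, nbins = length(peaks))
    small <- which(sizes > 0 & sizes < params$min_cluster_size)
    if (!length(small) || sum(sizes >= params$min_cluster_size) == 0) break
    victim <- small[which.min(sizes[small])]
    peaks <- peaks[-victim]
    member_of <- assign_nearest(cp, peaks)
  }
  sizes <- tabulate(member_of, nbins = length(peaks))
  live <- which(sizes >= params$min_cluster_size)
  if (!length(live))
    stop_inference("no cluster reaches min_cluster_size; subclone inference failed")
  peaks <- peaks[live]
  member_of <- assign_nearest(cp, peaks)

  prev <- vapply(seq_along(peaks),
                 function(i) min(1, mean(cp[member_of == i])), numeric(1))
  ord <- order(-prev, peaks)
  clusters <- data.frame(
    cluster = sprintf("C%d", seq_along(ord)),
    prevalence = prev[ord],
    n_total = vapply(ord, function(i) sum(member_of == i), integer(1)),
    n_nonsynonymous = vapply(ord, function(i)
      sum(est$effect[member_of == i] == "nonsynonymous"), integer(1)),
    stringsAsFactors = FALSE)
  members <- lapply(ord, function(i) sort(est$key[member_of == i]))
  names(members) <- clusters$cluster
  structure(list(clusters = clusters, members = members,
                 n_filtered = sum(!keep)),
            class = "subclone_clusters")
}

#' @export
print.subclone_clusters <- function(x, ...) {
  cat(sprintf("Subclone clusters: %d populations (%d variants filtered out)\n",
              nrow(x$clusters), x$n_filtered))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Construct a clones x mutations incidence matrix
#'
#' @param clones Data frame `clone`, `prevalence`.
#' @param mutations Character vector of variant keys (column order).
#' @param incidence Logical matrix, rows = clones, cols = mutations; entry
#'   TRUE when the mutation is carried (novel or inherited) by that clone.
#' @param flags Character vector of structural flags.
#' @return A `clone_matrix`.
#' @export
new_clone_matrix <- function(clones, mutations, incidence, flags = character()) {
  stopifnot(nrow(incidence) == nrow(clones), ncol(incidence) == length(mutations))
  dimnames(incidence) <- list(clones$clone, mutations)
  if (anyDuplicated(incidence) > 0)
    stop_structure("incidence matrix rows are not distinct")
  structure(list(clones = clones, mutations = mutations,
                 incidence = incidence, flags = flags),
            class = "clone_matrix")
}

#' @export
print.clone_matrix <- function(x, ...) {
  cat(sprintf("Clone-mutation matrix: %d clones x %d mutations",
              nrow(x$incidence), ncol(x$incidence)))
  if (length(x$flags)) cat(" [flags: ", paste(x$flags, collapse = "; "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Nest subclone clusters into a clones x mutations matrix
#'
#' Greedy pigeonhole (sum-rule) nesting: clusters are processed in
#' descending prevalence; each cluster's parent is the already-placed
#' cluster with the smallest prevalence whose unallocated prevalence (own
#' prevalence minus the prevalences of children already attached) is at
#' least this cluster's prevalence minus `nesting_tolerance`. When no
#' cluster qualifies, the cluster is attached to the highest-prevalence
#' cluster and a sum-rule conflict is flagged. A clone's incidence row is
#' the union of the novel mutation sets (cluster members) along its path to
#' the top.
#'
#' @param clusters A `subclone_clusters` object.
#' @param params A [subclone_params()].
#' @return A `clone_matrix` (flags record any sum-rule conflicts).
#' @export
build_incidence_matrix <- function(clusters, params = subclone_params()) {
  stopifnot(inherits(clusters, "subclone_clusters"))
  cl <- clusters$clusters
  stopifnot(!is.unsorted(rev(cl$prevalence)))
  n <- nrow(cl)
  parent <- rep(NA_integer_, n)
  n_children <- integer(n)
  alloc <- numeric(n)          # prevalence already claimed by children
  flags <- character()
  for (i in seq_len(n)[-1]) {
    placed <- seq_len(i - 1L)
    free <- cl$prevalence[placed] - alloc[placed]
    ok <- placed[free >= cl$prevalence[i] - params$nesting_tolerance]
    if (length(ok)) {
      # smallest qualifying prevalence; ties -> fewer children, then id
      o <- ok[order(cl$prevalence[ok], n_children[ok], cl$cluster[ok])]
      parent[i] <- o[1L]
    } else {
      parent[i] <- which.max(cl$prevalence[placed])
      flags <- c(flags, sprintf("sum_rule_conflict:%s", cl$cluster[i]))
    }
    alloc[parent[i]] <- alloc[parent[i]] + cl$prevalence[i]
    n_children[parent[i]] <- n_children[parent[i]] + 1L
  }
  mutations <- sort(unique(unlist(clusters$members)))
  incidence <- matrix(FALSE, nrow = n, ncol = length(mutations),
                      dimnames = list(cl$cluster, mutations))
  for (i in seq_len(n)) {
    path <- i
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    incidence[i, unlist(clusters$members[cl$cluster[path]])] <- TRUE
  }
  new_clone_matrix(clones = cl[, c("cluster", "prevalence")] |>
                     stats::setNames(c("clone", "prevalence")),
                   mutations = mutations, incidence = incidence, flags = flags)
}

#' Write an incidence matrix as TSV
#'
#' Rows are clones (with a prevalence column); columns are variant keys;
#' entries are 0/1.
#'
#' @param matrix A `clone_matrix`.
#' @param path Output path.
#' @export
write_clone_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "clone_matrix"))
  df <- data.frame(clone = matrix$clones$clone,
                   prevalence = matrix$clones$prevalence,
                   matrix$incidence * 1L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
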