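# End-to-end orchestration: simulate (or load) -> somatic subtraction ->
# gene copy number -> subclone clustering -> clone tree -> report. The run
# is a pure function of its configuration: one global seed fans out to
# per-stage child seeds by fixed offsets, and all intermediate files are
# plain text (VCF/TSV/JSON/Newick) for diffability.

validate_run_config <- function(config) {
  if (!is.list(config)) stop_config("run config must be a list")
  allowed <- c("seed", "outdir", "simulate", "inputs", "subclones", "force_tree")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(config$seed)) stop_config("missing config key", field = "seed")
  if (is.null(config$outdir)) stop_config("missing config key", field = "outdir")
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in)
    stop_config("exactly one of 'simulate' or 'inputs' must be given")
  if (has_in) {
    need <- c("parental", "resistant", "bed", "depth")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop_config(sprintf("inputs block missing: %s", paste(miss, collapse = ", ")),
                  field = "inputs")
  }
  invisible(config)
}

#' Run the full clonal-evolution pipeline
#'
#' Executes simulate (or load) -> somatic subtraction -> gene copy number ->
#' cellular-prevalence clustering -> incidence matrix -> clone tree, writing
#' every stage's inputs and outputs under the configured output directory
#' and a final `report.json`. Identical configurations yield identical
#' reports.
#'
#' @param config A list with `seed`, `outdir`, exactly one of `simulate`
#'   (arguments for [sim_config()], the seed is injected) or `inputs`
#'   (paths `parental`, `resistant`, `bed`, `depth`), and optionally
#'   `subclones` (arguments for [subclone_params()]) and `force_tree`.
#' @return A `clone_run` object: `report` (the serialised summary),
#'   `tree`, `matrix`, `clusters`, `acquired`, `gcn`, `truth` (simulated
#'   runs only) and `paths`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = class(e)))
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      scfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
      truth <- simulate_clone_tree(scfg)
      out <- simulate_read_counts(truth, scfg)
      write_simulation(out, outdir)
      out
    })
    parental <- sim$parental
    resistant <- sim$resistant
    profile <- sim$depth_profile
  } else {
    parental <- stage("load", read_variants(config$inputs$parental))
    resistant <- stage("load", read_variants(config$inputs$resistant))
    profile <- stage("load", read_depth_profile(config$inputs$bed, config$inputs$depth))
  }

  acquired <- stage("subtract", {
    acq <- suppressMessages(subtract_somatic(parental, resistant))
    write_variants(acq, file.path(outdir, "acquired.tsv"), format = "tsv")
    acq
  })

  gcn <- stage("gcn", {
    g <- compute_gcn(profile)
    write_gcn(g, file.path(outdir, "gcn.tsv"))
    g
  })

  params <- do.call(subclone_params, if (is.null(config$subclones)) list()
                    else config$subclones)
  copies <- absolute_copies(gcn, params$baseline_ploidy)

  clusters <- stage("subclones", {
    est <- prevalence_table(acquired, copies = copies, params = params)
    cluster_prevalences(est, params = params)
  })
  cmatrix <- stage("subclones", {
    m <- build_incidence_matrix(clusters, params = params)
    write_clone_matrix(m, file.path(outdir, "clone_matrix.tsv"))
    m
  })

  tree <- stage("tree", {
    tr <- assign_ancestry(cmatrix, force = isTRUE(config$force_tree))
    effects <- stats::setNames(acquired$effect, variant_keys(acquired))
    tr <- decorate_tree(tr, effects)
    to_newick(tr, file.path(outdir, "tree.nwk"))
    write_tree_report(tr, file.path(outdir, "tree.json"))
    tr
  })

  run <- structure(list(tree = tree, matrix = cmatrix, clusters = clusters,
                        acquired = acquired, gcn = gcn, truth = truth,
                        config = config),
                   class = "clone_run")

  comparison <- if (!is.null(truth)) compare_to_truth(run, truth) else NULL

  report <- list(
    seed = config$seed,
    n_parental = nrow(parental),
    n_resistant = nrow(resistant),
    n_acquired = nrow(acquired),
    n_filtered = clusters$n_filtered,
    n_clusters = nrow(clusters$clusters),
    clusters = clusters$clusters,
    matrix_flags = cmatrix$flags,
    tree_flags = tree$flags,
    newick = to_newick(tree),
    comparison = comparison)
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  run$report <- report
  run$paths <- c(outdir = outdir, report = report_path)
  run
}

#' @export
print.clone_run <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %s): %d acquired variants -> %d subclones\n",
              x$config$seed, nrow(x$acquired), nrow(x$clusters$clusters)))
  cat("tree:", x$report$newick, "\n")
  if (!is.null(x$report$comparison))
    cat(sprintf("vs truth: RF = %d, prevalence RMSE = %.4f, acquired Jaccard = %.3f\n",
                x$report$comparison$rf_distance,
                x$report$comparison$prevalence_rmse,
                x$report$comparison$acquired_jaccard))
  invisible(x)
}

#' Ground-truth clone tree as a `clone_tree`
#' @param truth A `clone_truth`.
#' @return A `clone_tree` over the true clones.
#' @export
truth_tree <- function(truth) {
  stopifnot(inherits(truth, "clone_truth"))
  parent <- stats::setNames(
    ifelse(is.na(truth$parent), NA_character_, truth$clones[truth$parent]),
    truth$clones)
  new_clone_tree(nodes = truth$clones, parent = parent, novel = truth$novel,
                 prevalence = stats::setNames(truth$cum_prev, truth$clones))
}

tree_clades <- function(tree) {
  kids <- split(tree$nodes[!is.na(tree$parent)],
                tree$parent[!is.na(tree$parent)])
  subtree <- function(n) {
    out <- n
    for (k in kids[[n]]) out <- c(out, subtree(k))
    out
  }
  non_root <- tree$nodes[!is.na(tree$parent)]
  vapply(non_root, function(n) paste(sort(subtree(n)), collapse = "|"),
         character(1))
}

#' Robinson-Foulds distance between two rooted clone trees
#'
#' Standard bipartition (clade) comparison on node labels: the number of
#' clades present in exactly one of the two trees.
#'
#' @param tree_a,tree_b `clone_tree`s over the same label set (labels
#'   absent from either are allowed and simply never match).
#' @return Non-negative integer; 0 means identical topology.
#' @export
rf_distance <- function(tree_a, tree_b) {
  ca <- tree_clades(tree_a)
  cb <- tree_clades(tree_b)
  length(setdiff(ca, cb)) + length(setdiff(cb, ca))
}

#' Compare an inferred run to the simulated ground truth
#'
#' Inferred subclones are matched to true clones by greedy maximal Jaccard
#' similarity of their incidence rows; the inferred tree is then relabelled
#' and compared to the true tree by Robinson-Foulds clade distance.
#' Prevalence RMSE is computed over matched clone pairs, and the acquired
#' mutation catalogue is compared to the true acquired set by Jaccard
#' index.
#'
#' @param run A `clone_run` (or a list with `tree`, `matrix`, `acquired`).
#' @param truth A `clone_truth`.
#' @return List `rf_distance`, `prevalence_rmse`, `acquired_jaccard`,
#'   `n_matched`, `n_inferred`, `n_true`.
#' @export
compare_to_truth <- function(run, truth) {
  stopifnot(inherits(truth, "clone_truth"))
  inf_m <- run$matrix
  tru_m <- truth$matrix
  inf_ids <- rownames(inf_m$incidence)
  tru_ids <- rownames(tru_m$incidence)
  # match on novel mutation sets (cluster members), which do not depend on
  # how the clusters were nested; fall back to cumulative rows
  inf_sets <- if (!is.null(run$clusters))
    run$clusters$members[inf_ids]
  else lapply(seq_along(inf_ids), function(i) colnames(inf_m$incidence)[inf_m$incidence[i, ]])
  tru_sets <- truth$novel[tru_ids]
  jac <- matrix(0, length(inf_ids), length(tru_ids),
                dimnames = list(inf_ids, tru_ids))
  for (i in seq_along(inf_ids)) {
    for (j in seq_along(tru_ids)) {
      si <- inf_sets[[i]]; sj <- tru_sets[[j]]
      jac[i, j] <- length(intersect(si, sj)) / length(union(si, sj))
    }
  }
  mapping <- character(0)
  J <- jac
  while (nrow(J) > 0 && ncol(J) > 0 && max(J) > 0) {
    best <- which(J == max(J), arr.ind = TRUE)
    best <- best[order(rownames(J)[best[, 1]], colnames(J)[best[, 2]]), , drop = FALSE]
    mapping[rownames(J)[best[1, 1]]] <- colnames(J)[best[1, 2]]
    J <- J[-best[1, 1], -best[1, 2], drop = FALSE]
  }

  relabel <- function(n) if (n %in% names(mapping)) mapping[[n]] else n
  inf_tree <- run$tree
  new_ids <- vapply(inf_tree$nodes, relabel, character(1))
  relabelled <- new_clone_tree(
    nodes = unname(new_ids),
    parent = stats::setNames(
      vapply(inf_tree$parent, function(p) if (is.na(p)) NA_character_ else relabel(p),
             character(1)),
      new_ids),
    novel = stats::setNames(inf_tree$novel, new_ids),
    prevalence = stats::setNames(inf_tree$prevalence, new_ids))
  rf <- rf_distance(relabelled, truth_tree(truth))

  inf_prev <- stats::setNames(inf_m$clones$prevalence, inf_m$clones$clone)
  tru_prev <- stats::setNames(tru_m$clones$prevalence, tru_m$clones$clone)
  matched <- names(mapping)
  rmse <- if (length(matched))
    sqrt(mean((inf_prev[matched] - tru_prev[mapping[matched]])^2)) else NA_real_

  acq_inf <- variant_keys(run$acquired)
  acq_tru <- colnames(tru_m$incidence)
  jacc <- length(intersect(acq_inf, acq_tru)) / length(union(acq_inf, acq_tru))

  list(rf_distance = rf, prevalence_rmse = rmse, acquired_jaccard = jacc,
       n_matched = length(matched), n_inferred = length(inf_ids),
       n_true = length(tru_ids))
}
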