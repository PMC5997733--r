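# Clone-tree reconstruction by subset containment. Under the infinite-sites
# assumption the cumulative mutation sets of subclones form a laminar family:
# the founder ("father") clone carries the variations that appear first, and
# every other clone descends from the clone whose mutation set is the
# inclusion-maximal proper subset of its own. The recursion is implemented
# directly, with an exhaustive enumeration oracle for verification.

new_clone_tree <- function(nodes, parent, novel, prevalence, flags = character()) {
  structure(list(nodes = nodes, parent = parent, novel = novel,
                 prevalence = prevalence,
                 branch_length = NULL, sweep_label = NULL, colour_group = NULL,
                 flags = flags),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("Clone tree: %d clones, root = %s\n",
              length(x$nodes), x$nodes[is.na(x$parent)]))
  for (n in x$nodes) {
    p <- x$parent[[n]]
    cat(sprintf("  %s <- %s (%d novel%s)\n", n,
                if (is.na(p)) "(root)" else p, length(x$novel[[n]]),
                if (!is.null(x$sweep_label))
                  sprintf(", %d non-synonymous", x$sweep_label[[n]]) else ""))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# strict-subset matrix over incidence rows: out[i,j] TRUE iff row i is a
# proper subset of row j (rows assumed distinct)
strict_subset_matrix <- function(inc) {
  A <- inc * 1L
  missing <- A %*% t(1L - A)          # missing[i,j] = |i \ j|
  missing == 0L & !diag(TRUE, nrow(A))
}

#' Assign clone ancestry by recursive subset containment
#'
#' The root is the clone whose mutation set is contained in every other
#' clone's set; each remaining clone's parent is the clone whose set is the
#' inclusion-maximal proper subset of its own. Ties between equally maximal
#' candidate fathers are broken toward larger set size, then higher
#' prevalence, then lexicographic id, and flagged. Input that violates
#' subset containment (no valid root, or a variant appearing novel on two
#' branches) raises a structure error unless `force = TRUE`, in which case
#' parents are chosen by maximal Jaccard containment and every forced edge
#' is flagged.
#'
#' @param matrix A `clone_matrix`.
#' @param force Attach non-nesting clones by maximal Jaccard overlap
#'   instead of failing.
#' @return A `clone_tree` (undecorated; see [decorate_tree()]).
#' @export
assign_ancestry <- function(matrix, force = FALSE) {
  stopifnot(inherits(matrix, "clone_matrix"))
  inc <- matrix$incidence
  K <- nrow(inc)
  ids <- rownames(inc)
  prev <- stats::setNames(matrix$clones$prevalence, matrix$clones$clone)[ids]
  if (K == 1L) {
    return(new_clone_tree(nodes = ids,
                          parent = stats::setNames(NA_character_, ids),
                          novel = stats::setNames(list(sort(colnames(inc)[inc[1, ]])), ids),
                          prevalence = prev))
  }
  if (anyDuplicated(inc) > 0)
    stop_structure("incidence rows are not distinct")
  sub <- strict_subset_matrix(inc)
  card <- rowSums(inc)
  flags <- character()

  root_cand <- which(vapply(seq_len(K), function(i) all(sub[i, -i]), logical(1)))
  if (length(root_cand) == 1L) {
    root <- root_cand
  } else if (force) {
    o <- order(card, -prev, ids)
    root <- o[1L]
    flags <- c(flags, sprintf("forced_root:%s", ids[root]))
  } else {
    minimal <- which(vapply(seq_len(K), function(i) !any(sub[-i, i]), logical(1)))
    stop_structure(sprintf(
      "no clone's mutation set is contained in all others; minimal antichain: %s",
      paste(ids[minimal], collapse = ", ")))
  }

  parent <- stats::setNames(rep(NA_character_, K), ids)
  for (j in seq_len(K)) {
    if (j == root) next
    cand <- setdiff(which(sub[, j]), j)
    if (!length(cand)) {
      if (!force)
        stop_structure(sprintf("clone %s has no candidate ancestor", ids[j]))
      others <- setdiff(which(card < card[j] | (card == card[j] & seq_len(K) < j)), j)
      if (!length(others)) others <- setdiff(seq_len(K), j)
      jac <- vapply(others, function(i)
        sum(inc[i, ] & inc[j, ]) / sum(inc[i, ] | inc[j, ]), numeric(1))
      o <- others[order(-jac, -prev[others], ids[others])]
      parent[j] <- ids[o[1L]]
      flags <- c(flags, sprintf("forced_edge:%s", ids[j]))
      next
    }
    maximal <- cand[vapply(cand, function(i)
      !any(sub[i, setdiff(cand, i)]), logical(1))]
    if (length(maximal) > 1L) {
      flags <- c(flags, sprintf("ancestry_tie:%s", ids[j]))
      maximal <- maximal[order(-card[maximal], -prev[maximal], ids[maximal])]
    }
    parent[j] <- ids[maximal[1L]]
  }

  novel <- lapply(seq_len(K), function(j) {
    p <- parent[j]
    row <- inc[j, ]
    if (!is.na(p)) row <- row & !inc[p, ]
    sort(colnames(inc)[row])
  })
  names(novel) <- ids

  first_seen <- table(unlist(novel))
  repeated <- names(first_seen)[first_seen > 1]
  if (length(repeated)) {
    if (!force)
      stop_structure(sprintf(
        "containment violated: variant(s) arise independently on multiple branches: %s",
        paste(utils::head(repeated, 5), collapse = ", ")))
    flags <- c(flags, sprintf("repeated_variant:%s", repeated))
  }
  new_clone_tree(nodes = ids, parent = parent, novel = novel,
                 prevalence = prev, flags = flags)
}

#' Exhaustive-enumeration oracle for clone ancestry
#'
#' Enumerates every rooted spanning tree over the clones and keeps those in
#' which each child's mutation set strictly contains its parent's, each
#' parent is inclusion-maximal (no third clone fits strictly between), the
#' root has no proper subset among the clones, and no variant is novel on
#' two branches. Intended purely as a test oracle for [assign_ancestry()];
#' enumeration is exponential and limited to 8 clones.
#'
#' @param matrix A `clone_matrix` with at most 8 clones.
#' @return A `clone_tree`; a structure error when no tree satisfies
#'   containment. When several trees qualify the lexicographically first is
#'   returned with an `ambiguous` flag.
#' @export
brute_force_ancestry <- function(matrix) {
  stopifnot(inherits(matrix, "clone_matrix"))
  inc <- matrix$incidence
  K <- nrow(inc)
  if (K > 8L)
    stop_config("brute_force_ancestry supports at most 8 clones", field = "matrix")
  ids <- rownames(inc)
  prev <- stats::setNames(matrix$clones$prevalence, matrix$clones$clone)[ids]
  if (K == 1L)
    return(new_clone_tree(ids, stats::setNames(NA_character_, ids),
                          stats::setNames(list(sort(colnames(inc)[inc[1, ]])), ids),
                          prev))
  if (anyDuplicated(inc) > 0)
    stop_structure("incidence rows are not distinct")

  E <- K + 1L                       # virtual empty set, parent of the root
  sub <- strict_subset_matrix(inc)
  sub_aug <- rbind(cbind(sub, FALSE), c(rep(TRUE, K), FALSE))
  max_ok <- matrix(FALSE, E, K)
  for (j in seq_len(K)) {
    for (i in seq_len(K)) {
      if (!sub[i, j]) next
      between <- any(vapply(seq_len(K), function(k)
        k != i && k != j && sub[i, k] && sub[k, j], logical(1)))
      max_ok[i, j] <- !between
    }
    max_ok[E, j] <- !any(sub[, j])  # root must have no proper subset
  }
  # novel-set overlap table: OV[i, pi, j, pj] = |(m_i \ m_pi) & (m_j \ m_pj)|
  rows_aug <- rbind(inc, rep(FALSE, ncol(inc)))
  OV <- array(0L, dim = c(K, E, K, E))
  for (i in seq_len(K)) for (pi in seq_len(E)) {
    ni <- inc[i, ] & !rows_aug[pi, ]
    if (!any(ni)) next
    for (j in seq_len(K)) for (pj in seq_len(E)) {
      if (j <= i) next
      OV[i, pi, j, pj] <- sum(ni & inc[j, ] & !rows_aug[pj, ])
    }
  }
  pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)

  found <- NULL
  n_found <- 0L
  for (root in seq_len(K)) {
    non_root <- setdiff(seq_len(K), root)
    opts <- lapply(non_root, function(j) setdiff(seq_len(K), j))
    n_opts <- K - 1L
    total <- n_opts ^ length(non_root)
    chunk <- 200000L
    start <- 0L
    while (start < total) {
      idx <- start + seq_len(min(chunk, total - start)) - 1L
      P <- matrix(E, nrow = length(idx), ncol = K)
      rem <- idx
      for (d in seq_along(non_root)) {
        digit <- rem %% n_opts
        rem <- rem %/% n_opts
        P[, non_root[d]] <- opts[[d]][digit + 1L]
      }
      valid <- rep(TRUE, nrow(P))
      for (j in seq_len(K)) {
        pj <- P[, j]
        if (j == root) {
          valid <- valid & max_ok[E, j]
        } else {
          valid <- valid & sub_aug[cbind(pj, j)] & max_ok[cbind(pj, j)]
        }
        if (!any(valid)) break
      }
      if (any(valid)) {
        ovsum <- numeric(nrow(P))
        for (q in seq_len(nrow(pairs))) {
          i <- pairs[q, 1]; j <- pairs[q, 2]
          ovsum <- ovsum + OV[cbind(i, P[, i], j, P[, j])]
        }
        valid <- valid & ovsum == 0
      }
      hits <- which(valid)
      if (length(hits)) {
        n_found <- n_found + length(hits)
        if (is.null(found)) found <- P[hits[1L], ]
      }
      start <- start + length(idx)
    }
  }
  if (is.null(found))
    stop_structure("no rooted tree satisfies subset containment (brute force)")
  parent <- stats::setNames(ifelse(found == E, NA_character_, ids[found]), ids)
  novel <- lapply(seq_len(K), function(j) {
    row <- inc[j, ]
    if (found[j] != E) row <- row & !inc[found[j], ]
    sort(colnames(inc)[row])
  })
  names(novel) <- ids
  new_clone_tree(ids, parent, novel, prev,
                 flags = if (n_found > 1L) "ambiguous" else character())
}

#' Decorate a clone tree with branch semantics
#'
#' Branch length of a node is the number of novel variants it acquires
#' (synonymous plus non-synonymous); the sweep label counts the
#' non-synonymous novel variants defining the clonal sweep; the colour
#' group of a node is its child-of-root ancestor (the root forms its own
#' group), so each top-level branch defines the main colour of its
#' subclones.
#'
#' @param tree A `clone_tree`.
#' @param effects Named character vector mapping every variant key in the
#'   tree to `synonymous` / `nonsynonymous` / `other`.
#' @return The decorated `clone_tree`.
#' @export
decorate_tree <- function(tree, effects) {
  stopifnot(inherits(tree, "clone_tree"))
  all_keys <- unlist(tree$novel, use.names = FALSE)
  unknown <- setdiff(all_keys, names(effects))
  if (length(unknown))
    stop_data(sprintf("no effect annotation for variant(s): %s",
                      paste(utils::head(unknown, 5), collapse = ", ")))
  tree$branch_length <- vapply(tree$novel, length, integer(1))
  tree$sweep_label <- vapply(tree$novel, function(k)
    sum(effects[k] == "nonsynonymous"), integer(1))
  root <- tree$nodes[is.na(tree$parent)]
  colour <- stats::setNames(rep(NA_character_, length(tree$nodes)), tree$nodes)
  for (n in tree$nodes) {
    path <- n
    while (!is.na(tree$parent[[path[1]]])) path <- c(tree$parent[[path[1]]], path)
    colour[n] <- if (length(path) == 1L) root else path[2L]
  }
  tree$colour_group <- colour
  tree
}

#' Export a clone tree to Newick
#'
#' Node labels are `<clone>_sweep<N>` (N = non-synonymous novel variants)
#' and branch lengths are novel-variant counts. Children are ordered by
#' descending prevalence, then id, so output is deterministic.
#'
#' @param tree A decorated `clone_tree`.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  lab <- function(n) {
    if (is.null(tree$sweep_label)) n
    else sprintf("%s_sweep%d", n, tree$sweep_label[[n]])
  }
  len <- function(n) {
    if (is.null(tree$branch_length)) length(tree$novel[[n]])
    else tree$branch_length[[n]]
  }
  children <- function(n) {
    kids <- tree$nodes[!is.na(tree$parent) & tree$parent == n]
    kids[order(-tree$prevalence[kids], kids)]
  }
  emit <- function(n) {
    kids <- children(n)
    inner <- if (length(kids))
      sprintf("(%s)", paste(vapply(kids, emit, character(1)), collapse = ",")) else ""
    sprintf("%s%s:%d", inner, lab(n), len(n))
  }
  root <- tree$nodes[is.na(tree$parent)]
  nwk <- paste0(emit(root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Serialise a clone tree report to JSON
#'
#' Parent map, novel sets, branch lengths, sweep labels, colour groups,
#' prevalences and flags.
#'
#' @param tree A `clone_tree`.
#' @param path Output path.
#' @export
write_tree_report <- function(tree, path) {
  stopifnot(inherits(tree, "clone_tree"))
  obj <- list(nodes = tree$nodes,
              parent = as.list(tree$parent),
              novel = tree$novel,
              prevalence = as.list(tree$prevalence),
              branch_length = as.list(tree$branch_length),
              sweep_label = as.list(tree$sweep_label),
              colour_group = as.list(tree$colour_group),
              flags = tree$flags,
              newick = to_newick(tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
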