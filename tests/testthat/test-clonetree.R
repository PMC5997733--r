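test_that("a single clone yields a root-only tree", {
  m <- matrix_from_sets(list(A = c("m1", "m2")))
  tree <- assign_ancestry(m)
  expect_identical(tree$nodes, "A")
  expect_true(is.na(tree$parent[["A"]]))
  expect_identical(tree$novel[["A"]], c("m1", "m2"))
})

test_that("subset containment resolves the canonical small topologies", {
  # A={m1}, B={m1,m2}, C={m1,m3}: root A with children B and C
  m <- matrix_from_sets(list(A = "m1", B = c("m1", "m2"), C = c("m1", "m3")),
                        prevalence = c(1, 0.5, 0.3))
  tree <- assign_ancestry(m)
  expect_true(is.na(tree$parent[["A"]]))
  expect_identical(tree$parent[["B"]], "A")
  expect_identical(tree$parent[["C"]], "A")
  bf <- brute_force_ancestry(m)
  expect_identical(tree$parent, bf$parent)

  # chain A -> B -> C
  m2 <- matrix_from_sets(list(A = "m1", B = c("m1", "m2"),
                              C = c("m1", "m2", "m3")),
                         prevalence = c(1, 0.5, 0.3))
  tree2 <- assign_ancestry(m2)
  expect_identical(unname(tree2$parent[c("A", "B", "C")]),
                   c(NA, "A", "B"))
  expect_identical(tree2$parent, brute_force_ancestry(m2)$parent)
})

test_that("recursion agrees with exhaustive enumeration on random laminar systems", {
  set.seed(123)
  for (i in 1:150) {
    K <- sample(2:6, 1)
    truth <- random_laminar_truth(K, seed = 5000 + i)
    tree <- assign_ancestry(truth$matrix)
    oracle <- brute_force_ancestry(truth$matrix)
    expect_identical(tree$parent, oracle$parent)
    # and both recover the generating topology
    expect_identical(unname(tree$parent),
                     unname(ifelse(is.na(truth$parent), NA_character_,
                                   truth$clones[truth$parent])))
  }
})

test_that("non-laminar systems raise the same structure error on both paths", {
  # no clone contained in all others
  antichain <- matrix_from_sets(list(A = c("m1", "m2"), B = c("m1", "m3")))
  expect_error(assign_ancestry(antichain), class = "cs_structure_error")
  expect_error(brute_force_ancestry(antichain), class = "cs_structure_error")
  # valid root but a variant arising independently on two branches
  repeated <- matrix_from_sets(list(A = "m1", B = c("m1", "m2", "m3"),
                                    C = c("m1", "m3", "m4")))
  expect_error(assign_ancestry(repeated), class = "cs_structure_error")
  expect_error(brute_force_ancestry(repeated), class = "cs_structure_error")
})

test_that("force mode attaches non-nesting clones and flags every forced edge", {
  repeated <- matrix_from_sets(list(A = "m1", B = c("m1", "m2", "m3"),
                                    C = c("m1", "m3", "m4")),
                               prevalence = c(1, 0.6, 0.3))
  tree <- assign_ancestry(repeated, force = TRUE)
  expect_length(tree$nodes, 3)
  expect_equal(sum(is.na(tree$parent)), 1)
  expect_true(any(grepl("repeated_variant", tree$flags)))
  antichain <- matrix_from_sets(list(A = c("m1", "m2"), B = c("m1", "m3")),
                                prevalence = c(0.6, 0.4))
  forced <- assign_ancestry(antichain, force = TRUE)
  expect_true(any(grepl("forced", forced$flags)))
})

test_that("decoration computes branch lengths, sweeps and colour groups", {
  m <- matrix_from_sets(list(A = c("m1", "m2"),
                             B = c("m1", "m2", "m3", "m4", "m5", "m6", "m7"),
                             C = c("m1", "m2", "m8")),
                        prevalence = c(1, 0.5, 0.3))
  effects <- c(m1 = "nonsynonymous", m2 = "synonymous", m3 = "nonsynonymous",
               m4 = "nonsynonymous", m5 = "synonymous", m6 = "synonymous",
               m7 = "other", m8 = "nonsynonymous")
  tree <- decorate_tree(assign_ancestry(m), effects)
  expect_equal(unname(tree$branch_length[c("A", "B", "C")]), c(2L, 5L, 1L))
  expect_equal(unname(tree$sweep_label[c("A", "B", "C")]), c(1L, 2L, 1L))
  # root forms its own colour group; each child of the root starts one
  expect_identical(unname(tree$colour_group[c("A", "B", "C")]),
                   c("A", "B", "C"))
  expect_error(decorate_tree(assign_ancestry(m), effects[-3]),
               class = "cs_data_error")
})

test_that("branch lengths conserve the total acquired-variant count", {
  truth <- random_laminar_truth(K = 6, seed = 77)
  effects <- stats::setNames(truth$variants$effect, truth$variants$key)
  tree <- decorate_tree(assign_ancestry(truth$matrix), effects)
  expect_equal(sum(tree$branch_length), ncol(truth$matrix$incidence))
})

test_that("Newick export is deterministic and parseable", {
  single <- decorate_tree(assign_ancestry(matrix_from_sets(list(cloneA = c("m1", "m2")))),
                          c(m1 = "nonsynonymous", m2 = "synonymous"))
  expect_identical(to_newick(single), "cloneA_sweep1:2;")

  m <- matrix_from_sets(list(A = "m1", B = c("m1", "m2"), C = c("m1", "m3")),
                        prevalence = c(1, 0.3, 0.5))
  effects <- c(m1 = "nonsynonymous", m2 = "synonymous", m3 = "nonsynonymous")
  tree <- decorate_tree(assign_ancestry(m), effects)
  nwk <- to_newick(tree)
  # children ordered by descending prevalence: C (0.5) before B (0.3)
  expect_identical(nwk, "(C_sweep1:1,B_sweep0:1)A_sweep1:1;")
  expect_identical(to_newick(tree), nwk)
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("C_sweep1", "B_sweep0"))
  expect_identical(ph$node.label, "A_sweep1")
  expect_equal(sort(ph$edge.length), c(1, 1))
})

test_that("tree reports serialise to JSON with full semantics", {
  truth <- random_laminar_truth(K = 4, seed = 19)
  effects <- stats::setNames(truth$variants$effect, truth$variants$key)
  tree <- decorate_tree(assign_ancestry(truth$matrix), effects)
  path <- tempfile(fileext = ".json")
  write_tree_report(tree, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(rep$nodes, truth$clones)
  expect_identical(rep$newick, to_newick(tree))
  expect_equal(sum(unlist(rep$branch_length)), ncol(truth$matrix$incidence))
})

test_that("trees rebuilt from the true incidence matrix match the truth exactly", {
  truth <- random_laminar_truth(K = 5, seed = 23)
  tree <- assign_ancestry(truth$matrix)
  expect_equal(rf_distance(tree, truth_tree(truth)), 0)
})
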