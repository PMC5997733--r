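test_that("a single-clone tree is degenerate: one root carrying everything", {
  truth <- simulate_clone_tree(sim_config(n_clones = 1, seed = 3))
  expect_length(truth$clones, 1)
  expect_true(is.na(truth$parent))
  expect_equal(truth$fractions, 1)
  expect_equal(truth$cum_prev, 1)
  expect_identical(sort(colnames(truth$matrix$incidence)[truth$matrix$incidence[1, ]]),
                   truth$novel[["clone1"]])
  expect_true(all(truth$matrix$incidence))
})

test_that("identical seeds give byte-identical simulations, different seeds differ", {
  cfg <- sim_config(n_clones = 4, seed = 11)
  a <- simulate_read_counts(simulate_clone_tree(cfg), cfg)
  b <- simulate_read_counts(simulate_clone_tree(cfg), cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  cfg2 <- sim_config(n_clones = 4, seed = 12)
  c <- simulate_read_counts(simulate_clone_tree(cfg2), cfg2)
  expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
})

test_that("simulated clone structures are internally consistent", {
  for (s in 1:5) {
    truth <- simulate_clone_tree(sim_config(n_clones = 6, seed = s))
    # subpopulation fractions sum to 1
    expect_equal(sum(truth$fractions), 1, tolerance = 1e-9)
    # novel sets are pairwise disjoint and their union is the acquired set
    all_novel <- unlist(truth$novel, use.names = FALSE)
    expect_false(anyDuplicated(all_novel) > 0)
    expect_setequal(all_novel, colnames(truth$matrix$incidence))
    # independent recount: every cumulative row equals the union of novel
    # sets along the root path implied by the parent vector
    for (i in seq_along(truth$clones)) {
      path <- i
      while (!is.na(truth$parent[path[1]])) path <- c(truth$parent[path[1]], path)
      expected <- sort(unlist(truth$novel[path], use.names = FALSE))
      got <- sort(colnames(truth$matrix$incidence)[truth$matrix$incidence[i, ]])
      expect_identical(got, expected)
    }
    # cumulative prevalence of each clone is its subtree fraction sum
    for (i in seq_along(truth$clones)) {
      sub <- i
      repeat {
        kids <- which(truth$parent %in% sub & !(seq_along(truth$clones) %in% sub))
        if (!length(kids)) break
        sub <- c(sub, kids)
      }
      expect_equal(truth$cum_prev[i], sum(truth$fractions[sub]), tolerance = 1e-12)
    }
  }
})

test_that("per-clone novel counts are respected and laminar by construction", {
  truth <- simulate_clone_tree(sim_config(n_clones = 5,
                                          mean_novel_variants_per_clone = 10,
                                          seed = 1))
  expect_equal(sum(lengths(truth$novel)), ncol(truth$matrix$incidence))
  expect_equal(unname(lengths(truth$novel)), unname(truth$n_novel))
  # pairwise nesting-or-disjointness of rows after removing the shared
  # root-novel trunk
  inc <- truth$matrix$incidence
  root <- which(is.na(truth$parent))
  branchy <- inc[, !inc[root, ], drop = FALSE]
  K <- nrow(branchy)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    a <- branchy[i, ]; b <- branchy[j, ]
    nested <- all(!a | b) || all(!b | a)
    disjoint <- !any(a & b)
    expect_true(nested || disjoint)
  }
})

test_that("read counts follow the expected VAF model at high depth", {
  cfg <- sim_config(n_clones = 4, mean_depth = 20000, sequencing_error_rate = 0,
                    seed = 5)
  truth <- simulate_clone_tree(cfg)
  sim <- simulate_read_counts(truth, cfg)
  res <- sim$resistant
  v <- truth$variants[match(variant_keys(res), truth$variants$key), ]
  copies <- truth$gene_cn[v$gene]
  carrier <- ifelse(v$class == "acquired",
                    truth$cum_prev[match(v$clone, truth$clones)], 1)
  expected <- ifelse(v$class == "germline", 0.5, carrier / copies)
  vaf <- res$alt_reads / (res$alt_reads + res$ref_reads)
  expect_lt(max(abs(vaf - expected)), 0.02)
  # parental holds only germline + trunk; trunk variants sit near VAF 0.5
  par_v <- truth$variants[match(variant_keys(sim$parental), truth$variants$key), ]
  expect_true(all(par_v$class %in% c("germline", "trunk")))
  trunk_vaf <- with(sim$parental[par_v$class == "trunk", ],
                    alt_reads / (alt_reads + ref_reads))
  se <- sqrt(0.25 / 20000) / sqrt(length(trunk_vaf))
  expect_lt(abs(mean(trunk_vaf) - 0.5), 3 * se + 1e-3)
})

test_that("depth profile reflects copy-number events multiplicatively", {
  cfg <- sim_config(n_clones = 2, cn_events = list(GENEX = 3), seed = 9)
  truth <- simulate_clone_tree(cfg)
  sim <- simulate_read_counts(truth, cfg)
  prof <- sim$depth_profile
  gx <- prof$median_depth[prof$gene == "GENEX"]
  rest <- prof$median_depth[prof$gene != "GENEX"]
  expect_gt(median(gx) / median(rest), 1.3)
  expect_equal(median(gx) / 150, 1.5, tolerance = 0.2)
})

test_that("ddPCR droplet simulation honours degenerate fractional abundances", {
  cfg <- sim_config(seed = 21)
  w0 <- simulate_ddpcr_well(0, 5000, cfg)
  expect_equal(w0$pos_mut, 0L)
  w1 <- simulate_ddpcr_well(1, 50000, cfg)
  expect_equal(w1$pos_wt, 0L)
  expect_error(simulate_ddpcr_well(1.2, 5000, cfg), class = "cs_config_error")
})

test_that("ddPCR simulation + Poisson correction recovers the true FA", {
  fas <- vapply(1:150, function(s) {
    w <- simulate_ddpcr_well(0.25, 5000, sim_config(seed = s))
    quantify_well(w)$fa_corrected
  }, numeric(1))
  expect_lt(abs(mean(fas) / 100 - 0.25), 0.01)
})

test_that("single-cell wells honour the mixing rate", {
  truth <- simulate_clone_tree(sim_config(n_clones = 4, seed = 2))
  pure <- simulate_single_cell_wells(truth, 50, mixing_rate = 0, seed = 1)
  expect_true(all(vapply(pure, function(w) length(w$clones), integer(1)) == 1))
  mixed <- simulate_single_cell_wells(truth, 50, mixing_rate = 1, seed = 1)
  expect_true(all(vapply(mixed, function(w) length(unique(w$clones)), integer(1)) == 2))
  some <- simulate_single_cell_wells(truth, 200, mixing_rate = 0.1, seed = 3)
  frac <- mean(vapply(some, function(w) length(w$clones) == 2, logical(1)))
  half <- 1.96 * sqrt(0.1 * 0.9 / 200)
  expect_gte(frac, 0.1 - half)
  expect_lte(frac, 0.1 + half)
  # genotype is the union of the clones' cumulative sets
  w <- mixed[[1]]
  inc <- truth$matrix$incidence
  expected <- sort(unique(unlist(lapply(w$clones, function(cl)
    colnames(inc)[inc[cl, ]]))))
  expect_identical(w$genotype, expected)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_clones = 0), class = "cs_config_error")
  expect_error(sim_config(n_clones = 0), "n_clones")
  expect_error(sim_config(sequencing_error_rate = 1), "sequencing_error_rate")
  expect_error(sim_config(nonsynonymous_fraction = 1.4), "nonsynonymous_fraction")
  expect_error(sim_config(droplet_volume = 0), "droplet_volume")
})

test_that("simulation files round-trip through their plain-text formats", {
  cfg <- sim_config(n_clones = 3, seed = 13)
  sim <- simulate_read_counts(simulate_clone_tree(cfg), cfg)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_variants(paths[["resistant_vcf"]])
  expect_identical(variant_keys(back), variant_keys(sim$resistant))
  expect_identical(back$alt_reads, sim$resistant$alt_reads)
  prof <- read_depth_profile(paths[["bed"]], paths[["depth"]])
  expect_equal(prof$median_depth, sim$depth_profile$median_depth)
  truth_json <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(unname(truth_json$cum_prev), unname(sim$truth$cum_prev))
})
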