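test_that("a header-only VCF reads as an empty table", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t")), path)
  tab <- read_variants(path)
  expect_s3_class(tab, "variant_table")
  expect_equal(nrow(tab), 0)
})

test_that("variant tables round-trip through VCF and TSV", {
  df <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                   pos = c(500L, 100L, 90L),
                   ref = c("G", "A", "C"), alt = c("T", "G", "A"),
                   gene = c("KRAS", "APC", NA), effect = c("nonsynonymous", "synonymous", "other"),
                   alt_reads = c(7L, 30L, 0L), ref_reads = c(93L, 70L, 55L),
                   stringsAsFactors = FALSE)
  tab <- variant_table(df, sample_id = "R1")
  # constructor sorts deterministically
  expect_identical(tab$pos, c(90L, 100L, 500L))
  for (fmt in c("tsv", "vcf")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_variants(tab, path, format = fmt)
    back <- read_variants(path, sample_id = "R1")
    expect_identical(variant_keys(back), variant_keys(tab))
    expect_identical(back$alt_reads, tab$alt_reads)
    expect_identical(back$ref_reads, tab$ref_reads)
    expect_identical(back$gene, tab$gene)
    expect_identical(back$effect, tab$effect)
  }
})

test_that("multi-allelic VCF records split into biallelic keys", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t"),
               paste("chr1", "1000", ".", "A", "G,T", ".", "PASS", ".",
                     "GT:AD", "0/1:10,5,3", sep = "\t")), path)
  tab <- read_variants(path)
  expect_equal(nrow(tab), 2)
  expect_setequal(variant_keys(tab), c("chr1:1000:A:G", "chr1:1000:A:T"))
  expect_equal(tab$alt_reads[match("chr1:1000:A:G", variant_keys(tab))], 5L)
  expect_equal(tab$alt_reads[match("chr1:1000:A:T", variant_keys(tab))], 3L)
  expect_true(all(tab$ref_reads == 10L))
})

test_that("somatic subtraction is exact set difference on variant keys", {
  parental <- table_from_keys(c("chr1:1:A:T", "chr2:2:C:G"), "P")
  resistant <- table_from_keys(c("chr1:1:A:T", "chr2:2:C:G", "chr3:3:G:A"), "R1")
  out <- suppressMessages(subtract_somatic(parental, resistant))
  expect_identical(variant_keys(out), "chr3:3:G:A")
  expect_identical(attr(out, "sample_id"), "R1.acquired")
  same <- suppressMessages(subtract_somatic(resistant, resistant))
  expect_equal(nrow(same), 0)
})

test_that("subtraction satisfies the partition property on random tables", {
  set.seed(42)
  for (rep in 1:20) {
    universe <- sprintf("chr%d:%d:A:C", sample(1:5, 40, TRUE), sample(1e6, 40))
    universe <- unique(universe)
    pk <- sample(universe, rbinom(1, length(universe), 0.5))
    rk <- sample(universe, rbinom(1, length(universe), 0.5))
    if (!length(rk)) next
    p <- table_from_keys(pk, "P")
    r <- table_from_keys(rk, "R")
    out <- suppressMessages(subtract_somatic(p, r))
    ok <- variant_keys(out)
    expect_length(intersect(ok, pk), 0)
    expect_true(all(ok %in% rk))
    expect_setequal(ok, setdiff(rk, pk))
  }
})

test_that("subtraction recovers the simulated acquired catalogue exactly", {
  cfg <- sim_config(n_clones = 4, sequencing_error_rate = 0, seed = 7)
  truth <- simulate_clone_tree(cfg)
  sim <- simulate_read_counts(truth, cfg)
  acq <- suppressMessages(subtract_somatic(sim$parental, sim$resistant))
  expect_setequal(variant_keys(acq), colnames(truth$matrix$incidence))
})

test_that("shared/private classification counts owners correctly", {
  r1 <- table_from_keys(c("chr1:1:A:T", "chr2:2:C:G"), "R1.acquired")
  r2 <- table_from_keys(c("chr1:1:A:T", "chr3:3:G:A"), "R2.acquired")
  cls <- classify_shared_private(list(r1, r2))
  expect_identical(cls$class[cls$key == "chr1:1:A:T"], "common")
  expect_identical(cls$class[cls$key == "chr2:2:C:G"], "private")
  expect_identical(cls$owner[cls$key == "chr2:2:C:G"], "R1.acquired")
  expect_identical(attr(cls, "counts"), c(common = 1L, private = 2L))
  expect_error(classify_shared_private(list(r1)), class = "cs_config_error")
})

test_that("constructed shared trunks are classified common", {
  shared <- sprintf("chr9:%d:A:G", 1:5)
  r1 <- table_from_keys(c(shared, "chr1:10:A:T"), "R1")
  r2 <- table_from_keys(c(shared, "chr2:20:C:A"), "R2")
  cls <- classify_shared_private(list(r1, r2))
  expect_equal(sum(cls$class == "common"), 5)
})

test_that("driver annotation matches exact gene/protein pairs only", {
  df <- data.frame(chrom = "chr12", pos = c(100L, 200L, 300L),
                   ref = "G", alt = "A",
                   gene = c("KRAS", "KRAS", "BRAF"),
                   protein = c("p.G12D", "p.G13D", NA),
                   stringsAsFactors = FALSE)
  tab <- variant_table(df)
  drivers <- list(KRAS = "p.G12D", MAP2K1 = "p.I103N")
  ann <- annotate_drivers(tab, drivers)
  expect_identical(ann$driver, c("KRAS p.G12D", NA, NA))
  none <- annotate_drivers(tab, list())
  expect_true(all(is.na(none$driver)))
})

test_that("malformed inputs raise parse errors", {
  expect_error(read_variants(tempfile(), format = "tsv"), class = "cs_parse_error")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t0\tA\tT"), bad)
  expect_error(read_variants(bad), class = "cs_parse_error")
  expect_error(variant_table(data.frame(chrom = "chr1", pos = 5, ref = "A", alt = "A")),
               class = "cs_parse_error")
})
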