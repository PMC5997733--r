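#' Variant identity key
#'
#' Variant identity throughout the package is `(chrom, pos, ref, alt)`;
#' genotype and quality fields play no role in set algebra.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return Character keys `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a variant table
#'
#' A variant table is a data frame of per-variant records for one sample with
#' columns `chrom`, `pos` (1-based), `ref`, `alt`, optional `gene` and
#' `effect` (`synonymous` / `nonsynonymous` / `other`), and read counts
#' `alt_reads` / `ref_reads`. Rows are keyed uniquely by
#' `(chrom, pos, ref, alt)` and kept in a stable deterministic order.
#'
#' @param df Data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param sample_id Sample label.
#' @return A `variant_table`.
#' @export
variant_table <- function(df, sample_id = "sample") {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data(sprintf("variant table missing column(s): %s", paste(miss, collapse = ", ")),
              class = "cs_parse_error")
  if (!"gene" %in% names(df)) df$gene <- rep(NA_character_, nrow(df))
  if (!"effect" %in% names(df)) df$effect <- rep("other", nrow(df))
  if (!"alt_reads" %in% names(df)) df$alt_reads <- rep(NA_integer_, nrow(df))
  if (!"ref_reads" %in% names(df)) df$ref_reads <- rep(NA_integer_, nrow(df))
  keep_cols <- c("chrom", "pos", "ref", "alt", "gene", "effect",
                 "alt_reads", "ref_reads", intersect("protein", names(df)))
  df <- df[, keep_cols]
  df$pos <- as.integer(df$pos)
  if (any(df$pos < 1L, na.rm = TRUE))
    stop_data("variant positions must be 1-based (>= 1)", class = "cs_parse_error")
  if (any(df$ref == df$alt))
    stop_data("ref and alt alleles must differ", class = "cs_parse_error")
  if (any(df$alt_reads < 0L, na.rm = TRUE) || any(df$ref_reads < 0L, na.rm = TRUE))
    stop_data("read counts must be non-negative", class = "cs_parse_error")
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  dup <- duplicated(key)
  if (any(dup))
    stop_data(sprintf("duplicate variant key(s): %s",
                      paste(unique(key[dup]), collapse = ", ")),
              class = "cs_parse_error")
  structure(df, sample_id = sample_id,
            class = c("variant_table", "data.frame"))
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("Variant table '%s': %d variants\n", attr(x, "sample_id"), nrow(x)))
  NextMethod()
}

#' Keys of a variant table
#' @param table A `variant_table`.
#' @return Character vector of `(chrom,pos,ref,alt)` keys.
#' @export
variant_keys <- function(table) {
  variant_key(table$chrom, table$pos, table$ref, table$alt)
}

#' Read a variant table from VCF or TSV
#'
#' The VCF dialect is minimal VCF v4.2 with `AD` (ref,alt) and `DP` in
#' FORMAT and optional `GENE=` / `EFFECT=` INFO fields. Multi-allelic
#' records are split into biallelic keys. The TSV dialect has the header
#' `chrom pos ref alt gene effect alt_reads ref_reads`.
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @param sample_id Sample label; defaults to the file's sample column (VCF)
#'   or the base file name.
#' @return A `variant_table`; round-trips losslessly with [write_variants()]
#'   on the supported fields.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"), sample_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (!file.exists(path))
    stop_data(sprintf("file not found: %s", path), class = "cs_parse_error")
  if (format == "tsv") {
    df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                   error = function(e) stop_data(
                     sprintf("malformed TSV '%s': %s", path, conditionMessage(e)),
                     class = "cs_parse_error"))
    if (is.null(sample_id))
      sample_id <- sub("\\.[^.]*$", "", basename(path))
    return(variant_table(df, sample_id = sample_id))
  }
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_data(
                  sprintf("malformed VCF '%s': %s", path, conditionMessage(e)),
                  class = "cs_parse_error"))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    sid <- if (is.null(sample_id)) sub("\\.[^.]*$", "", basename(path)) else sample_id
    return(variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    stringsAsFactors = FALSE), sample_id = sid))
  }
  info_field <- function(info, tag) {
    m <- regmatches(info, regexpr(sprintf("(?:^|;)%s=([^;]*)", tag), info, perl = TRUE))
    out <- rep(NA_character_, length(info))
    hit <- vapply(m, length, integer(1)) > 0
    out[hit] <- sub(sprintf("^;?%s=", tag), "", unlist(m))
    out
  }
  has_gt <- ncol(v@gt) >= 2
  ad <- if (has_gt) vcfR::extract.gt(v, element = "AD") else NULL
  sid <- if (!is.null(sample_id)) sample_id
         else if (has_gt) colnames(v@gt)[2] else sub("\\.[^.]*$", "", basename(path))
  rows <- list()
  warned <- FALSE
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    counts <- rep(NA_integer_, length(alts) + 1L)
    if (!is.null(ad) && !is.na(ad[i, 1])) {
      parsed <- suppressWarnings(as.integer(strsplit(ad[i, 1], ",", fixed = TRUE)[[1]]))
      if (length(parsed) == length(alts) + 1L) counts <- parsed
    } else if (!warned) {
      warning("missing AD/DP in one or more records; read counts set absent",
              call. = FALSE)
      warned <- TRUE
    }
    for (a in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        gene = info_field(fix$INFO[i], "GENE"),
        effect = ifelse(is.na(info_field(fix$INFO[i], "EFFECT")), "other",
                        info_field(fix$INFO[i], "EFFECT")),
        alt_reads = counts[a + 1L], ref_reads = counts[1L],
        stringsAsFactors = FALSE)
    }
  }
  variant_table(do.call(rbind, rows), sample_id = sid)
}

#' Write a variant table to VCF or TSV
#'
#' @param table A `variant_table`.
#' @param path Output path.
#' @param format `"vcf"` (minimal v4.2, AD/DP in FORMAT, GENE/EFFECT in
#'   INFO) or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(table, path, format = c("tsv", "vcf")) {
  stopifnot(inherits(table, "variant_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(table), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  sid <- attr(table, "sample_id")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sid, sep = "\t"))
  info <- ifelse(is.na(table$gene), paste0("EFFECT=", table$effect),
                 paste0("GENE=", table$gene, ";EFFECT=", table$effect))
  gt <- sprintf("0/1:%s,%s:%s",
                ifelse(is.na(table$ref_reads), ".", table$ref_reads),
                ifelse(is.na(table$alt_reads), ".", table$alt_reads),
                ifelse(is.na(table$ref_reads) | is.na(table$alt_reads), ".",
                       table$ref_reads + table$alt_reads))
  body <- paste(table$chrom, table$pos, ".", table$ref, table$alt, ".",
                "PASS", info, "GT:AD:DP", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Somatic subtraction of a parental sample from a resistant derivative
#'
#' Returns exactly the variants of the resistant table whose
#' `(chrom,pos,ref,alt)` key is absent from the parental table — the
#' catalogue of mutations acquired during the evolution of resistance.
#' Parental-only variants are dropped silently (their count is reported via
#' a message). No VAF or quality filtering is applied here; thresholding
#' belongs to downstream subclone inference.
#'
#' @param parental,resistant `variant_table`s keyed identically.
#' @return A `variant_table` with sample id `<resistant>.acquired`.
#' @export
subtract_somatic <- function(parental, resistant) {
  stopifnot(inherits(parental, "variant_table"), inherits(resistant, "variant_table"))
  pk <- variant_keys(parental)
  rk <- variant_keys(resistant)
  keep <- !(rk %in% pk)
  dropped_parental_only <- sum(!(pk %in% rk))
  message(sprintf("subtract_somatic: %d acquired, %d shared removed, %d parental-only ignored",
                  sum(keep), sum(!keep), dropped_parental_only))
  out <- as.data.frame(resistant)[keep, , drop = FALSE]
  variant_table(out, sample_id = paste0(attr(resistant, "sample_id"), ".acquired"))
}

#' Classify acquired variants as shared or private across derivatives
#'
#' A variant key present in two or more acquired catalogues is `common`;
#' a key present in exactly one is `private` to its owner.
#'
#' @param acquired_tables List of two or more `variant_table`s (acquired
#'   catalogues of different resistant derivatives).
#' @return Data frame `key`, `class` (`common`/`private`), `owner`
#'   (sample id for private keys, `NA` for common), with an attribute
#'   `counts` giving the per-class totals.
#' @export
classify_shared_private <- function(acquired_tables) {
  if (length(acquired_tables) < 2)
    stop_config("classify_shared_private needs at least 2 acquired tables",
                field = "acquired_tables")
  keysets <- lapply(acquired_tables, variant_keys)
  ids <- vapply(acquired_tables, function(t) attr(t, "sample_id"), character(1))
  all_keys <- sort(unique(unlist(keysets)))
  n_in <- vapply(all_keys, function(k)
    sum(vapply(keysets, function(s) k %in% s, logical(1))), integer(1))
  owner <- rep(NA_character_, length(all_keys))
  priv <- n_in == 1L
  owner[priv] <- vapply(all_keys[priv], function(k)
    ids[which(vapply(keysets, function(s) k %in% s, logical(1)))], character(1))
  out <- data.frame(key = all_keys,
                    class = ifelse(n_in >= 2L, "common", "private"),
                    owner = owner, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(common = sum(out$class == "common"),
                           private = sum(out$class == "private"))
  out
}

#' Annotate known resistance-driver alterations
#'
#' Marks variants whose `(gene, protein change)` pair matches a supplied
#' driver list (for example `list(KRAS = "p.G12D", MAP2K1 = "p.I103N")`).
#' Matching is exact; variants without a protein label are never annotated.
#'
#' @param table A `variant_table`, optionally with a `protein` column.
#' @param driver_list Named list mapping gene to character vector of protein
#'   change labels.
#' @return The table with a `driver` column (`<gene> <label>` or `NA`).
#' @export
annotate_drivers <- function(table, driver_list) {
  stopifnot(inherits(table, "variant_table"))
  if (length(driver_list) && (is.null(names(driver_list)) || !all(nzchar(names(driver_list)))))
    stop_config("driver_list must be named by gene", field = "driver_list")
  protein <- if ("protein" %in% names(table)) table$protein
             else rep(NA_character_, nrow(table))
  driver <- rep(NA_character_, nrow(table))
  for (g in names(driver_list)) {
    hit <- !is.na(table$gene) & table$gene == g &
      !is.na(protein) & protein %in% driver_list[[g]]
    driver[hit] <- paste(g, protein[hit])
  }
  table$driver <- driver
  table
}
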