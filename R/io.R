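#' Read a genotype panel from a VCF file
#'
#' Diploid biallelic GT fields are encoded as `0/0 -> 0`, `0/1` or
#' `1/0 -> 1`, `1/1 -> 2`, missing (`./.` or `.`) `-> 9`. Multiallelic
#' records and records whose GT refers to an allele index above 1 are
#' skipped; the count of skipped sites is reported as a message and stored
#' in the `dropped_sites` attribute. Phased separators (`|`) are accepted.
#'
#' @param path Path to a VCF file (plain or bgzip/gzip compressed).
#' @param populations Optional data frame (`sample_id`, `population`)
#'   assigning samples to populations; unlisted samples get population
#'   `"unassigned"`.
#' @return A [genotype_panel()], loci in genome order.
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_dropped <- sum(!biallelic)
  if (!any(biallelic))
    stop("no biallelic sites in ", path, call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(alt))
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]

  code_one <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(9L, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  codes <- apply(gt, 2, code_one)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  codes <- t(codes)  # samples x loci

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  loci <- tibble::tibble(snp_id = ids,
                         chromosome = fix[, "CHROM"],
                         position_bp = as.integer(fix[, "POS"]))
  sample_ids <- colnames(gt)
  samples <- tibble::tibble(sample_id = sample_ids,
                            population = "unassigned")
  if (!is.null(populations)) {
    populations <- tibble::as_tibble(populations)
    m <- match(sample_ids, populations$sample_id)
    samples$population[!is.na(m)] <-
      as.character(populations$population[m[!is.na(m)]])
  }
  if (n_dropped > 0)
    message("read_vcf: skipped ", n_dropped, " multiallelic site(s)")
  panel <- genotype_panel(codes, loci, samples)
  attr(panel, "dropped_sites") <- n_dropped
  panel
}

#' Read a genotype panel from a tab-delimited table
#'
#' Two dialects are supported. `simple_matrix`: first column `sample_id`,
#' optional second column `population`, remaining columns one per SNP
#' (header = SNP id) holding codes 0/1/2/9; an accompanying locus map can be
#' supplied via `loci`, otherwise loci are placed on chromosome "1" at
#' 1-based column index positions. `hapmap_like`: one row per SNP with
#' columns `rs` (id), `chrom`, `pos`, then one column per sample holding a
#' two-letter allele pair (e.g. "AG"); the first allele listed at each locus
#' (scanning its genotypes in sample order) is taken as wildtype, so "AA"
#' -> 0, "AG"/"GA" -> 1, "GG" -> 2, and "NN" or "--" -> 9.
#'
#' @param path Path to the tab-delimited file.
#' @param dialect `"simple_matrix"` or `"hapmap_like"`.
#' @param loci Optional locus map for `simple_matrix`
#'   (`snp_id`, `chromosome`, `position_bp`).
#' @param populations Optional sample-to-population table as in [read_vcf()].
#' @return A [genotype_panel()].
#' @export
read_genotype_table <- function(path,
                                dialect = c("simple_matrix", "hapmap_like"),
                                loci = NULL, populations = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (dialect == "simple_matrix") {
    stopifnot(names(tab)[1] == "sample_id")
    has_pop <- identical(names(tab)[2], "population")
    first_snp <- if (has_pop) 3L else 2L
    snp_ids <- names(tab)[first_snp:ncol(tab)]
    codes <- as.matrix(tab[, first_snp:ncol(tab)])
    suppressWarnings(storage.mode(codes) <- "integer")
    if (anyNA(codes))
      stop("unknown code characters in ", path, call. = FALSE)
    if (is.null(loci))
      loci <- tibble::tibble(snp_id = snp_ids, chromosome = "1",
                             position_bp = seq_along(snp_ids))
    samples <- tibble::tibble(
      sample_id = tab$sample_id,
      population = if (has_pop) tab$population else "unassigned")
  } else {
    stopifnot(all(c("rs", "chrom", "pos") %in% names(tab)))
    sample_cols <- setdiff(names(tab), c("rs", "chrom", "pos"))
    if (length(sample_cols) == 0) stop("no sample columns", call. = FALSE)
    pairs <- as.matrix(tab[, sample_cols])
    codes <- matrix(9L, nrow = length(sample_cols), ncol = nrow(tab))
    for (j in seq_len(nrow(tab))) {
      g <- toupper(pairs[j, ])
      a <- unlist(strsplit(g, ""), use.names = FALSE)
      a <- a[a %in% c("A", "C", "G", "T")]
      if (length(a) == 0) next  # all missing
      wildtype <- a[1]
      alleles <- unique(a)
      if (length(alleles) > 2)
        stop("more than two alleles at ", tab$rs[j], call. = FALSE)
      n_wt <- vapply(strsplit(g, ""),
                     function(p) sum(p == wildtype), integer(1))
      ok <- grepl("^[ACGT][ACGT]$", g)
      codes[ok, j] <- 2L - n_wt[ok]
    }
    loci <- tibble::tibble(snp_id = tab$rs, chromosome = tab$chrom,
                           position_bp = as.integer(tab$pos))
    samples <- tibble::tibble(sample_id = sample_cols,
                              population = "unassigned")
  }
  if (!is.null(populations)) {
    populations <- tibble::as_tibble(populations)
    m <- match(samples$sample_id, populations$sample_id)
    samples$population[!is.na(m)] <-
      as.character(populations$population[m[!is.na(m)]])
  }
  genotype_panel(codes, loci, samples)
}

#' Write a panel in the simple_matrix dialect
#'
#' The inverse of `read_genotype_table(dialect = "simple_matrix")`: a TSV
#' with `sample_id`, `population`, then one column per SNP. A JSON sidecar
#' (`<path>.meta.json`) records the locus map and sample order so the panel
#' round-trips exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(panel, path) {
  tab <- tibble::as_tibble(panel$codes)
  names(tab) <- panel$loci$snp_id
  tab <- dplyr::bind_cols(panel$samples[, c("sample_id", "population")], tab)
  readr::write_tsv(tab, path, progress = FALSE)
  meta <- list(loci = panel$loci, samples = panel$samples$sample_id)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Partition SNPs into six annotation groups
#'
#' SNP functional annotations are collapsed into six mutually exclusive
#' groups by precedence: group1 (missense, nonsense, frameshift, splice-3),
#' group2 (coding-synonymous), group3 (untranslated 3'/5'), group4
#' (near-gene 3'/5'), group5 (intron), group6 (unknown / everything else).
#' A SNP carrying annotations from several groups is assigned the
#' highest-precedence one. Groups 1-3 are "coding", 4-6 "non-coding".
#'
#' @param snp_ids Character vector of SNP ids to classify.
#' @param raw_labels Named list: `snp_id` -> character vector of annotation
#'   strings. SNPs absent from the list, or with an empty set, get group6.
#' @return Tibble with columns `snp_id`, `group` (factor `group1..group6`)
#'   and `coding` (logical).
#' @export
partition_by_annotation <- function(snp_ids, raw_labels) {
  vocab <- list(
    group1 = c("missense", "nonsense", "frameshift", "splice-3"),
    group2 = "coding-synonymous",
    group3 = c("untranslated-3", "untranslated-5",
               "untranslated 3'", "untranslated 5'"),
    group4 = c("near-gene-3", "near-gene-5",
               "near-gene 3'", "near-gene 5'"),
    group5 = "intron",
    group6 = "unknown")
  known <- unlist(vocab, use.names = FALSE)
  assign_one <- function(labels) {
    labels <- as.character(labels)
    unknown <- setdiff(labels, known)
    if (length(unknown) > 0)
      warning("unknown annotation label(s) treated as group6: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    for (g in paste0("group", 1:5))
      if (any(labels %in% vocab[[g]])) return(g)
    "group6"
  }
  group <- vapply(snp_ids, function(id) {
    labels <- raw_labels[[id]]
    if (is.null(labels) || length(labels) == 0) "group6" else
      assign_one(labels)
  }, character(1))
  tibble::tibble(
    snp_id = snp_ids,
    group = factor(group, levels = paste0("group", 1:6)),
    coding = group %in% paste0("group", 1:3))
}
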