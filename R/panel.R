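#' Construct a genotype panel
#'
#' A `genotype_panel` is the universal input of every analysis in this
#' package: a samples-by-loci matrix of genotype codes together with a locus
#' map and a sample-to-population assignment. Codes follow the standard
#' dosage-like convention: `0` homozygous wildtype (AA), `1` heterozygous
#' (AB), `2` homozygous variant (BB), `9` missing.
#'
#' @param codes Integer matrix, one row per sample and one column per locus,
#'   values in `{0, 1, 2, 9}`. Row names, if present, must match `samples`.
#' @param loci Data frame with columns `snp_id`, `chromosome`, `position_bp`
#'   (1-based), one row per matrix column, in column order. An optional
#'   `annotation_class` column is carried along.
#' @param samples Data frame with columns `sample_id` and `population`, one
#'   row per matrix row, in row order.
#' @param sort Sort loci genome-wise (autosomes in natural order, then X,
#'   ascending position within chromosome)? Default `TRUE`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `codes` (integer matrix), `loci` (tibble) and `samples` (tibble).
#' @export
#' @examples
#' panel <- genotype_panel(
#'   codes = rbind(c(0L, 1L, 2L), c(1L, 1L, 9L)),
#'   loci = data.frame(snp_id = c("rs1", "rs2", "rs3"),
#'                     chromosome = "1", position_bp = c(100, 200, 300)),
#'   samples = data.frame(sample_id = c("s1", "s2"), population = "POP")
#' )
#' panel
genotype_panel <- function(codes, loci, samples, sort = TRUE) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  loci <- tibble::as_tibble(loci)
  samples <- tibble::as_tibble(samples)

  stopifnot(all(c("snp_id", "chromosome", "position_bp") %in% names(loci)),
            all(c("sample_id", "population") %in% names(samples)))
  loci$chromosome <- normalize_chromosome(loci$chromosome)
  loci$position_bp <- as.integer(loci$position_bp)
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)

  if (nrow(codes) != nrow(samples))
    stop("codes has ", nrow(codes), " rows but ", nrow(samples),
         " samples are declared", call. = FALSE)
  if (ncol(codes) != nrow(loci))
    stop("codes has ", ncol(codes), " columns but ", nrow(loci),
         " loci are declared", call. = FALSE)
  bad <- !codes %in% c(0L, 1L, 2L, 9L)
  if (any(bad))
    stop("invalid genotype codes (not 0/1/2/9): e.g. ",
         paste(utils::head(unique(codes[bad]), 3), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(loci$snp_id))
    stop("duplicate snp_id in locus map", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id", call. = FALSE)
  if (any(loci$position_bp < 0, na.rm = TRUE))
    stop("negative position_bp", call. = FALSE)

  dimnames(codes) <- list(samples$sample_id, loci$snp_id)
  panel <- structure(list(codes = codes, loci = loci, samples = samples),
                     class = "genotype_panel")
  if (sort) panel <- sort_loci(panel) else panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$codes), " samples x ", ncol(x$codes),
      " loci\n", sep = "")
  cat("  populations: ",
      paste(names(table(x$samples$population)), "(",
            as.integer(table(x$samples$population)), ")",
            sep = "", collapse = ", "), "\n", sep = "")
  cat("  chromosomes: ",
      paste(unique(x$loci$chromosome), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$codes)

#' Number of samples / loci in a panel
#' @param panel A [genotype_panel()].
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$codes)

#' @rdname n_samples
#' @export
n_loci <- function(panel) ncol(panel$codes)

#' Sample ids belonging to one population
#' @param panel A [genotype_panel()].
#' @param population Population label.
#' @return Character vector of sample ids.
#' @export
population_samples <- function(panel, population) {
  ids <- panel$samples$sample_id[panel$samples$population == population]
  if (length(ids) == 0)
    stop("unknown population: ", population, call. = FALSE)
  ids
}

# strip a "chr" prefix so mixed-dialect inputs agree
normalize_chromosome <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

# ordering key: autosomes numerically first, then X (then anything else)
chromosome_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(!is.na(num), num,
                 ifelse(toupper(chrom) == "X", 1e6,
                        1e6 + as.numeric(factor(chrom))))
  rank
}

#' Sort panel loci genome-wise
#'
#' Orders loci with autosomes first (natural numeric order), then the X
#' chromosome, and by ascending base-pair position within each chromosome.
#' Matrix columns are permuted consistently. Idempotent.
#'
#' @param panel A [genotype_panel()].
#' @return The panel with loci (and code columns) in genome order.
#' @export
sort_loci <- function(panel) {
  loci <- panel$loci
  key <- paste(loci$chromosome, loci$position_bp, loci$snp_id)
  if (anyDuplicated(key))
    stop("duplicate (chromosome, position, snp_id) locus", call. = FALSE)
  ord <- order(chromosome_rank(loci$chromosome), loci$position_bp,
               loci$snp_id, method = "radix")
  panel$loci <- loci[ord, ]
  panel$codes <- panel$codes[, ord, drop = FALSE]
  panel
}

#' Restrict a panel to a subset of loci
#'
#' Genome order is preserved regardless of the order of `snp_ids`.
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids Character vector of locus ids to keep.
#' @return A smaller `genotype_panel`.
#' @export
subset_loci <- function(panel, snp_ids) {
  keep <- panel$loci$snp_id %in% snp_ids
  missing <- setdiff(snp_ids, panel$loci$snp_id)
  if (length(missing) > 0)
    stop("unknown snp_id: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  if (!any(keep)) stop("empty locus subset", call. = FALSE)
  panel$loci <- panel$loci[keep, ]
  panel$codes <- panel$codes[, keep, drop = FALSE]
  panel
}

#' Restrict a panel to a subset of samples
#' @param panel A [genotype_panel()].
#' @param sample_ids Character vector of sample ids to keep.
#' @return A smaller `genotype_panel`.
#' @export
subset_samples <- function(panel, sample_ids) {
  missing <- setdiff(sample_ids, panel$samples$sample_id)
  if (length(missing) > 0)
    stop("unknown sample: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  keep <- panel$samples$sample_id %in% sample_ids
  panel$samples <- panel$samples[keep, ]
  panel$codes <- panel$codes[keep, , drop = FALSE]
  panel
}
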