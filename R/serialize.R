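#' Serialize one individual as a single-column genotype file
#'
#' The byte stream on which per-individual CE is defined: one code
#' character per line, i.e. for each locus in genome order its code
#' character (`0`, `1`, `2` or `9`) followed by a single newline (0x0A).
#' Payload length is exactly `2 * n_loci` bytes; there is no trailing
#' blank line.
#'
#' @param panel A [genotype_panel()] (loci already in genome order).
#' @param sample Sample id.
#' @return Raw vector with attributes `layout = "individual_column"` and
#'   `n_genotypes`.
#' @export
serialize_individual <- function(panel, sample) {
  if (!sample %in% panel$samples$sample_id)
    stop("unknown sample: ", sample, call. = FALSE)
  codes <- panel$codes[sample, ]
  if (length(codes) == 0) stop("panel has no loci", call. = FALSE)
  serialize_codes(codes)
}

#' Serialize a code vector as a single-column stream
#'
#' Lower-level form of [serialize_individual()] for code vectors that do
#' not live in a panel (e.g. randomized sequences).
#'
#' @param codes Integer vector over `{0, 1, 2, 9}`.
#' @return Raw vector, `2 * length(codes)` bytes.
#' @export
serialize_codes <- function(codes) {
  if (length(codes) == 0) stop("empty code sequence", call. = FALSE)
  bytes <- rbind(code_bytes(codes), as.raw(0x0AL))
  out <- as.raw(bytes)
  attr(out, "layout") <- "individual_column"
  attr(out, "n_genotypes") <- length(codes)
  out
}

#' Serialize a population window as a row matrix
#'
#' The byte stream on which window CE is defined: one newline-terminated
#' row of code characters per sample, loci in columns. Payload length is
#' `n_samples * (n_loci + 1)` bytes.
#'
#' @param panel A [genotype_panel()].
#' @param samples Character vector of sample ids (rows, in this order).
#' @param loci_idx Integer vector of locus column indices (the window).
#' @return Raw vector with attributes `layout = "population_matrix"` and
#'   `n_genotypes`.
#' @export
serialize_matrix <- function(panel, samples, loci_idx) {
  if (length(samples) == 0 || length(loci_idx) == 0)
    stop("empty sample or locus selection", call. = FALSE)
  missing <- setdiff(samples, panel$samples$sample_id)
  if (length(missing) > 0)
    stop("unknown sample: ", missing[1], call. = FALSE)
  block <- panel$codes[samples, loci_idx, drop = FALSE]
  serialize_rows(block)
}

# rows of a code matrix -> newline-terminated byte rows
serialize_rows <- function(block) {
  nl <- as.raw(0x0AL)
  rows <- apply(block, 1, function(r) c(code_bytes(r), nl), simplify = FALSE)
  out <- as.raw(unlist(rows, use.names = FALSE))
  attr(out, "layout") <- "population_matrix"
  attr(out, "n_genotypes") <- length(block)
  out
}

# ASCII bytes for codes 0/1/2/9 ("0" = 0x30)
code_bytes <- function(codes) {
  if (!all(codes %in% c(0L, 1L, 2L, 9L)))
    stop("invalid genotype codes in sequence", call. = FALSE)
  as.raw(0x30L + as.integer(codes))
}

# parse a character string like "012012" into an integer code vector
parse_code_string <- function(s) {
  as.integer(strsplit(s, "", fixed = TRUE)[[1]])
}
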