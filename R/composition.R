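#' Composition summary of a genotype code sequence
#'
#' Counts of the four codes, percent heterozygosity and Shannon entropy.
#' `%Het` is `100 * n_1 / (n_0 + n_1 + n_2)`: missing calls (code 9) are
#' part of the compressed payload but are excluded from heterozygosity,
#' which is a genotype-call statistic. Entropy is over the `{0, 1, 2}`
#' proportions in bits, with `0 * log(0) = 0`, so it ranges over
#' `[0, log2(3)]`.
#'
#' @param codes Integer vector (or matrix, taken cell-wise) over
#'   `{0, 1, 2, 9}`.
#' @return One-row tibble: `n0`, `n1`, `n2`, `n_missing`, `n_called`,
#'   `het_percent`, `shannon_entropy_bits`. If every code is missing,
#'   `het_percent` and entropy are `NA` with a warning.
#' @export
composition <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) == 0) stop("empty code sequence", call. = FALSE)
  if (!all(codes %in% c(0L, 1L, 2L, 9L)))
    stop("invalid genotype codes", call. = FALSE)
  n0 <- sum(codes == 0L); n1 <- sum(codes == 1L)
  n2 <- sum(codes == 2L); n9 <- sum(codes == 9L)
  called <- n0 + n1 + n2
  if (called == 0) {
    warning("all codes missing; heterozygosity undefined", call. = FALSE)
    het <- NA_real_; ent <- NA_real_
  } else {
    het <- 100 * n1 / called
    p <- c(n0, n1, n2) / called
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  }
  tibble::tibble(n0 = n0, n1 = n1, n2 = n2, n_missing = n9,
                 n_called = called, het_percent = het,
                 shannon_entropy_bits = ent)
}

#' Genome-wide CE and heterozygosity per sample
#'
#' One point of the CE-versus-heterozygosity plane per sample: the CE of
#' the single-column serialization of the full genome-ordered genotype
#' profile, paired with its composition summary.
#'
#' @param panel A [genotype_panel()].
#' @param samples Sample ids (default: every sample in the panel).
#' @param profile A [ce_profile()].
#' @return Tibble, one row per sample: `sample_id`, `population`,
#'   `n_snps`, `het_percent`, `shannon_entropy_bits`, `ce` (fraction) and
#'   `ce_percent` (truncated to 2 decimals).
#' @export
genome_ce <- function(panel, samples = NULL, profile = ce_profile()) {
  if (is.null(samples)) samples <- panel$samples$sample_id
  rows <- purrr::map(samples, function(s) {
    payload <- serialize_individual(panel, s)
    ce_frac <- compression_efficiency(payload, profile)$ce
    comp <- composition(panel$codes[s, ])
    tibble::tibble(
      sample_id = s,
      population = panel$samples$population[
        match(s, panel$samples$sample_id)],
      n_snps = n_loci(panel),
      het_percent = comp$het_percent,
      shannon_entropy_bits = comp$shannon_entropy_bits,
      ce = ce_frac,
      ce_percent = ce_percent(ce_frac))
  })
  dplyr::bind_rows(rows)
}

#' CE and heterozygosity over a locus subset
#'
#' As [genome_ce()] but restricted to a mask of loci (e.g. the coding
#' groups from [partition_by_annotation()]); genome order is preserved.
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids Non-empty subset of panel locus ids.
#' @param samples Sample ids (default all).
#' @param profile A [ce_profile()].
#' @return As [genome_ce()].
#' @export
subset_ce <- function(panel, snp_ids, samples = NULL,
                      profile = ce_profile()) {
  genome_ce(subset_loci(panel, snp_ids), samples = samples,
            profile = profile)
}

#' Scatter of CE against heterozygosity
#'
#' @param ce_table Output of [genome_ce()] (or [subset_ce()]).
#' @return A ggplot: per-sample CE percent (y) against percent
#'   heterozygosity (x), coloured by population.
#' @export
plot_ce_het <- function(ce_table) {
  ggplot2::ggplot(ce_table,
                  ggplot2::aes(x = .data$het_percent,
                               y = 100 * .data$ce,
                               colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "heterozygosity (%)",
                  y = "compression efficiency (%)",
                  colour = "population") +
    ggplot2::theme_minimal()
}
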