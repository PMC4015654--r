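#' Per-population CE and heterozygosity summaries
#'
#' @param panel A [genotype_panel()].
#' @param profile A [ce_profile()].
#' @return Tibble, one row per population: `population`, `n_samples`,
#'   `mean_ce`, `sd_ce` (NA for single-sample populations), `mean_het`.
#' @export
population_summaries <- function(panel, profile = ce_profile()) {
  genome_ce(panel, profile = profile) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_ce = mean(.data$ce),
      sd_ce = if (dplyr::n() > 1) stats::sd(.data$ce) else NA_real_,
      mean_het = mean(.data$het_percent),
      .groups = "drop")
}

#' Pairwise |dCE| against F_ST
#'
#' Enumerates all unordered population pairs (`k` populations give
#' `k (k - 1) / 2` pairs), takes the absolute difference of mean
#' population CE for each pair, joins the supplied F_ST value, and
#' correlates the two metrics.
#'
#' @param summaries Output of [population_summaries()].
#' @param fst_table Data frame with columns `pop_a`, `pop_b`, `fst`
#'   covering every pair (order within a pair does not matter).
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A `dce_fst` object: list with `pairs` (tibble: `pop_a`,
#'   `pop_b`, `abs_dce`, `fst`) and `correlation` (tibble: `method`,
#'   `estimate`, `p_value`, `n_pairs`; estimate `NA` with fewer than 3
#'   pairs). [tidy()] returns the pairs, [glance()] the correlation row.
#' @export
pairwise_dce_vs_fst <- function(summaries, fst_table,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  fst_table <- tibble::as_tibble(fst_table)
  pops <- summaries$population
  if (length(pops) < 2) stop("need at least 2 populations", call. = FALSE)
  pairs <- utils::combn(pops, 2)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  fst_key <- key(fst_table$pop_a, fst_table$pop_b)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    m <- match(key(a, b), fst_key)
    if (is.na(m))
      stop("fst_table is missing pair ", a, " / ", b, call. = FALSE)
    tibble::tibble(
      pop_a = a, pop_b = b,
      abs_dce = abs(summaries$mean_ce[summaries$population == a] -
                      summaries$mean_ce[summaries$population == b]),
      fst = fst_table$fst[m])
  })
  pairs_tbl <- dplyr::bind_rows(rows)
  if (nrow(pairs_tbl) >= 3) {
    ct <- stats::cor.test(pairs_tbl$abs_dce, pairs_tbl$fst,
                          method = method, exact = FALSE)
    corr <- tibble::tibble(method = method,
                           estimate = unname(ct$estimate),
                           p_value = ct$p.value,
                           n_pairs = nrow(pairs_tbl))
  } else {
    warning("fewer than 3 pairs; correlation undefined", call. = FALSE)
    corr <- tibble::tibble(method = method, estimate = NA_real_,
                           p_value = NA_real_, n_pairs = nrow(pairs_tbl))
  }
  structure(list(pairs = pairs_tbl, correlation = corr),
            class = "dce_fst")
}

#' @export
print.dce_fst <- function(x, ...) {
  cat("<dce_fst> ", nrow(x$pairs), " population pair(s); ",
      x$correlation$method, " r = ",
      signif(x$correlation$estimate, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dce_fst <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.dce_fst <- function(x, ...) x$correlation

#' @exportS3Method ggplot2::autoplot
autoplot.dce_fst <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$fst, y = .data$abs_dce)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = expression(F[ST]), y = "|ΔCE|") +
    ggplot2::theme_minimal()
}

#' Hudson F_ST between two populations
#'
#' Reference estimator for synthetic validation: per locus,
#' `N = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`
#' over `D = p1 (1 - p2) + p2 (1 - p1)`, with allele frequencies computed
#' from genotype codes (`p = (2 n_2 + n_1) / (2 n_called)`, counting the
#' variant allele) and `n` the number of called genotypes. The genome
#' value is the ratio of averages, clamped at 0; per-locus values may be
#' negative. Loci monomorphic in both populations (D = 0) are excluded.
#'
#' @param panel A [genotype_panel()].
#' @param pop_a,pop_b Population labels, each with >= 2 samples.
#' @return List with `fst` (genome ratio-of-averages) and `per_locus`
#'   (tibble: `snp_id`, `fst`, `numerator`, `denominator`).
#' @export
hudson_fst <- function(panel, pop_a, pop_b) {
  freq <- function(pop) {
    ids <- population_samples(panel, pop)
    if (length(ids) < 2)
      stop("population ", pop, " has fewer than 2 samples", call. = FALSE)
    codes <- panel$codes[ids, , drop = FALSE]
    called <- colSums(codes != 9L)
    alt <- colSums((codes == 1L) + 2L * (codes == 2L))
    list(p = ifelse(called > 0, alt / (2 * called), NA_real_), n = called)
  }
  fa <- freq(pop_a); fb <- freq(pop_b)
  p1 <- fa$p; p2 <- fb$p; n1 <- fa$n; n2 <- fb$n
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / pmax(n1 - 1, 1) -
    p2 * (1 - p2) / pmax(n2 - 1, 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  usable <- !is.na(den) & den > 0
  per_locus <- tibble::tibble(
    snp_id = panel$loci$snp_id[usable],
    fst = unname(num[usable] / den[usable]),
    numerator = unname(num[usable]),
    denominator = unname(den[usable]))
  genome <- if (sum(usable) == 0) 0 else
    max(0, sum(num[usable]) / sum(den[usable]))
  list(fst = genome, per_locus = per_locus)
}
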