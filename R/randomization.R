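#' Order-destroying permutation null (RAND1)
#'
#' A uniform random permutation of the input code multiset -- the exact
#' genotype proportions of the individual are preserved (including missing
#' codes) while all order, and hence all LD-driven regularity, is
#' destroyed.
#'
#' @param codes Integer code vector over `{0, 1, 2, 9}`.
#' @param seed Optional integer seed (local to this call).
#' @return Permuted code vector of the same length and multiset.
#' @export
rand1 <- function(codes, seed = NULL) {
  if (length(codes) == 0) stop("empty code sequence", call. = FALSE)
  if (length(codes) == 1) return(codes)  # sample(x) would expand 1:x
  with_seed(seed, sample(codes))
}

#' Population-proportion null (RAND2)
#'
#' I.i.d. draws from `{0, 1, 2}` preserving the individual's
#' heterozygosity while taking the homozygote split from the population:
#' `P(1) = het_fraction`, `P(0) = (1 - het) * homo_ratio`,
#' `P(2) = (1 - het) * (1 - homo_ratio)`. For example, 20% heterozygosity
#' with a 3:1 population homozygote ratio (`homo_ratio = 0.75`) yields
#' expected proportions 60% / 20% / 20%. Missing codes are never emitted.
#'
#' @param n_loci Sequence length.
#' @param het_fraction Heterozygote probability in `[0, 1]`.
#' @param homo_ratio Fraction of the homozygote mass assigned to code 0,
#'   in `[0, 1]` (default 0.5, the maximally entropic split).
#' @param seed Optional integer seed.
#' @param exact If `TRUE`, draw an exact-count multiset (rounded to
#'   `n_loci`) and permute it instead of i.i.d. sampling.
#' @return Integer code vector of length `n_loci`.
#' @export
rand2 <- function(n_loci, het_fraction, homo_ratio = 0.5, seed = NULL,
                  exact = FALSE) {
  stopifnot(n_loci >= 1,
            het_fraction >= 0, het_fraction <= 1,
            homo_ratio >= 0, homo_ratio <= 1)
  p <- c(`0` = (1 - het_fraction) * homo_ratio,
         `1` = het_fraction,
         `2` = (1 - het_fraction) * (1 - homo_ratio))
  with_seed(seed, {
    if (exact) {
      counts <- round(p * n_loci)
      counts[2] <- n_loci - counts[1] - counts[3]
      sample(rep(c(0L, 1L, 2L), times = pmax(counts, 0)))
    } else {
      sample(c(0L, 1L, 2L), n_loci, replace = TRUE, prob = p)
    }
  })
}

#' Sorted upper bound
#'
#' Sorting a code sequence ascending (all 0s, then 1s, 2s, 9s) models
#' "totally regular": for a fixed multiset it is the most compressible
#' arrangement, giving the upper CE boundary of the information space.
#'
#' @param codes Integer code vector.
#' @return Sorted code vector.
#' @export
sorted_bound <- function(codes) {
  if (length(codes) == 0) stop("empty code sequence", call. = FALSE)
  sort(codes)
}

#' Expected CE under a randomization scheme
#'
#' Generates `replicates` randomized single-column serializations of one
#' individual's genome profile and reports the mean and sd of their CE
#' next to the real sequence's CE. Schemes: `"rand1"` (permutation,
#' [rand1()]), `"rand2"` (population-proportion i.i.d., [rand2()], using
#' the individual's observed heterozygosity and the supplied or observed
#' population homozygote ratio), `"sorted"` (deterministic upper bound,
#' [sorted_bound()]).
#'
#' @param panel A [genotype_panel()].
#' @param sample Sample id.
#' @param scheme `"rand1"`, `"rand2"` or `"sorted"`.
#' @param replicates Number of randomized replicates (default 10).
#' @param homo_ratio Population fraction of homozygote codes that are 0;
#'   default `NULL` computes it from the sample's population.
#' @param seed Optional integer seed.
#' @param profile A [ce_profile()].
#' @return One-row tibble: `sample_id`, `scheme`, `replicates`, `real_ce`,
#'   `mean_ce`, `sd_ce` (CE as fractions).
#' @export
expected_ce <- function(panel, sample,
                        scheme = c("rand1", "rand2", "sorted"),
                        replicates = 10L, homo_ratio = NULL, seed = NULL,
                        profile = ce_profile()) {
  scheme <- match.arg(scheme)
  codes <- panel$codes[sample, ]
  real <- compression_efficiency(serialize_codes(codes), profile)$ce

  if (scheme == "rand2" && is.null(homo_ratio)) {
    pop <- panel$samples$population[match(sample, panel$samples$sample_id)]
    pop_codes <- panel$codes[population_samples(panel, pop), , drop = FALSE]
    n0 <- sum(pop_codes == 0L); n2 <- sum(pop_codes == 2L)
    homo_ratio <- if (n0 + n2 == 0) 0.5 else n0 / (n0 + n2)
  }
  comp <- composition(codes)
  het <- comp$het_percent / 100

  draw <- function(rep_seed) {
    switch(scheme,
      rand1 = rand1(codes, seed = rep_seed),
      rand2 = rand2(length(codes), het, homo_ratio, seed = rep_seed),
      sorted = sorted_bound(codes))
  }
  if (scheme == "sorted") replicates <- 1L
  rep_seeds <- derive_seeds(seed, replicates)
  ces <- vapply(seq_len(replicates), function(i) {
    compression_efficiency(serialize_codes(draw(rep_seeds[i])),
                           profile)$ce
  }, numeric(1))
  tibble::tibble(sample_id = sample, scheme = scheme,
                 replicates = replicates, real_ce = real,
                 mean_ce = mean(ces),
                 sd_ce = if (replicates > 1) stats::sd(ces) else NA_real_)
}

#' RAND2 noise-floor curve over the heterozygosity range
#'
#' The mean CE of maximally chaotic RAND2 sequences at each grid point of
#' heterozygosity defines the signal-to-noise boundary of the information
#' space: real genotype sequences sit above it, and its minimum falls at
#' roughly one-third heterozygosity, where the three-symbol stream is most
#' entropic. At 100% heterozygosity the string is all 1s (highly
#' compressible); at 0% it is a random two-symbol string, which still
#' compresses better than the three-symbol minimum.
#'
#' @param het_grid Heterozygosity fractions in `[0, 1]` (default
#'   `seq(0, 1, 0.01)`).
#' @param homo_ratio Homozygote split (default 0.5, the boundary-defining
#'   even split).
#' @param n_loci Sequence length per replicate (default 50000).
#' @param replicates Replicates per grid point (default 10).
#' @param seed Optional integer seed.
#' @param profile A [ce_profile()].
#' @return A `noise_floor` tibble: `het`, `mean_ce`, `sd_ce` (fractions).
#' @export
noise_floor <- function(het_grid = seq(0, 1, by = 0.01), homo_ratio = 0.5,
                        n_loci = 50000L, replicates = 10L, seed = NULL,
                        profile = ce_profile()) {
  stopifnot(all(het_grid >= 0 & het_grid <= 1),
            !is.unsorted(het_grid, strictly = TRUE))
  grid_seeds <- derive_seeds(seed, length(het_grid) * replicates)
  k <- 0L
  rows <- purrr::map(het_grid, function(h) {
    ces <- vapply(seq_len(replicates), function(i) {
      k <<- k + 1L
      codes <- rand2(n_loci, h, homo_ratio, seed = grid_seeds[k])
      compression_efficiency(serialize_codes(codes), profile)$ce
    }, numeric(1))
    tibble::tibble(het = h, mean_ce = mean(ces),
                   sd_ce = if (replicates > 1) stats::sd(ces) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("noise_floor", class(out))
  out
}

#' Heterozygosity at the noise-floor minimum
#'
#' @param curve A [noise_floor()] tibble.
#' @return The `het` grid value (fraction) with minimal mean CE.
#' @export
noise_floor_minimum <- function(curve) {
  curve$het[which.min(curve$mean_ce)]
}

#' @exportS3Method ggplot2::autoplot
autoplot.noise_floor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$het,
                                       y = 100 * .data$mean_ce)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 100 * noise_floor_minimum(object),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "heterozygosity (%)",
                  y = "mean CE of RAND2 sequences (%)") +
    ggplot2::theme_minimal()
}

# run expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# spawn reproducible sub-seeds (kept below 2^31) from one master seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(NA_integer_, n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
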