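#' Specification for a simulated genotype panel
#'
#' The simulator produces diploid biallelic panels with the statistical
#' structure the CE method exploits: tunable heterozygosity (via the
#' allele-frequency distribution), haplotype-block LD (via a
#' mosaic-of-founders model), drift-diverged populations, and planted
#' regions that are either population-shared complex haplotypes or runs
#' of homozygosity.
#'
#' Each sample's two haplotypes are mosaics of the population's founder
#' haplotypes: a walk that switches to a uniformly chosen founder with
#' probability `recomb_prob` between adjacent loci. Fewer founders and
#' lower switching probability mean longer shared blocks, i.e. more LD.
#'
#' @param n_populations Number of populations.
#' @param n_samples Samples per population.
#' @param n_chromosomes Number of chromosomes.
#' @param loci_per_chromosome SNPs per chromosome.
#' @param spacing_bp Inter-SNP spacing in bp (default 2000).
#' @param n_founders Founder haplotypes per population (default 20).
#' @param recomb_prob Founder-switch probability per inter-SNP interval
#'   (default 0.01).
#' @param freq_shape1,freq_shape2 Beta parameters of the ancestral
#'   allele-frequency distribution (default 1, 1: uniform, giving ~33%
#'   expected heterozygosity).
#' @param drift_generations Wright-Fisher generations of independent
#'   drift per population (scalar or one per population; default 0).
#' @param effective_size Diploid effective size during drift (default 100).
#' @param planted_regions Optional data frame with columns `population`,
#'   `chromosome` (index), `start_locus`, `end_locus` (1-based within
#'   chromosome), `sharing_fraction` in (0, 1], `mode`
#'   (`"shared_haplotype"` or `"roh"`).
#' @param missing_rate Per-cell missing (code 9) rate (default 0).
#' @param include_x Label the last chromosome "X" instead of its number?
#'   Default `FALSE`.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_populations = 2L, n_samples = 30L,
                     n_chromosomes = 2L, loci_per_chromosome = 300L,
                     spacing_bp = 2000L, n_founders = 20L,
                     recomb_prob = 0.01, freq_shape1 = 1, freq_shape2 = 1,
                     drift_generations = 0L, effective_size = 100L,
                     planted_regions = NULL, missing_rate = 0,
                     include_x = FALSE) {
  stopifnot(n_populations >= 1, n_samples >= 1, n_chromosomes >= 1,
            loci_per_chromosome >= 1, n_founders >= 2,
            recomb_prob >= 0, recomb_prob <= 1,
            missing_rate >= 0, missing_rate < 1)
  drift_generations <- rep_len(as.integer(drift_generations), n_populations)
  if (!is.null(planted_regions)) {
    planted_regions <- tibble::as_tibble(planted_regions)
    stopifnot(all(c("population", "chromosome", "start_locus", "end_locus",
                    "sharing_fraction", "mode") %in%
                    names(planted_regions)))
    stopifnot(all(planted_regions$sharing_fraction > 0),
              all(planted_regions$sharing_fraction <= 1),
              all(planted_regions$mode %in% c("shared_haplotype", "roh")),
              all(planted_regions$start_locus >= 1),
              all(planted_regions$end_locus <= loci_per_chromosome),
              all(planted_regions$start_locus <= planted_regions$end_locus))
  }
  structure(list(
    n_populations = as.integer(n_populations),
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    loci_per_chromosome = as.integer(loci_per_chromosome),
    spacing_bp = as.integer(spacing_bp),
    n_founders = as.integer(n_founders),
    recomb_prob = recomb_prob,
    freq_shape1 = freq_shape1, freq_shape2 = freq_shape2,
    drift_generations = drift_generations,
    effective_size = as.integer(effective_size),
    planted_regions = planted_regions,
    missing_rate = missing_rate,
    include_x = include_x), class = "sim_spec")
}

#' Wright-Fisher drift of allele frequencies
#'
#' Binomial resampling of `2 * effective_size` allele copies per
#' generation; fixation (0 or 1) is absorbing.
#'
#' @param freqs Numeric vector of allele frequencies in `[0, 1]`.
#' @param generations Number of generations (0 returns `freqs`).
#' @param effective_size Diploid effective population size.
#' @param seed Optional integer seed.
#' @return Drifted frequency vector.
#' @export
drift_populations <- function(freqs, generations, effective_size,
                              seed = NULL) {
  stopifnot(all(freqs >= 0 & freqs <= 1), generations >= 0,
            effective_size >= 1)
  with_seed(seed, {
    p <- freqs
    n_copies <- 2L * as.integer(effective_size)
    for (g in seq_len(generations))
      p <- stats::rbinom(length(p), n_copies, p) / n_copies
    p
  })
}

#' Simulate a genotype panel with known truth
#'
#' See [sim_spec()] for the generative model. Planted
#' `shared_haplotype` regions overwrite the region in a random
#' `sharing_fraction` of the population's samples with one fixed
#' founder-haplotype pair whose members differ at ~30% of the region's
#' loci, so the shared pattern is compositionally complex (in-region
#' heterozygosity stays well above 10% among carriers by construction).
#' `roh` regions overwrite carriers with the homozygous pattern of a
#' single founder haplotype.
#'
#' @param spec A [sim_spec()].
#' @param seed Optional integer seed; the same spec and seed give a
#'   byte-identical panel.
#' @return List with `panel` (a [genotype_panel()]) and `truth`: list of
#'   `planted` (tibble with bp coordinates and carrier ids), `freqs`
#'   (loci x populations matrix of post-drift frequencies) and `founders`
#'   (list of founder haplotype matrices per population).
#' @export
simulate_panel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(seed, {
    n_chr <- spec$n_chromosomes
    l_chr <- spec$loci_per_chromosome
    n_loci_total <- n_chr * l_chr
    chrom_labels <- as.character(seq_len(n_chr))
    if (spec$include_x) chrom_labels[n_chr] <- "X"

    loci <- tibble::tibble(
      snp_id = paste0("snp_", rep(chrom_labels, each = l_chr), "_",
                      rep(seq_len(l_chr), n_chr)),
      chromosome = rep(chrom_labels, each = l_chr),
      position_bp = rep(seq_len(l_chr), n_chr) * spec$spacing_bp)

    p0 <- stats::rbeta(n_loci_total, spec$freq_shape1, spec$freq_shape2)
    pop_names <- paste0("POP", seq_len(spec$n_populations))
    freqs <- matrix(NA_real_, n_loci_total, spec$n_populations,
                    dimnames = list(loci$snp_id, pop_names))
    founders <- list()
    codes <- matrix(0L, spec$n_populations * spec$n_samples, n_loci_total)
    sample_ids <- character(nrow(codes))
    populations <- character(nrow(codes))
    planted_truth <- list()

    mosaic <- function(fd) {
      # one haplotype: founder-index walk with per-interval switching
      n <- ncol(fd)
      switches <- c(TRUE, stats::runif(n - 1) < spec$recomb_prob)
      idx <- cumsum(switches)
      picks <- sample.int(nrow(fd), sum(switches), replace = TRUE)
      fd[cbind(picks[idx], seq_len(n))]
    }

    for (pp in seq_len(spec$n_populations)) {
      p <- drift_populations(p0, spec$drift_generations[pp],
                             spec$effective_size)
      freqs[, pp] <- p
      fd <- matrix(stats::rbinom(spec$n_founders * n_loci_total, 1L,
                                 rep(p, each = spec$n_founders)),
                   nrow = spec$n_founders)
      founders[[pop_names[pp]]] <- fd
      row0 <- (pp - 1L) * spec$n_samples
      for (s in seq_len(spec$n_samples)) {
        codes[row0 + s, ] <- mosaic(fd) + mosaic(fd)
        sample_ids[row0 + s] <- paste0(pop_names[pp], "_", s)
        populations[row0 + s] <- pop_names[pp]
      }
    }

    pr <- spec$planted_regions
    if (!is.null(pr)) for (r in seq_len(nrow(pr))) {
      pp <- match(pr$population[r], pop_names)
      if (is.na(pp)) stop("planted region names unknown population ",
                          pr$population[r], call. = FALSE)
      chr_i <- as.integer(pr$chromosome[r])
      cols <- (chr_i - 1L) * l_chr + (pr$start_locus[r]:pr$end_locus[r])
      w <- length(cols)
      fd <- founders[[pop_names[pp]]]
      h_a <- fd[1L, cols]
      if (pr$mode[r] == "shared_haplotype") {
        flip <- sample.int(w, max(1L, round(0.3 * w)))
        h_b <- h_a
        h_b[flip] <- 1L - h_b[flip]
        pattern <- h_a + h_b
      } else {
        pattern <- 2L * h_a
      }
      row0 <- (pp - 1L) * spec$n_samples
      n_carriers <- max(1L, round(pr$sharing_fraction[r] * spec$n_samples))
      carriers <- row0 + sort(sample.int(spec$n_samples, n_carriers))
      for (cc in carriers) codes[cc, cols] <- pattern
      planted_truth[[r]] <- tibble::tibble(
        population = pop_names[pp],
        chromosome = chrom_labels[chr_i],
        start_bp = pr$start_locus[r] * spec$spacing_bp,
        end_bp = pr$end_locus[r] * spec$spacing_bp,
        mode = pr$mode[r],
        n_carriers = n_carriers,
        carrier_ids = list(sample_ids[carriers]))
    }

    if (spec$missing_rate > 0) {
      drop <- stats::runif(length(codes)) < spec$missing_rate
      codes[drop] <- 9L
    }

    panel <- genotype_panel(
      codes, loci,
      tibble::tibble(sample_id = sample_ids, population = populations))
    list(panel = panel,
         truth = list(planted = dplyr::bind_rows(planted_truth),
                      freqs = freqs, founders = founders))
  })
}
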