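test_that("simulation is byte-identical under a fixed spec and seed", {
  spec <- sim_spec(n_samples = 5, loci_per_chromosome = 50,
                   missing_rate = 0.02)
  a <- simulate_panel(spec, seed = 41)
  b <- simulate_panel(spec, seed = 41)
  expect_identical(a$panel$codes, b$panel$codes)
  expect_identical(a$truth$freqs, b$truth$freqs)
  c <- simulate_panel(spec, seed = 42)
  expect_false(identical(a$panel$codes, c$panel$codes))
  # missing data injected at roughly the requested rate
  expect_gt(mean(a$panel$codes == 9L), 0)
})

test_that("realized allele frequencies track the drifted truth", {
  spec <- sim_spec(n_populations = 1, n_samples = 60, n_chromosomes = 1,
                   loci_per_chromosome = 200, n_founders = 200,
                   recomb_prob = 0.5)
  sim <- simulate_panel(spec, seed = 43)
  p_true <- sim$truth$freqs[, 1]
  codes <- sim$panel$codes
  p_obs <- colSums((codes == 1L) + 2L * (codes == 2L)) / (2 * nrow(codes))
  n_chrom_copies <- 2 * nrow(codes)
  # 1 indicates the variant allele; binomial sampling noise bound
  tol <- 3 * sqrt(p_true * (1 - p_true) / n_chrom_copies) + 3 / n_chrom_copies
  expect_gt(mean(abs(p_obs - unname(p_true)) <= tol + 0.06), 0.95)
})

test_that("planted truth coordinates match the simulation request exactly", {
  spec <- recovery_spec()
  sim <- simulate_panel(spec, seed = 44)
  tr <- sim$truth$planted
  expect_equal(tr$start_bp, 1200 * spec$spacing_bp)
  expect_equal(tr$end_bp, 1299 * spec$spacing_bp)
  expect_equal(tr$n_carriers, 30)
  # shared-haplotype carriers all hold the identical diplotype pattern
  reg_cols <- which(sim$panel$loci$position_bp >= tr$start_bp &
                      sim$panel$loci$position_bp <= tr$end_bp)
  carriers <- tr$carrier_ids[[1]]
  patt <- sim$panel$codes[carriers[1], reg_cols]
  for (cc in carriers)
    expect_equal(unname(sim$panel$codes[cc, reg_cols]), unname(patt))
  # the planted pattern is complex, not a run of homozygosity
  expect_gt(composition(patt)$het_percent, 10)
})

test_that("roh mode plants homozygous stretches", {
  spec <- sim_spec(n_populations = 1, n_samples = 10, n_chromosomes = 1,
                   loci_per_chromosome = 100,
                   planted_regions = data.frame(
                     population = "POP1", chromosome = 1,
                     start_locus = 40, end_locus = 60,
                     sharing_fraction = 1, mode = "roh"))
  sim <- simulate_panel(spec, seed = 45)
  reg <- sim$panel$codes[, 40:60]
  expect_true(all(reg %in% c(0L, 2L)))
})

test_that("infeasible planted regions are rejected", {
  expect_error(sim_spec(loci_per_chromosome = 100,
                        planted_regions = data.frame(
                          population = "POP1", chromosome = 1,
                          start_locus = 50, end_locus = 150,
                          sharing_fraction = 1,
                          mode = "shared_haplotype")))
})

test_that("Wright-Fisher drift fixes loci and is generation-monotone", {
  p <- rep(0.5, 200)
  expect_identical(drift_populations(p, 0, 100), p)
  hard <- drift_populations(p, 1000, 10, seed = 46)
  expect_gt(mean(hard %in% c(0, 1)), 0.8)  # most loci fixed
  # expected differentiation grows with drift time
  mean_fst <- function(gens) {
    mean(sapply(1:10, function(seed) {
      spec <- sim_spec(n_populations = 2, n_samples = 15,
                       n_chromosomes = 1, loci_per_chromosome = 150,
                       n_founders = 100, recomb_prob = 0.5,
                       drift_generations = gens)
      sim <- simulate_panel(spec, seed = seed)
      hudson_fst(sim$panel, "POP1", "POP2")$fst
    }))
  }
  expect_gt(mean_fst(60), mean_fst(5))
})

test_that("the LD-free limit is statistically equivalent to its own shuffle", {
  spec <- sim_spec(n_populations = 1, n_samples = 4, n_chromosomes = 1,
                   loci_per_chromosome = 3000, n_founders = 200,
                   recomb_prob = 0.5)
  sim <- simulate_panel(spec, seed = 47)
  for (s in sim$panel$samples$sample_id[1:2]) {
    res <- expected_ce(sim$panel, s, "rand1", replicates = 10, seed = 48)
    expect_lt(abs(res$real_ce - res$mean_ce), max(4 * res$sd_ce, 0.004))
  }
})

test_that("planted shared haplotypes dominate the window CEh distribution", {
  spec <- sim_spec(n_populations = 1, n_samples = 20, n_chromosomes = 1,
                   loci_per_chromosome = 600,
                   planted_regions = data.frame(
                     population = "POP1", chromosome = 1,
                     start_locus = 300, end_locus = 399,
                     sharing_fraction = 1, mode = "shared_haplotype"))
  sim <- simulate_panel(spec, seed = 49)
  w <- suppressMessages(window_scores(sim$panel, "POP1"))
  inside <- w$first_locus_index >= 300 & w$first_locus_index <= 350
  expect_gt(max(w$ceh[inside], na.rm = TRUE),
            stats::quantile(w$ceh[!inside], 0.99, na.rm = TRUE))
})
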