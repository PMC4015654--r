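test_that("window combinatorics follow the step-1 sliding rule", {
  p50 <- random_panel(3, 50, seed = 21)
  w50 <- window_scores(p50, "POP")
  expect_equal(nrow(w50), 1L)
  p52 <- random_panel(3, 52, seed = 22)
  w52 <- window_scores(p52, "POP")
  expect_equal(nrow(w52), 3L)
  expect_equal(w52$first_locus_index, 1:3)
  # chromosomes shorter than the window are skipped with a warning
  p_mixed <- random_panel(3, 60, seed = 23)
  p_mixed$loci$chromosome <- rep(c("1", "2"), c(55, 5))
  expect_warning(w <- window_scores(p_mixed, "POP"),
                 "chromosome 2.*skipped")
  expect_equal(nrow(w), 6L)
  expect_error(suppressWarnings(window_scores(random_panel(2, 10, seed = 1),
                                              "POP")),
               "no chromosome")
  expect_error(window_scores(p50, "GHOST"), "unknown population")
})

test_that("window CE, het and CEh agree with direct computation", {
  panel <- random_panel(4, 52, seed = 24)
  w <- window_scores(panel, "POP")
  direct <- compression_efficiency(
    serialize_matrix(panel, paste0("s", 1:4), 2:51))$ce
  expect_equal(w$ce[2], direct)
  sub <- panel$codes[, 2:51]
  expect_equal(w$het_percent[2], 100 * sum(sub == 1) / sum(sub != 9))
  expect_equal(w$ceh, 100 * w$ce / w$het_percent)
})

test_that("zero-heterozygosity windows get undefined CEh and are excluded", {
  codes <- rbind(rep(c(0L, 2L), 30), rep(c(2L, 0L), 30))
  codes[, 51:60] <- 1L  # only the tail carries heterozygotes
  panel <- toy_panel(codes, population = c("P", "P"))
  expect_message(w <- window_scores(panel, "P", window = 10L),
                 "zero heterozygosity")
  expect_true(anyNA(w$ceh))
  expect_true(all(is.na(w$ceh[w$het_percent == 0])))
})

test_that("z-normalization yields mean 0, sd 1 per stratum with sample sd", {
  w <- tibble::tibble(
    population = "P", chromosome = "1", first_locus_index = 1:3,
    window = 1L, ce = 0.5, het_percent = 30, ceh = c(1, 2, 3))
  z <- normalize_z(w)$z
  expect_equal(z, c(-1, 0, 1))  # sample (n-1) sd convention
  expect_error(normalize_z(dplyr::mutate(w, ceh = 2)), "zero CEh variance")
  expect_error(normalize_z(w[1, ]), "fewer than 2")
})

test_that("the X stratum is normalized separately from autosomes", {
  w <- tibble::tibble(
    population = "P",
    chromosome = rep(c("1", "X"), each = 4),
    first_locus_index = c(1:4, 1:4), window = 1L, ce = 0.5,
    het_percent = 30,
    ceh = c(1, 2, 3, 4, 11, 12, 13, 14))
  z1 <- normalize_z(w)$z
  # shifting every autosomal CEh leaves the X z untouched
  w2 <- w
  w2$ceh[w2$chromosome == "1"] <- w2$ceh[w2$chromosome == "1"] + 100
  z2 <- normalize_z(w2)$z
  expect_equal(z1[w$chromosome == "X"], z2[w$chromosome == "X"])
  expect_equal(z1[w$chromosome == "1"], z2[w$chromosome == "1"])
  for (s in c("1", "X")) {
    expect_equal(mean(z1[w$chromosome == s]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(z1[w$chromosome == s]), 1, tolerance = 1e-9)
  }
})

test_that("per-SNP CEhZ averages the covering windows", {
  loci <- tibble::tibble(snp_id = paste0("rs", 1:52), chromosome = "1",
                         position_bp = (1:52) * 1000L)
  w <- tibble::tibble(
    population = "P", chromosome = "1", first_locus_index = 1:3,
    window = 50L, ce = 0.5, het_percent = 30, ceh = c(1, 2, 3),
    z = c(1, 2, 3))
  s <- per_snp_cehz(w, loci)
  expect_equal(nrow(s), 52L)
  # enumeration of covering windows: SNP 1 -> {w1}, SNP 2 -> {w1, w2},
  # SNP 3..50 -> {w1,w2,w3}, SNP 51 -> {w2,w3}, SNP 52 -> {w3}
  expect_equal(s$cehz[1], 1)
  expect_equal(s$cehz[2], 1.5)
  expect_equal(s$cehz[3], 2)
  expect_equal(s$cehz[51], 2.5)
  expect_equal(s$cehz[52], 3)
  expect_equal(s$n_windows[1], 1L)
  expect_equal(s$n_windows[26], 3L)
  # constant z propagates unchanged
  w$z <- 0.7
  expect_equal(per_snp_cehz(w, loci)$cehz, rep(0.7, 52))
})

test_that("per-SNP CEhZ stays within the covering windows' z range", {
  panel <- random_panel(5, 120, seed = 25)
  w <- normalize_z(window_scores(panel, "POP", window = 20L))
  s <- per_snp_cehz(w, panel$loci)
  for (i in seq_len(nrow(s))) {
    covering <- w$z[w$first_locus_index <= i &
                      w$first_locus_index + 20L > i]
    expect_gte(s$cehz[i], min(covering) - 1e-12)
    expect_lte(s$cehz[i], max(covering) + 1e-12)
  }
  # interior SNPs are covered by exactly `window` windows
  expect_equal(s$n_windows[60], 20L)
})

test_that("peak clustering matches a brute-force single-link oracle", {
  mk_scores <- function(pos, cehz) {
    tibble::tibble(snp_id = paste0("rs", seq_along(pos)),
                   chromosome = "1", position_bp = pos,
                   population = "P", cehz = cehz,
                   n_windows = 1L)
  }
  # all below threshold -> no peaks
  expect_equal(nrow(call_peaks(mk_scores(c(1e4, 2e4), c(1, 2)))), 0L)
  # two passing SNPs 25 kb apart -> two regions
  two <- call_peaks(mk_scores(c(10000L, 35000L), c(5, 4)))
  expect_equal(nrow(two), 2L)
  # planted run of 60 passing SNPs spaced 1 kb + one 30 kb beyond -> 2
  pos <- c(seq(100000L, by = 1000L, length.out = 60),
           100000L + 59000L + 30000L)
  run <- call_peaks(mk_scores(pos, rep(5, 61)))
  expect_equal(nrow(run), 2L)
  big <- run[which.max(run$n_snps), ]
  expect_equal(big$n_snps, 60L)
  expect_equal(big$start_bp, 100000L - 1L)  # BED 0-based half-open
  expect_equal(big$end_bp, 159000L)
  # brute-force oracle on random inputs
  set.seed(77)
  for (rep in 1:5) {
    pos <- sort(sample.int(2e5, 40))
    cehz <- stats::runif(40, 0, 6)
    got <- call_peaks(mk_scores(pos, cehz))
    sel <- sort(pos[cehz >= 3])
    n_oracle <- if (length(sel) == 0) 0L else
      1L + sum(diff(sel) > 20000L)
    expect_equal(nrow(got), n_oracle)
    expect_equal(sum(got$n_snps), length(sel))
  }
})

test_that("mean3x thresholding uses the per-chromosome mean CEhZ", {
  s <- tibble::tibble(snp_id = paste0("rs", 1:4), chromosome = "1",
                      position_bp = c(1e5, 2e5, 3e5, 4e5),
                      population = "P",
                      cehz = c(1, 1, 1, 9), n_windows = 1L)
  # mean = 3, cutoff = 9 -> only the last SNP passes
  peaks <- call_peaks(s, threshold_mode = "mean3x")
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$snp_ids[[1]], "rs4")
})

test_that("BED export round-trips coordinates", {
  peaks <- tibble::tibble(
    population = "P", chromosome = c("2", "1"),
    start_bp = c(100L, 5000L), end_bp = c(200L, 9000L),
    n_snps = c(3L, 2L), max_cehz = c(4.2, 3.5), mean_cehz = c(3.8, 3.1),
    snp_ids = list(c("a", "b", "c"), c("d", "e")))
  path <- tempfile(fileext = ".bed")
  write_bed(peaks, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "^2\t100\t200\tP:1\t")
  back <- read.table(path, sep = "\t")
  expect_equal(back$V2, c(100L, 5000L))
  expect_equal(back$V3, c(200L, 9000L))
  # independent reader agrees on the half-open convention
  gr <- rtracklayer::import(path)
  expect_equal(BiocGenerics::start(gr), c(101L, 5001L))
  expect_equal(BiocGenerics::end(gr), c(200L, 9000L))
  # empty peak set -> empty file
  empty_path <- tempfile(fileext = ".bed")
  write_bed(peaks[0, ], empty_path)
  expect_equal(length(readLines(empty_path)), 0L)
})

test_that("the scan is deterministic: identical input gives identical BED", {
  sim <- simulate_panel(sim_spec(n_populations = 1, n_samples = 10,
                                 n_chromosomes = 1,
                                 loci_per_chromosome = 200), seed = 3)
  run <- function() {
    scan <- suppressMessages(ce_scan(sim$panel, threshold = 1.5))
    path <- tempfile(fileext = ".bed")
    write_bed(scan$peaks, path)
    readBin(path, "raw", file.size(path))
  }
  expect_identical(run(), run())
})

test_that("scan results expose tidy, glance and autoplot methods", {
  sim <- simulate_panel(sim_spec(n_populations = 2, n_samples = 8,
                                 n_chromosomes = 1,
                                 loci_per_chromosome = 120), seed = 5)
  scan <- suppressMessages(ce_scan(sim$panel, window = 30L))
  td <- generics::tidy(scan)
  expect_s3_class(td, "tbl_df")
  expect_equal(sort(unique(td$population)), c("POP1", "POP2"))
  gl <- generics::glance(scan)
  expect_equal(nrow(gl), 2L)
  expect_true(all(c("n_snps", "mean_cehz", "n_peaks") %in% names(gl)))
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})
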