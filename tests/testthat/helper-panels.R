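# Small panels and fixtures built in code.

toy_panel <- function(codes = rbind(c(0L, 1L, 2L, 9L),
                                    c(1L, 1L, 0L, 2L)),
                      chromosome = rep("1", ncol(codes)),
                      position_bp = seq_len(ncol(codes)) * 100L,
                      population = rep("POP", nrow(codes))) {
  genotype_panel(
    codes,
    loci = data.frame(snp_id = paste0("rs", seq_len(ncol(codes))),
                      chromosome = chromosome,
                      position_bp = position_bp),
    samples = data.frame(sample_id = paste0("s", seq_len(nrow(codes))),
                         population = population))
}

# panel with one chromosome of n identical-structure random loci
random_panel <- function(n_samples, n_loci, seed,
                         chromosome = "1", population = "POP") {
  set.seed(seed)
  codes <- matrix(sample(c(0L, 1L, 2L), n_samples * n_loci,
                         replace = TRUE), n_samples, n_loci)
  toy_panel(codes, chromosome = rep(chromosome, n_loci),
            population = rep(population, n_samples))
}

# a tiny 3-sample, 4-site VCF; returns the path
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##contig=<ID=2>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampleA", "sampleB", "sampleC", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1/0", "./.", "0/0", sep = "\t"),
    paste("2", "150", "rs3", "G", "A", ".", "PASS", ".", "GT",
          "1|1", "0|0", "0|1", sep = "\t"),
    paste("2", "300", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/0", sep = "\t")), path)
  path
}

# hand-encoded truth for the toy VCF (samples x loci, genome order)
toy_vcf_codes <- function() {
  rbind(sampleA = c(0L, 1L, 2L, 0L),
        sampleB = c(1L, 9L, 0L, 0L),
        sampleC = c(2L, 0L, 1L, 0L))
}

# study conditions of the planted-region recovery experiment
recovery_spec <- function() {
  sim_spec(n_populations = 1, n_samples = 30, n_chromosomes = 1,
           loci_per_chromosome = 2500,
           planted_regions = data.frame(
             population = "POP1", chromosome = 1,
             start_locus = 1200, end_locus = 1299,
             sharing_fraction = 1.0, mode = "shared_haplotype"))
}

# study conditions of the drift-divergence concordance experiment
divergence_sim <- function(seed) {
  spec <- sim_spec(n_populations = 4, n_samples = 20, n_chromosomes = 2,
                   loci_per_chromosome = 300,
                   drift_generations = c(5, 20, 60, 120))
  simulate_panel(spec, seed = seed)
}

# Hudson FST table for every population pair of a panel
fst_pairs <- function(panel) {
  pops <- unique(panel$samples$population)
  do.call(rbind, apply(utils::combn(pops, 2), 2, function(pr) {
    data.frame(pop_a = pr[1], pop_b = pr[2],
               fst = hudson_fst(panel, pr[1], pr[2])$fst)
  }))
}
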