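#' Window-level CE, heterozygosity and CEh for one population
#'
#' Slides overlapping windows of `window` consecutive SNPs (step 1, so
#' neighbouring windows share `window - 1` SNPs) along each chromosome;
#' windows never span chromosome boundaries and chromosomes shorter than
#' the window are skipped with a warning. For each window the CE of the
#' population row-matrix serialization (samples in rows, the window's SNPs
#' in columns) is paired with the window-wide percent heterozygosity over
#' all matrix cells (missing excluded), and the heterozygosity-corrected
#' statistic `CEh = CE% / %Het`. Windows with zero heterozygosity have
#' undefined CEh (`NA`) and are excluded downstream.
#'
#' @param panel A [genotype_panel()].
#' @param population Population label.
#' @param window Window size in SNPs (default 50).
#' @param profile A [ce_profile()].
#' @return Tibble, one row per window: `population`, `chromosome`,
#'   `first_locus_index` (global column index of the window's first SNP),
#'   `window`, `ce` (fraction), `het_percent`, `ceh`.
#' @export
window_scores <- function(panel, population, window = 50L,
                          profile = ce_profile()) {
  samples <- population_samples(panel, population)
  window <- as.integer(window)
  loci <- panel$loci
  chroms <- unique(loci$chromosome)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    idx <- which(loci$chromosome == chroms[k])
    if (length(idx) < window) {
      warning("chromosome ", chroms[k], " has ", length(idx),
              " < ", window, " loci; skipped", call. = FALSE)
      next
    }
    block <- panel$codes[samples, idx, drop = FALSE]
    n_win <- length(idx) - window + 1L
    ce <- numeric(n_win); het <- numeric(n_win)
    for (i in seq_len(n_win)) {
      sub <- block[, i:(i + window - 1L), drop = FALSE]
      payload <- serialize_rows(sub)
      sb <- length(payload)
      sa <- compressed_size(payload, profile)
      ce[i] <- (sb - sa) / sb
      n1 <- sum(sub == 1L)
      called <- sum(sub != 9L)
      het[i] <- if (called == 0) NA_real_ else 100 * n1 / called
    }
    out[[k]] <- tibble::tibble(
      population = population, chromosome = chroms[k],
      first_locus_index = idx[seq_len(n_win)], window = window,
      ce = ce, het_percent = het)
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0)
    stop("no chromosome with at least ", window, " loci", call. = FALSE)
  out$ceh <- ifelse(!is.na(out$het_percent) & out$het_percent > 0,
                    100 * out$ce / out$het_percent, NA_real_)
  n_undef <- sum(is.na(out$ceh))
  if (n_undef > 0)
    message(n_undef, " window(s) with zero heterozygosity excluded ",
            "from CEh")
  out
}

#' Standardize window CEh within normalization strata
#'
#' Within each stratum -- all autosomes pooled, the X chromosome on its
#' own (its systematically different homozygosity would otherwise shift
#' the genome-wide mean) -- CEh is centred on the stratum mean and scaled
#' by the stratum standard deviation (sample, `n - 1`, denominator).
#' Windows with undefined CEh carry no z-score.
#'
#' @param windows Output of [window_scores()].
#' @return `windows` with an added `z` column; per stratum the defined z
#'   have mean 0 and sd 1.
#' @export
normalize_z <- function(windows) {
  stratum <- ifelse(toupper(windows$chromosome) == "X", "X", "autosome")
  z <- rep(NA_real_, nrow(windows))
  for (s in unique(stratum)) {
    in_s <- stratum == s & !is.na(windows$ceh)
    vals <- windows$ceh[in_s]
    if (length(vals) < 2)
      stop("fewer than 2 windows with defined CEh in stratum ", s,
           call. = FALSE)
    sdv <- stats::sd(vals)
    if (sdv == 0)
      stop("zero CEh variance in stratum ", s, call. = FALSE)
    z[in_s] <- (vals - mean(vals)) / sdv
  }
  windows$z <- z
  windows
}

#' Per-SNP CEhZ scores
#'
#' Each SNP is assigned the arithmetic mean of the z-scores of all windows
#' covering it (for interior SNPs on a long chromosome that is `window`
#' windows; fewer near chromosome termini). Windows with undefined z do
#' not contribute and are not counted in `n_windows`.
#'
#' @param windows Output of [normalize_z()].
#' @param loci Locus map of the scanned panel (`panel$loci`).
#' @return Tibble, one row per covered SNP: `snp_id`, `chromosome`,
#'   `position_bp`, `population`, `cehz`, `n_windows`. SNPs covered only
#'   by undefined-z windows get `NA` CEhZ.
#' @export
per_snp_cehz <- function(windows, loci) {
  if (!"z" %in% names(windows))
    stop("windows must be normalized first (see normalize_z)",
         call. = FALSE)
  w <- windows$window[1]
  zsum <- numeric(nrow(loci))
  zcnt <- integer(nrow(loci))
  covered <- logical(nrow(loci))
  for (i in seq_len(nrow(windows))) {
    span <- windows$first_locus_index[i]:(windows$first_locus_index[i] + w - 1L)
    covered[span] <- TRUE
    if (!is.na(windows$z[i])) {
      zsum[span] <- zsum[span] + windows$z[i]
      zcnt[span] <- zcnt[span] + 1L
    }
  }
  keep <- which(covered)
  cehz <- ifelse(zcnt[keep] > 0, zsum[keep] / zcnt[keep], NA_real_)
  if (anyNA(cehz))
    message(sum(is.na(cehz)),
            " SNP(s) covered only by undefined-CEh windows")
  tibble::tibble(
    snp_id = loci$snp_id[keep],
    chromosome = loci$chromosome[keep],
    position_bp = loci$position_bp[keep],
    population = windows$population[1],
    cehz = cehz,
    n_windows = zcnt[keep])
}

#' Cluster high-CEhZ SNPs into peak regions
#'
#' SNPs passing the detection threshold are single-link clustered: a new
#' region starts whenever the gap to the previous passing SNP on the same
#' chromosome exceeds `cluster_gap_bp`. Two threshold readings are
#' provided: `"z3"` (default) selects SNPs with `CEhZ >= threshold`
#' standardized units; `"mean3x"` selects SNPs with
#' `CEhZ >= threshold * mean(CEhZ)` per chromosome (degenerate when the
#' post-normalization mean is near zero, hence not the default).
#'
#' @param snp_scores Output of [per_snp_cehz()].
#' @param threshold_mode `"z3"` or `"mean3x"`.
#' @param threshold Multiplier / cutoff (default 3).
#' @param cluster_gap_bp Maximum within-region gap in bp (default 20000).
#' @return Tibble of regions (possibly empty): `population`, `chromosome`,
#'   `start_bp`, `end_bp` (0-based half-open, BED convention), `n_snps`,
#'   `max_cehz`, `mean_cehz`, `snp_ids` (list column).
#' @export
call_peaks <- function(snp_scores, threshold_mode = c("z3", "mean3x"),
                       threshold = 3, cluster_gap_bp = 20000L) {
  threshold_mode <- match.arg(threshold_mode)
  empty <- tibble::tibble(
    population = character(), chromosome = character(),
    start_bp = integer(), end_bp = integer(), n_snps = integer(),
    max_cehz = numeric(), mean_cehz = numeric(), snp_ids = list())
  regions <- list()
  for (chrom in unique(snp_scores$chromosome)) {
    sc <- snp_scores[snp_scores$chromosome == chrom &
                       !is.na(snp_scores$cehz), , drop = FALSE]
    if (nrow(sc) == 0) next
    cutoff <- if (threshold_mode == "z3") threshold else
      threshold * mean(sc$cehz)
    sel <- sc[sc$cehz >= cutoff, , drop = FALSE]
    if (nrow(sel) == 0) next
    sel <- sel[order(sel$position_bp), , drop = FALSE]
    gap <- c(Inf, diff(sel$position_bp))
    cluster <- cumsum(gap > cluster_gap_bp)
    for (cl in unique(cluster)) {
      part <- sel[cluster == cl, , drop = FALSE]
      regions[[length(regions) + 1L]] <- tibble::tibble(
        population = part$population[1], chromosome = chrom,
        start_bp = min(part$position_bp) - 1L,
        end_bp = max(part$position_bp),
        n_snps = nrow(part),
        max_cehz = max(part$cehz),
        mean_cehz = mean(part$cehz),
        snp_ids = list(part$snp_id))
    }
  }
  if (length(regions) == 0) return(empty)
  out <- dplyr::bind_rows(regions)
  out[order(-out$max_cehz), ]
}

#' Write peak regions as a BED file
#'
#' Standard 6-column BED: chrom, chromStart, chromEnd (0-based half-open),
#' name (`population:rank` by descending max CEhZ), score
#' (`round(100 * mean_cehz)` clamped to 0-1000), strand (`.`).
#'
#' @param peaks Output of [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    file.create(path)
    return(invisible(path))
  }
  peaks <- peaks[order(-peaks$max_cehz), ]
  bed <- data.frame(
    chrom = peaks$chromosome,
    start = peaks$start_bp,
    end = peaks$end_bp,
    name = paste0(peaks$population, ":", seq_len(nrow(peaks))),
    score = pmin(1000, pmax(0, round(100 * peaks$mean_cehz))),
    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Population-level CEhZ scan
#'
#' The full high-resolution pipeline for one or more populations:
#' window-level CE and CEh ([window_scores()]), genome-wide z-score
#' normalization with a separate X stratum ([normalize_z()]), per-SNP
#' CEhZ averaging ([per_snp_cehz()]) and peak clustering ([call_peaks()]).
#'
#' @param panel A [genotype_panel()].
#' @param populations Populations to scan (default: all in the panel).
#' @param window Window size in SNPs (default 50).
#' @param profile A [ce_profile()].
#' @param threshold_mode,threshold,cluster_gap_bp See [call_peaks()].
#' @return A `ce_scan` object: list with tibbles `windows`, `snp_scores`,
#'   `peaks` and a `params` list. [tidy()] returns the per-SNP scores,
#'   [glance()] a per-population summary, [autoplot()] a CEhZ track plot.
#' @export
ce_scan <- function(panel, populations = NULL, window = 50L,
                    profile = ce_profile(),
                    threshold_mode = c("z3", "mean3x"), threshold = 3,
                    cluster_gap_bp = 20000L) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(populations))
    populations <- unique(panel$samples$population)
  windows <- list(); snp_scores <- list(); peaks <- list()
  for (pop in populations) {
    w <- normalize_z(window_scores(panel, pop, window, profile))
    s <- per_snp_cehz(w, panel$loci)
    p <- call_peaks(s, threshold_mode, threshold, cluster_gap_bp)
    windows[[pop]] <- w; snp_scores[[pop]] <- s; peaks[[pop]] <- p
  }
  structure(list(
    windows = dplyr::bind_rows(windows),
    snp_scores = dplyr::bind_rows(snp_scores),
    peaks = dplyr::bind_rows(peaks),
    params = list(window = as.integer(window), profile = profile,
                  threshold_mode = threshold_mode, threshold = threshold,
                  cluster_gap_bp = as.integer(cluster_gap_bp))),
    class = "ce_scan")
}

#' @export
print.ce_scan <- function(x, ...) {
  cat("<ce_scan> ", length(unique(x$snp_scores$population)),
      " population(s), ", nrow(x$windows), " windows of ",
      x$params$window, " SNPs, ", nrow(x$peaks), " peak region(s)\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ce_scan <- function(x, ...) x$snp_scores

#' @exportS3Method generics::glance
glance.ce_scan <- function(x, ...) {
  x$snp_scores |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      mean_cehz = mean(.data$cehz, na.rm = TRUE),
      max_cehz = max(.data$cehz, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::left_join(
      x$peaks |>
        dplyr::group_by(.data$population) |>
        dplyr::summarise(n_peaks = dplyr::n(), .groups = "drop"),
      by = "population") |>
    dplyr::mutate(n_peaks = dplyr::coalesce(.data$n_peaks, 0L))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ce_scan <- function(object, ...) {
  ggplot2::ggplot(object$snp_scores,
                  ggplot2::aes(x = .data$position_bp / 1e6,
                               y = .data$cehz)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$params$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(population ~ chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "CEhZ") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write the per-SNP CEhZ track as TSV
#'
#' Columns: chromosome, position_bp, snp_id, population, cehz, n_windows
#' -- suitable for bedGraph conversion.
#'
#' @param scan A [ce_scan()] object (or a per-SNP score tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_track <- function(scan, path) {
  scores <- if (inherits(scan, "ce_scan")) scan$snp_scores else scan
  readr::write_tsv(
    scores[, c("chromosome", "position_bp", "snp_id", "population",
               "cehz", "n_windows")],
    path, progress = FALSE)
  invisible(path)
}
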