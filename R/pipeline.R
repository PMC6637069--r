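#' Simulate haplotype fixtures to disk
#'
#' Writes a seeded synthetic haplotype table (binary alleles on clustered
#' SNP positions) and, optionally, a simulated fragment matrix derived
#' from a pair of complementary haplotypes.
#'
#' @param kind Sequence generator: `"logistic"`, `"tent"`, `"henon"`,
#'   `"bernoulli"` or `"markov"`.
#' @param n Number of SNPs (ignored when `n_clusters` is given; then the
#'   clustered position generator fixes the count).
#' @param seed Integer seed (echoed in the run log).
#' @param out_dir Output directory (created if needed).
#' @param p Bernoulli success probability (`kind = "bernoulli"`).
#' @param p_stay Markov stay probability (`kind = "markov"`).
#' @param n_clusters,cluster_sizes,within_gap,between_gap Passed to
#'   [gen_snp_positions()] to build clustered positions; by default one
#'   cluster spaced 100 bp apart.
#' @param fragments If `TRUE` also write `fragments.txt`, a simulated
#'   fragment matrix over the haplotype and its complement.
#' @param read_len,err_rate,target_coverage Fragment-simulation settings.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(kind = c("logistic", "tent", "henon", "bernoulli",
                                  "markov"),
                         n = 2000L, seed = 1L, out_dir = ".", p = 0.5,
                         p_stay = 0.9, n_clusters = NULL,
                         cluster_sizes = NULL, within_gap = c(50L, 500L),
                         between_gap = c(30000L, 60000L), fragments = FALSE,
                         read_len = 10L, err_rate = 0,
                         target_coverage = 5) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(n_clusters)) {
    if (is.null(cluster_sizes)) cluster_sizes <- c(900L, 1200L)
    pos <- gen_snp_positions(n_clusters, cluster_sizes, within_gap,
                             between_gap, seed = seed)
    n <- length(pos)
  } else {
    pos <- seq(1000L, by = 100L, length.out = n)
  }
  seq_seed <- (as.integer(seed) + 104729L) %% .Machine$integer.max
  h <- switch(kind,
    bernoulli = gen_random_binary(p, n, seed = seq_seed),
    markov = gen_markov_binary(n, p_stay = p_stay, seed = seq_seed),
    gen_chaotic_binary(kind, n, seed = seq_seed))
  h <- allele_seq(parse_alleles(h), positions = pos, chrom = "chrS")
  paths <- list(haplotype = file.path(out_dir, "haplotype.tsv"))
  write_haplotype_table(h, paths$haplotype)
  if (fragments) {
    h2 <- allele_seq(1L - parse_alleles(h), positions = pos, chrom = "chrS")
    fm <- gen_fragment_matrix(h, h2, read_len = read_len,
                              err_rate = err_rate,
                              target_coverage = target_coverage,
                              seed = (as.integer(seed) + 15485863L) %%
                                .Machine$integer.max)
    paths$fragments <- file.path(out_dir, "fragments.txt")
    write_fragment_matrix(fm, paths$fragments)
  }
  write_run_config(file.path(out_dir, "simulate_config.txt"),
                   list(subcommand = "simulate", kind = kind, n = n,
                        seed = seed, p = p, p_stay = p_stay,
                        fragments = fragments))
  message("run_simulate: seed = ", seed, "; wrote ",
          paste(unlist(paths), collapse = ", "))
  invisible(paths)
}

#' Chaos analysis workflow over a haplotype table
#'
#' Reads a haplotype table, extracts dense SNP subsequences (distance
#' threshold `r`, minimum length `thr`), and runs the surrogate test on
#' the correlation dimension plus the Eckmann Lyapunov estimate on each
#' kept subsequence; optionally also the multifractal spectrum of each
#' subsequence's CGR point set. Reports are written as TSV.
#'
#' @param input Path to a haplotype TSV (see [read_haplotype_table()]).
#' @param out_dir Output directory.
#' @param r Distance threshold in bp (default 30000).
#' @param thr Minimum subsequence length (strict, default 800).
#' @param n_surrogates Surrogates per subsequence (default 10).
#' @param mfa Also write per-subsequence multifractal spectra.
#' @param seed Integer seed (surrogate phases).
#' @return Invisibly, a list with the subsequence `summary`, the chaos
#'   `report` data frame, and the written paths.
#' @export
run_analyze <- function(input, out_dir = ".", r = 30000, thr = 800,
                        n_surrogates = 10L, mfa = FALSE, seed = 1L) {
  h <- read_haplotype_table(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subs_all <- split_by_distance(h, r = r)
  subs <- filter_min_length(subs_all, thr = thr)
  summary <- data.frame(chrom = if (length(h)) chrom(h) else NA_character_,
                        n_subsequences = attr(subs, "n_total") %||% 0L,
                        n_above_thr = attr(subs, "n_kept") %||% 0L)
  report <- chaos_report(subs, n_surrogates = n_surrogates, seed = seed)
  paths <- list(summary = file.path(out_dir, "subsequence_summary.tsv"),
                report = file.path(out_dir, "chaos_report.tsv"))
  utils::write.table(summary, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report, paths$report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (mfa && length(subs) > 0L) {
    for (i in seq_along(subs)) {
      pts <- cgr_encode_binary(subs[[i]]$seq)$values
      sp <- multifractal_spectrum(pts)
      write_mf_spectrum(sp, file.path(out_dir, sprintf("mfa_S%d.tsv", i)))
    }
  }
  pct <- if (nrow(report)) 100 * mean(report$is_chaotic) else NA_real_
  write_run_config(file.path(out_dir, "analyze_config.txt"),
                   list(subcommand = "analyze", input = input, r = r,
                        thr = thr, n_surrogates = n_surrogates, mfa = mfa,
                        seed = seed, pct_chaotic = pct))
  message(sprintf("run_analyze: %d/%d subsequences kept; %s chaotic",
                  summary$n_above_thr, summary$n_subsequences,
                  if (is.na(pct)) "NA%" else sprintf("%.1f%%", pct)))
  invisible(list(summary = summary, report = report, pct_chaotic = pct,
                 paths = paths))
}

#' Gap-filling workflow over a haplotype table
#'
#' Reads a haplotype table, optionally corrupts a gap-free input with a
#' given gap fraction (for evaluation against the known truth), fills all
#' gaps by the chaos-game/local-projection method, and writes the filled
#' table plus a metrics report. When positions are present, the haplotype
#' is processed independently per dense subsequence (distance threshold
#' `r`), mirroring the analysis workflow.
#'
#' @param input Path to a haplotype TSV (gaps allowed as `-`).
#' @param out_dir Output directory.
#' @param corrupt_fraction If non-`NULL`, the input must be gap-free and
#'   this fraction of sites is blanked before filling; rates against the
#'   original are reported.
#' @param config A [gap_fill_config].
#' @param r,thr Subsequence extraction settings (see [run_analyze()]).
#' @param seed Integer seed (corruption positions).
#' @return Invisibly, a list with the `filled` sequence, `metrics` data
#'   frame and written paths.
#' @export
run_gapfill <- function(input, out_dir = ".", corrupt_fraction = NULL,
                        config = gap_fill_config(), r = 30000, thr = 800,
                        seed = 1L) {
  h <- read_haplotype_table(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(corrupt_fraction)) {
    if (has_gaps(h))
      stop("input already contains gaps; corruption requires gap-free input",
           call. = FALSE)
    truth <- h
    cr <- corrupt_with_gaps(h, corrupt_fraction, seed = seed)
    h <- cr$seq
  }
  subs <- if (!is.null(positions(h))) split_by_distance(h, r = r) else
    list(structure(list(start = 1L, end = length(h), seq = h),
                   class = "subsequence"))
  filled_all <- parse_alleles(h)
  metrics <- list()
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    res <- fill_gaps(s$seq, config)
    filled_all[s$start:s$end] <- parse_alleles(res$filled)
    row <- data.frame(id = paste0("S", i), start = s$start, end = s$end,
                      length = length(s$seq), n_gaps = length(res$mask),
                      rate_gaps = NA_real_, rate_overall = NA_real_)
    if (!is.null(truth)) {
      rr <- reconstruction_rate(truth[s$start:s$end], res$filled, res$mask)
      row$rate_gaps <- rr$rate_gaps
      row$rate_overall <- rr$rate_overall
    }
    metrics[[i]] <- row
  }
  metrics <- do.call(rbind, metrics)
  filled <- allele_seq(filled_all, positions = positions(h), chrom = chrom(h))
  paths <- list(filled = file.path(out_dir, "filled_haplotype.tsv"),
                metrics = file.path(out_dir, "gapfill_metrics.tsv"))
  write_haplotype_table(filled, paths$filled)
  utils::write.table(metrics, paths$metrics, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  agg <- if (!is.null(truth) && nrow(metrics)) {
    reconstruction_rate(truth, filled, which(is.na(parse_alleles(h))))
  } else NULL
  write_run_config(file.path(out_dir, "gapfill_config.txt"),
                   list(subcommand = "gapfill", input = input,
                        corrupt_fraction = corrupt_fraction %||% "none",
                        lp_half_window = config$lp_half_window,
                        manifold_rank = config$manifold_rank,
                        n_iterations = config$n_iterations,
                        threshold = config$threshold, r = r, thr = thr,
                        seed = seed,
                        rate_gaps = if (is.null(agg)) "NA" else agg$rate_gaps,
                        rate_overall = if (is.null(agg)) "NA" else agg$rate_overall))
  if (!is.null(agg))
    message(sprintf("run_gapfill: rate_gaps = %.4f, rate_overall = %.4f",
                    agg$rate_gaps, agg$rate_overall))
  invisible(list(filled = filled, metrics = metrics, aggregate = agg,
                 paths = paths))
}

# resolved-configuration snapshot, one key: value per line
write_run_config <- function(path, config) {
  lines <- vapply(names(config), function(k)
    paste0(k, ": ", paste(format(config[[k]]), collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
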