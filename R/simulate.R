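#' Draw ground-truth fitness and RNA effects for a variant library
#'
#' Assigns each programmed variant a true depletion slope (log2
#' fold-change per day), a true RNA-abundance effect (log2) and an
#' initial plasmid-library frequency. Defaults emulate an essential-gene
#' SGE screen: truncating and canonical-splice variants deplete at about
#' -0.2 log2/day, synonymous/intronic variants sit near 0, and a minority
#' of missense and splice-region variants are loss-of-function. Initial
#' frequencies are symmetric-Dirichlet to mimic uneven oligo synthesis.
#'
#' @param variants An [enumerate_variants()] table.
#' @param seed Integer seed.
#' @param lof_slope,lof_sd Mean and SD of the loss-of-function slope.
#' @param neutral_sd SD of neutral slopes (mean 0).
#' @param lof_rate Named numeric: probability that a variant of each
#'   consequence is loss-of-function (consequences not named are neutral).
#' @param nmd_rna_mean,nmd_rna_sd RNA effect for transcript-depleting
#'   variants (stop_gained, canonical_splice, and LoF synonymous/intronic
#'   variants, which model cryptic splice disruption).
#' @param rna_noise_sd RNA effect SD for all other variants (mean 0).
#' @param concentration Symmetric-Dirichlet concentration for the initial
#'   library frequencies.
#' @param wt_fraction Fraction of each library left as unedited wild-type
#'   reads; initial variant frequencies sum to `1 - wt_fraction`.
#' @return Data frame of class `sge_truth`: `variant_id`, `true_slope`,
#'   `true_rna_effect`, `initial_freq`, plus the variant annotation columns.
#' @export
simulate_truth <- function(variants, seed = 1L,
                           lof_slope = -0.2, lof_sd = 0.03,
                           neutral_sd = 0.015,
                           lof_rate = c(stop_gained = 1, canonical_splice = 0.94,
                                        stop_lost = 1, missense = 0.13,
                                        splice_region = 0.13,
                                        inframe_deletion = 0.15,
                                        synonymous = 0.005, intron = 0.01,
                                        start_lost = 0),
                           nmd_rna_mean = -2.24, nmd_rna_sd = 0.8,
                           rna_noise_sd = 0.15,
                           concentration = 50, wt_fraction = 0.05) {
  n <- nrow(variants)
  with_seed(seed, {
    p_lof <- lof_rate[variants$consequence]
    p_lof[is.na(p_lof)] <- 0
    is_lof <- stats::runif(n) < p_lof
    slope <- ifelse(is_lof,
                    stats::rnorm(n, lof_slope, lof_sd),
                    stats::rnorm(n, 0, neutral_sd))
    slope <- pmin(slope, 0.05)  # depletion screen: strong positive fitness unrealistic

    nmd <- variants$consequence %in% c("stop_gained", "canonical_splice") |
      (is_lof & variants$consequence %in% c("synonymous", "intron"))
    rna <- ifelse(nmd,
                  stats::rnorm(n, nmd_rna_mean, nmd_rna_sd),
                  stats::rnorm(n, 0, rna_noise_sd))

    f0 <- stats::rgamma(n, shape = concentration, rate = 1)
    f0 <- f0 / sum(f0) * (1 - wt_fraction)

    out <- cbind(variants,
                 data.frame(true_slope = slope, true_lof = is_lof,
                            true_rna_effect = rna, initial_freq = f0))
    class(out) <- c("sge_truth", "data.frame")
    out
  })
}

#' Gaussian cut-site position effect
#'
#' Smooth positional bias added to every variant's apparent slope:
#' a Gaussian dip centred at the cut site, emulating reduced recovery of
#' edits near the break. Returns a function of target-local position.
#'
#' @param cut_site Target-local cut-site position.
#' @param amplitude Peak effect in log2/day at the cut site (negative =
#'   apparent extra depletion).
#' @param width Gaussian SD in nt.
#' @return `function(pos)` giving the positional effect.
#' @export
position_effect_gaussian <- function(cut_site, amplitude = -0.04, width = 15) {
  force(cut_site); force(amplitude); force(width)
  function(pos) amplitude * exp(-((pos - cut_site)^2) / (2 * width^2))
}

#' Simulate count tables for an SGE study
#'
#' Generates per-variant integer counts for the plasmid library (day 0),
#' day-5 and day-13 genomic-DNA replicates, day-5 RNA replicates, and a
#' negative-control library. The expected frequency of variant `v` at day
#' `t` is proportional to `f0_v * 2^((s_v + g(pos_v)) * t)` renormalised
#' over the library (wild-type reads carry slope 0); counts are drawn
#' multinomially (or Dirichlet-multinomially when `dispersion > 0`), so
#' every library's counts sum exactly to its depth.
#'
#' RNA expectations apply each variant's RNA effect to its day-5 DNA
#' frequency restricted to the target's RNA window. The negative control
#' is dominated by wild-type reads with a small valid-read contamination.
#'
#' @param target An `sge_target`.
#' @param truth An [simulate_truth()] table.
#' @param design List with `replicates` (default 3), `timepoints`
#'   (days; must include 0; default `c(0, 5, 13)`), `depth` (reads per
#'   DNA replicate library, default 2e5), `library_depth` (plasmid
#'   library; defaults to `depth` — real designs sequence it deeper),
#'   `rna_depth`, `nc_depth`.
#' @param position_effect Function of target-local position giving the
#'   positional slope bias `g(pos)`; `NULL` for none. Default
#'   [position_effect_gaussian()] at the target's cut site.
#' @param dispersion Dirichlet-multinomial overdispersion (0 = multinomial).
#' @param nc_valid_fraction Expected valid-read fraction of the negative
#'   control library.
#' @param seed Integer seed (each library draws from a derived sub-seed).
#' @return An `sge_counts` object: list with `counts` (long data frame:
#'   `variant_id`, `sample_type`, `replicate`, `count`), `libraries`
#'   (per-library totals: `total_reads_received`, `total_valid_reads`,
#'   `wildtype_reads`), `target_id`.
#' @export
simulate_counts <- function(target, truth,
                            design = list(), position_effect = NULL,
                            dispersion = 0, nc_valid_fraction = 0.002,
                            seed = 1L) {
  stopifnot(inherits(target, "sge_target"))
  replicates <- design$replicates %||% 3L
  timepoints <- design$timepoints %||% c(0, 5, 13)
  depth <- design$depth %||% 2e5
  library_depth <- design$library_depth %||% depth
  rna_depth <- design$rna_depth %||% depth
  nc_depth <- design$nc_depth %||% depth
  if (!0 %in% timepoints) stop("timepoints must include 0 (plasmid library)")
  if (depth <= 0 || library_depth <= 0 || rna_depth <= 0 || nc_depth <= 0) {
    stop("depth must be positive")
  }
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (is.null(position_effect)) {
    position_effect <- position_effect_gaussian(target$cut_site)
  }

  f0 <- truth$initial_freq
  wt0 <- 1 - sum(f0)
  if (wt0 < -1e-8) stop("initial frequencies sum to more than 1")
  wt0 <- max(wt0, 0)
  g <- position_effect(truth$pos)
  slope_eff <- truth$true_slope + g

  freq_at <- function(t) {
    p <- f0 * 2^(slope_eff * t)
    tot <- sum(p) + wt0
    list(var = p / tot, wt = wt0 / tot)
  }

  libs <- list(list(sample_type = "library", replicate = 1L, day = 0,
                    depth = library_depth))
  for (t in setdiff(timepoints, 0)) {
    st <- sprintf("day%d_dna", t)
    for (r in seq_len(replicates)) {
      libs[[length(libs) + 1L]] <- list(sample_type = st, replicate = r,
                                        day = t, depth = depth)
    }
  }
  for (r in seq_len(replicates)) {
    libs[[length(libs) + 1L]] <- list(sample_type = "day5_rna", replicate = r,
                                      day = 5, depth = rna_depth)
  }
  libs[[length(libs) + 1L]] <- list(sample_type = "negative_control",
                                    replicate = 1L, day = NA, depth = nc_depth)

  seeds <- derive_seeds(seed, length(libs))
  in_rna <- truth$pos >= target$rna_window[1] & truth$pos <= target$rna_window[2]

  counts <- vector("list", length(libs))
  lib_rows <- vector("list", length(libs))
  for (i in seq_along(libs)) {
    L <- libs[[i]]
    if (L$sample_type == "negative_control") {
      fr <- freq_at(0)
      p <- c(fr$var * nc_valid_fraction, 0)
      p[length(p)] <- 1 - sum(p[-length(p)])
    } else if (L$sample_type == "day5_rna") {
      fr <- freq_at(5)
      p_var <- ifelse(in_rna, fr$var * 2^truth$true_rna_effect, 0)
      tot <- sum(p_var) + fr$wt
      p <- c(p_var / tot, fr$wt / tot)
    } else {
      fr <- freq_at(L$day)
      p <- c(fr$var, fr$wt)
    }
    cnt <- with_seed(seeds[i], draw_library(L$depth, p, dispersion))
    nvar <- length(p) - 1L
    counts[[i]] <- data.frame(
      variant_id = truth$variant_id,
      sample_type = L$sample_type, replicate = L$replicate,
      count = cnt[seq_len(nvar)], stringsAsFactors = FALSE)
    lib_rows[[i]] <- data.frame(
      sample_type = L$sample_type, replicate = L$replicate,
      day = L$day,
      total_reads_received = as.integer(L$depth),
      total_valid_reads = sum(cnt[seq_len(nvar)]),
      wildtype_reads = cnt[length(cnt)], stringsAsFactors = FALSE)
  }

  new_sge_counts(do.call(rbind, counts), do.call(rbind, lib_rows),
                 target$target_id)
}

draw_library <- function(depth, p, dispersion) {
  if (dispersion > 0) {
    alpha <- p / dispersion
    gam <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    gam[alpha == 0] <- 0
    p <- gam / sum(gam)
  }
  as.integer(stats::rmultinom(1, size = depth, prob = p)[, 1])
}

new_sge_counts <- function(counts, libraries, target_id) {
  rownames(counts) <- NULL
  rownames(libraries) <- NULL
  structure(list(counts = counts, libraries = libraries,
                 target_id = target_id),
            class = "sge_counts")
}

#' @export
print.sge_counts <- function(x, ...) {
  cat(sprintf("<sge_counts> target %s: %d variants x %d libraries\n",
              x$target_id, length(unique(x$counts$variant_id)),
              nrow(x$libraries)))
  print(x$libraries)
  invisible(x)
}

#' Emit simulated merged reads for one or more libraries
#'
#' Turns each count into one read of the variant-modified edited
#' reference sequence, adds the library's wild-type (unedited) reads,
#' then injects i.i.d. substitution errors and homopolymer length
#' slippage (a run of >= 4 identical bases gains or loses 1-2 bases).
#'
#' @param target An `sge_target`.
#' @param counts An `sge_counts` object.
#' @param variants The [enumerate_variants()] table used to build `counts`.
#' @param error_rate Per-base substitution error probability.
#' @param homopolymer_slip_rate Per-run slip probability per read.
#' @param libraries Optional data frame (`sample_type`, `replicate`) to
#'   restrict which libraries are emitted; default all.
#' @param seed Integer seed.
#' @param shuffle Shuffle read order within each library (default TRUE).
#' @return Named list of character vectors of reads, one per library,
#'   names like `"library_1"`, `"day5_dna_2"`.
#' @export
emit_reads <- function(target, counts, variants, error_rate = 0,
                       homopolymer_slip_rate = 0, libraries = NULL,
                       seed = 1L, shuffle = TRUE) {
  if (error_rate < 0 || error_rate > 1 ||
      homopolymer_slip_rate < 0 || homopolymer_slip_rate > 1) {
    stop("error rates must lie in [0, 1]")
  }
  seqs <- vapply(seq_len(nrow(variants)), function(i) {
    variant_sequence(target, variants[i, ])
  }, character(1))
  names(seqs) <- variants$variant_id

  lib_df <- counts$libraries
  if (!is.null(libraries)) {
    keep <- interaction(lib_df$sample_type, lib_df$replicate) %in%
      interaction(libraries$sample_type, libraries$replicate)
    lib_df <- lib_df[keep, , drop = FALSE]
  }
  seeds <- derive_seeds(seed, nrow(lib_df))
  out <- vector("list", nrow(lib_df))
  for (i in seq_len(nrow(lib_df))) {
    st <- lib_df$sample_type[i]; rp <- lib_df$replicate[i]
    cc <- counts$counts[counts$counts$sample_type == st &
                          counts$counts$replicate == rp, ]
    reads <- rep(seqs[cc$variant_id], cc$count)
    reads <- c(reads, rep(target$ref_seq, lib_df$wildtype_reads[i]))
    reads <- unname(reads)
    out[[i]] <- with_seed(seeds[i], {
      if (shuffle) reads <- sample(reads)
      reads <- inject_errors(reads, error_rate)
      inject_slippage(reads, homopolymer_slip_rate)
    })
  }
  names(out) <- paste(lib_df$sample_type, lib_df$replicate, sep = "_")
  out
}

inject_errors <- function(reads, rate) {
  if (rate == 0 || length(reads) == 0) return(reads)
  lens <- nchar(reads)
  hit <- which(stats::runif(length(reads)) < 1 - (1 - rate)^lens)
  for (i in hit) {
    n_err <- max(1L, stats::rbinom(1, lens[i], rate))
    pos <- sample.int(lens[i], min(n_err, lens[i]))
    for (p in pos) {
      substring(reads[i], p, p) <-
        sample(setdiff(DNA_BASES, str_at(reads[i], p)), 1)
    }
  }
  reads
}

inject_slippage <- function(reads, rate) {
  if (rate == 0 || length(reads) == 0) return(reads)
  for (i in seq_along(reads)) {
    runs <- find_homopolymer_runs(reads[i])
    if (nrow(runs) == 0) next
    slip <- which(stats::runif(nrow(runs)) < rate)
    # apply right-to-left so earlier run coordinates stay valid
    for (j in rev(slip)) {
      delta <- sample(c(-2L, -1L, 1L, 2L), 1)
      s <- runs$start[j]; L <- runs$length[j]
      newlen <- max(1L, L + delta)
      reads[i] <- paste0(substring(reads[i], 1L, s - 1L),
                         strrep(runs$base[j], newlen),
                         substring(reads[i], s + L, nchar(reads[i])))
    }
  }
  reads
}

#' Write reads to a FASTQ file
#'
#' Phred-33 FASTQ with a fixed quality character. Gzip output is chosen
#' by a `.gz` suffix.
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param quality Single quality character applied to every base.
#' @param prefix Read-name prefix.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I", prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s%06d", prefix, seq_along(reads))
  qual <- Biostrings::BStringSet(strrep(quality, nchar(reads)))
  xq <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(
    xq, filepath = path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ path (gzip allowed).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

#' Simulate a labelled truth set for assay calibration
#'
#' Draws functional-class calls for known pathogenic and benign variants:
#' each pathogenic variant is called functionally abnormal with
#' probability `p_abnormal_given_path`, each benign one with
#' `p_abnormal_given_benign`. Used to exercise OddsPath calibration with
#' known operating characteristics.
#'
#' @param n_path,n_benign Truth-set sizes (> 0).
#' @param p_abnormal_given_path,p_abnormal_given_benign Per-class
#'   probabilities of an abnormal assay call, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame: `variant_id`, `clinical_label`
#'   (`"pathogenic"`/`"benign"`), `functional_class`
#'   (`"functionally_abnormal"`/`"functionally_normal"`).
#' @export
simulate_truth_labels <- function(n_path, n_benign,
                                  p_abnormal_given_path,
                                  p_abnormal_given_benign, seed = 1L) {
  if (n_path <= 0 || n_benign <= 0) stop("truth-set sizes must be positive")
  stopifnot(p_abnormal_given_path >= 0, p_abnormal_given_path <= 1,
            p_abnormal_given_benign >= 0, p_abnormal_given_benign <= 1)
  with_seed(seed, {
    ab <- c(stats::runif(n_path) < p_abnormal_given_path,
            stats::runif(n_benign) < p_abnormal_given_benign)
    data.frame(
      variant_id = sprintf("truth%04d", seq_len(n_path + n_benign)),
      clinical_label = rep(c("pathogenic", "benign"), c(n_path, n_benign)),
      functional_class = ifelse(ab, "functionally_abnormal",
                                "functionally_normal"),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a case-control carrier contingency table
#'
#' Case carrier probability solves
#' `p_case / (1 - p_case) = OR * p_ctl / (1 - p_ctl)`; carrier counts are
#' binomial draws.
#'
#' @param n_case,n_control Cohort sizes.
#' @param carrier_freq_control Control carrier frequency in (0, 1).
#' @param odds_ratio True odds ratio (> 0).
#' @param seed Integer seed.
#' @return List of class `sge_contingency`: `a` (case carriers), `b`
#'   (case non-carriers), `c` (control carriers), `d` (control
#'   non-carriers).
#' @export
simulate_cohort <- function(n_case, n_control, carrier_freq_control,
                            odds_ratio, seed = 1L) {
  if (odds_ratio <= 0) stop("odds_ratio must be positive")
  if (carrier_freq_control <= 0 || carrier_freq_control >= 1) {
    stop("carrier_freq_control must lie in (0, 1)")
  }
  odds_ctl <- carrier_freq_control / (1 - carrier_freq_control)
  p_case <- odds_ratio * odds_ctl / (1 + odds_ratio * odds_ctl)
  with_seed(seed, {
    a <- stats::rbinom(1, n_case, p_case)
    c_ <- stats::rbinom(1, n_control, carrier_freq_control)
    structure(list(a = a, b = n_case - a, c = c_, d = n_control - c_),
              class = "sge_contingency")
  })
}
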