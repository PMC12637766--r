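#' Default quality-control thresholds
#'
#' One place for every QC gate; each is overridable per call. The
#' defaults are the screen's gates: the plasmid library needs at least
#' 500,000 merged reads, at least 30% of them valid and no more than 10%
#' wild-type; the negative control may contain no more than 1% valid
#' reads; each day-5/day-13 replicate needs at least 150,000 valid reads;
#' each timepoint needs at least two valid replicates; and the minimum
#' pairwise Pearson correlation between replicate frequency vectors must
#' be at least 0.5. All thresholds are inclusive on the passing side.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(min_library_reads = 500000,
       min_library_valid_fraction = 0.30,
       max_library_wildtype_fraction = 0.10,
       max_negative_control_valid_fraction = 0.01,
       min_replicate_valid_reads = 150000,
       min_valid_replicates = 2L,
       min_pairwise_r = 0.5)
}

#' Run library- and replicate-level quality control
#'
#' Applies the gates described in [qc_thresholds()] to a count table and
#' (if frequencies are supplied) the replicate-correlation gate, and
#' reports a per-library pass table, per-timepoint replicate summaries,
#' failure reasons, and the overall target verdict. The verdict is a pure
#' function of its inputs.
#'
#' @param counts An `sge_counts` covering the plasmid library, negative
#'   control and timepoint replicates.
#' @param freqs Optional `sge_freqs` for the correlation gate.
#' @param thresholds Threshold list, see [qc_thresholds()].
#' @param cor_log Use `log10(frequency + 1e-7)` for replicate
#'   correlations instead of raw frequencies.
#' @return List of class `sge_qc`: `libraries` (per-library metrics and
#'   flags), `timepoints` (valid-replicate counts and minimum pairwise
#'   r), `failure_reasons`, `target_pass`.
#' @export
run_library_qc <- function(counts, freqs = NULL,
                           thresholds = qc_thresholds(), cor_log = FALSE) {
  stopifnot(inherits(counts, "sge_counts"))
  lib <- counts$libraries
  if (!"library" %in% lib$sample_type) stop("plasmid library column missing")
  th <- utils::modifyList(qc_thresholds(), thresholds)
  reasons <- character()

  lib$valid_fraction <- lib$total_valid_reads / lib$total_reads_received
  lib$wildtype_fraction <- lib$wildtype_reads / lib$total_reads_received
  lib$pass <- TRUE

  i <- which(lib$sample_type == "library")
  if (lib$total_reads_received[i[1]] < th$min_library_reads) {
    lib$pass[i] <- FALSE
    reasons <- c(reasons, "library_depth")
  }
  if (lib$valid_fraction[i[1]] < th$min_library_valid_fraction) {
    lib$pass[i] <- FALSE
    reasons <- c(reasons, "library_valid_fraction")
  }
  if (lib$wildtype_fraction[i[1]] > th$max_library_wildtype_fraction) {
    lib$pass[i] <- FALSE
    reasons <- c(reasons, "library_wildtype_fraction")
  }

  j <- which(lib$sample_type == "negative_control")
  if (length(j) > 0 &&
      any(lib$valid_fraction[j] > th$max_negative_control_valid_fraction)) {
    lib$pass[j] <- FALSE
    reasons <- c(reasons, "negative_control")
  }

  tp_types <- grep("^day[0-9]+_dna$", unique(lib$sample_type), value = TRUE)
  tp_rows <- list()
  for (st in tp_types) {
    k <- which(lib$sample_type == st)
    rep_ok <- lib$total_valid_reads[k] >= th$min_replicate_valid_reads
    lib$pass[k[!rep_ok]] <- FALSE
    if (any(!rep_ok)) reasons <- c(reasons, paste0(st, "_replicate_depth"))
    min_r <- NA_real_
    if (!is.null(freqs)) {
      cors <- replicate_correlations(freqs, st, log10_transform = cor_log)
      min_r <- cors$min_r
      if (is.na(min_r) || min_r < th$min_pairwise_r) {
        reasons <- c(reasons, paste0(st, "_correlation"))
      }
    }
    if (sum(rep_ok) < th$min_valid_replicates) {
      reasons <- c(reasons, paste0(st, "_replicates"))
    }
    tp_rows[[st]] <- data.frame(sample_type = st,
                                n_valid_replicates = sum(rep_ok),
                                min_pairwise_r = min_r)
  }

  structure(list(libraries = lib,
                 timepoints = do.call(rbind, tp_rows),
                 failure_reasons = unique(reasons),
                 target_pass = length(reasons) == 0),
            class = "sge_qc")
}

#' @export
print.sge_qc <- function(x, ...) {
  cat(sprintf("<sge_qc> target %s\n",
              if (x$target_pass) "PASS" else "FAIL"))
  if (!x$target_pass) {
    cat("  failures:", paste(x$failure_reasons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pairwise replicate correlations at one timepoint
#'
#' Pearson correlation between replicate frequency vectors over shared
#' variants; the gate fails when the minimum pairwise r drops below 0.5
#' (or with fewer than two replicates).
#'
#' @param freqs An `sge_freqs` object.
#' @param sample_type Timepoint library type, e.g. `"day5_dna"`.
#' @param log10_transform Correlate `log10(frequency + 1e-7)` instead of
#'   raw frequencies (raw frequencies are heavy-tailed).
#' @return List: `matrix` (replicate-by-replicate Pearson r), `min_r`.
#' @export
replicate_correlations <- function(freqs, sample_type,
                                   log10_transform = FALSE) {
  stopifnot(inherits(freqs, "sge_freqs"))
  ff <- freqs$freqs[freqs$freqs$sample_type == sample_type, ]
  reps <- sort(unique(ff$replicate))
  if (length(reps) < 2L) {
    return(list(matrix = NULL, min_r = NA_real_))
  }
  wide <- stats::reshape(
    ff[, c("variant_id", "replicate", "frequency")],
    idvar = "variant_id", timevar = "replicate", direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (log10_transform) m <- log10(m + 1e-7)
  cm <- stats::cor(m, method = "pearson")
  dimnames(cm) <- list(reps, reps)
  list(matrix = cm, min_r = min(cm[upper.tri(cm)]))
}
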