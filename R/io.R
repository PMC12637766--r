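#' Serialise / restore a target specification as JSON
#'
#' @param target An `sge_target`.
#' @param path Output (input) path.
#' @return `path` (`write_target_json`) or an `sge_target`
#'   (`read_target_json`).
#' @export
write_target_json <- function(target, path) {
  stopifnot(inherits(target, "sge_target"))
  jsonlite::write_json(unclass(target), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_target_json
#' @export
read_target_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sge_target(target_id = x$target_id, ref_seq = x$ref_seq,
             edited_region = x$edited_region,
             fixed_edits = as.data.frame(x$fixed_edits),
             cut_site = x$cut_site, coding_region = x$coding_region,
             genomic_offset = x$genomic_offset, exon_label = x$exon_label,
             excluded_positions = x$excluded_positions %||% integer(),
             rna_window = x$rna_window)
}

#' Write a count or frequency table as TSV
#'
#' Long format with header: `variant_id`, `sample_type`, `replicate`,
#' `count` (and `frequency` when present).
#'
#' @param x An `sge_counts` or `sge_freqs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  df <- if (inherits(x, "sge_freqs")) x$freqs else x$counts
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long count table from TSV
#'
#' Expects the [write_counts_tsv()] layout plus a separate library-totals
#' table; library totals may instead be recomputed as column sums
#' (`total_valid_reads = sum(count)`), appropriate when the TSV holds
#' valid-variant counts only.
#'
#' @param path Count TSV path.
#' @param libraries Optional data frame of per-library totals
#'   (`sample_type`, `replicate`, `total_reads_received`,
#'   `total_valid_reads`, `wildtype_reads`).
#' @param target_id Target label.
#' @return An `sge_counts`.
#' @export
read_counts_tsv <- function(path, libraries = NULL, target_id = "target") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "sample_type", "replicate", "count") %in%
                  names(df)))
  if (is.null(libraries)) {
    agg <- stats::aggregate(count ~ sample_type + replicate, df, sum)
    libraries <- data.frame(sample_type = agg$sample_type,
                            replicate = agg$replicate, day = NA,
                            total_reads_received = agg$count,
                            total_valid_reads = agg$count,
                            wildtype_reads = 0L)
  }
  new_sge_counts(df[, c("variant_id", "sample_type", "replicate", "count")],
                 libraries, target_id)
}

#' Write scores in a MaveDB-style CSV
#'
#' Columns: `hgvs_nt`, `hgvs_pro`, `score`, `score_se`, `rna_score`,
#' `n_points`, `source_targets`, plus `functional_class` / `rna_class`
#' when present.
#'
#' @param scores An `sge_scores` data frame (optionally carrying
#'   `rna_score`, `functional_class`, `rna_class` columns).
#' @param variants [enumerate_variants()] table for HGVS annotation.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, variants, path) {
  idx <- match(scores$variant_id, variants$variant_id)
  out <- data.frame(hgvs_nt = scores$variant_id,
                    hgvs_pro = variants$aa_change[idx],
                    score = scores$functional_score,
                    score_se = scores$score_se,
                    rna_score = scores$rna_score %||%
                      rep(NA_real_, nrow(scores)),
                    n_points = scores$n_points,
                    source_targets = scores$source_targets)
  for (extra in c("functional_class", "rna_class")) {
    if (!is.null(scores[[extra]])) out[[extra]] <- scores[[extra]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a QC report as JSON
#'
#' @param qc An `sge_qc` report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(qc, path) {
  jsonlite::write_json(unclass(qc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
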