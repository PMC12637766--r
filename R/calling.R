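#' Classify one merged amplicon read against a target specification
#'
#' Applies the read-validity rules of the screen. A read is:
#' \itemize{
#'   \item `invalid` if it contains an `N`;
#'   \item `unedited_wildtype` if it equals the unedited reference (no
#'     fixed edits, i.e. an uncut/un-repaired allele);
#'   \item `hdr_wildtype` if it has the expected length, carries all
#'     fixed edits and has no additional mismatch inside the edited
#'     region;
#'   \item `valid_snv` if it has the expected length, carries all fixed
#'     edits and exactly one additional edited-region mismatch (the
#'     programmed SNV); mismatches outside the edited region are
#'     tolerated;
#'   \item `valid_del3` if it is 3 nt short and exactly matches the
#'     edited reference with one programmed 3-bp deletion applied (fixed
#'     edits overlapped by the deletion are waived; edited-region
#'     mismatches on top of a deletion invalidate the read; repeat
#'     ambiguity resolves to the leftmost deletion start);
#'   \item `invalid` otherwise (wrong length, missing fixed edits, two or
#'     more edited-region mismatches, or substitution plus deletion).
#' }
#'
#' For targets containing homopolymer runs of at least four nucleotides,
#' a change in sequenced run length of up to two bases is permitted: the
#' read is re-anchored by restoring one run to its expected length before
#' the length test, and the rules above are then applied to the
#' run-normalised read.
#'
#' @param read A/C/G/T/N string (merged, orientation-normalised read).
#' @param target An `sge_target`.
#' @param homopolymer_allowance Apply the run-length tolerance (default
#'   TRUE; it is a no-op for targets without qualifying runs).
#' @return List of class `sge_read_call`: `category`, `variant_id`
#'   (empty unless a valid variant call), `n_mismatches_in_region`.
#' @export
classify_read <- function(read, target, homopolymer_allowance = TRUE) {
  if (!is.character(read) || length(read) != 1L || !nzchar(read)) {
    stop("read must be a non-empty string")
  }
  stopifnot(inherits(target, "sge_target"))
  if (grepl("N", read, fixed = TRUE)) return(read_call("invalid"))
  if (identical(read, target$ref_seq)) return(read_call("unedited_wildtype"))

  L_exp <- nchar(target$edited_ref_seq)
  candidates <- read
  if (homopolymer_allowance && nrow(target$homopolymer_runs) > 0 &&
      !nchar(read) %in% c(L_exp, L_exp - 3L)) {
    candidates <- c(normalize_homopolymers(read, target, L_exp),
                    normalize_homopolymers(read, target, L_exp - 3L))
  }
  for (cand in candidates) {
    call <- classify_exact(cand, target)
    if (!is.null(call) && call$category != "invalid") return(call)
  }
  read_call("invalid")
}

read_call <- function(category, variant_id = "", n_mm = NA_integer_) {
  structure(list(category = category, variant_id = variant_id,
                 n_mismatches_in_region = n_mm),
            class = "sge_read_call")
}

# Length-exact classification (no homopolymer tolerance).
classify_exact <- function(read, target) {
  L_exp <- nchar(target$edited_ref_seq)
  if (nchar(read) == L_exp) {
    classify_substitution(read, target)
  } else if (nchar(read) == L_exp - 3L) {
    vid <- match_deletion(read, target)
    if (is.na(vid)) read_call("invalid") else read_call("valid_del3", vid, 0L)
  } else {
    read_call("invalid")
  }
}

classify_substitution <- function(read, target) {
  er <- target$edited_region
  mm <- mismatch_positions(read, target$edited_ref_seq)
  # a mismatch at a fixed-edit position means the marker edit is absent
  if (any(mm %in% target$fixed_edits$pos)) return(read_call("invalid"))
  in_region <- mm[mm >= er[1] & mm <= er[2]]
  if (length(in_region) == 0L) return(read_call("hdr_wildtype", n_mm = 0L))
  if (length(in_region) > 1L) return(read_call("invalid"))
  pos <- in_region
  read_call("valid_snv",
            snv_id(target, pos, str_at(target$edited_ref_seq, pos),
                   str_at(read, pos)),
            1L)
}

#' Match a 3-nt-short read against the programmed deletion templates
#'
#' Compares the read with the edited reference carrying each programmed
#' 3-bp deletion in turn (ascending start, so repeat-induced ties resolve
#' to the leftmost start, consistent with indel left-alignment). A match
#' requires all fixed edits not overlapped by the deletion and zero
#' further mismatches inside the edited region; mismatches outside it are
#' tolerated.
#'
#' @param read Read of length `nchar(edited_ref_seq) - 3`.
#' @param target An `sge_target`.
#' @return The matched deletion's `variant_id`, or `NA_character_`.
#' @export
match_deletion <- function(read, target) {
  edited <- target$edited_ref_seq
  L <- nchar(edited)
  if (nchar(read) != L - 3L) return(NA_character_)
  er <- target$edited_region
  fe_pos <- target$fixed_edits$pos
  for (p in seq(er[1], er[2] - 2L)) {
    template <- paste0(substring(edited, 1L, p - 1L),
                       substring(edited, p + 3L, L))
    mm <- mismatch_positions(read, template)
    if (length(mm) > 0L) {
      orig <- ifelse(mm < p, mm, mm + 3L)
      if (any(orig >= er[1] & orig <= er[2])) next
      if (any(orig %in% fe_pos)) next
    }
    return(del3_id(target, p))
  }
  NA_character_
}

# Try to restore one homopolymer run to its expected length so that the
# read reaches target_len; returns zero or more normalised candidates.
normalize_homopolymers <- function(read, target, target_len) {
  d <- nchar(read) - target_len
  if (d == 0L) return(read)
  if (abs(d) > 2L) return(character())
  runs <- target$homopolymer_runs
  out <- character()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; L <- runs$length[i]; b <- runs$base[i]
    if (s > nchar(read) || str_at(read, s) != b) next
    j <- s
    while (j < nchar(read) && str_at(read, j + 1L) == b) j <- j + 1L
    k <- s
    while (k > 1L && str_at(read, k - 1L) == b) k <- k - 1L
    if ((j - k + 1L) != L + d) next
    out <- c(out, paste0(substring(read, 1L, k - 1L), strrep(b, L),
                         substring(read, j + 1L, nchar(read))))
  }
  unique(out)
}

#' Count programmed variants in a library of reads
#'
#' Classifies every read (identical reads are classified once and
#' weighted by multiplicity) and tabulates per-variant counts and
#' library-level totals. The editing rate is the fraction of received
#' reads that carry a usable edit:
#' `(valid_snv + valid_del3 reads) / total_reads_received`.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param target An `sge_target`.
#' @param sample_type,replicate Library key recorded in the result.
#' @param homopolymer_allowance Passed to [classify_read()].
#' @return An `sge_counts` object with one library column; its
#'   `libraries` entry additionally reports `hdr_wildtype_reads`,
#'   `invalid_reads` and `editing_rate`.
#' @export
count_variants <- function(reads, target, sample_type = "library",
                           replicate = 1L, homopolymer_allowance = TRUE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  n_total <- length(reads)
  if (n_total == 0L) {
    warning("no reads received; returning empty count table")
    return(new_sge_counts(
      data.frame(variant_id = character(), sample_type = character(),
                 replicate = integer(), count = integer()),
      data.frame(sample_type = sample_type, replicate = replicate, day = NA,
                 total_reads_received = 0L, total_valid_reads = 0L,
                 wildtype_reads = 0L, hdr_wildtype_reads = 0L,
                 invalid_reads = 0L, editing_rate = NA_real_),
      target$target_id))
  }
  tab <- table(reads)
  uniq <- names(tab)
  w <- as.integer(tab)
  cats <- character(length(uniq))
  vids <- character(length(uniq))
  for (i in seq_along(uniq)) {
    call <- classify_read(uniq[i], target, homopolymer_allowance)
    cats[i] <- call$category
    vids[i] <- call$variant_id
  }
  valid <- cats %in% c("valid_snv", "valid_del3")
  var_counts <- if (any(valid)) {
    agg <- tapply(w[valid], vids[valid], sum)
    data.frame(variant_id = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(), count = integer())
  }
  var_counts$sample_type <- rep(sample_type, nrow(var_counts))
  var_counts$replicate <- rep(as.integer(replicate), nrow(var_counts))
  var_counts <- var_counts[, c("variant_id", "sample_type", "replicate", "count")]

  n_valid <- sum(w[valid])
  lib <- data.frame(
    sample_type = sample_type, replicate = as.integer(replicate), day = NA,
    total_reads_received = n_total,
    total_valid_reads = n_valid,
    wildtype_reads = sum(w[cats == "unedited_wildtype"]),
    hdr_wildtype_reads = sum(w[cats == "hdr_wildtype"]),
    invalid_reads = sum(w[cats == "invalid"]),
    editing_rate = n_valid / n_total,
    stringsAsFactors = FALSE)
  new_sge_counts(var_counts, lib, target$target_id)
}

#' Combine single-library count tables
#'
#' @param ... `sge_counts` objects (e.g. from [count_variants()]).
#' @return One `sge_counts` with all libraries.
#' @export
bind_counts <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) > 0, all(vapply(xs, inherits, logical(1), "sge_counts")))
  new_sge_counts(do.call(rbind, lapply(xs, `[[`, "counts")),
                 do.call(rbind, lapply(xs, function(x) {
                   lib <- x$libraries
                   lib[setdiff(c("day"), names(lib))] <- NA
                   lib
                 })),
                 xs[[1]]$target_id)
}

#' Convert counts to filtered frequencies
#'
#' Frequency is `count / total_valid_reads` of the library. Variants with
#' a raw count below `min_count` in the plasmid library or in any of the
#' replicate/timepoint DNA libraries are excluded (`min_count`), and
#' variants at known cell-line-variant positions are dropped
#' (`cell_line_position`).
#'
#' @param counts An `sge_counts` object covering all libraries.
#' @param target An `sge_target` (supplies excluded positions).
#' @param variants Optional [enumerate_variants()] table supplying
#'   variant positions (needed for the cell-line-position filter) and the
#'   full variant universe (variants never observed get count 0).
#' @param min_count Minimum raw count (default 10).
#' @param min_count_sample_types Libraries the min-count filter scans;
#'   default the plasmid library and every DNA timepoint library.
#' @return An `sge_freqs` object: list with `freqs` (long data frame
#'   adding `frequency` to the count columns), `libraries`, `excluded`
#'   (data frame `variant_id`, `reason`), `target_id`.
#' @export
compute_frequencies <- function(counts, target, variants = NULL,
                                min_count = 10L,
                                min_count_sample_types = NULL) {
  stopifnot(inherits(counts, "sge_counts"))
  lib <- counts$libraries
  if (any(lib$total_valid_reads == 0)) {
    stop("library with zero valid reads: ",
         paste(lib$sample_type[lib$total_valid_reads == 0], collapse = ", "))
  }
  dna_types <- grep("^(library$|day[0-9]+_dna$)", unique(lib$sample_type),
                    value = TRUE)
  if (is.null(min_count_sample_types)) min_count_sample_types <- dna_types

  cc <- counts$counts
  universe <- if (is.null(variants)) unique(cc$variant_id) else variants$variant_id
  # complete the grid so unobserved variants count as 0 everywhere
  grid <- merge(data.frame(variant_id = universe, stringsAsFactors = FALSE),
                lib[, c("sample_type", "replicate")])
  cc <- merge(grid, cc, by = c("variant_id", "sample_type", "replicate"),
              all.x = TRUE)
  cc$count[is.na(cc$count)] <- 0L

  scan <- cc[cc$sample_type %in% min_count_sample_types, ]
  low <- unique(scan$variant_id[scan$count < min_count])

  excluded <- data.frame(variant_id = low,
                         reason = rep("min_count", length(low)),
                         stringsAsFactors = FALSE)
  if (!is.null(variants) && length(target$excluded_positions) > 0) {
    span <- ifelse(variants$vtype == "del3", 2L, 0L)
    hits <- vapply(seq_len(nrow(variants)), function(i) {
      any(target$excluded_positions >= variants$pos[i] &
            target$excluded_positions <= variants$pos[i] + span[i])
    }, logical(1))
    at_excl <- variants$variant_id[hits]
    at_excl <- setdiff(at_excl, excluded$variant_id)
    excluded <- rbind(excluded,
                      data.frame(variant_id = at_excl,
                                 reason = rep("cell_line_position",
                                              length(at_excl)),
                                 stringsAsFactors = FALSE))
  }

  keep <- !(cc$variant_id %in% excluded$variant_id)
  ff <- cc[keep, , drop = FALSE]
  tot <- lib$total_valid_reads[
    match(interaction(ff$sample_type, ff$replicate),
          interaction(lib$sample_type, lib$replicate))]
  ff$frequency <- ff$count / tot
  rownames(ff) <- NULL

  structure(list(freqs = ff, libraries = lib, excluded = excluded,
                 target_id = counts$target_id),
            class = "sge_freqs")
}

#' @export
print.sge_freqs <- function(x, ...) {
  cat(sprintf("<sge_freqs> target %s: %d variants x %d libraries (%d excluded)\n",
              x$target_id, length(unique(x$freqs$variant_id)),
              nrow(x$libraries), nrow(x$excluded)))
  invisible(x)
}
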