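# Shared fixtures and independent oracles, built in code at test time.

make_test_target <- function(seed = 7, length = 160L, ...) {
  generate_target(length = length, seed = seed, ...)
}

# Brute-force read-classification oracle: enumerate every single
# substitution and every single 3-bp deletion of the edited reference and
# test exact string equality (homopolymer allowance off). Independent of
# the mismatch-walking logic in classify_read.
oracle_classify_read <- function(read, target) {
  edited <- target$edited_ref_seq
  er <- target$edited_region
  L <- nchar(edited)
  if (grepl("N", read, fixed = TRUE)) return("invalid")
  if (identical(read, target$ref_seq)) return("unedited_wildtype")
  if (identical(read, edited)) return("hdr_wildtype")
  if (nchar(read) == L) {
    for (pos in seq_len(L)) {
      ref <- substring(edited, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        cand <- edited
        substring(cand, pos, pos) <- alt
        if (identical(read, cand)) {
          if (pos %in% target$fixed_edits$pos) return("invalid")
          if (pos >= er[1] && pos <= er[2]) {
            return(sprintf("valid_snv:%s:c.%d%s>%s",
                           target$target_id, pos, ref, alt))
          }
          return("hdr_wildtype")
        }
      }
    }
    return("invalid")
  }
  if (nchar(read) == L - 3L) {
    for (p in seq(er[1], er[2] - 2L)) {
      cand <- paste0(substring(edited, 1L, p - 1L),
                     substring(edited, p + 3L, L))
      if (identical(read, cand)) {
        return(sprintf("valid_del3:%s:c.%d_%ddel",
                       target$target_id, p, p + 2L))
      }
    }
    return("invalid")
  }
  "invalid"
}

call_signature <- function(call) {
  if (call$category %in% c("valid_snv", "valid_del3")) {
    paste0(call$category, ":", call$variant_id)
  } else {
    call$category
  }
}

# Random reads spanning every classification category, plus junk. Extra
# mismatches are placed inside the edited region so that the pure
# string-equality oracle and the rule-based caller see the same thing
# (out-of-region tolerance is exercised by its own unit test).
random_read_mix <- function(target, n, seed = 1) {
  variants <- enumerate_variants(target)
  edited <- target$edited_ref_seq
  er <- target$edited_region
  L <- nchar(edited)
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      kind <- sample(c("variant", "wt", "hdr", "extra_mm", "del_plus_sub",
                       "no_fixed", "junk"), 1)
      base <- if (kind == "wt") {
        target$ref_seq
      } else if (kind == "hdr") {
        edited
      } else if (kind == "no_fixed") {
        fe <- target$fixed_edits[sample(nrow(target$fixed_edits), 1), ]
        s <- edited
        substring(s, fe$pos, fe$pos) <- fe$ref
        s
      } else if (kind == "junk") {
        paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                     prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
              collapse = "")
      } else {
        v <- variants[sample(nrow(variants), 1), ]
        variant_sequence(target, v)
      }
      n_extra <- if (kind %in% c("extra_mm", "del_plus_sub")) {
        sample(1:2, 1)
      } else if (kind == "variant" && runif(1) < 0.3) {
        1L  # sometimes add an out-of-region or in-region extra mismatch
      } else 0L
      if (n_extra > 0) {
        hi <- min(er[2] - 3L, nchar(base))
        for (p in sample(seq(er[1], hi), n_extra)) {
          substring(base, p, p) <-
            sample(setdiff(c("A", "C", "G", "T"), substring(base, p, p)), 1)
        }
      }
      base
    }, character(1))
  })
}

# Bare-hands sge_counts builder for unit tests of downstream stages.
make_counts <- function(counts_df, libraries_df, target_id = "t") {
  sgescreen:::new_sge_counts(counts_df, libraries_df, target_id)
}

make_lib_row <- function(sample_type, replicate, total = NULL, valid,
                         wildtype = 0L, day = NA) {
  data.frame(sample_type = sample_type, replicate = as.integer(replicate),
             day = day,
             total_reads_received = if (is.null(total)) valid + wildtype else total,
             total_valid_reads = valid, wildtype_reads = wildtype,
             stringsAsFactors = FALSE)
}

# Minimal sge_freqs builder (frequencies = count / total_valid).
make_freqs <- function(counts_df, libraries_df, target_id = "t") {
  cc <- counts_df
  tot <- libraries_df$total_valid_reads[
    match(interaction(cc$sample_type, cc$replicate),
          interaction(libraries_df$sample_type, libraries_df$replicate))]
  cc$frequency <- cc$count / tot
  structure(list(freqs = cc, libraries = libraries_df,
                 excluded = data.frame(variant_id = character(),
                                       reason = character()),
                 target_id = target_id),
            class = "sge_freqs")
}

# sge_ratios builder for smoother/scorer unit tests.
make_ratios <- function(variant_id, position, replicate, day5, day13,
                        in_fit = TRUE) {
  out <- data.frame(variant_id = variant_id, position = position,
                    replicate = replicate, day5_ratio = day5,
                    day13_ratio = day13,
                    in_fit_subset = in_fit, stringsAsFactors = FALSE)
  class(out) <- c("sge_ratios", "data.frame")
  attr(out, "days") <- c(5, 13)
  out
}

gmm_model <- function(means, vars, weights = c(0.5, 0.5)) {
  structure(list(means = means, variances = vars, weights = weights,
                 component_labels = c("functionally_abnormal",
                                      "functionally_normal"),
                 degenerate = FALSE),
            class = "sge_gmm")
}
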