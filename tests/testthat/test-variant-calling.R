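test_that("read classification applies the validity rules", {
  t <- make_test_target(seed = 7)
  edited <- t$edited_ref_seq
  er <- t$edited_region
  fe <- t$fixed_edits
  # a free edited-region position (not a fixed edit)
  pos <- setdiff(seq(er[1], er[2]), fe$pos)[30]
  ref <- substring(edited, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]

  snv_read <- edited
  substring(snv_read, pos, pos) <- alt
  call <- classify_read(snv_read, t)
  expect_equal(call$category, "valid_snv")
  expect_equal(call$variant_id, sprintf("%s:c.%d%s>%s", t$target_id, pos, ref, alt))
  expect_equal(call$n_mismatches_in_region, 1L)

  # exact HDR backbone: all fixed edits, no programmed variant
  expect_equal(classify_read(edited, t)$category, "hdr_wildtype")
  # unedited allele
  expect_equal(classify_read(t$ref_seq, t)$category, "unedited_wildtype")

  # missing one fixed edit -> invalid
  miss <- snv_read
  substring(miss, fe$pos[1], fe$pos[1]) <- fe$ref[1]
  expect_equal(classify_read(miss, t)$category, "invalid")

  # a second edited-region mismatch -> invalid
  pos2 <- setdiff(seq(er[1], er[2]), c(fe$pos, pos))[5]
  two <- snv_read
  substring(two, pos2, pos2) <-
    setdiff(c("A", "C", "G", "T"), substring(two, pos2, pos2))[1]
  expect_equal(classify_read(two, t)$category, "invalid")

  # mismatch outside the edited region is tolerated
  outside <- snv_read
  substring(outside, 3, 3) <-
    setdiff(c("A", "C", "G", "T"), substring(outside, 3, 3))[1]
  expect_equal(classify_read(outside, t)$category, "valid_snv")

  # N anywhere -> invalid; empty read -> error
  nn <- snv_read
  substring(nn, 10, 10) <- "N"
  expect_equal(classify_read(nn, t)$category, "invalid")
  expect_error(classify_read("", t), "non-empty")
})

test_that("3-bp deletion reads match templates with leftmost tie-breaking", {
  t <- make_test_target(seed = 7)
  edited <- t$edited_ref_seq
  er <- t$edited_region
  p <- er[1] + 19L
  del_read <- paste0(substring(edited, 1, p - 1),
                     substring(edited, p + 3, nchar(edited)))
  call <- classify_read(del_read, t)
  expect_equal(call$category, "valid_del3")
  expect_equal(call$variant_id, sprintf("%s:c.%d_%ddel", t$target_id, p, p + 2))

  # deletion plus an edited-region substitution -> invalid
  free <- setdiff(seq(er[1], er[2] - 3), seq(p, p + 2))[40]
  bad <- del_read
  q <- if (free < p) free else free - 3L
  substring(bad, q, q) <-
    setdiff(c("A", "C", "G", "T"), substring(bad, q, q))[1]
  expect_equal(classify_read(bad, t)$category, "invalid")

  # repeat ambiguity: identical read sequences resolve to the leftmost start
  seq <- paste0(strrep("ACGT", 8), "TGATGA", strrep("GTCA", 8))
  rt <- sge_target("rep", seq, edited_region = c(20, 50),
                   fixed_edits = data.frame(pos = 22, ref = substring(seq, 22, 22),
                                            alt = setdiff(c("A", "C", "G", "T"),
                                                          substring(seq, 22, 22))[1]),
                   cut_site = 35, coding_region = c(20, 49))
  # deleting TGA at 33 or at 36 gives the same string
  r33 <- paste0(substring(rt$edited_ref_seq, 1, 32),
                substring(rt$edited_ref_seq, 36, nchar(seq)))
  r36 <- paste0(substring(rt$edited_ref_seq, 1, 35),
                substring(rt$edited_ref_seq, 39, nchar(seq)))
  expect_identical(r33, r36)
  expect_equal(match_deletion(r33, rt), "rep:c.33_35del")
  v <- enumerate_variants(rt)
  expect_false(v$canonical[v$variant_id == "rep:c.36_38del"])
  expect_equal(v$canonical_id[v$variant_id == "rep:c.36_38del"],
               "rep:c.33_35del")
})

test_that("homopolymer length slippage of up to two bases is tolerated", {
  seq <- paste0(strrep("ACGT", 10), "CAAAAAG", strrep("GTCA", 12),
                strrep("ACGT", 4))
  hp <- sge_target("hp", seq, edited_region = c(21, 90),
                   fixed_edits = data.frame(pos = 60, ref = substring(seq, 60, 60),
                                            alt = setdiff(c("A", "C", "G", "T"),
                                                          substring(seq, 60, 60))[1]),
                   cut_site = 55, coding_region = c(21, 89))
  run <- hp$homopolymer_runs[hp$homopolymer_runs$base == "A", ][1, ]
  expect_equal(run$length, 5)
  edited <- hp$edited_ref_seq

  pos <- 80L
  snv_read <- edited
  substring(snv_read, pos, pos) <-
    setdiff(c("A", "C", "G", "T"), substring(edited, pos, pos))[1]
  shrink <- function(r, d) {
    paste0(substring(r, 1, run$start - 1), strrep("A", run$length + d),
           substring(r, run$start + run$length, nchar(r)))
  }
  for (d in c(-2L, -1L, 1L, 2L)) {
    slipped <- shrink(snv_read, d)
    expect_equal(nchar(slipped), nchar(edited) + d)
    call <- classify_read(slipped, hp)
    expect_equal(call$category, "valid_snv")
    expect_equal(call$variant_id, classify_read(snv_read, hp)$variant_id)
    # with the allowance off, the wrong length is invalid
    expect_equal(classify_read(slipped, hp, homopolymer_allowance = FALSE)$category,
                 "invalid")
  }
  # a 3-base slip exceeds the allowance
  expect_equal(classify_read(shrink(snv_read, 3L), hp)$category, "invalid")
})

test_that("classification agrees with the brute-force enumeration oracle", {
  t <- make_test_target(seed = 13)
  reads <- random_read_mix(t, 300, seed = 21)
  got <- vapply(reads, function(r) {
    call_signature(classify_read(r, t, homopolymer_allowance = FALSE))
  }, character(1), USE.NAMES = FALSE)
  want <- vapply(reads, oracle_classify_read, character(1), target = t,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("adding a second edited-region mismatch to any valid SNV read invalidates it", {
  t <- make_test_target(seed = 5)
  er <- t$edited_region
  v <- enumerate_variants(t)
  v <- v[v$vtype == "snv" & v$callable, ]
  withr::with_seed(31, {
    for (i in sample(nrow(v), 25)) {
      r <- variant_sequence(t, v[i, ])
      expect_equal(classify_read(r, t)$category, "valid_snv")
      p2 <- sample(setdiff(seq(er[1], er[2]), c(v$pos[i], t$fixed_edits$pos)), 1)
      substring(r, p2, p2) <-
        sample(setdiff(c("A", "C", "G", "T"), substring(r, p2, p2)), 1)
      expect_equal(classify_read(r, t)$category, "invalid")
    }
  })
})

test_that("count tables conserve reads and report the editing rate", {
  t <- make_test_target(seed = 9)
  v <- enumerate_variants(t)
  v <- v[v$canonical & v$callable, ]
  snv <- v[v$vtype == "snv", ][1:3, ]
  reads <- c(rep(variant_sequence(t, snv[1, ]), 10),
             rep(variant_sequence(t, snv[2, ]), 15),
             rep(variant_sequence(t, snv[3, ]), 5),
             rep(t$ref_seq, 60),
             rep(t$edited_ref_seq, 7),
             strrep("N", nchar(t$ref_seq)),
             strrep("N", nchar(t$ref_seq)),
             "ACGT")
  cv <- count_variants(reads, t, "library", 1)
  lib <- cv$libraries
  expect_equal(lib$total_reads_received, length(reads))
  expect_equal(lib$total_valid_reads, 30)
  expect_equal(lib$editing_rate, 30 / length(reads))
  expect_equal(lib$wildtype_reads, 60)
  expect_equal(lib$hdr_wildtype_reads, 7)
  expect_equal(lib$total_valid_reads + lib$wildtype_reads +
                 lib$hdr_wildtype_reads + lib$invalid_reads,
               lib$total_reads_received)
  got <- cv$counts$count[match(snv$variant_id, cv$counts$variant_id)]
  expect_equal(got, c(10, 15, 5))
  expect_warning(count_variants(character(), t), "no reads")
})

test_that("frequencies divide by valid reads and apply both exclusion rules", {
  vids <- c("v1", "v2", "v3", "v4")
  libs <- rbind(make_lib_row("library", 1, valid = 500000),
                make_lib_row("day5_dna", 1, valid = 200000),
                make_lib_row("day13_dna", 1, valid = 200000))
  cdf <- expand.grid(variant_id = vids, stringsAsFactors = FALSE,
                     sample_type = libs$sample_type, replicate = 1L)
  cdf$count <- 1000L
  cdf$count[cdf$variant_id == "v1" & cdf$sample_type == "library"] <- 250L
  cdf$count[cdf$variant_id == "v2" & cdf$sample_type == "library"] <- 9L
  cdf$count[cdf$variant_id == "v3" & cdf$sample_type == "day13_dna"] <- 4L
  cnt <- make_counts(cdf, libs)
  variants <- data.frame(variant_id = vids, vtype = "snv",
                         pos = c(30, 31, 32, 33), stringsAsFactors = FALSE)
  target <- make_test_target(seed = 1)
  target$excluded_positions <- 33L

  fr <- compute_frequencies(cnt, target, variants, min_count = 10)
  expect_equal(fr$freqs$frequency[fr$freqs$variant_id == "v1" &
                                    fr$freqs$sample_type == "library"],
               250 / 500000)
  expect_setequal(fr$excluded$variant_id, c("v2", "v3", "v4"))
  expect_equal(fr$excluded$reason[fr$excluded$variant_id == "v2"], "min_count")
  expect_equal(fr$excluded$reason[fr$excluded$variant_id == "v3"], "min_count")
  expect_equal(fr$excluded$reason[fr$excluded$variant_id == "v4"],
               "cell_line_position")
  expect_false("v2" %in% fr$freqs$variant_id)

  libs0 <- libs
  libs0$total_valid_reads[1] <- 0L
  expect_error(compute_frequencies(make_counts(cdf, libs0), target, variants),
               "zero valid reads")
})

test_that("zero-error emitted reads recount exactly (round trip)", {
  sim <- simulate_sge_study(seed = 17, length = 120,
                            design = list(depth = 8000, rna_depth = 8000,
                                          nc_depth = 8000))
  reads <- emit_reads(sim$target, sim$counts, sim$variants, error_rate = 0,
                      homopolymer_slip_rate = 0, seed = 23)
  lib <- sim$counts$libraries
  for (i in seq_len(nrow(lib))) {
    st <- lib$sample_type[i]; rp <- lib$replicate[i]
    cv <- count_variants(reads[[paste(st, rp, sep = "_")]], sim$target, st, rp)
    truth_c <- sim$counts$counts[sim$counts$counts$sample_type == st &
                                   sim$counts$counts$replicate == rp, ]
    m <- merge(truth_c[, c("variant_id", "count")],
               cv$counts[, c("variant_id", "count")],
               by = "variant_id", all = TRUE, suffixes = c("_sim", "_called"))
    m[is.na(m)] <- 0
    expect_equal(m$count_called, m$count_sim)
    expect_equal(cv$libraries$wildtype_reads, lib$wildtype_reads[i])
  }
  # error_rate = 1 destroys essentially every read
  noisy <- emit_reads(sim$target, sim$counts, sim$variants, error_rate = 1,
                      libraries = data.frame(sample_type = "library",
                                             replicate = 1L), seed = 3)
  cv1 <- count_variants(noisy$library_1[1:2000], sim$target)
  expect_lt(cv1$libraries$editing_rate, 0.01)
})
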