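# Frequency fixture: one library, n replicates each of day-5 DNA/day-13
# DNA/day-5 RNA, with per-variant counts given as a named list of vectors.
freqs_fixture <- function(counts_by_lib, totals_by_lib) {
  rows <- list()
  libs <- list()
  for (key in names(counts_by_lib)) {
    st <- sub("\\.[0-9]+$", "", key)
    rp <- as.integer(sub("^.*\\.", "", key))
    cnt <- counts_by_lib[[key]]
    rows[[key]] <- data.frame(variant_id = names(cnt), sample_type = st,
                              replicate = rp, count = as.numeric(cnt),
                              stringsAsFactors = FALSE)
    libs[[key]] <- make_lib_row(st, rp, valid = totals_by_lib[[key]])
  }
  make_freqs(do.call(rbind, rows), do.call(rbind, libs))
}

two_var_variants <- data.frame(
  variant_id = c("a", "b", "c"), vtype = "snv", pos = c(30, 40, 50),
  position = c(1030, 1040, 1050), stringsAsFactors = FALSE)

test_that("day-5 log2 ratios follow the frequency arithmetic", {
  fr <- freqs_fixture(
    list(library.1 = c(a = 1000, b = 500, c = 1000),
         day5_dna.1 = c(a = 500, b = 500, c = 400),
         day13_dna.1 = c(a = 250, b = 500, c = 100)),
    list(library.1 = 1e6, day5_dna.1 = 1e6, day13_dna.1 = 1e6))
  rt <- log2_ratio_table(fr, two_var_variants, pseudocount = 0)
  expect_equal(rt$day5_ratio[rt$variant_id == "a"], -1)
  expect_equal(rt$day13_ratio[rt$variant_id == "a"], -2)
  expect_equal(rt$day5_ratio[rt$variant_id == "b"], 0)
  # the half-starting-frequency rule is inclusive on the passing side
  expect_true(rt$in_fit_subset[rt$variant_id == "a"])
  expect_true(rt$in_fit_subset[rt$variant_id == "b"])
  expect_false(rt$in_fit_subset[rt$variant_id == "c"])

  # pseudocount keeps zero counts finite
  fr0 <- freqs_fixture(
    list(library.1 = c(a = 1000, b = 500, c = 100),
         day5_dna.1 = c(a = 0, b = 500, c = 100),
         day13_dna.1 = c(a = 0, b = 500, c = 100)),
    list(library.1 = 1e6, day5_dna.1 = 1e6, day13_dna.1 = 1e6))
  rt0 <- log2_ratio_table(fr0, two_var_variants, pseudocount = 0.5)
  expect_true(is.finite(rt0$day5_ratio[rt0$variant_id == "a"]))
  expect_lt(rt0$day5_ratio[rt0$variant_id == "a"], -5)
})

test_that("the positional smoother recovers constant and smooth signals", {
  n <- 300
  pos <- seq_len(n) + 1000
  ids <- sprintf("v%03d", seq_len(n))

  # constant ratios fit a constant
  rc <- make_ratios(ids, pos, 1L, rep(-0.3, n), rep(-0.6, n))
  fc <- fit_position_smoother(rc)
  expect_true(all(abs(fc$loess_fit - (-0.3)) < 1e-6))

  # sinusoidal position effect, amplitude 0.5, recovered to RMSE < 0.05
  g <- 0.5 * sin(2 * pi * (pos - 1000) / 150)
  noise <- withr::with_seed(8, rnorm(n, 0, 0.05))
  rs <- make_ratios(ids, pos, 1L, g + noise, 2 * g + noise)
  fs <- fit_position_smoother(rs, span = 0.20)
  expect_lt(sqrt(mean((fs$loess_fit - g)^2)), 0.05)

  # out-of-subset variants still receive a fitted value
  rs$in_fit_subset[10] <- FALSE
  fs2 <- fit_position_smoother(rs)
  expect_true(is.finite(fs2$loess_fit[10]))

  # too few fit points: smoothing skipped with warning, fits zero
  small <- make_ratios(ids[1:5], pos[1:5], 1L, g[1:5], g[1:5])
  expect_warning(fsm <- fit_position_smoother(small), "smoothing skipped")
  expect_true(all(fsm$loess_fit == 0))
})

test_that("adjustment subtracts each replicate's day-5 fit from both days", {
  r <- make_ratios(c("a", "b"), c(1, 2), 1L, c(-1.2, 0.4), c(-2.0, 0.8))
  r$loess_fit <- c(-0.2, 0.1)
  a <- adjust_ratios(r)
  expect_equal(a$adjusted_day5, c(-1.0, 0.3))
  expect_equal(a$adjusted_day13, c(-1.8, 0.7))
  # no fit column: identity
  r2 <- make_ratios("a", 1, 1L, -1.2, -2.0)
  a2 <- adjust_ratios(r2)
  expect_equal(a2$adjusted_day5, a2$day5_ratio)
})

test_that("the regression slope is the functional score", {
  # collinear worked example through the origin: slope exactly -0.2
  r <- make_ratios(rep("a", 2), rep(1, 2), 1:2, rep(-1.0, 2), rep(-2.6, 2))
  r <- adjust_ratios(r)
  sc <- score_variants(r)
  expect_equal(sc$functional_score, -0.2)
  expect_equal(sc$score_se, 0)
  expect_equal(sc$n_points, 6L)

  # all-zero adjusted ratios give slope 0
  r0 <- adjust_ratios(make_ratios(rep("a", 2), rep(1, 2), 1:2,
                                  rep(0, 2), rep(0, 2)))
  expect_equal(score_variants(r0)$functional_score, 0)

  # one replicate = 3 points: too few, score missing
  r1 <- adjust_ratios(make_ratios("a", 1, 1L, -1, -2.6))
  expect_true(is.na(score_variants(r1)$functional_score))
})

test_that("pooled two-target scoring interpolates and degrades gracefully", {
  ra <- adjust_ratios(make_ratios(rep("a", 2), rep(1, 2), 1:2,
                                  rep(-0.5, 2), rep(-1.3, 2)))
  # identical data in both targets: same slope as one target
  both <- score_overlapping(ra, ra)
  one <- score_variants(ra)
  expect_equal(both$functional_score, one$functional_score)
  expect_equal(both$source_targets, 2L)

  # pooled slope lies between the single-target slopes
  rb <- adjust_ratios(make_ratios(rep("a", 2), rep(1, 2), 1:2,
                                  rep(-1.5, 2), rep(-3.9, 2)))
  sa <- score_variants(ra)$functional_score
  sb <- score_variants(rb)$functional_score
  sp <- score_overlapping(ra, rb)$functional_score
  expect_true(sp > min(sa, sb) && sp < max(sa, sb))

  # empty second target: equals the single-target score
  empty <- ra[0, ]
  expect_equal(score_overlapping(ra, empty)$functional_score, sa)
})

test_that("RNA scores are window-renormalised per-replicate medians", {
  t <- make_test_target(seed = 2)
  v <- enumerate_variants(t)
  v <- v[v$canonical & v$callable & v$vtype == "snv", ]
  v <- v[!duplicated(v$pos), ][1:2, ]  # two distinct positions
  v$variant_id <- c("a", "b")
  t$rna_window <- t$edited_region

  # counts chosen so renormalised DNA freq of a = 0.002 and RNA freq = 0.0005
  mk <- function(rna_a, rna_b, rep) {
    stats::setNames(list(c(a = 20, b = 9980), c(a = rna_a, b = rna_b)),
                    c(sprintf("day5_dna.%d", rep), sprintf("day5_rna.%d", rep)))
  }
  counts <- c(list(library.1 = c(a = 100, b = 100)),
              mk(5, 9995, 1), mk(20 * 2^-1.2, 10000 - 20 * 2^-1.2, 2),
              mk(20 * 2^-3, 10000 - 20 * 2^-3, 3))
  totals <- as.list(stats::setNames(rep(10000, 7), names(counts)))
  fr <- freqs_fixture(counts, totals)
  rs <- rna_score(fr, t, v, pseudocount = 0)
  # replicate scores for a: log2(0.0005/0.002) = -2.0, then -1.2, -3.0
  expect_equal(rs$rna_score[rs$variant_id == "a"], -2.0, tolerance = 1e-3)
  expect_equal(rs$n_rna_replicates[rs$variant_id == "a"], 3L)

  # two-target combination is the mean of the per-target scores
  ra <- data.frame(variant_id = c("a", "b"), rna_score = c(-1, 0),
                   n_rna_replicates = 3L)
  rb <- data.frame(variant_id = c("a", "c"), rna_score = c(-2, -4),
                   n_rna_replicates = 3L)
  comb <- combine_rna_scores(ra, rb)
  expect_equal(comb$rna_score[comb$variant_id == "a"], -1.5)
  expect_equal(comb$rna_score[comb$variant_id == "c"], -4)

  # variants outside the RNA window get no score
  t2 <- t
  t2$rna_window <- c(v$pos[1], v$pos[1])
  rs2 <- rna_score(fr, t2, v, pseudocount = 0)
  expect_false("b" %in% rs2$variant_id)
})

test_that("scores recover a neutral-dominated truth and stay scale invariant", {
  sim <- simulate_sge_study(seed = 41, length = 200,
                            design = list(depth = 2e5))
  res <- score_sge_study(sim$counts, sim$target, sim$variants)
  sc <- merge(res$scores, sim$truth[, c("variant_id", "true_slope", "true_lof")])
  expect_gt(sum(is.finite(sc$functional_score)) / nrow(sc), 0.95)
  # neutral-dominated regime: slope estimates essentially unbiased
  expect_lt(abs(mean(sc$functional_score - sc$true_slope, na.rm = TRUE)), 0.02)
  # loss-of-function variants separate cleanly from neutral ones
  expect_lt(mean(sc$functional_score[sc$true_lof]), -0.12)
  expect_lt(abs(mean(sc$functional_score[!sc$true_lof])), 0.02)

  # multiplying every count by 10 leaves scores (essentially) unchanged
  cnt10 <- sim$counts
  cnt10$counts$count <- cnt10$counts$count * 10L
  cnt10$libraries$total_reads_received <-
    cnt10$libraries$total_reads_received * 10L
  cnt10$libraries$total_valid_reads <-
    cnt10$libraries$total_valid_reads * 10L
  cnt10$libraries$wildtype_reads <- cnt10$libraries$wildtype_reads * 10L
  res10 <- score_sge_study(cnt10, sim$target, sim$variants)
  m <- merge(res$scores[, c("variant_id", "functional_score")],
             res10$scores[, c("variant_id", "functional_score")],
             by = "variant_id")
  expect_lt(max(abs(m$functional_score.x - m$functional_score.y), na.rm = TRUE),
            0.01)
})

test_that("with no position effect and null slopes, smoothing does not inflate ratios", {
  t <- generate_target(length = 260, seed = 51)
  v <- enumerate_variants(t)
  v <- v[v$canonical & v$callable, ]
  tr <- simulate_truth(v, seed = 52)
  tr$true_slope <- 0
  cnt <- simulate_counts(t, tr, design = list(depth = 2e5),
                         position_effect = function(p) rep(0, length(p)),
                         seed = 53)
  res <- score_sge_study(cnt, t, v, min_count = 0)
  r <- res$ratios
  expect_lte(mean(abs(r$adjusted_day5), na.rm = TRUE),
             mean(abs(r$day5_ratio), na.rm = TRUE) + 0.01)
  # null model: scores are unbiased within 2 standard errors of the mean
  sc <- res$scores$functional_score
  expect_gte(length(sc), 200)
  expect_lt(abs(mean(sc, na.rm = TRUE)),
            2 * stats::sd(sc, na.rm = TRUE) / sqrt(sum(is.finite(sc))))
})
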