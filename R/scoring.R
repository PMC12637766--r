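#' Per-replicate log2 frequency ratios
#'
#' For each variant and replicate, computes the log2 ratio of its day-5
#' (and day-13) frequency to its frequency in the initial plasmid
#' library. A pseudocount (default 0.5) is added to every raw count
#' before any frequency enters a log ratio, keeping fully depleted
#' variants finite; raw counts remain the basis of the min-count filter
#' and QC. Variants whose day-5 frequency is at least half their starting
#' frequency form the smoothing fit subset.
#'
#' @param freqs An `sge_freqs` object.
#' @param variants [enumerate_variants()] table (supplies the genomic
#'   smoothing coordinate of each variant).
#' @param pseudocount Added to every count before ratio frequencies.
#' @param days Numeric vector of the two sampled days (default `c(5, 13)`).
#' @return Data frame of class `sge_ratios`: `variant_id`, `position`,
#'   `replicate`, `day5_ratio`, `day13_ratio`, `in_fit_subset`.
#' @export
log2_ratio_table <- function(freqs, variants, pseudocount = 0.5,
                             days = c(5, 13)) {
  stopifnot(inherits(freqs, "sge_freqs"), length(days) == 2L)
  ff <- freqs$freqs
  lib <- freqs$libraries
  tot <- lib$total_valid_reads[
    match(interaction(ff$sample_type, ff$replicate),
          interaction(lib$sample_type, lib$replicate))]
  ff$pfreq <- (ff$count + pseudocount) / tot

  st5 <- sprintf("day%g_dna", days[1])
  st13 <- sprintf("day%g_dna", days[2])
  f0 <- ff[ff$sample_type == "library", c("variant_id", "pfreq")]
  names(f0)[2] <- "f0"
  f5 <- ff[ff$sample_type == st5, c("variant_id", "replicate", "pfreq")]
  names(f5)[3] <- "f5"
  f13 <- ff[ff$sample_type == st13, c("variant_id", "replicate", "pfreq")]
  names(f13)[3] <- "f13"

  out <- merge(merge(f5, f13, by = c("variant_id", "replicate"), all = TRUE),
               f0, by = "variant_id")
  out$day5_ratio <- log2(out$f5 / out$f0)
  out$day13_ratio <- log2(out$f13 / out$f0)
  out$in_fit_subset <- out$f5 >= 0.5 * out$f0
  out$position <- variants$position[match(out$variant_id, variants$variant_id)]
  out <- out[order(out$replicate, out$position, out$variant_id),
             c("variant_id", "position", "replicate",
               "day5_ratio", "day13_ratio", "in_fit_subset")]
  rownames(out) <- NULL
  class(out) <- c("sge_ratios", "data.frame")
  attr(out, "days") <- days
  out
}

#' Fit the positional smoother to day-5 ratios
#'
#' A one-dimensional LOESS (local linear, tricube weights, no robustness
#' iterations) of day-5 log2 ratios against genomic position, fitted
#' separately per replicate and only on variants whose day-5 frequency is
#' at least half the starting frequency. Fitted values are evaluated at
#' every variant position, including those outside the fit subset. This
#' attenuates the cut-site position effect on observed counts.
#'
#' @param ratios An [log2_ratio_table()] result.
#' @param span LOESS span as a fraction of fit-subset points (default 0.20).
#' @param min_fit_points Below this many fit points the smoother is
#'   skipped (fits are 0) with a warning.
#' @return `ratios` with a `loess_fit` column added.
#' @export
fit_position_smoother <- function(ratios, span = 0.20, min_fit_points = 10L) {
  stopifnot(inherits(ratios, "sge_ratios"))
  ratios$loess_fit <- 0
  for (r in unique(ratios$replicate)) {
    sel <- ratios$replicate == r
    fitset <- sel & ratios$in_fit_subset & is.finite(ratios$day5_ratio)
    if (sum(fitset) < min_fit_points) {
      warning(sprintf(
        "replicate %s: only %d fit points (< %d); smoothing skipped",
        r, sum(fitset), min_fit_points))
      next
    }
    fit <- stats::loess(day5_ratio ~ position, data = ratios[fitset, ],
                        span = span, degree = 1, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    ratios$loess_fit[sel] <- stats::predict(
      fit, newdata = data.frame(position = ratios$position[sel]))
  }
  ratios
}

#' Subtract positional fits from the log2 ratios
#'
#' Each replicate's day-5 positional fit is subtracted from its day-5
#' ratios and from the same replicate's cognate day-13 ratios.
#'
#' @param ratios A [fit_position_smoother()] result (must carry
#'   `loess_fit`; ratios without a fit pass through unadjusted).
#' @return `ratios` with `adjusted_day5` and `adjusted_day13` columns.
#' @export
adjust_ratios <- function(ratios) {
  stopifnot(inherits(ratios, "sge_ratios"))
  if (is.null(ratios$loess_fit)) ratios$loess_fit <- 0
  ratios$adjusted_day5 <- ratios$day5_ratio - ratios$loess_fit
  ratios$adjusted_day13 <- ratios$day13_ratio - ratios$loess_fit
  ratios
}

# Long (day, adjusted ratio) points per variant, anchored at (0, 0) once
# per replicate so replicate count weights the fit.
points_from_ratios <- function(ratios) {
  stopifnot(!is.null(ratios$adjusted_day5))
  days <- attr(ratios, "days") %||% c(5, 13)
  data.frame(
    variant_id = rep(ratios$variant_id, 3L),
    day = rep(c(0, days), each = nrow(ratios)),
    value = c(rep(0, nrow(ratios)), ratios$adjusted_day5,
              ratios$adjusted_day13),
    stringsAsFactors = FALSE)
}

ols_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) {
    return(list(slope = NA_real_, se = NA_real_, n = n))
  }
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  res <- y - (my + slope * (x - mx))
  se <- sqrt(sum(res^2) / (n - 2L) / sxx)
  list(slope = slope, se = se, n = n)
}

#' Score variants by regression of adjusted ratios on time
#'
#' Ordinary least squares of adjusted log2 frequency ratio against day,
#' per variant, over the points `(0, 0)` (the anchored starting
#' frequency, once per replicate), `(5, adjusted day-5 ratio)` and
#' `(13, adjusted day-13 ratio)` for each replicate. The slope — the
#' estimated log2 fold-change per day — is the functional score; its
#' standard error is reported. Variants with fewer than four finite
#' points are left unscored.
#'
#' @param ratios An [adjust_ratios()] result.
#' @return Data frame of class `sge_scores`: `variant_id`,
#'   `functional_score`, `score_se`, `n_points`, `source_targets`.
#' @export
score_variants <- function(ratios) {
  pts <- points_from_ratios(ratios)
  score_points(pts, source_targets = 1L)
}

score_points <- function(pts, source_targets) {
  sp <- split(pts, pts$variant_id)
  out <- data.frame(
    variant_id = names(sp),
    functional_score = rep(NA_real_, length(sp)),
    score_se = rep(NA_real_, length(sp)),
    n_points = rep(NA_integer_, length(sp)),
    source_targets = rep(as.integer(source_targets), length(sp)),
    stringsAsFactors = FALSE)
  for (i in seq_along(sp)) {
    f <- ols_slope(sp[[i]]$day, sp[[i]]$value)
    out$functional_score[i] <- f$slope
    out$score_se[i] <- f$se
    out$n_points[i] <- f$n
  }
  rownames(out) <- NULL
  class(out) <- c("sge_scores", "data.frame")
  out
}

#' Jointly score variants covered by two adjacent targets
#'
#' For variants present in both targets, the regression pools both
#' targets' (day, adjusted ratio) points into a single fit
#' (`source_targets = 2`); variants present in only one target keep
#' their single-target score.
#'
#' @param ratios_a,ratios_b [adjust_ratios()] results from two targets
#'   (`ratios_b` may have zero rows).
#' @return An `sge_scores` data frame over the union of variants.
#' @export
score_overlapping <- function(ratios_a, ratios_b) {
  pts_a <- points_from_ratios(ratios_a)
  if (is.null(ratios_b) || nrow(ratios_b) == 0L) {
    return(score_points(pts_a, source_targets = 1L))
  }
  pts_b <- points_from_ratios(ratios_b)
  shared <- intersect(unique(pts_a$variant_id), unique(pts_b$variant_id))
  pooled <- score_points(rbind(pts_a[pts_a$variant_id %in% shared, ],
                               pts_b[pts_b$variant_id %in% shared, ]),
                         source_targets = 2L)
  only_a <- score_points(pts_a[!pts_a$variant_id %in% shared, ],
                         source_targets = 1L)
  only_b <- score_points(pts_b[!pts_b$variant_id %in% shared, ],
                         source_targets = 1L)
  out <- rbind(pooled, only_a, only_b)
  out <- out[order(out$variant_id), ]
  rownames(out) <- NULL
  class(out) <- c("sge_scores", "data.frame")
  out
}

#' RNA-abundance scores
#'
#' Per replicate, the log2 ratio of a variant's frequency in the day-5
#' RNA library to its day-5 DNA frequency, where the DNA frequencies are
#' first renormalised over the variants inside the RNA amplicon window
#' (only those positions are sequenced in RNA). Replicate scores are
#' collapsed by the median. Variants outside the window get no RNA score.
#'
#' @param freqs An `sge_freqs` object (must include `day5_rna` libraries).
#' @param target An `sge_target` (supplies the RNA window).
#' @param variants [enumerate_variants()] table (variant positions).
#' @param pseudocount Added to counts before frequencies.
#' @return Data frame: `variant_id`, `rna_score` (median over
#'   replicates), `n_rna_replicates`.
#' @export
rna_score <- function(freqs, target, variants, pseudocount = 0.5) {
  stopifnot(inherits(freqs, "sge_freqs"))
  ff <- freqs$freqs
  if (!"day5_rna" %in% ff$sample_type) stop("no day5_rna libraries present")
  win <- target$rna_window
  pos <- variants$pos[match(ff$variant_id, variants$variant_id)]
  span_end <- pos + ifelse(
    variants$vtype[match(ff$variant_id, variants$variant_id)] == "del3", 2L, 0L)
  in_win <- pos >= win[1] & span_end <= win[2]

  reps <- sort(unique(ff$replicate[ff$sample_type == "day5_rna"]))
  per_rep <- list()
  for (r in reps) {
    dna <- ff[ff$sample_type == "day5_dna" & ff$replicate == r &
                in_win, c("variant_id", "count")]
    rna <- ff[ff$sample_type == "day5_rna" & ff$replicate == r &
                in_win, c("variant_id", "count")]
    m <- merge(dna, rna, by = "variant_id", suffixes = c("_dna", "_rna"))
    f_dna <- (m$count_dna + pseudocount) / sum(m$count_dna + pseudocount)
    f_rna <- (m$count_rna + pseudocount) / sum(m$count_rna + pseudocount)
    per_rep[[as.character(r)]] <- data.frame(
      variant_id = m$variant_id, replicate = r,
      score = log2(f_rna / f_dna), stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, per_rep)
  med <- tapply(long$score, long$variant_id, stats::median)
  nrep <- tapply(long$score, long$variant_id, function(x) sum(is.finite(x)))
  data.frame(variant_id = names(med), rna_score = as.numeric(med),
             n_rna_replicates = as.integer(nrep),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine RNA scores of variants covered by two targets
#'
#' The final reported RNA score of a variant covered by two adjacent
#' targets is the mean of the two per-target scores.
#'
#' @param rna_a,rna_b [rna_score()] results.
#' @return Combined data frame over the union of variants.
#' @export
combine_rna_scores <- function(rna_a, rna_b) {
  m <- merge(rna_a, rna_b, by = "variant_id", all = TRUE,
             suffixes = c("_a", "_b"))
  m$rna_score <- rowMeans(cbind(m$rna_score_a, m$rna_score_b), na.rm = TRUE)
  m$rna_score[is.nan(m$rna_score)] <- NA_real_
  m$n_rna_replicates <- pmax(m$n_rna_replicates_a, m$n_rna_replicates_b,
                             na.rm = TRUE)
  m[, c("variant_id", "rna_score", "n_rna_replicates")]
}
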