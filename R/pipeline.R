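#' Simulate a complete single-target SGE study
#'
#' Convenience wrapper chaining [generate_target()],
#' [enumerate_variants()], [simulate_truth()] and [simulate_counts()]
#' under one seed.
#'
#' @param seed Integer seed driving every stage.
#' @param length,cut_site,n_fixed_edits,intron_flank Target geometry,
#'   see [generate_target()].
#' @param design Count-simulation design, see [simulate_counts()].
#' @param position_effect Positional bias function (default Gaussian dip
#'   at the cut site); `NULL` is passed through to [simulate_counts()].
#' @param dispersion Count overdispersion.
#' @param truth_args Extra arguments for [simulate_truth()].
#' @return List: `target`, `variants`, `truth`, `counts`.
#' @export
simulate_sge_study <- function(seed = 1L, length = 160L, cut_site = NULL,
                               n_fixed_edits = 2L, intron_flank = 12L,
                               design = list(), position_effect = NULL,
                               dispersion = 0, truth_args = list()) {
  seeds <- derive_seeds(seed, 3L)
  target <- generate_target(length = length, cut_site = cut_site,
                            n_fixed_edits = n_fixed_edits,
                            intron_flank = intron_flank, seed = seeds[1])
  variants <- enumerate_variants(target)
  # only canonical, callable variants are distinguishable at the read level
  variants <- variants[variants$canonical & variants$callable, ]
  truth <- do.call(simulate_truth,
                   c(list(variants = variants, seed = seeds[2]), truth_args))
  counts <- simulate_counts(target, truth, design = design,
                            position_effect = position_effect,
                            dispersion = dispersion, seed = seeds[3])
  list(target = target, variants = variants, truth = truth, counts = counts)
}

#' Score a count table end to end
#'
#' Frequencies with filtering, log2 ratios, positional smoothing,
#' adjustment, per-variant regression scores and (when RNA libraries are
#' present) RNA scores, merged with the variant annotation.
#'
#' @param counts An `sge_counts` over all libraries.
#' @param target The `sge_target`.
#' @param variants The [enumerate_variants()] table.
#' @param min_count Minimum raw count filter (default 10).
#' @param span LOESS span (default 0.20).
#' @param pseudocount Pseudocount for log ratios (default 0.5).
#' @param smooth Apply the positional smoother (default TRUE).
#' @return List: `freqs`, `ratios`, `scores` (annotated `sge_scores`
#'   with `rna_score` where available).
#' @export
score_sge_study <- function(counts, target, variants, min_count = 10L,
                            span = 0.20, pseudocount = 0.5, smooth = TRUE) {
  freqs <- compute_frequencies(counts, target, variants,
                               min_count = min_count)
  ratios <- log2_ratio_table(freqs, variants, pseudocount = pseudocount)
  if (smooth) {
    ratios <- fit_position_smoother(ratios, span = span)
  }
  ratios <- adjust_ratios(ratios)
  scores <- score_variants(ratios)

  idx <- match(scores$variant_id, variants$variant_id)
  scores$consequence <- variants$consequence[idx]
  scores$vtype <- variants$vtype[idx]
  scores$exon_label <- variants$exon_label[idx]

  if ("day5_rna" %in% freqs$freqs$sample_type) {
    rna <- rna_score(freqs, target, variants, pseudocount = pseudocount)
    scores$rna_score <- rna$rna_score[match(scores$variant_id,
                                            rna$variant_id)]
  }
  list(freqs = freqs, ratios = ratios, scores = scores)
}

#' Classify scored variants into functional classes
#'
#' Fits the two-component mixture to the SNV scores with the anchored
#' initialisation, assigns posterior-based SNV classes, derives the
#' reusable score thresholds, classifies deletions by threshold, and
#' (when RNA scores are present) derives the RNA threshold and classes.
#'
#' @param scores Annotated `sge_scores` from [score_sge_study()].
#' @param cutoff Posterior cutoff (default 0.95).
#' @param min_scores Minimum SNV scores for the mixture fit.
#' @return List: `scores` (with `functional_class` and `rna_class`
#'   columns), `model` (`sge_gmm`), `thresholds` (`sge_thresholds`).
#' @export
classify_sge_study <- function(scores, cutoff = 0.95, min_scores = 100L) {
  snv <- scores$vtype == "snv" & is.finite(scores$functional_score)
  inits <- init_means(scores$functional_score[snv],
                      scores$consequence[snv], scores$exon_label[snv],
                      nonsense_exclude_exons = character())
  model <- fit_gmm(scores$functional_score[snv], inits,
                   min_scores = min_scores)
  scores$functional_class <- NA_character_
  scores$functional_class[snv] <-
    assign_classes(scores$functional_score[snv], model, cutoff)
  thresholds <- derive_thresholds(scores$functional_score[snv], model,
                                  cutoff)
  del <- scores$vtype == "del3"
  scores$functional_class[del] <-
    classify_deletions(scores$functional_score[del], thresholds)

  if (!is.null(scores$rna_score)) {
    rt <- rna_threshold_and_classes(scores$rna_score, scores$consequence,
                                    scores$exon_label,
                                    exclude_exons = character())
    thresholds$rna_threshold <- rt$rna_threshold
    scores$rna_class <- rt$classes
  }
  list(scores = scores, model = model, thresholds = thresholds)
}
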