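#' OddsPath calibration of a functional assay
#'
#' The ClinGen-style Bayesian odds of pathogenicity attributable to the
#' assay. With prior `P1` (the fraction pathogenic in the truth set) and
#' posterior `P2` (the fraction pathogenic among truth variants in an
#' assay class),
#' `OddsPath = (P2 * (1 - P1)) / ((1 - P2) * P1)`,
#' computed for the functionally-abnormal class (evidence towards
#' pathogenic) and the functionally-normal class (towards benign).
#' Truth variants with indeterminate (or missing) functional class are
#' excluded. A zero cell (a class containing no counter-examples) is
#' continuity-adjusted by adding one counter-example and flagged.
#'
#' @param truth Data frame with columns `clinical_label`
#'   (`"pathogenic"`/`"benign"`; `"P"`, `"LP"`, `"B"`, `"LB"`,
#'   `"pathogenic_or_LP"` and `"benign_or_LB"` are also accepted) and
#'   `functional_class` (`"functionally_abnormal"`,
#'   `"functionally_normal"`, `"indeterminate"`).
#' @return List of class `sge_oddspath`: `P1`, `P2_abnormal`,
#'   `P2_normal`, `oddspath_pathogenic`, `oddspath_benign`, the cell
#'   counts, and `zero_cell_adjusted`.
#' @export
compute_oddspath <- function(truth) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty truth set")
  lab <- normalize_clinical_label(truth$clinical_label)
  fc <- truth$functional_class
  keep <- lab %in% c("pathogenic", "benign") &
    fc %in% c("functionally_abnormal", "functionally_normal")
  lab <- lab[keep]; fc <- fc[keep]
  nP <- sum(lab == "pathogenic")
  nB <- sum(lab == "benign")
  if (nP == 0L || nB == 0L) {
    stop("need at least one pathogenic and one benign truth variant ",
         "with a non-indeterminate functional class")
  }
  P1 <- nP / (nP + nB)

  aP <- sum(lab == "pathogenic" & fc == "functionally_abnormal")
  aB <- sum(lab == "benign" & fc == "functionally_abnormal")
  nP2 <- sum(lab == "pathogenic" & fc == "functionally_normal")
  nB2 <- sum(lab == "benign" & fc == "functionally_normal")

  adjusted <- FALSE
  if (aP + aB > 0L && aB == 0L) { aB <- 1L; adjusted <- TRUE }
  if (nP2 + nB2 > 0L && nP2 == 0L) { nP2 <- 1L; adjusted <- TRUE }

  odds <- function(P2) (P2 * (1 - P1)) / ((1 - P2) * P1)
  P2_ab <- if (aP + aB > 0L) aP / (aP + aB) else NA_real_
  P2_no <- if (nP2 + nB2 > 0L) nP2 / (nP2 + nB2) else NA_real_

  structure(list(
    P1 = P1, P2_abnormal = P2_ab, P2_normal = P2_no,
    oddspath_pathogenic = if (is.na(P2_ab)) NA_real_ else odds(P2_ab),
    oddspath_benign = if (is.na(P2_no)) NA_real_ else odds(P2_no),
    n_pathogenic = nP, n_benign = nB,
    abnormal_cell = c(pathogenic = aP, benign = aB),
    normal_cell = c(pathogenic = nP2, benign = nB2),
    zero_cell_adjusted = adjusted), class = "sge_oddspath")
}

normalize_clinical_label <- function(x) {
  x <- tolower(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("pathogenic", "likely_pathogenic", "p", "lp", "plp",
               "pathogenic_or_lp")] <- "pathogenic"
  out[x %in% c("benign", "likely_benign", "b", "lb", "blb",
               "benign_or_lb")] <- "benign"
  out[x %in% c("vus", "uncertain", "uncertain_significance")] <- "VUS"
  out
}

#' @export
print.sge_oddspath <- function(x, ...) {
  cat(sprintf(
    "<sge_oddspath> P1=%.4f | pathogenic: %.3f | benign: %.4g%s\n",
    x$P1, x$oddspath_pathogenic, x$oddspath_benign,
    if (x$zero_cell_adjusted) " [zero cell adjusted]" else ""))
  invisible(x)
}

#' Map OddsPath values to ACMG/AMP evidence strengths and points
#'
#' Pathogenic (PS3) thresholds on OddsPath: > 350 very strong (+8
#' points), > 18.7 strong (+4), > 4.3 moderate (+2), > 2.08 supporting
#' (+1); below that, no evidence. Benign (BS3) uses the reciprocal
#' thresholds on the normal-class OddsPath with negative points.
#'
#' @param oddspath An `sge_oddspath` (or a list with
#'   `oddspath_pathogenic` and `oddspath_benign`).
#' @return List: `ps3_strength`, `ps3_points`, `bs3_strength`,
#'   `bs3_points`.
#' @export
map_evidence_strength <- function(oddspath) {
  op <- oddspath$oddspath_pathogenic
  ob <- oddspath$oddspath_benign
  ps3 <- if (is.na(op) || op <= 2.08) c("none", 0)
  else if (op > 350) c("very_strong", 8)
  else if (op > 18.7) c("strong", 4)
  else if (op > 4.3) c("moderate", 2)
  else c("supporting", 1)
  bs3 <- if (is.na(ob) || ob >= 1 / 2.08) c("none", 0)
  else if (ob < 1 / 350) c("very_strong", -8)
  else if (ob < 1 / 18.7) c("strong", -4)
  else if (ob < 1 / 4.3) c("moderate", -2)
  else c("supporting", -1)
  list(ps3_strength = ps3[1], ps3_points = as.numeric(ps3[2]),
       bs3_strength = bs3[1], bs3_points = as.numeric(bs3[2]))
}

#' Combine ACMG/AMP evidence points into a classification
#'
#' Points are summed (supporting ±1, moderate ±2, strong ±4, very strong
#' ±8) and mapped to the points-based thresholds: total >= 10
#' pathogenic, 6 to 9 likely pathogenic, -1 to 5 VUS, -6 to -2 likely
#' benign (the modified -2-point LB rule), <= -7 benign.
#'
#' @param points Named numeric vector of per-criterion points (e.g.
#'   `c(PS3 = 4, PM2 = 1)`). Duplicate criterion names are an error.
#' @return List: `total_points`, `classification` in
#'   `{"P", "LP", "VUS", "LB", "B"}`.
#' @export
combine_points <- function(points) {
  if (length(points) > 0 && !is.null(names(points)) &&
      anyDuplicated(names(points)[nzchar(names(points))])) {
    stop("duplicate evidence criteria supplied")
  }
  total <- sum(points)
  cls <- if (total >= 10) "P"
  else if (total >= 6) "LP"
  else if (total >= -1) "VUS"
  else if (total >= -6) "LB"
  else "B"
  list(total_points = total, classification = cls)
}

#' ROC curve and AUC of scores against a binary truth labelling
#'
#' Rank-based AUC (ties averaged; the Mann-Whitney statistic) for the
#' ability of the score to separate pathogenic from benign variants. By
#' default a lower score is more pathogenic.
#'
#' @param scores Numeric scores.
#' @param labels Logical or character: `TRUE`/`"pathogenic"` for the
#'   positive class.
#' @param lower_is_pathogenic Orientation (default TRUE).
#' @return List: `auc`, `curve` (data frame `fpr`, `tpr`), `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels, lower_is_pathogenic = TRUE) {
  if (is.character(labels)) {
    labels <- normalize_clinical_label(labels) == "pathogenic"
  }
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels)[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in the truth labels")
  }
  pred <- if (lower_is_pathogenic) -scores else scores
  r <- rank(pred)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(pred), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pred[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(pred[!labels] >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg)
}

#' Fisher's exact test odds ratio for a 2x2 carrier table
#'
#' The odds ratio is the cross-product `(a * d) / (b * c)`; the p-value
#' is the two-sided exact (hypergeometric) test; the 95% confidence
#' interval uses the Woolf log-OR normal approximation
#' `exp(log(OR) +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, 0.5 is added to every cell for the OR and CI (flagged).
#'
#' @param a,b,c,d Case carriers, case non-carriers, control carriers,
#'   control non-carriers; `a` may instead be an `sge_contingency` or a
#'   2x2 matrix.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `sge_fisher`: `or`, `p_value`, `ci` (length 2),
#'   `continuity_corrected`.
#' @export
fisher_or <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (inherits(a, "sge_contingency")) {
    d <- a$d; c <- a$c; b <- a$b; a <- a$a
  } else if (is.matrix(a)) {
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  structure(list(or = or, p_value = p, ci = ci,
                 continuity_corrected = corrected),
            class = "sge_fisher")
}

#' @export
print.sge_fisher <- function(x, ...) {
  cat(sprintf("<sge_fisher> OR = %.3f (95%% CI %.3f-%.3f), p = %.3g%s\n",
              x$or, x$ci[1], x$ci[2], x$p_value,
              if (x$continuity_corrected) " [continuity corrected]" else ""))
  invisible(x)
}

#' Z-test comparing two odds ratios via their confidence intervals
#'
#' Standard errors are recovered from the 95% CIs on the log-OR scale,
#' `SE_i = (log(upper_i) - log(lower_i)) / (2 * 1.96)`, and
#' `Z = (log(OR1) - log(OR2)) / sqrt(SE1^2 + SE2^2)` with a two-sided
#' normal p-value.
#'
#' @param or1,or2 Odds ratios (or `sge_fisher` objects, in which case the
#'   CI arguments are taken from them).
#' @param ci1,ci2 Length-2 95% CIs on the OR scale.
#' @return List: `z`, `p_value`.
#' @export
compare_odds_ratios <- function(or1, ci1 = NULL, or2 = NULL, ci2 = NULL) {
  if (inherits(or1, "sge_fisher")) {
    if (is.null(or2)) or2 <- ci1
    ci1 <- or1$ci
    or1 <- or1$or
  }
  if (inherits(or2, "sge_fisher")) {
    ci2 <- or2$ci
    or2 <- or2$or
  }
  if (any(c(ci1, ci2, or1, or2) <= 0)) {
    stop("odds ratios and CI bounds must be positive")
  }
  se1 <- (log(ci1[2]) - log(ci1[1])) / (2 * stats::qnorm(0.975))
  se2 <- (log(ci2[2]) - log(ci2[1])) / (2 * stats::qnorm(0.975))
  z <- (log(or1) - log(or2)) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
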