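#' Initial component means for the functional-class mixture
#'
#' The neutral (functionally normal) component is initialised at the mean
#' of the middle 95% (2.5-97.5 percentile trim) of scores of SNVs
#' expected to be neutral — synonymous and intronic SNVs. The abnormal
#' component is initialised at the mean score of all nonsense SNVs
#' outside the excluded exons (by default exons 1, 4 and 11, where
#' truncation may escape selection).
#'
#' @param scores Numeric functional scores (one per SNV).
#' @param consequences Character consequences parallel to `scores`.
#' @param exon_labels Exon labels parallel to `scores`.
#' @param neutral_consequences Consequences treated as neutral anchors.
#' @param nonsense_exclude_exons Exons whose nonsense SNVs are excluded
#'   from the abnormal anchor.
#' @param min_neutral,min_nonsense Minimum anchor sizes.
#' @return Numeric `c(mean_abnormal_init, mean_normal_init)`.
#' @export
init_means <- function(scores, consequences, exon_labels,
                       neutral_consequences = c("synonymous", "intron"),
                       nonsense_exclude_exons = c("exon1", "exon4", "exon11"),
                       min_neutral = 20L, min_nonsense = 5L) {
  ok <- is.finite(scores)
  neutral <- scores[ok & consequences %in% neutral_consequences]
  nonsense <- scores[ok & consequences == "stop_gained" &
                       !exon_labels %in% nonsense_exclude_exons]
  if (length(neutral) < min_neutral) {
    stop("too few synonymous/intronic scores to anchor the neutral component")
  }
  if (length(nonsense) < min_nonsense) {
    stop("too few eligible nonsense scores to anchor the abnormal component")
  }
  q <- stats::quantile(neutral, c(0.025, 0.975), names = FALSE, type = 7)
  neutral_trim <- neutral[neutral >= q[1] & neutral <= q[2]]
  c(abnormal = mean(nonsense), normal = mean(neutral_trim))
}

#' Fit a two-component Gaussian mixture to SNV scores
#'
#' Univariate EM with free means, variances and weights, initialised at
#' the [init_means()] anchors (initial weights 0.5/0.5; initial
#' variances default to the overall sample variance). Converged when the
#' log-likelihood improves by less than `tol` (default 1e-6) or after
#' `max_iter` iterations (a warning is raised and the best model
#' returned). Components are reported with the abnormal
#' (lesser-mean) component first. The fit is deterministic.
#'
#' @param scores Numeric SNV functional scores (>= 100 finite values).
#' @param means_init Length-2 numeric, `c(abnormal, normal)` initial means.
#' @param vars_init Optional length-2 initial variances.
#' @param weights_init Initial mixing weights (default 0.5/0.5).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param min_scores Minimum number of scores required.
#' @return List of class `sge_gmm`: `means`, `variances`, `weights`
#'   (component 1 = abnormal, 2 = normal), `loglik` (trace), `converged`,
#'   `n_iter`, `degenerate`.
#' @export
fit_gmm <- function(scores, means_init, vars_init = NULL,
                    weights_init = c(0.5, 0.5), tol = 1e-6,
                    max_iter = 500L, min_scores = 100L) {
  x <- scores[is.finite(scores)]
  if (length(x) < min_scores) {
    stop("need at least ", min_scores, " scores to fit the mixture")
  }
  stopifnot(length(means_init) == 2L)
  mu <- as.numeric(means_init)
  v <- if (is.null(vars_init)) rep(stats::var(x), 2L) else as.numeric(vars_init)
  v <- pmax(v, 1e-10)
  w <- weights_init / sum(weights_init)

  n <- length(x)
  ll_trace <- numeric()
  ll_old <- -Inf
  converged <- FALSE
  emptied <- FALSE
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) {  # one component emptied out
      w <- c(n1, n2) / n
      emptied <- TRUE
      break
    }
    mu[1] <- sum(g1 * x) / n1
    mu[2] <- sum((1 - g1) * x) / n2
    v[1] <- max(sum(g1 * (x - mu[1])^2) / n1, 1e-10)
    v[2] <- max(sum((1 - g1) * (x - mu[2])^2) / n2, 1e-10)
    w <- c(n1, n2) / n
  }
  if (!converged) warning("EM did not converge; returning best model")

  # component 1 = abnormal = lesser mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); v <- rev(v); w <- rev(w)
  }
  degenerate <- emptied || min(w) < 1e-3 || abs(mu[1] - mu[2]) < 1e-8
  structure(list(means = mu, variances = v, weights = w,
                 component_labels = c("functionally_abnormal",
                                      "functionally_normal"),
                 loglik = ll_trace, converged = converged,
                 n_iter = length(ll_trace), degenerate = degenerate),
            class = "sge_gmm")
}

#' @export
print.sge_gmm <- function(x, ...) {
  cat(sprintf(
    "<sge_gmm> abnormal: N(%.4f, %.4f^2) w=%.3f | normal: N(%.4f, %.4f^2) w=%.3f%s\n",
    x$means[1], sqrt(x$variances[1]), x$weights[1],
    x$means[2], sqrt(x$variances[2]), x$weights[2],
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Posterior component probabilities under a fitted mixture
#'
#' @param model An `sge_gmm`.
#' @param scores Numeric scores.
#' @return Matrix with columns `abnormal`, `normal`.
#' @export
gmm_posterior <- function(model, scores) {
  d1 <- model$weights[1] * stats::dnorm(scores, model$means[1],
                                        sqrt(model$variances[1]))
  d2 <- model$weights[2] * stats::dnorm(scores, model$means[2],
                                        sqrt(model$variances[2]))
  tot <- d1 + d2
  tot[tot == 0] <- .Machine$double.xmin
  cbind(abnormal = d1 / tot, normal = d2 / tot)
}

#' Assign functional classes from mixture posteriors
#'
#' An SNV whose posterior probability of the abnormal component exceeds
#' the cutoff (default 0.95) is functionally abnormal; analogously for
#' the normal component; everything else is indeterminate.
#'
#' @param scores Numeric scores.
#' @param model An `sge_gmm`.
#' @param cutoff Posterior cutoff.
#' @return Character vector in `{"functionally_abnormal",
#'   "functionally_normal", "indeterminate"}` (`NA` scores give `NA`).
#' @export
assign_classes <- function(scores, model, cutoff = 0.95) {
  post <- gmm_posterior(model, scores)
  out <- rep("indeterminate", length(scores))
  out[post[, "abnormal"] > cutoff] <- "functionally_abnormal"
  out[post[, "normal"] > cutoff] <- "functionally_normal"
  out[!is.finite(scores)] <- NA_character_
  out
}

#' Derive reusable score thresholds from the fitted mixture
#'
#' The loss-of-function threshold is the score of the observed variant
#' whose abnormal-component posterior is closest to the cutoff; the
#' functionally-normal threshold analogously for the normal component.
#' These thresholds are applied, without refitting, to variant sets the
#' mixture was not fitted on (the 3-bp deletions).
#'
#' @param scores Observed SNV scores.
#' @param model An `sge_gmm`.
#' @param cutoff Posterior cutoff (default 0.95).
#' @param rna_threshold Optional RNA threshold stored alongside.
#' @return List of class `sge_thresholds`: `lof_threshold`,
#'   `normal_threshold`, `rna_threshold`.
#' @export
derive_thresholds <- function(scores, model, cutoff = 0.95,
                              rna_threshold = NA_real_) {
  x <- scores[is.finite(scores)]
  post <- gmm_posterior(model, x)
  lof <- x[which.min(abs(post[, "abnormal"] - cutoff))]
  nrm <- x[which.min(abs(post[, "normal"] - cutoff))]
  structure(list(lof_threshold = lof, normal_threshold = nrm,
                 rna_threshold = rna_threshold),
            class = "sge_thresholds")
}

#' Classify deletion scores by the SNV-derived thresholds
#'
#' Scores at or below the loss-of-function threshold are functionally
#' abnormal, scores at or above the normal threshold are functionally
#' normal, scores between are indeterminate.
#'
#' @param scores Numeric deletion scores.
#' @param thresholds An `sge_thresholds`.
#' @return Character class labels.
#' @export
classify_deletions <- function(scores, thresholds) {
  out <- rep("indeterminate", length(scores))
  out[scores <= thresholds$lof_threshold] <- "functionally_abnormal"
  out[scores >= thresholds$normal_threshold] <- "functionally_normal"
  out[!is.finite(scores)] <- NA_character_
  out
}

#' RNA-abundance threshold and classes
#'
#' The threshold is one standard deviation above the mean nonsense RNA
#' score, where mean and SD come from the bottom 97.5% of RNA scores of
#' nonsense SNVs outside the excluded exons (default exons 1, 2 and 11).
#' A variant's RNA abundance is "normal" iff its RNA score is at least
#' the threshold, else "low".
#'
#' @param rna_scores Numeric RNA scores for all variants.
#' @param consequences,exon_labels Parallel annotation vectors.
#' @param exclude_exons Exons whose nonsense variants are excluded.
#' @param min_nonsense Minimum eligible nonsense RNA scores required.
#' @return List: `rna_threshold`, `classes` (character, `NA` for
#'   variants without an RNA score), `mu`, `sigma`, `n_anchor`.
#' @export
rna_threshold_and_classes <- function(rna_scores, consequences, exon_labels,
                                      exclude_exons = c("exon1", "exon2",
                                                        "exon11"),
                                      min_nonsense = 10L) {
  eligible <- is.finite(rna_scores) & consequences == "stop_gained" &
    !exon_labels %in% exclude_exons
  anchor <- rna_scores[eligible]
  if (length(anchor) < min_nonsense) {
    return(list(rna_threshold = NA_real_,
                classes = rep(NA_character_, length(rna_scores)),
                mu = NA_real_, sigma = NA_real_, n_anchor = length(anchor)))
  }
  cutoff <- stats::quantile(anchor, 0.975, names = FALSE, type = 7)
  bottom <- anchor[anchor <= cutoff]
  mu <- mean(bottom)
  sigma <- stats::sd(bottom)
  if (is.na(sigma)) sigma <- 0
  thr <- mu + sigma
  classes <- ifelse(rna_scores >= thr, "normal", "low")
  classes[!is.finite(rna_scores)] <- NA_character_
  list(rna_threshold = thr, classes = classes, mu = mu, sigma = sigma,
       n_anchor = length(bottom))
}
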