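#' ROC analysis of labeled phenotype similarity scores
#'
#' Positives are the mtDNA-disease group; both nuclear groups pool into the
#' negative class. Candidate thresholds are the midpoints between adjacent
#' distinct scores plus `-Inf`/`Inf` sentinels, and the prediction rule is
#' `score >= threshold => positive`. The AUC is the area under the
#' empirical step curve (trapezoids over the per-threshold operating
#' points), which equals the probability that a random positive outscores a
#' random negative with ties counted 1/2. The 95% CI uses the DeLong
#' structural-component variance with normal quantiles, clipped to [0, 1];
#' a percentile bootstrap is available as a cross-check.
#'
#' @param scores data.frame with columns `score` and `group`; `group`
#'   values in `"mtDNA"` (positive), `"nuclear_mito"`, `"nuclear_other"`
#'   (negative). Alternatively supply a logical `positive` column directly.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples when `ci_method = "bootstrap"`.
#' @param conf confidence level (default 0.95).
#' @return Object of class `roc_result`: `thresholds` (ascending), `sens`,
#'   `spec`, `auc`, `auc_ci`, `youden_threshold`, `youden_j`, `n_pos`,
#'   `n_neg`.
#' @export
roc <- function(scores, ci_method = c("delong", "bootstrap"),
                n_boot = 2000, conf = 0.95) {
  ci_method <- match.arg(ci_method)
  pos <- roc_positive_flag(scores)
  s <- as.numeric(scores$score)
  if (anyNA(s)) {
    pos <- pos[!is.na(s)]
    s <- s[!is.na(s)]
  }
  x <- s[pos]   # positives
  y <- s[!pos]  # negatives
  if (length(x) == 0L || length(y) == 0L) {
    stop("ROC needs at least one positive and one negative score")
  }

  u <- sort(unique(s))
  thresholds <- if (length(u) > 1L) {
    c(-Inf, (u[-length(u)] + u[-1L]) / 2, Inf)
  } else {
    c(-Inf, Inf)
  }
  sens <- vapply(thresholds, function(th) mean(x >= th), numeric(1))
  spec <- vapply(thresholds, function(th) mean(y < th), numeric(1))

  # trapezoid over the operating points, walked in threshold order
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)

  ci <- if (ci_method == "delong") {
    delong_ci(x, y, auc, conf)
  } else {
    bootstrap_ci(x, y, n_boot, conf)
  }

  j <- sens + spec - 1
  jmax <- max(j)
  ji <- which(j == jmax)[[1L]]  # thresholds ascending: tie -> smallest

  structure(
    list(
      thresholds = thresholds, sens = sens, spec = spec,
      auc = auc, auc_ci = ci,
      youden_threshold = thresholds[[ji]], youden_j = jmax,
      n_pos = length(x), n_neg = length(y)
    ),
    class = "roc_result"
  )
}

roc_positive_flag <- function(scores) {
  if ("positive" %in% names(scores)) return(as.logical(scores$positive))
  if (!"group" %in% names(scores)) stop("scores need a `group` or `positive` column")
  g <- as.character(scores$group)
  bad <- setdiff(unique(g), c("mtDNA", "nuclear_mito", "nuclear_other"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  g == "mtDNA"
}

# DeLong (1988) variance from structural components.
delong_ci <- function(x, y, auc, conf) {
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s10 <- if (length(x) > 1L) stats::var(v10) else 0
  s01 <- if (length(y) > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / length(x) + s01 / length(y))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

bootstrap_ci <- function(x, y, n_boot, conf) {
  aucs <- vapply(seq_len(n_boot), function(i) {
    xb <- sample(x, replace = TRUE)
    yb <- sample(y, replace = TRUE)
    psi <- outer(xb, yb, function(a, b) (a > b) + 0.5 * (a == b))
    mean(psi)
  }, numeric(1))
  unname(stats::quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(
    sprintf(
      "roc_result: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg, Youden threshold %.3f (J = %.3f)\n",
      x$auc, x$auc_ci[[1L]], x$auc_ci[[2L]], x$n_pos, x$n_neg,
      x$youden_threshold, x$youden_j
    )
  )
  invisible(x)
}

#' Optimal threshold by Youden's index
#'
#' Maximizes `J = sensitivity + specificity - 1` over the ROC's candidate
#' thresholds. Ties break toward the smallest threshold, i.e. toward
#' maximal sensitivity — appropriate for a screening filter where missing a
#' true mtDNA case is the costly error.
#'
#' @param r a `roc_result`.
#' @return List with `threshold`, `sens`, `spec`, `j`.
#' @export
youden_optimal <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  j <- r$sens + r$spec - 1
  i <- which(j == max(j))[[1L]]
  list(threshold = r$thresholds[[i]], sens = r$sens[[i]], spec = r$spec[[i]], j = j[[i]])
}

#' Sensitivity and specificity at a fixed threshold
#'
#' Under the rule `score >= threshold => positive (mtDNA)`.
#'
#' @param scores labeled score data.frame, see [roc()].
#' @param threshold the score cut-off.
#' @return List with `sens` and `spec`.
#' @export
sens_spec_at <- function(scores, threshold) {
  pos <- roc_positive_flag(scores)
  s <- as.numeric(scores$score)
  keep <- !is.na(s)
  pos <- pos[keep]
  s <- s[keep]
  if (!any(pos) || all(pos)) stop("both classes must be present")
  list(sens = mean(s[pos] >= threshold), spec = mean(s[!pos] < threshold))
}

#' Phenotype-similarity tier
#'
#' Partitions [0, 1] into low (`score < low_cut`), medium
#' (`low_cut <= score < high_cut`) and high (`score >= high_cut`); the
#' default boundaries 0.3 and 0.5 are the calibrated screening cut-offs
#' (0.3 is the highly sensitive floor; 0.5 the rounded Youden-region
#' threshold).
#'
#' @param score numeric vector of scores in `[0, 1]`.
#' @param low_cut,high_cut tier boundaries, `0 < low_cut < high_cut < 1`.
#' @return Character vector in `{"low", "medium", "high"}`.
#' @export
classify_tier <- function(score, low_cut = 0.3, high_cut = 0.5) {
  stopifnot(low_cut > 0, high_cut > low_cut, high_cut < 1)
  score <- as.numeric(score)
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop("scores must lie in [0, 1]")
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score < low_cut, "low",
                ifelse(score < high_cut, "medium", "high")))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' The omnibus H statistic and p value come from [stats::kruskal.test()]
#' (tie-corrected). Dunn's pairwise z statistics use pooled mid-ranks with
#' the tie correction `sum(t^3 - t) / (12 (N - 1))` subtracted from the
#' rank variance `N (N + 1) / 12`; p values are two-sided normal and
#' Bonferroni-adjusted over the number of pairs.
#'
#' @param groups named list of numeric vectors (one per group, each with at
#'   least 2 observations; at least 2 groups).
#' @return Object of class `group_comparison`: `kw_h`, `kw_p`, and
#'   `pairwise` (data.frame `pair`, `z`, `p_raw`, `p_adj`).
#' @export
kruskal_dunn <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    stop("each group needs >= 2 observations (got ",
         paste(sizes, collapse = ", "), ")")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), sizes), levels = names(groups))
  kw <- stats::kruskal.test(values, labels)

  n_total <- length(values)
  rk <- rank(values)  # mid-ranks
  mean_ranks <- tapply(rk, labels, mean)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n_total - 1))
  var_base <- n_total * (n_total + 1) / 12 - tie_corr

  combos <- utils::combn(names(groups), 2L)
  k <- ncol(combos)
  rows <- lapply(seq_len(k), function(i) {
    g1 <- combos[1L, i]
    g2 <- combos[2L, i]
    se <- sqrt(var_base * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(
      pair = paste(g1, g2, sep = " vs "), z = z, p_raw = p,
      p_adj = min(1, p * k), stringsAsFactors = FALSE
    )
  })
  structure(
    list(
      kw_h = unname(kw$statistic), kw_p = kw$p.value,
      pairwise = do.call(rbind, rows)
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4f, p = %.4g\n", x$kw_h, x$kw_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
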