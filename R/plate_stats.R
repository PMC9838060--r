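# Plate-level statistics: efficiencies, replicate aggregation, group
# comparisons, and the simulation-based detection limit.

#' Editing, transfection and co-transfection efficiencies
#'
#' `editing_efficiency()` is the headline reporter statistic: the
#' percentage of transfected (mCherry-positive) cells that are
#' GFP-positive. `transfection_efficiency()` is the percentage of counted
#' cells that are transfected. `cotransfection_efficiency()` uses the
#' independent (non-nested) GFP gate — GFP-positive over mCherry-positive
#' counts — and may exceed 100 (reported unclipped).
#'
#' Zero denominators yield `NA` with a warning; such wells are excluded
#' from aggregation. Raw values are returned; round with [report_pct()]
#' (one decimal) for reporting.
#'
#' @param summary A well-summary data.frame ([summarize_well()]) or a list
#'   with the needed count fields.
#' @return Numeric vector of percentages (one per well).
#' @export
editing_efficiency <- function(summary) {
  num <- summary$n_gfp_positive
  den <- summary$n_transfected
  bad <- den == 0
  if (any(bad))
    warning(sum(bad), " well(s) with zero transfected cells: efficiency undefined")
  ifelse(bad, NA_real_, 100 * num / den)
}

#' @rdname editing_efficiency
#' @export
transfection_efficiency <- function(summary) {
  bad <- summary$n_cells == 0
  if (any(bad))
    warning(sum(bad), " empty well(s): transfection efficiency undefined")
  ifelse(bad, NA_real_, 100 * summary$n_transfected / summary$n_cells)
}

#' @rdname editing_efficiency
#' @export
cotransfection_efficiency <- function(summary) {
  bad <- summary$n_transfected == 0
  if (any(bad))
    warning(sum(bad), " well(s) with zero mCherry-positive cells")
  ifelse(bad, NA_real_, 100 * summary$n_gfp_any / summary$n_transfected)
}

#' Aggregate per-well efficiencies into condition results
#'
#' Replicate aggregation is the mean of per-well efficiencies (wells are
#' the biological replicates and are plotted as dots); the pooled-count
#' ratio is also emitted for reference. The negative-control mean
#' (no-guide / reporter-only wells of the same plate) is attached to every
#' condition, and `mean_corrected` subtracts it: reporter background is an
#' additive false-positive rate that affects condition and control wells
#' alike.
#'
#' @param summaries Well summaries ([summarize_well()]).
#' @param layout [plate_layout()] (used for replicate/control structure).
#' @param statistic Which efficiency to aggregate (function).
#' @return data.frame with one row per non-control condition: `condition`,
#'   `n_wells`, `mean`, `sd`, `pooled`, `control_mean`, `mean_corrected`,
#'   `n_cells_pooled`.
#' @export
aggregate_condition <- function(summaries, layout,
                                statistic = editing_efficiency) {
  eff <- suppressWarnings(statistic(summaries))
  summaries$efficiency <- eff
  ctrl <- summaries$control_role != "none"
  control_mean <- if (any(ctrl)) mean(eff[ctrl], na.rm = TRUE) else NA_real_
  conds <- unique(summaries$condition[!ctrl])
  rows <- lapply(conds, function(cn) {
    s <- summaries[summaries$condition == cn & !ctrl, , drop = FALSE]
    ok <- !is.na(s$efficiency)
    if (!any(ok)) {
      warning("condition '", cn, "' has no usable wells; dropped")
      return(NULL)
    }
    s <- s[ok, , drop = FALSE]
    pooled <- 100 * sum(s$n_gfp_positive) / max(sum(s$n_transfected), 1)
    data.frame(condition = cn, n_wells = nrow(s),
               mean = mean(s$efficiency),
               sd = if (nrow(s) > 1) sd(s$efficiency) else 0,
               pooled = pooled,
               control_mean = control_mean,
               mean_corrected = mean(s$efficiency) -
                 (if (is.na(control_mean)) 0 else control_mean),
               n_cells_pooled = sum(s$n_cells),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-proportion z test
#'
#' The pooled-variance z-score test for two proportions, as used to compare
#' editing rates between transformant populations.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two groups.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @return List with `z`, `p.value`, `p1`, `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p.value <- switch(alternative,
                    two.sided = 2 * pnorm(-abs(z)),
                    greater = pnorm(z, lower.tail = FALSE),
                    less = pnorm(z))
  list(z = z, p.value = p.value, p1 = p1, p2 = p2)
}

# Compact letter display: groups sharing a letter are not significantly
# different (insert-and-absorb algorithm over the pairwise p matrix).
significance_letters <- function(groups, pairs, alpha = 0.05) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (r in seq_len(nrow(pairs))) {
    if (!is.na(pairs$p_adj[r]) && pairs$p_adj[r] < alpha) {
      sig[pairs$group1[r], pairs$group2[r]] <- TRUE
      sig[pairs$group2[r], pairs$group1[r]] <- TRUE
    }
  }
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        sets[[length(sets) + 1L]] <- setdiff(sets[[s]], i)
        sets[[s]] <- setdiff(sets[[s]], j)
      }
    }
    # absorb duplicated / contained sets
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]))
        keep[a] <- FALSE
    }
    sets <- sets[keep]
  }
  letters_out <- vapply(seq_len(k), function(i) {
    paste(letters[sort(which(vapply(sets, function(s) i %in% s, logical(1))))],
          collapse = "")
  }, character(1))
  stats::setNames(letters_out, groups)
}

#' Compare condition groups
#'
#' The comparison tests used in reporter-screen figures: one-way ANOVA with
#' Tukey HSD, Kruskal-Wallis with Dunn's post hoc (Holm-adjusted),
#' Mann-Whitney (exact where possible), and the two-proportion z test
#' (pairwise, Holm-adjusted for > 2 groups). Significance letters are
#' assigned at `alpha`.
#'
#' @param values Numeric observations (per-well efficiencies), or for
#'   `two_proportion_z` a data.frame with columns `successes`, `totals`.
#' @param groups Group label per observation / per proportion row.
#' @param test One of `"anova_tukey"`, `"kw_dunn"`, `"mannwhitney"`,
#'   `"two_proportion_z"`.
#' @param alpha Significance level for letters (default 0.05).
#' @param alternative Sidedness for the Mann-Whitney test (default
#'   `"two.sided"`); ignored by the other tests.
#' @return List with `test`, `omnibus_p`, `pairwise` (data.frame `group1`,
#'   `group2`, `estimate`, `p_adj`) and `letters`.
#' @export
compare_groups <- function(values, groups,
                           test = c("anova_tukey", "kw_dunn", "mannwhitney",
                                    "two_proportion_z"),
                           alpha = 0.05, alternative = "two.sided") {
  test <- match.arg(test)
  if (test == "two_proportion_z") {
    stopifnot(is.data.frame(values), all(c("successes", "totals") %in% names(values)))
    glab <- as.character(groups)
    if (length(unique(glab)) < 2)
      stop_pq("need >= 2 groups", class = "protoquant_input_error")
    agg <- rowsum(values[, c("successes", "totals")], glab)
    gl <- rownames(agg)
    pairs <- utils::combn(gl, 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     estimate = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    for (r in seq_len(nrow(pw))) {
      a <- pw$group1[r]; b <- pw$group2[r]
      zt <- two_proportion_z(agg[a, "successes"], agg[a, "totals"],
                             agg[b, "successes"], agg[b, "totals"])
      pw$estimate[r] <- zt$p1 - zt$p2
      pw$p[r] <- zt$p.value
    }
    pw$p_adj <- if (nrow(pw) > 1) p.adjust(pw$p, "holm") else pw$p
    omni <- min(pw$p_adj)
    return(list(test = test, omnibus_p = omni,
                pairwise = pw[, c("group1", "group2", "estimate", "p_adj")],
                letters = significance_letters(gl, pw, alpha)))
  }

  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop_pq("need >= 2 groups", class = "protoquant_input_error")
  if (test == "anova_tukey") {
    sizes <- table(groups)
    if (any(sizes < 2))
      stop_pq("anova_tukey needs >= 2 observations per group; use kw_dunn or pool replicates",
              class = "protoquant_input_error")
    fit <- aov(values ~ groups)
    omni <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(group1 = vapply(nm, `[`, "", 2),
                     group2 = vapply(nm, `[`, "", 1),
                     estimate = tk[, "diff"], p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE)
  } else if (test == "kw_dunn") {
    omni <- kruskal.test(values, groups)$p.value
    pw <- dunn_test(values, groups)
  } else { # mannwhitney
    if (nlevels(groups) != 2)
      stop_pq("mannwhitney compares exactly 2 groups",
              class = "protoquant_input_error")
    lv <- levels(groups)
    wt <- wilcox.test(values[groups == lv[1]], values[groups == lv[2]],
                      exact = TRUE, alternative = alternative)
    omni <- wt$p.value
    pw <- data.frame(group1 = lv[1], group2 = lv[2],
                     estimate = median(values[groups == lv[1]]) -
                       median(values[groups == lv[2]]),
                     p_adj = wt$p.value, stringsAsFactors = FALSE)
  }
  rownames(pw) <- NULL
  list(test = test, omnibus_p = omni, pairwise = pw,
       letters = significance_letters(levels(groups), pw, alpha))
}

# Dunn's post hoc test on rank sums (two-sided z statistics with the
# tie-corrected variance), Holm-adjusted.
dunn_test <- function(values, groups, method = "holm") {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- table(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    estimate = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    out$estimate[k] <- z
    out$p[k] <- 2 * pnorm(-abs(z))
  }
  out$p_adj <- p.adjust(out$p, method)
  out[, c("group1", "group2", "estimate", "p_adj")]
}

#' Minimal detectable editing efficiency by simulation
#'
#' Estimates, over a grid of candidate true editing rates, the power of a
#' one-sided two-proportion z test comparing the pooled GFP-positive count
#' across replicate wells against the pooled negative-control background,
#' and reports the smallest rate reaching the target power. This mirrors
#' how replicate plates are screened for activity above background, and is
#' a property of the replicate structure (wells x transfected cells per
#' well), not a constant of the method.
#'
#' @param n_replicates Replicate wells per condition.
#' @param cells_per_well Transfected cells per well (the efficiency
#'   denominator).
#' @param background_rate Background GFP-positive rate in control wells
#'   (proportion, e.g. 0.001).
#' @param n_control_wells Control wells pooled for the background estimate.
#' @param grid Candidate true rates (proportions); default logarithmic
#'   0.05\%-10\%.
#' @param n_sim Monte-Carlo replicates per grid point (default 2000).
#' @param power Target power (default 0.8).
#' @param alpha Test level (default 0.05, one-sided).
#' @param seed RNG seed for the simulation.
#' @return List with `threshold_pct` (minimal detectable rate, percent;
#'   `NA` if no grid rate reaches the target power), `threshold_se_pct`
#'   (binomial SE of the power estimate at the threshold, on the power
#'   scale), and `power_curve` (data.frame `rate_pct`, `power`).
#' @export
detection_threshold <- function(n_replicates, cells_per_well,
                                background_rate = 0,
                                n_control_wells = n_replicates,
                                grid = exp(seq(log(5e-4), log(0.10),
                                               length.out = 15)),
                                n_sim = 2000, power = 0.8, alpha = 0.05,
                                seed = 1L) {
  if (n_replicates < 1 || cells_per_well < 1)
    stop_pq("replicates and cells per well must be >= 1",
            class = "protoquant_input_error")
  if (background_rate >= max(grid))
    stop_pq("background rate at or above the candidate grid maximum: undetectable range",
            class = "protoquant_range_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "detection"))
  n_t <- n_replicates * cells_per_well
  n_c <- n_control_wells * cells_per_well
  pw <- vapply(grid, function(rate) {
    x1 <- rbinom(n_sim, n_t, rate)
    x2 <- rbinom(n_sim, n_c, background_rate)
    p <- (x1 + x2) / (n_t + n_c)
    se <- sqrt(p * (1 - p) * (1 / n_t + 1 / n_c))
    z <- ifelse(se == 0, 0, (x1 / n_t - x2 / n_c) / se)
    mean(pnorm(z, lower.tail = FALSE) < alpha)
  }, numeric(1))
  hit <- which(pw >= power)
  thr <- if (length(hit)) grid[min(hit)] else NA_real_
  thr_se <- if (length(hit))
    sqrt(pw[min(hit)] * (1 - pw[min(hit)]) / n_sim) else NA_real_
  list(threshold_pct = 100 * thr, threshold_se_pct = thr_se,
       power_curve = data.frame(rate_pct = 100 * grid, power = pw))
}
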