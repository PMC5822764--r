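#' One-way ANOVA with Bonferroni post hoc pairwise tests
#'
#' Classical (equal-variance) one-way analysis of variance across groups,
#' followed by pairwise two-sample t tests on the pooled-variance (ANOVA
#' mean-square-error) scale with a Bonferroni multiplier equal to the
#' number of pairwise comparisons. This is the conventional "ANOVA with a
#' post hoc Bonferroni test" of clinical tables; Welch corrections are
#' deliberately not applied.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group membership, same length.
#' @param parameter,region Optional labels carried into the result.
#' @return Object of class `group_comparison`: data frame `groups` (group,
#'   n, mean, sd), `f_statistic`, `p_value`, data frame `pairwise`
#'   (group1, group2, t, p_raw, p_adj with `p_adj = min(1, m * p_raw)`),
#'   `flag` (`"ok"` or `"degenerate"`).
#' @export
anova_bonferroni <- function(values, groups, parameter = NA_character_,
                             region = NA_character_) {
  groups <- factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- tapply(values, groups, length)
  if (any(n < 2L)) stop("each group needs n >= 2", call. = FALSE)

  gstats <- data.frame(group = levels(groups), n = as.integer(n),
                       mean = as.numeric(tapply(values, groups, mean)),
                       sd = as.numeric(tapply(values, groups, stats::sd)),
                       stringsAsFactors = FALSE)

  if (all(gstats$sd == 0)) {
    # no within-group variance: the F ratio is undefined (0/0 with equal
    # means, infinite otherwise) — flagged, never reported as a number
    return(structure(list(parameter = parameter, region = region,
                          groups = gstats, f_statistic = NA_real_,
                          p_value = NA_real_, pairwise = NULL,
                          flag = "degenerate"),
                     class = "group_comparison"))
  }

  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  f_stat <- sm[["F value"]][1]
  p_val <- sm[["Pr(>F)"]][1]
  mse <- sm[["Mean Sq"]][2]
  df_w <- sm[["Df"]][2]

  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   t = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- match(pairs[1, j], gstats$group)
    i2 <- match(pairs[2, j], gstats$group)
    se <- sqrt(mse * (1 / gstats$n[i1] + 1 / gstats$n[i2]))
    tj <- (gstats$mean[i1] - gstats$mean[i2]) / se
    pj <- 2 * stats::pt(-abs(tj), df_w)
    pw$t[j] <- tj
    pw$p_raw[j] <- pj
    pw$p_adj[j] <- min(1, m * pj)
  }

  structure(list(parameter = parameter, region = region, groups = gstats,
                 f_statistic = f_stat, p_value = p_val, pairwise = pw,
                 flag = "ok"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  hdr <- paste(stats::na.omit(c(x$parameter, x$region)), collapse = " / ")
  cat(sprintf("<group_comparison>%s F = %.4g, p = %.3g [%s]\n",
              if (nzchar(hdr)) paste0(" ", hdr, ":") else "",
              x$f_statistic, x$p_value, x$flag))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square without continuity correction,
#' df = (rows - 1)(cols - 1); used for categorical demographics such as the
#' gender split across groups.
#'
#' @param counts Matrix of nonnegative counts (e.g. 2 x k: male/female by
#'   group).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal total", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' Group comparison table across parameters and regions
#'
#' Runs [anova_bonferroni()] for every parameter x region cell of a
#' per-limb parameter table, mirroring the layout of a clinical
#' blood-flow-parameters table (group mean ± SD with significance versus
#' the control group).
#'
#' @param limb_table Data frame with columns `group`, `region` and the
#'   parameter columns.
#' @param parameters Parameter columns to compare (default
#'   `c("bfi", "i_max", "mtt", "auc")`).
#' @param control Reference group for the significance stars (default "C").
#' @return List with `comparisons` (list of `group_comparison`) and
#'   `table` (long data frame: parameter, region, group, n, mean, sd,
#'   p_overall, p_vs_control, stars).
#' @export
group_stats_table <- function(limb_table,
                              parameters = c("bfi", "i_max", "mtt", "auc"),
                              control = "C") {
  comparisons <- list()
  rows <- NULL
  for (p in parameters) {
    for (rg in unique(limb_table$region)) {
      sub <- limb_table[limb_table$region == rg, ]
      cmp <- anova_bonferroni(sub[[p]], sub$group, parameter = p, region = rg)
      comparisons[[paste(p, rg, sep = ".")]] <- cmp
      for (i in seq_len(nrow(cmp$groups))) {
        g <- cmp$groups$group[i]
        p_vs_c <- NA_real_
        if (!is.null(cmp$pairwise) && g != control) {
          hit <- (cmp$pairwise$group1 == control & cmp$pairwise$group2 == g) |
                 (cmp$pairwise$group2 == control & cmp$pairwise$group1 == g)
          if (any(hit)) p_vs_c <- cmp$pairwise$p_adj[hit][1]
        }
        stars <- if (is.na(p_vs_c)) "" else
          if (p_vs_c < 0.001) "***" else if (p_vs_c < 0.01) "**" else
          if (p_vs_c < 0.05) "*" else "n.s."
        rows <- rbind(rows, data.frame(
          parameter = p, region = rg, group = g, n = cmp$groups$n[i],
          mean = cmp$groups$mean[i], sd = cmp$groups$sd[i],
          p_overall = cmp$p_value, p_vs_control = p_vs_c, stars = stars,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(comparisons = comparisons, table = rows)
}
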