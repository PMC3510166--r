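#' Percent reduction of G-LISA RhoA activity versus a reference condition
#'
#' `percent_reduction = (1 - mean(OD treated) / mean(OD reference)) * 100`;
#' positive values are reductions, negative values increases. When `doses`
#' is supplied (a named numeric vector mapping condition labels to
#' concentrations), a dose-response series of percent reductions versus the
#' reference is returned alongside, ordered by concentration.
#'
#' @param table an `nq_assay_table` (or data.frame with `condition`, `OD`).
#' @param treated,reference condition labels.
#' @param doses optional named numeric vector of concentrations.
#' @return list: `percent_reduction`, `treated_mean`, `reference_mean`, and
#'   optionally `dose_response` (data.frame `condition`, `dose`,
#'   `percent_reduction`).
#' @export
activity_reduction <- function(table, treated, reference, doses = NULL) {
  m <- condition_means(table, c(treated, reference))
  out <- list(percent_reduction = (1 - m[[treated]] / m[[reference]]) * 100,
              treated_mean = m[[treated]], reference_mean = m[[reference]])
  if (!is.null(doses)) {
    mm <- condition_means(table, names(doses))
    dr <- data.frame(condition = names(doses), dose = unname(doses),
                     percent_reduction =
                       (1 - unlist(mm) / m[[reference]]) * 100)
    out$dose_response <- dr[order(dr$dose), ]
  }
  out
}

#' Percent change of BrdU proliferation versus a reference condition
#'
#' Same arithmetic as [activity_reduction()], applied to BrdU OD(450-540)
#' readings: positive percentages are proliferation reductions.
#'
#' @inheritParams activity_reduction
#' @return list with `percent_reduction`, `treated_mean`, `reference_mean`.
#' @export
proliferation_change <- function(table, treated, reference) {
  activity_reduction(table, treated, reference)
}

condition_means <- function(table, conditions) {
  missing <- setdiff(conditions, unique(table$condition))
  if (length(missing))
    stop_field(paste0("condition(s) absent from table: ",
                      paste(missing, collapse = ", ")))
  sapply(conditions, function(cd) mean(table$OD[table$condition == cd]),
         simplify = FALSE)
}

#' Delta-delta-Ct qPCR fold change
#'
#' `dCt = mean Ct(gene) - mean Ct(reference gene)` within each condition;
#' `fold = 2^-(dCt_treated - dCt_control)` (amplification efficiency fixed
#' at 2). With the noiseless generator this inverts the configured
#' expression shift exactly.
#'
#' @param ct_table an `nq_ct_table` (columns `condition`, `gene`,
#'   `replicate`, `Ct`).
#' @param gene target gene label.
#' @param reference_gene housekeeping gene (default `"gapdh"`).
#' @param control_condition reference condition label.
#' @param treated_condition treated label; default: the single non-control
#'   condition in the table.
#' @return fold change (scalar).
#' @export
qpcr_fold_change <- function(ct_table, gene, reference_gene = "gapdh",
                             control_condition = "control",
                             treated_condition = NULL) {
  if (!all(c(gene, reference_gene) %in% ct_table$gene))
    stop_field(paste0("unknown gene label: ",
                      paste(setdiff(c(gene, reference_gene),
                                    ct_table$gene), collapse = ", ")))
  treated_condition <- treated_condition %||%
    setdiff(unique(ct_table$condition), control_condition)
  if (length(treated_condition) != 1)
    stop_field("specify `treated_condition` (table has several non-control conditions)")
  mean_ct <- function(cond, g) {
    x <- ct_table$Ct[ct_table$condition == cond & ct_table$gene == g]
    if (length(x) < 2) stop_field(sprintf(
      "missing triplicates for gene %s in condition %s", g, cond))
    mean(x)
  }
  dct_c <- mean_ct(control_condition, gene) - mean_ct(control_condition, reference_gene)
  dct_t <- mean_ct(treated_condition, gene) - mean_ct(treated_condition, reference_gene)
  2^(-(dct_t - dct_c))
}

#' Classical test battery for condition comparisons
#'
#' Runs the statistical design used for plate and image readouts: one-way
#' ANOVA across condition groups, repeated-measures ANOVA (imaging positions
#' as subjects), or a paired t-test, followed by Bonferroni-adjusted
#' pairwise comparisons at `alpha` for the ANOVA designs.
#'
#' @param groups for `one_way`: a named list of numeric vectors. For
#'   `repeated_measures`: a data.frame with columns `group`, `subject`,
#'   `value` (balanced: every subject in every group). For `paired_t`: a
#'   list of exactly two equal-length vectors.
#' @param design `"one_way"`, `"repeated_measures"` or `"paired_t"`.
#' @param alpha significance level for the post-hoc flags.
#' @return list of class `nq_stat_result`: `test`, `statistic` (F or t),
#'   `df` (pair), `p_value`, `posthoc` (data.frame of pairwise
#'   Bonferroni-adjusted comparisons, ANOVA designs only), `alpha`.
#' @export
run_stats <- function(groups, design = c("one_way", "repeated_measures",
                                         "paired_t"),
                      alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired_t") {
    stopifnot(is.list(groups), length(groups) == 2)
    if (length(groups[[1]]) != length(groups[[2]]))
      stop_field("paired t-test requires equal-length vectors")
    tt <- stats::t.test(groups[[1]], groups[[2]], paired = TRUE)
    return(structure(list(test = "paired t-test",
                          statistic = unname(tt$statistic),
                          df = c(unname(tt$parameter), NA),
                          p_value = tt$p.value, posthoc = NULL,
                          alpha = alpha),
                     class = "nq_stat_result"))
  }
  if (design == "one_way") {
    stopifnot(is.list(groups), length(groups) >= 2)
    if (is.null(names(groups)))
      names(groups) <- paste0("g", seq_along(groups))
    d <- data.frame(value = unlist(groups),
                    group = factor(rep(names(groups),
                                       lengths(groups)),
                                   levels = names(groups)))
    fit <- stats::aov(value ~ group, data = d)
    s <- summary(fit)[[1]]
    ph <- with(d, stats::pairwise.t.test(value, group,
                                         p.adjust.method = "bonferroni"))
    pm <- ph$p.value
    pairs <- do.call(rbind, lapply(rownames(pm), function(a)
      do.call(rbind, lapply(colnames(pm), function(b)
        if (!is.na(pm[a, b]))
          data.frame(group1 = a, group2 = b, p_adj = pm[a, b],
                     significant = pm[a, b] < alpha)))))
    return(structure(list(test = "one-way ANOVA",
                          statistic = s[["F value"]][1],
                          df = c(s[["Df"]][1], s[["Df"]][2]),
                          p_value = s[["Pr(>F)"]][1],
                          posthoc = pairs, alpha = alpha),
                     class = "nq_stat_result"))
  }
  # repeated measures: positions as subjects
  stopifnot(is.data.frame(groups),
            all(c("group", "subject", "value") %in% names(groups)))
  tab <- table(groups$group, groups$subject)
  if (any(tab != 1)) {
    bad <- rownames(tab)[rowSums(tab != 1) > 0][1]
    stop_field(sprintf("unbalanced repeated-measures design in group '%s'", bad))
  }
  d <- groups
  d$group <- factor(d$group); d$subject <- factor(d$subject)
  fit <- stats::aov(value ~ group + Error(subject), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  ph <- stats::pairwise.t.test(d$value, d$group, paired = TRUE,
                               p.adjust.method = "bonferroni")
  pm <- ph$p.value
  pairs <- do.call(rbind, lapply(rownames(pm), function(a)
    do.call(rbind, lapply(colnames(pm), function(b)
      if (!is.na(pm[a, b]))
        data.frame(group1 = a, group2 = b, p_adj = pm[a, b],
                   significant = pm[a, b] < alpha)))))
  structure(list(test = "repeated-measures ANOVA",
                 statistic = s[["F value"]][1],
                 df = c(s[["Df"]][1], s[["Df"]][2]),
                 p_value = s[["Pr(>F)"]][1],
                 posthoc = pairs, alpha = alpha),
            class = "nq_stat_result")
}
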