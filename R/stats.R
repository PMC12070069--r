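#' Phenotype scoring proportions with Wilson intervals
#'
#' Converts scored-embryo counts into percent-affected values with Wilson
#' score confidence intervals. The Wilson interval is used (rather than
#' the Wald interval) because scored proportions in these assays are often
#' near 0% or 100%, where the Wald interval collapses.
#'
#' @param records Data frame with columns `condition`, `marker`,
#'   `n_scored`, `n_affected` (0 <= affected <= scored, scored >= 1).
#' @param conf_level Confidence level, default 0.95.
#' @return Data frame with `condition`, `marker`, `n_scored`,
#'   `n_affected`, `percent_affected`, `ci_low`, `ci_high` (percent).
#' @export
#' @examples
#' score_phenotypes(data.frame(condition = "Klf2MO", marker = "zic1",
#'                             n_scored = 74, n_affected = 67))
score_phenotypes <- function(records, conf_level = 0.95) {
  need <- c("condition", "marker", "n_scored", "n_affected")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_field("records", paste("missing columns:", paste(missing, collapse = ", ")))
  if (!(conf_level > 0 && conf_level < 1))
    stop_field("conf_level", "must be in (0, 1)")
  n <- records$n_scored; k <- records$n_affected
  if (any(n < 1) || any(n != round(n))) stop_field("n_scored", "must be integers >= 1")
  if (any(k < 0) || any(k > n) || any(k != round(k)))
    stop_field("n_affected", "must be integers in [0, n_scored]")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(condition = records$condition, marker = records$marker,
             n_scored = n, n_affected = k,
             percent_affected = 100 * p,
             ci_low = pmax(0, 100 * (centre - half)),
             ci_high = pmin(100, 100 * (centre + half)))
}

#' Read a scoring table from delimited text
#'
#' @param path CSV with columns `condition, marker, n_scored, n_affected`.
#' @return Data frame suitable for [score_phenotypes()].
#' @export
read_scoring_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "marker", "n_scored", "n_affected")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_field("path", paste("missing columns:", paste(missing, collapse = ", ")))
  df
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Per replicate, dCt = Ct(gene) - Ct(reference gene); per target gene,
#' ddCt = mean dCt(treated) - mean dCt(control) and fold change =
#' 2^(-ddCt) (Livak formulation with group means of replicate dCt).
#' Expression is typically normalized to ornithine decarboxylase (ODC).
#'
#' @param ct Data frame with columns `sample_group` (two levels),
#'   `replicate`, `gene`, `ct` (cycles).
#' @param reference_gene Housekeeping gene name, default `"ODC"`.
#' @param control_group,treated_group Level names in `sample_group`.
#' @return Data frame with `gene`, `mean_dct_control`, `mean_dct_treated`,
#'   `ddct`, `fold_change`.
#' @export
#' @examples
#' ct <- data.frame(sample_group = rep(c("control", "treated"), each = 2),
#'                  replicate = c(1, 1, 1, 1),
#'                  gene = rep(c("ODC", "sox3"), 2),
#'                  ct = c(20, 25, 20, 24))
#' ddct_fold_change(ct)$fold_change   # 2
ddct_fold_change <- function(ct, reference_gene = "ODC",
                             control_group = "control",
                             treated_group = "treated") {
  need <- c("sample_group", "replicate", "gene", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop_field("ct", paste("missing columns:", paste(missing, collapse = ", ")))
  groups <- c(control_group, treated_group)
  if (!all(groups %in% ct$sample_group))
    stop_field("sample_group", sprintf("must contain both '%s' and '%s'",
                                       control_group, treated_group))
  targets <- setdiff(unique(ct$gene), reference_gene)
  if (length(targets) == 0L)
    stop_field("ct", "no target genes besides the reference gene")
  # reference Ct per (group, replicate)
  ref <- ct[ct$gene == reference_gene, ]
  ref_key <- paste(ref$sample_group, ref$replicate)
  dct <- ct[ct$gene != reference_gene, ]
  key <- paste(dct$sample_group, dct$replicate)
  hit <- match(key, ref_key)
  if (anyNA(hit)) {
    bad <- unique(key[is.na(hit)])[1]
    stop(sprintf("replicate '%s' has no Ct for reference gene '%s'",
                 bad, reference_gene), call. = FALSE)
  }
  dct$dct <- dct$ct - ref$ct[hit]
  out <- lapply(targets, function(gene) {
    g <- dct[dct$gene == gene, ]
    mc <- mean(g$dct[g$sample_group == control_group])
    mt <- mean(g$dct[g$sample_group == treated_group])
    ddct <- mt - mc
    data.frame(gene = gene, mean_dct_control = mc, mean_dct_treated = mt,
               ddct = ddct, fold_change = 2^(-ddct))
  })
  do.call(rbind, out)
}

#' Read a Ct table from delimited text
#'
#' @param path CSV with columns `sample_group, replicate, gene, ct`.
#' @return Data frame suitable for [ddct_fold_change()].
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_group", "replicate", "gene", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_field("path", paste("missing columns:", paste(missing, collapse = ", ")))
  df
}

#' Two-group fold change with an unpaired two-tailed t-test
#'
#' Per gene, reports the fold change of group means (`group_a` over
#' `group_b`) and an unpaired, two-tailed t-test p-value. The default is
#' Student's pooled-variance form, which holds its nominal size at the
#' very small group sizes (n = 3 biological replicates) typical of these
#' assays; Welch's unequal-variance form, which is noticeably
#' conservative at such sizes, is available with `var_equal = FALSE`. If
#' both groups have zero within-group variance the test degenerates: p is
#' reported as exactly 1 for equal means and exactly 0 otherwise, with
#' `zero_variance = TRUE` and a warning.
#'
#' @param groups Data frame with columns `gene`, `group`, `value` (>= 2
#'   values per gene and group).
#' @param group_a,group_b Numerator and denominator group labels; default
#'   the first two levels encountered.
#' @param var_equal Logical; `TRUE` (default) for Student's pooled
#'   variance, `FALSE` for Welch.
#' @return Data frame with `gene`, `fold_change`, `t`, `df`, `p_value`,
#'   `zero_variance`, `method`.
#' @export
#' @examples
#' df <- data.frame(gene = "klf2", group = rep(c("a", "b"), each = 3),
#'                  value = c(4.1, 3.9, 4.0, 2.0, 2.1, 1.9))
#' fold_change_test(df, "a", "b")
fold_change_test <- function(groups, group_a = NULL, group_b = NULL,
                             var_equal = TRUE) {
  need <- c("gene", "group", "value")
  missing <- setdiff(need, names(groups))
  if (length(missing))
    stop_field("groups", paste("missing columns:", paste(missing, collapse = ", ")))
  levels <- unique(groups$group)
  if (is.null(group_a)) group_a <- levels[1]
  if (is.null(group_b)) group_b <- levels[2]
  if (!all(c(group_a, group_b) %in% levels))
    stop_field("group", "group_a/group_b not found in `group` column")
  out <- lapply(unique(groups$gene), function(gene) {
    a <- groups$value[groups$gene == gene & groups$group == group_a]
    b <- groups$value[groups$gene == gene & groups$group == group_b]
    if (length(a) < 2L || length(b) < 2L)
      stop_field("groups", sprintf("gene '%s' needs >= 2 values per group", gene))
    if (mean(b) == 0) stop(sprintf("gene '%s': zero mean denominator", gene),
                           call. = FALSE)
    fold <- mean(a) / mean(b)
    method <- if (var_equal) "student_t" else "welch_t"
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      equal <- isTRUE(all.equal(mean(a), mean(b)))
      warning(sprintf("gene '%s': zero within-group variance; degenerate p-value", gene))
      data.frame(gene = gene, fold_change = fold,
                 t = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                 df = length(a) + length(b) - 2,
                 p_value = if (equal) 1 else 0,
                 zero_variance = TRUE, method = method)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
      data.frame(gene = gene, fold_change = fold,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, zero_variance = FALSE,
                 method = method)
    }
  })
  do.call(rbind, out)
}
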