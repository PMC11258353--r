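# Two-round domain-insertion library screening analytics: permissive-site
# calling from round-1 colorimetric decay rates, allosteric-site calling
# from triplicate ligand-vs-vehicle t tests, summary fractions, secondary
# structure enrichment, and library coverage.

#' Round-1 permissive call from a colorimetric decay rate
#'
#' A variant is permissive (retains catalysis after domain insertion) when
#' its dye-decay rate within the screening window exceeds a fold threshold
#' over the empty-vector negative control, which itself accounts for
#' reagent decay over time. The visual bench criterion is formalised as a
#' configurable fold threshold (default 3-fold).
#'
#' @param r1_rate Round-1 decay rate of the variant (a.u./s, >= 0).
#' @param control_rate Decay rate of the negative control (>= 0).
#' @param fold_threshold Fold over control required to call permissive.
#' @return Logical (vectorised over `r1_rate`).
#' @export
round1_classify <- function(r1_rate, control_rate, fold_threshold = 3) {
  if (any(is.na(r1_rate)))
    abort_gbas("round-1 decay rate is missing", class = "gbas_missing_data")
  check_that(all(control_rate >= 0), "control rate must be >= 0")
  r1_rate >= fold_threshold * control_rate
}

#' Round-2 allosteric call from replicate activities
#'
#' Two-tailed unpaired t test between replicate activities under vehicle
#' (DMSO) and under the ligand; the variant is called allosteric when
#' `p < alpha` *and* it passed the permissive screen -- an inactive variant
#' is never allosteric, whatever its p value.
#'
#' @param dmso,ht Replicate activity vectors (each n >= 2).
#' @param permissive Logical from [round1_classify()].
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance t test if `TRUE` (default).
#' @return List with `p`, `allosteric`.
#' @export
round2_allosteric <- function(dmso, ht, permissive = TRUE, alpha = 0.05,
                              var_equal = TRUE) {
  if (length(dmso) < 2 || length(ht) < 2)
    abort_gbas("round-2 testing needs >= 2 replicates per condition",
               class = "gbas_insufficient_replicates")
  res <- compare_groups(dmso, ht, var_equal = var_equal)
  list(p = res$p, allosteric = isTRUE(permissive) && res$p < alpha)
}

#' Classify a full screening table
#'
#' Applies [round1_classify()] and [round2_allosteric()] to every row of a
#' screen table and appends `permissive`, `p_value`, `allosteric` columns.
#'
#' @param table Screen table data frame with columns `position`, `r1_rate`,
#'   `r1_control_rate`, `dmso_1..3`, `ht_1..3` (see
#'   [generate_screen_table()] / [read_screen_table()]).
#' @param fold_threshold Round-1 fold threshold.
#' @param alpha Round-2 significance level.
#' @param var_equal Pooled-variance t test if `TRUE`.
#' @return The table with classification columns appended.
#' @export
classify_screen <- function(table, fold_threshold = 3, alpha = 0.05,
                            var_equal = TRUE) {
  need <- c("position", "r1_rate", "r1_control_rate",
            paste0("dmso_", 1:3), paste0("ht_", 1:3))
  check_that(all(need %in% names(table)),
             paste("screen table must contain columns:",
                   paste(need, collapse = ", ")))
  table$permissive <- round1_classify(table$r1_rate, table$r1_control_rate,
                                      fold_threshold)
  dmso <- as.matrix(table[, paste0("dmso_", 1:3)])
  ht <- as.matrix(table[, paste0("ht_", 1:3)])
  res <- vapply(seq_len(nrow(table)), function(i) {
    out <- round2_allosteric(dmso[i, ], ht[i, ], table$permissive[i],
                             alpha, var_equal)
    c(out$p, as.numeric(out$allosteric))
  }, numeric(2))
  table$p_value <- res[1, ]
  table$allosteric <- as.logical(res[2, ])
  table
}

#' Summary of a classified screening profile
#'
#' Counts and fractions of permissive and allosteric insertion sites. A
#' table that has not been through [classify_screen()] but carries a
#' `truth_label` column (a synthetic fixture) is summarised from its truth
#' labels instead.
#'
#' @param table Classified screen table (with `permissive` and
#'   `allosteric` logical columns), or a truth-labelled fixture.
#' @return Object of class `profile_summary`: counts and fractions of
#'   permissive and allosteric insertion sites.
#' @export
profile_summary <- function(table) {
  if (!all(c("permissive", "allosteric") %in% names(table)) &&
      "truth_label" %in% names(table)) {
    table$permissive <- table$truth_label %in% c("permissive", "allosteric")
    table$allosteric <- table$truth_label == "allosteric"
  }
  check_that(all(c("permissive", "allosteric") %in% names(table)),
             "table must be classified first (see `classify_screen()`)")
  n <- nrow(table)
  np <- sum(table$permissive)
  na <- sum(table$allosteric)
  stopifnot(na <= np)
  structure(list(
    n_total = n, n_permissive = np, n_allosteric = na,
    frac_permissive = if (n > 0) np / n else 0,
    frac_allosteric = if (n > 0) na / n else 0
  ), class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("<profile_summary> %d positions: %d permissive (%.1f%%), %d allosteric (%.1f%%)\n",
              x$n_total, x$n_permissive, 100 * x$frac_permissive,
              x$n_allosteric, 100 * x$frac_allosteric))
  invisible(x)
}

#' Secondary-structure enrichment of insertion sites
#'
#' Distribution of a set of sites over secondary-structure classes (loop,
#' helix, sheet) compared against a length-weighted null: under no
#' structural preference, sites fall into each class in proportion to the
#' number of residues it covers. Tested with a chi-squared goodness-of-fit
#' test.
#'
#' @param sites Integer vector of residue positions.
#' @param ss Annotation data frame with columns `residue`, `ss_class`
#'   (values in loop/helix/sheet), and optionally `interface`.
#' @return List with `counts`, `fractions`, `expected`, `chisq`, `df`, `p`.
#' @export
structural_enrichment <- function(sites, ss) {
  check_that(all(c("residue", "ss_class") %in% names(ss)),
             "annotation needs `residue` and `ss_class` columns")
  if (!all(sites %in% ss$residue))
    abort_gbas("some sites have no secondary-structure annotation",
               class = "gbas_annotation_gap")
  classes <- c("loop", "helix", "sheet")
  check_that(all(ss$ss_class %in% classes),
             "ss_class values must be loop/helix/sheet")
  class_len <- table(factor(ss$ss_class, levels = classes))
  site_class <- ss$ss_class[match(sites, ss$residue)]
  counts <- table(factor(site_class, levels = classes))
  null_p <- as.numeric(class_len) / sum(class_len)
  present <- null_p > 0
  test <- suppressWarnings(
    stats::chisq.test(as.numeric(counts[present]), p = null_p[present]))
  list(counts = counts,
       fractions = as.numeric(counts) / max(1, length(sites)),
       expected = length(sites) * null_p,
       chisq = unname(test$statistic), df = unname(test$parameter),
       p = test$p.value)
}

#' Library coverage probability (coupon-collector model)
#'
#' Probability that `n_picks` equiprobable draws with replacement from a
#' library of `n_variants` sample every variant at least once, by
#' inclusion-exclusion:
#' `P = sum_{k=0..n} (-1)^k C(n,k) ((n-k)/n)^N`.
#' Also reports the union lower bound `1 - n (1 - 1/n)^N`. Terms are
#' evaluated in log space for numerical stability.
#'
#' @param n_picks Number of colonies picked, N (>= 0).
#' @param n_variants Library size, n (>= 1).
#' @return List with `p_full_coverage` and `lower_bound`.
#' @export
coverage_probability <- function(n_picks, n_variants) {
  check_that(n_picks >= 0, "`n_picks` must be >= 0")
  check_that(n_variants >= 1, "`n_variants` must be >= 1")
  N <- n_picks; n <- n_variants
  k <- 0:n
  frac <- (n - k) / n
  # ((n-k)/n)^N with the k = n term defined as 0^N (1 when N = 0)
  log_pow <- ifelse(frac > 0, N * log(frac), ifelse(N == 0, 0, -Inf))
  terms <- (-1)^k * exp(lchoose(n, k) + log_pow)
  p <- sum(terms)
  p <- min(max(p, 0), 1)
  list(p_full_coverage = p,
       lower_bound = max(0, 1 - n * (1 - 1 / n)^N))
}

#' Positional coverage from read counts
#'
#' @param read_counts Non-negative integer vector, one entry per insertion
#'   position (length 454 for the full scaffold).
#' @param n_positions Expected length (default 454).
#' @return List with `covered` (positions with >= 1 read) and
#'   `completeness` (fraction).
#' @export
coverage_from_reads <- function(read_counts, n_positions = 454) {
  if (length(read_counts) != n_positions)
    abort_gbas(sprintf("expected %d per-position read counts, got %d",
                       n_positions, length(read_counts)),
               class = "gbas_invalid_input")
  check_that(all(read_counts >= 0), "read counts must be >= 0")
  covered <- sum(read_counts >= 1)
  list(covered = covered, completeness = covered / n_positions)
}
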