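# Per-unit effect indices, peak-normalized rates, per-unit and population
# significance tests, pattern-proportion contingency analyses, and the
# end-to-end session pipeline.

#' Effect index of two spike counts
#'
#' `(B - A) / (B + A)`, where A is the spike count in the reference 10-min
#' block and B the count in the comparison block. Bounded in \[-1, 1\],
#' antisymmetric under swapping A and B, and insensitive to a unit's overall
#' firing rate.
#'
#' @param A,B non-negative spike counts with `A + B > 0`.
#' @return the index, or `NA` (with a warning) when `A + B == 0` — such
#'   units are flagged and excluded by callers.
#' @export
compute_index <- function(A, B) {
  if (any(!is.finite(c(A, B))) || A < 0 || B < 0)
    stop_validation("counts must be finite and >= 0")
  if (A + B == 0) {
    warning("effect index undefined for A = B = 0; returning NA")
    return(NA_real_)
  }
  (B - A) / (B + A)
}

#' Peak-normalized firing rates
#'
#' Each block's rate divided by the maximum rate across the blocks, so the
#' peak block maps to 1. Used to average rate time courses over units with
#' very different absolute rates.
#'
#' @param rates_by_block named numeric vector of block firing rates (Hz),
#'   at least one of them > 0.
#' @return named numeric vector of normalized rates.
#' @export
peak_normalized_rates <- function(rates_by_block) {
  if (!length(rates_by_block) || any(!is.finite(rates_by_block)) ||
      any(rates_by_block < 0))
    stop_validation("rates must be finite and >= 0")
  m <- max(rates_by_block)
  if (m == 0) {
    warning("all-zero rates; peak normalization undefined, returning NA")
    return(rates_by_block * NA_real_)
  }
  rates_by_block / m
}

#' Per-unit firing-rate change test between two blocks
#'
#' Bins each block's spikes into paired fixed-width bins (1 min by default,
#' 10 pairs for two 10-min blocks) and applies a paired two-sided Wilcoxon
#' signed-rank test to the bin counts. The direction is the sign of the
#' median paired difference. With all paired differences zero the test is
#' degenerate and the unit is reported as unchanged (p = 1).
#'
#' @param train a [spike_train()].
#' @param blockA,blockB [epoch()]s of equal length within the recording.
#' @param bin_s pairing bin width in seconds (default 60).
#' @param alpha significance level (default 0.05).
#' @return list with `direction` (-1, 0, +1), `p_value`, `significant`,
#'   `countA`, `countB`.
#' @export
per_unit_rate_change_test <- function(train, blockA, blockB, bin_s = 60,
                                      alpha = 0.05) {
  stopifnot(inherits(train, "spike_train"),
            inherits(blockA, "epoch"), inherits(blockB, "epoch"))
  lenA <- blockA$end - blockA$start
  lenB <- blockB$end - blockB$start
  if (abs(lenA - lenB) > 1e-9)
    stop_validation("blocks must have equal length (", lenA, " vs ", lenB, ")")
  nb <- floor(lenA / bin_s + 1e-9)
  if (nb < 1) stop_validation("blocks shorter than one pairing bin")
  bin_counts <- function(ep) {
    t <- slice_train(train, ep)$spike_times
    tabulate(pmin(floor(t / bin_s) + 1L, nb), nbins = nb)
  }
  a <- bin_counts(blockA)
  b <- bin_counts(blockB)
  d <- b - a
  if (all(d == 0))
    return(list(direction = 0L, p_value = 1, significant = FALSE,
                countA = sum(a), countB = sum(b)))
  res <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE))
  dir <- sign(stats::median(d))
  list(direction = as.integer(dir), p_value = res$p.value,
       significant = res$p.value < alpha,
       countA = sum(a), countB = sum(b))
}

#' Pattern-class proportions per period
#'
#' @param labels_by_period named list mapping period label to a vector of
#'   pattern-class labels (strings or [classify_pattern()] results), one per
#'   unit; every period must contain at least one unit.
#' @return an object of class `"proportion_table"`: list with `counts` and
#'   `proportions` (period x class matrices over the four pattern classes).
#' @export
pattern_proportions <- function(labels_by_period) {
  if (!length(labels_by_period) || is.null(names(labels_by_period)))
    stop_validation("labels_by_period must be a named list of label vectors")
  as_label <- function(x)
    if (inherits(x, "pattern_label")) x$label else as.character(x)
  counts <- t(vapply(labels_by_period, function(ls) {
    ls <- vapply(ls, as_label, character(1))
    if (!length(ls)) stop_validation("a period has no units")
    bad <- setdiff(unique(ls), PATTERN_CLASSES)
    if (length(bad)) stop_validation("unknown pattern class: ", bad[1])
    vapply(PATTERN_CLASSES, function(cl) sum(ls == cl), numeric(1))
  }, numeric(length(PATTERN_CLASSES))))
  structure(list(counts = counts, proportions = counts / rowSums(counts)),
            class = "proportion_table")
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("<proportion_table>\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Chi-squared test of a pattern-proportion change
#'
#' Pearson chi-squared test (no continuity correction, matching the usual
#' reporting of these contingency analyses) on a period x group contingency
#' table. `class_grouping` collapses the four classes into groups, e.g.
#' oscillatory vs non-oscillatory.
#'
#' @param table a [pattern_proportions()] result.
#' @param class_grouping named character vector mapping each of the four
#'   pattern classes to a group label. Default: oscillatory vs
#'   non-oscillatory.
#' @param correct logical; apply Yates continuity correction (default FALSE).
#' @return list with `chi2`, `df`, `p_value` and the collapsed `table`.
#' @export
proportion_change_test <- function(table,
                                   class_grouping = c("os-burst" = "osc",
                                                      "os-non-burst" = "osc",
                                                      "irr-burst" = "non-osc",
                                                      "irr-non-burst" = "non-osc"),
                                   correct = FALSE) {
  stopifnot(inherits(table, "proportion_table"))
  if (!all(PATTERN_CLASSES %in% names(class_grouping)))
    stop_validation("class_grouping must cover all four pattern classes")
  groups <- unique(unname(class_grouping[PATTERN_CLASSES]))
  collapsed <- vapply(groups, function(g)
    rowSums(table$counts[, names(class_grouping)[class_grouping == g],
                         drop = FALSE]),
    numeric(nrow(table$counts)))
  if (is.null(dim(collapsed)))
    collapsed <- matrix(collapsed, nrow = 1,
                        dimnames = list(rownames(table$counts), groups))
  expected <- outer(rowSums(collapsed), colSums(collapsed)) / sum(collapsed)
  if (any(expected == 0))
    stop_validation("structural zeros give zero expected counts; ",
                    "collapse or drop the empty group")
  res <- suppressWarnings(stats::chisq.test(collapsed, correct = correct))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, table = collapsed)
}

default_comparisons <- function(manifest) {
  labels <- vapply(manifest$epochs, `[[`, character(1), "label")
  cand <- list(harmaline = c("baseline", "harmaline"),
               dbs = c("harmaline", "dbs_on"),
               post_dbs = c("dbs_on", "dbs_off"))
  cand[vapply(cand, function(p) all(p %in% labels), logical(1))]
}

#' Run the full session analysis
#'
#' Orchestrates the end-to-end analysis of a session bundle: unit-inclusion
#' filtering, pattern classification per epoch, effect indices and per-unit
#' rate-change tests for the configured epoch comparisons,
#' pattern-proportion contingency tests, and (when force-plate data are
#' present) the MPR series and moving-area control. Deterministic given
#' inputs and config: running it twice yields identical reports.
#'
#' @param session_dir directory holding `spikes.csv`, `manifest.json` and
#'   optionally `force.csv` (see [write_session()]).
#' @param config optional named list overriding defaults: `osc_band` (Hz
#'   pair), `max_lag_ms`, `burst_max_isi_s`, `burst_min_sep_s`,
#'   `burst_fraction_cutoff`, `alpha`, `rate_bin_s`, `comparisons` (named
#'   list of epoch-label pairs `c(reference, comparison)`), `regions`.
#' @param out_dir optional directory; when given, the report tables are
#'   written as `patterns.csv`, `indices.csv`, `proportions.csv`, `mpr.csv`
#'   and `report.json`.
#' @return an object of class `"session_report"`: list with `patterns`
#'   (data.frame), `indices` (data.frame), `proportions` (per-region list of
#'   [pattern_proportions()]), `proportion_tests`, `mpr` (an `"mpr_series"`
#'   or `NULL`), `moving_area` (named numeric or `NULL`) and `config`.
#' @export
run_pipeline <- function(session_dir, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    osc_band = OSC_BAND, max_lag_ms = 5000,
    burst_max_isi_s = BURST_MAX_ISI, burst_min_sep_s = BURST_MIN_SEP,
    burst_fraction_cutoff = BURST_CELL_CUTOFF,
    alpha = 0.05, rate_bin_s = 60,
    comparisons = NULL, regions = REGIONS), config)

  ses <- read_session(session_dir)
  manifest <- ses$manifest
  comparisons <- cfg$comparisons %||% default_comparisons(manifest)
  labels <- vapply(manifest$epochs, `[[`, character(1), "label")

  selected <- list()
  for (rg in cfg$regions)
    selected <- c(selected, select_units(ses$trains, rg))
  if (!length(selected))
    stop_validation("no unit passes the inclusion filters")

  # pattern classification of every selected unit in every epoch
  patterns <- do.call(rbind, lapply(selected, function(tr) {
    do.call(rbind, lapply(manifest$epochs, function(ep) {
      sl <- slice_train(tr, ep)
      pl <- classify_pattern(sl, band = cfg$osc_band,
                             max_lag_ms = cfg$max_lag_ms,
                             max_isi = cfg$burst_max_isi_s,
                             min_sep = cfg$burst_min_sep_s,
                             burst_cutoff = cfg$burst_fraction_cutoff)
      data.frame(unit_id = tr$unit_id, region = tr$region, epoch = ep$label,
                 label = pl$label, oscillatory = pl$oscillatory,
                 burst = pl$burst, peak_freq_hz = pl$peak_freq,
                 burst_fraction = pl$burst_fraction, cv = pl$cv,
                 n_spikes = pl$n_spikes)
    }))
  }))

  # effect indices + per-unit signed-rank tests for each comparison
  indices <- do.call(rbind, lapply(names(comparisons), function(cmp) {
    pair <- comparisons[[cmp]]
    epA <- find_epoch(manifest, pair[1]); epB <- find_epoch(manifest, pair[2])
    if (is.null(epA) || is.null(epB)) return(NULL)
    do.call(rbind, lapply(selected, function(tr) {
      test <- per_unit_rate_change_test(tr, epA, epB,
                                        bin_s = cfg$rate_bin_s,
                                        alpha = cfg$alpha)
      idx <- if (test$countA + test$countB > 0)
        compute_index(test$countA, test$countB) else NA_real_
      data.frame(unit_id = tr$unit_id, region = tr$region, comparison = cmp,
                 A = test$countA, B = test$countB, index = idx,
                 direction = test$direction, p_value = test$p_value,
                 significant = test$significant)
    }))
  }))

  # pattern-proportion contingency per region across epochs
  proportions <- list(); proportion_tests <- list()
  for (rg in unique(patterns$region)) {
    sub <- patterns[patterns$region == rg, ]
    lbp <- split(sub$label, factor(sub$epoch, levels = labels))
    lbp <- lbp[vapply(lbp, length, integer(1)) > 0]
    if (length(lbp) >= 2) {
      tab <- pattern_proportions(lbp)
      proportions[[rg]] <- tab
      # degenerate cohorts (a structurally empty group) get an NA record
      # rather than aborting the whole session analysis
      proportion_tests[[rg]] <- tryCatch(
        proportion_change_test(tab),
        tremordbs_validation_error = function(e)
          list(chi2 = NA_real_, df = NA_real_, p_value = NA_real_,
               table = NULL, note = conditionMessage(e)))
    }
  }

  mpr <- NULL; areas <- NULL
  if (!is.null(ses$recording)) {
    mpr <- epoch_mpr(ses$recording, manifest)
    areas <- vapply(manifest$epochs, function(ep)
      moving_area(ses$recording$centroid, ep), numeric(1))
    names(areas) <- labels
  }

  report <- structure(list(patterns = patterns, indices = indices,
                           proportions = proportions,
                           proportion_tests = proportion_tests,
                           mpr = mpr, moving_area = areas, config = cfg),
                      class = "session_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$patterns, file.path(out_dir, "patterns.csv"),
                   row.names = FALSE)
  if (!is.null(report$indices))
    utils::write.csv(report$indices, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
  props <- do.call(rbind, lapply(names(report$proportions), function(rg) {
    pt <- report$proportions[[rg]]
    data.frame(region = rg, period = rownames(pt$proportions),
               class = rep(colnames(pt$proportions),
                           each = nrow(pt$proportions)),
               count = as.vector(pt$counts),
               proportion = as.vector(pt$proportions))
  }))
  if (!is.null(props))
    utils::write.csv(props, file.path(out_dir, "proportions.csv"),
                     row.names = FALSE)
  if (!is.null(report$mpr)) {
    utils::write.csv(report$mpr$per_frame, file.path(out_dir, "mpr.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    config = report$config,
    proportion_tests = lapply(report$proportion_tests, function(x)
      list(chi2 = x$chi2, df = x$df, p_value = x$p_value)),
    per_epoch_mpr = if (!is.null(report$mpr))
      as.list(report$mpr$per_epoch_mpr) else NULL,
    normalized_epoch_mpr = if (!is.null(report$mpr))
      as.list(report$mpr$normalized_epoch_mpr) else NULL,
    moving_area_mm2 = if (!is.null(report$moving_area))
      as.list(report$moving_area) else NULL,
    n_units = length(unique(report$patterns$unit_id)))
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>\n")
  cat("  units:", length(unique(x$patterns$unit_id)),
      " epochs:", length(unique(x$patterns$epoch)), "\n")
  for (rg in names(x$proportion_tests)) {
    pt <- x$proportion_tests[[rg]]
    cat(sprintf("  %s oscillatory-proportion test: chi2 = %.2f, p = %.3g\n",
                rg, pt$chi2, pt$p_value))
  }
  if (!is.null(x$mpr)) print(x$mpr)
  invisible(x)
}
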