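#' Read fluorescence traces and stimulus epochs
#'
#' Traces are long-format CSV with columns `time_s`, `fly_id`, optional `roi`,
#' and `f` (raw fluorescence, arbitrary units). Epochs are a JSON array of
#' objects `{label, onset_s, duration_s}` with labels such as `"CS+"`,
#' `"CS-"`, `"novel"`, `"light"`, `"shock"`.
#'
#' @param path File path.
#' @return Tibble of traces / epochs.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time_s", "fly_id", "f")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("read_traces(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' @rdname read_traces
#' @export
read_epochs <- function(path) {
  df <- jsonlite::fromJSON(path)
  need <- c("label", "onset_s", "duration_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("read_epochs(): missing fields: ", paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)[, need]
}

#' @rdname read_traces
#' @param epochs Epoch tibble (`label`, `onset_s`, `duration_s`).
#' @export
write_epochs <- function(epochs, path) {
  jsonlite::write_json(epochs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Compute dF/F0 for one trace
#'
#' Normalizes a raw fluorescence trace to a baseline F0. Two baseline
#' conventions are supported: `"pre_odor_2s"` takes the mean F over the 2 s
#' window ending at odor onset (per-stimulus baseline used for conditioning
#' recordings), `"first_9s"` takes the mean F over the first 9 s of the
#' recording (used for optogenetic connectivity recordings).
#'
#' @param trace Tibble with columns `time_s` and `f` (one fly / ROI).
#' @param baseline_mode `"pre_odor_2s"` or `"first_9s"`.
#' @param onset_s Stimulus onset (s); required for `"pre_odor_2s"`.
#' @return The input tibble with added columns `f0`, `f_over_f0` and `dff`
#'   (`(f - f0)/f0`).
#' @export
compute_dff <- function(trace, baseline_mode = c("pre_odor_2s", "first_9s"),
                        onset_s = NULL) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(is.data.frame(trace), all(c("time_s", "f") %in% names(trace)))
  t <- trace$time_s
  if (baseline_mode == "first_9s") {
    win <- t < min(t) + 9
  } else {
    if (is.null(onset_s)) stop("compute_dff(): onset_s required for pre_odor_2s")
    win <- t >= onset_s - 2 & t < onset_s
  }
  if (!any(win)) stop("compute_dff(): empty baseline window")
  f0 <- mean(trace$f[win])
  if (f0 <= 0) stop("compute_dff(): non-positive baseline")
  out <- tibble::as_tibble(trace)
  out$f0 <- f0
  out$f_over_f0 <- out$f / f0
  out$dff <- (out$f - f0) / f0
  out
}

#' Odor-response area under the curve
#'
#' Trapezoidal integral of the normalized fluorescence over the odor window
#' `[onset, onset + duration]` on the trace's native sampling grid. The onset
#' is snapped to the nearest sample. The integrand defaults to `f_over_f0`
#' (the fluorescence relative to baseline, so a flat trace integrates to the
#' window length); use `"dff"` for the baseline-subtracted integral.
#'
#' @param trace Tibble from [compute_dff()] (or any tibble with `time_s` and
#'   the integrand column).
#' @param onset_s Odor onset (s).
#' @param duration_s Odor duration (s), default 5.
#' @param integrand Column to integrate: `"f_over_f0"` (default) or `"dff"`.
#' @return AUC in (dimensionless) x seconds.
#' @export
odor_response_auc <- function(trace, onset_s, duration_s = 5,
                              integrand = c("f_over_f0", "dff")) {
  integrand <- match.arg(integrand)
  stopifnot(is.data.frame(trace), "time_s" %in% names(trace))
  if (!integrand %in% names(trace)) {
    stop("odor_response_auc(): column '", integrand,
         "' not found; run compute_dff() first")
  }
  t <- trace$time_s
  v <- trace[[integrand]]
  dt <- stats::median(diff(sort(t)))
  t_on <- t[which.min(abs(t - onset_s))]
  t_off <- t_on + duration_s
  if (t_on < min(t) - dt / 2 || t_off > max(t) + dt / 2) {
    stop("odor_response_auc(): integration window exceeds record")
  }
  # native samples inside the window plus linearly interpolated values at the
  # exact window edges, so the integral spans the full duration even when it
  # is not a whole number of sample periods
  inner <- t > t_on + 1e-9 & t < t_off - 1e-9
  xs <- c(t_on, t[inner], min(t_off, max(t)))
  ys <- stats::approx(t, v, xout = xs, rule = 2)$y
  if (length(xs) < 2) stop("odor_response_auc(): fewer than 2 samples in window")
  pracma::trapz(xs, ys)
}

#' Normalize CS odor responses to the novel-odor response
#'
#' Divides each conditioned-odor AUC by the novel-odor (e.g. IAA) AUC from
#' the same trial and fly, removing between-fly response-magnitude variance.
#' Flies whose novel-odor AUC is below `epsilon` (including negative values)
#' cannot be normalized; their ratios are returned as `NA` with a warning.
#'
#' @param auc_cs Numeric vector of conditioned-odor AUCs.
#' @param auc_novel Numeric vector of matching novel-odor AUCs (recycled).
#' @param epsilon Exclusion threshold; defaults to `1e-6 * max(abs(auc))`
#'   over the inputs.
#' @return Numeric vector of normalized AUCs (`NA` where excluded).
#' @export
normalize_to_novel <- function(auc_cs, auc_novel, epsilon = NULL) {
  pair <- vctrs_recycle2(as.numeric(auc_cs), as.numeric(auc_novel))
  auc_cs <- pair[[1]]; auc_novel <- pair[[2]]
  if (is.null(epsilon)) {
    epsilon <- 1e-6 * max(abs(c(auc_cs, auc_novel)), na.rm = TRUE)
  }
  bad <- is.na(auc_novel) | auc_novel < epsilon
  if (any(bad)) {
    warning("normalize_to_novel(): ", sum(bad),
            " trial(s) with novel-odor AUC below epsilon excluded")
  }
  out <- auc_cs / auc_novel
  out[bad] <- NA_real_
  out
}

#' Normality-gated paired cohort test
#'
#' Compares per-fly paired CS+ and CS- values the way imaging cohorts are
#' analyzed: a Shapiro-Wilk test on the paired differences (alpha = 0.05)
#' gates the choice between a paired t test (differences consistent with
#' normality) and a Wilcoxon matched-pairs signed-rank test.
#'
#' @param cs_plus,cs_minus Equal-length paired numeric vectors, `n >= 5`.
#' @param alpha Normality-gate level (default 0.05).
#' @return A `paired_cohort` object with fields `n`, `test_used`,
#'   `statistic`, `p_value`, `pairs` (tibble) and `summary` (boxplot
#'   quartiles/median/min/max per condition). See [tidy()] / [glance()].
#' @export
paired_group_test <- function(cs_plus, cs_minus, alpha = 0.05) {
  cs_plus <- as.numeric(cs_plus); cs_minus <- as.numeric(cs_minus)
  if (length(cs_plus) != length(cs_minus)) {
    stop("paired_group_test(): unequal pair lengths")
  }
  keep <- !(is.na(cs_plus) | is.na(cs_minus))
  cs_plus <- cs_plus[keep]; cs_minus <- cs_minus[keep]
  n <- length(cs_plus)
  if (n < 5) stop("paired_group_test(): need at least 5 complete pairs, got ", n)
  d <- cs_plus - cs_minus
  if (all(d == 0)) {
    test_used <- "degenerate"; statistic <- 0; p <- 1
  } else if (stats::sd(d) == 0) {
    # identical nonzero shift in every fly: direction certain
    test_used <- "degenerate"; statistic <- sign(d[1]) * Inf; p <- 0
  } else {
    sw_p <- stats::shapiro.test(d)$p.value
    if (sw_p > alpha) {
      tt <- stats::t.test(cs_plus, cs_minus, paired = TRUE)
      test_used <- "paired t"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(cs_plus, cs_minus, paired = TRUE,
                                                exact = FALSE, correct = TRUE))
      test_used <- "Wilcoxon signed-rank"
      statistic <- unname(wt$statistic); p <- wt$p.value
    }
  }
  box <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(q25 = q[1], median = q[2], q75 = q[3], min = min(v), max = max(v))
  }
  out <- list(
    n = n, test_used = test_used, statistic = statistic, p_value = p,
    pairs = tibble::tibble(fly = seq_len(n), cs_plus = cs_plus,
                           cs_minus = cs_minus, difference = d),
    summary = dplyr::bind_rows(
      dplyr::mutate(box(cs_plus), condition = "CS+", .before = 1),
      dplyr::mutate(box(cs_minus), condition = "CS-", .before = 1)))
  class(out) <- "paired_cohort"
  out
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("<paired_cohort> n = ", x$n, ", ", x$test_used,
      sprintf(": statistic = %.4g, p = %.4g\n", x$statistic, x$p_value), sep = "")
  print(x$summary)
  invisible(x)
}

#' Optogenetically evoked response
#'
#' Compares mean dF/F0 in the 1 s before stimulation onset with the 1 s after
#' it, per preparation, and tests the cohort with a paired t test.
#'
#' @param dff_traces Tibble with columns `fly_id`, `time_s`, `dff` (e.g. from
#'   [compute_dff()] with the `"first_9s"` baseline).
#' @param stim_onset_s Stimulation onset (s); every preparation must have at
#'   least 1 s of record on each side.
#' @return An `optogenetic_result`: per-preparation pre/post means, cohort
#'   `statistic` and `p_value`.
#' @export
optogenetic_response <- function(dff_traces, stim_onset_s) {
  stopifnot(all(c("fly_id", "time_s", "dff") %in% names(dff_traces)))
  per <- dff_traces |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::group_map(function(tr, key) {
      if (min(tr$time_s) > stim_onset_s - 1 || max(tr$time_s) < stim_onset_s + 1 - 1e-9) {
        stop("optogenetic_response(): preparation ", key$fly_id,
             " lacks 1 s of record on each side of onset")
      }
      pre <- tr$dff[tr$time_s >= stim_onset_s - 1 & tr$time_s < stim_onset_s]
      post <- tr$dff[tr$time_s >= stim_onset_s & tr$time_s < stim_onset_s + 1]
      tibble::tibble(fly_id = key$fly_id, pre_mean = mean(pre), post_mean = mean(post))
    }) |>
    dplyr::bind_rows()
  d <- per$post_mean - per$pre_mean
  if (all(d == 0)) {
    statistic <- 0; p <- 1; test_used <- "degenerate"
  } else {
    tt <- stats::t.test(per$post_mean, per$pre_mean, paired = TRUE)
    statistic <- unname(tt$statistic); p <- tt$p.value; test_used <- "paired t"
  }
  out <- list(per_preparation = per, n = nrow(per), test_used = test_used,
              statistic = statistic, p_value = p)
  class(out) <- "optogenetic_result"
  out
}

#' @export
print.optogenetic_result <- function(x, ...) {
  cat("<optogenetic_result> n = ", x$n, ", ", x$test_used,
      sprintf(": statistic = %.4g, p = %.4g\n", x$statistic, x$p_value), sep = "")
  invisible(x)
}

#' Per-fly odor-response quantification pipeline
#'
#' Runs the full imaging quantification for a cohort: for every fly and every
#' odor epoch, dF/F0 with the 2-s pre-odor baseline, trapezoidal AUC over the
#' odor window, then normalization of each odor's AUC by the fly's novel-odor
#' AUC from the same trial.
#'
#' @param traces Long tibble: `fly_id`, `time_s`, `f`.
#' @param epochs Epoch tibble: `label`, `onset_s`, `duration_s`; must contain
#'   one `novel_label` epoch.
#' @param integrand Passed to [odor_response_auc()].
#' @param novel_label Label of the normalizing odor epoch (default `"novel"`).
#' @param epsilon Passed to [normalize_to_novel()].
#' @return Tibble `fly_id`, `odor`, `auc`, `normalized_auc` (wide per odor via
#'   `tidyr::pivot_wider()` if needed).
#' @export
odor_response_table <- function(traces, epochs, integrand = c("f_over_f0", "dff"),
                                novel_label = "novel", epsilon = NULL) {
  integrand <- match.arg(integrand)
  stopifnot(all(c("fly_id", "time_s", "f") %in% names(traces)),
            all(c("label", "onset_s", "duration_s") %in% names(epochs)))
  odors <- epochs[!epochs$label %in% c("shock", "light"), ]
  if (!novel_label %in% odors$label) {
    stop("odor_response_table(): no '", novel_label, "' epoch to normalize by")
  }
  per <- traces |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::group_map(function(tr, key) {
      aucs <- vapply(seq_len(nrow(odors)), function(i) {
        dff <- compute_dff(tr, "pre_odor_2s", onset_s = odors$onset_s[i])
        odor_response_auc(dff, odors$onset_s[i], odors$duration_s[i], integrand)
      }, numeric(1))
      tibble::tibble(fly_id = key$fly_id, odor = odors$label, auc = aucs)
    }) |>
    dplyr::bind_rows()
  novel <- per[per$odor == novel_label, c("fly_id", "auc")]
  names(novel)[2] <- "auc_novel"
  out <- dplyr::left_join(per, novel, by = "fly_id")
  out$normalized_auc <- normalize_to_novel(out$auc, out$auc_novel, epsilon)
  out$auc_novel <- NULL
  out
}
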