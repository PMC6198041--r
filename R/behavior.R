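#' T-maze performance index
#'
#' PI = (flies in the CS+ arm - flies in the CS- arm) / total flies. Negative
#' values indicate learned avoidance of the shock-paired odor. Non-choosing
#' flies count toward the denominator by default.
#'
#' @param counts Data frame with columns `n_csplus_arm`, `n_csminus_arm` and
#'   optionally `n_nonchoosers` (default 0); one row per group/replicate.
#' @param include_nonchoosers Include non-choosers in the total (default
#'   `TRUE`).
#' @return The input as a tibble with an added `pi` column.
#' @examples
#' performance_index(data.frame(n_csplus_arm = 30, n_csminus_arm = 70))
#' @export
performance_index <- function(counts, include_nonchoosers = TRUE) {
  stopifnot(is.data.frame(counts),
            all(c("n_csplus_arm", "n_csminus_arm") %in% names(counts)))
  out <- tibble::as_tibble(counts)
  if (!"n_nonchoosers" %in% names(out)) out$n_nonchoosers <- 0L
  neg <- out$n_csplus_arm < 0 | out$n_csminus_arm < 0 | out$n_nonchoosers < 0
  if (any(neg, na.rm = TRUE)) stop("performance_index(): negative counts")
  total <- out$n_csplus_arm + out$n_csminus_arm +
    if (include_nonchoosers) out$n_nonchoosers else 0L
  if (any(total == 0)) stop("performance_index(): zero total flies")
  out$pi <- (out$n_csplus_arm - out$n_csminus_arm) / total
  out
}

#' Average reciprocally trained groups
#'
#' One experimental n is the mean performance of two groups trained with the
#' odors swapped (reciprocal design), cancelling innate odor bias.
#'
#' @param pi_a,pi_b Performance indices of the two reciprocal groups
#'   (vectorized).
#' @return Tibble with columns `pi` (the mean) and `reciprocal = TRUE`.
#' @export
reciprocal_score <- function(pi_a, pi_b) {
  pair <- vctrs_recycle2(as.numeric(pi_a), as.numeric(pi_b))
  if (any(abs(c(pair[[1]], pair[[2]])) > 1, na.rm = TRUE)) {
    stop("reciprocal_score(): |pi| > 1")
  }
  tibble::tibble(pi = (pair[[1]] + pair[[2]]) / 2, reciprocal = TRUE)
}

#' Read a T-maze count table
#'
#' @param path CSV with columns `group`, `replicate`, `n_csplus_arm`,
#'   `n_csminus_arm`, optional `n_nonchoosers`.
#' @return Tibble.
#' @export
read_tmaze_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "n_csplus_arm", "n_csminus_arm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("read_tmaze_counts(): missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

# ---- Protocol timelines -----------------------------------------------------

#' Protocol phase constructors
#'
#' Building blocks for conditioning protocols, mirroring the standard
#' aversive T-maze regimen: a training trial pairs 1 min of the CS+ odor with
#' twelve 90 V electric shocks at 5 s intervals (first shock 1.2 s after odor
#' onset), followed by 45 s of clean air and 1 min of the CS- odor alone.
#' Re-exposure presents the CS+ (or CS-) without shock for a number of trials
#' separated by an inter-trial interval (ITI, measured from the end of one
#' trial to the start of the next). A test phase offers the choice between
#' the two odors.
#'
#' @param odor_duration_s Odor presentation length (s).
#' @param n_shocks,shock_voltage,shock_interval_s,first_shock_delay_s Shock
#'   train parameters.
#' @param air_gap_s Clean air between CS+ offset and CS- onset (s).
#' @param n_trials,iti_s Re-exposure trial count and end-to-start gap (s).
#' @param odor Which odor is re-exposed (`"CS+"` or `"CS-"`).
#' @param duration_s Phase duration (s).
#' @param temperature_c Optional temperature annotation for a phase.
#' @return A phase spec list for [build_protocol()].
#' @export
phase_training <- function(odor_duration_s = 60, n_shocks = 12,
                           shock_voltage = 90, shock_interval_s = 5,
                           first_shock_delay_s = 1.2, air_gap_s = 45) {
  list(type = "train", odor_duration_s = odor_duration_s, n_shocks = n_shocks,
       shock_voltage = shock_voltage, shock_interval_s = shock_interval_s,
       first_shock_delay_s = first_shock_delay_s, air_gap_s = air_gap_s)
}

#' @rdname phase_training
#' @export
phase_reexposure <- function(n_trials = 2, iti_s = 900, odor = "CS+",
                             odor_duration_s = 60) {
  list(type = "reexposure", n_trials = n_trials, iti_s = iti_s, odor = odor,
       odor_duration_s = odor_duration_s)
}

#' @rdname phase_training
#' @export
phase_rest <- function(duration_s = 1800, temperature_c = NULL) {
  list(type = "rest", duration_s = duration_s, temperature_c = temperature_c)
}

#' @rdname phase_training
#' @export
phase_test <- function(duration_s = 120) {
  list(type = "test", duration_s = duration_s)
}

#' @rdname phase_training
#' @export
phase_retrain <- function(...) {
  out <- phase_training(...)
  out$type <- "retrain"
  out
}

#' Build a protocol timeline
#'
#' Expands an ordered list of phase specs into a deterministic event table.
#' Phases run back to back; within a training phase the CS+ odor starts at
#' phase onset, shock k fires at `first_shock_delay_s + (k-1) *
#' shock_interval_s` after CS+ onset (so the default train of 12 ends 56.2 s
#' in), and the CS- odor starts at CS+ offset plus the air gap. Within a
#' re-exposure phase, trial i starts at `(i-1) * (odor_duration_s + iti_s)`.
#'
#' @param phases List of phase specs from [phase_training()] etc., in order.
#' @return A `protocol_timeline` tibble: `phase`, `phase_index`, `channel`
#'   (`odor`/`shock`/`temperature`/`annotation`), `label`, `onset_s`,
#'   `duration_s`, `value` (shock voltage or temperature; `NA` otherwise).
#' @examples
#' tl <- build_protocol(list(phase_training(), phase_rest(1800),
#'                           phase_reexposure(n_trials = 2, iti_s = 900),
#'                           phase_rest(1800), phase_test()))
#' sum(tl$channel == "shock")
#' @export
build_protocol <- function(phases) {
  if (!is.list(phases) || length(phases) == 0) stop("build_protocol(): no phases")
  if (!is.null(phases$type)) phases <- list(phases) # single phase passed bare
  events <- list()
  t0 <- 0
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    if (is.null(ph$type)) stop("build_protocol(): phase ", i, " has no type")
    add <- function(channel, label, onset, duration, value = NA_real_) {
      events[[length(events) + 1]] <<- tibble::tibble(
        phase = ph$type, phase_index = i, channel = channel, label = label,
        onset_s = onset, duration_s = duration, value = value)
    }
    if (ph$type %in% c("train", "retrain")) {
      stopifnot(ph$odor_duration_s > 0)
      last_shock <- ph$first_shock_delay_s + (ph$n_shocks - 1) * ph$shock_interval_s
      if (ph$n_shocks > 0 && last_shock > ph$odor_duration_s) {
        stop("build_protocol(): shock train (last shock at ",
             format(last_shock), " s) exceeds the ", ph$odor_duration_s,
             " s CS+ window")
      }
      add("odor", "CS+", t0, ph$odor_duration_s)
      for (k in seq_len(ph$n_shocks)) {
        add("shock", "shock", t0 + ph$first_shock_delay_s + (k - 1) * ph$shock_interval_s,
            0, ph$shock_voltage)
      }
      cs_minus_on <- t0 + ph$odor_duration_s + ph$air_gap_s
      add("odor", "CS-", cs_minus_on, ph$odor_duration_s)
      t0 <- cs_minus_on + ph$odor_duration_s
    } else if (ph$type == "reexposure") {
      stopifnot(ph$n_trials >= 1, ph$iti_s >= 0, ph$odor_duration_s > 0)
      for (k in seq_len(ph$n_trials)) {
        add("odor", ph$odor, t0 + (k - 1) * (ph$odor_duration_s + ph$iti_s),
            ph$odor_duration_s)
      }
      t0 <- t0 + ph$n_trials * ph$odor_duration_s + (ph$n_trials - 1) * ph$iti_s
    } else if (ph$type == "rest") {
      stopifnot(ph$duration_s > 0)
      add("annotation", "rest", t0, ph$duration_s)
      if (!is.null(ph$temperature_c)) {
        add("temperature", "temperature", t0, ph$duration_s, ph$temperature_c)
      }
      t0 <- t0 + ph$duration_s
    } else if (ph$type == "test") {
      stopifnot(ph$duration_s > 0)
      add("annotation", "test", t0, ph$duration_s)
      t0 <- t0 + ph$duration_s
    } else {
      stop("build_protocol(): unknown phase type '", ph$type, "'")
    }
  }
  out <- dplyr::bind_rows(events)
  # odor epochs must not overlap
  od <- out[out$channel == "odor", ]
  if (nrow(od) > 1) {
    od <- od[order(od$onset_s), ]
    if (any(od$onset_s[-1] < (od$onset_s + od$duration_s)[-nrow(od)] - 1e-9)) {
      stop("build_protocol(): overlapping odor epochs")
    }
  }
  class(out) <- c("protocol_timeline", class(out))
  out
}

#' Serialize / read a protocol timeline
#'
#' @param timeline A `protocol_timeline` tibble.
#' @param path JSON path.
#' @return `read_timeline()` returns the timeline tibble.
#' @export
write_timeline <- function(timeline, path) {
  jsonlite::write_json(tibble::as_tibble(timeline), path,
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  df <- tibble::as_tibble(jsonlite::fromJSON(path))
  df$phase_index <- as.integer(df$phase_index)
  df$value <- as.numeric(df$value)
  class(df) <- c("protocol_timeline", class(df))
  df
}

#' Compare performance across experimental groups
#'
#' Two groups are compared with an unpaired two-sided t test; three or more
#' with a one-way ANOVA followed by Tukey's multiple-comparisons test.
#'
#' @param scores Data frame with a grouping column and a score column.
#' @param group_col,value_col Column names (defaults `"group"`, `"pi"`).
#' @return A `group_comparison` object: `test_used`, `statistic`, `p_value`,
#'   `group_summary` tibble, and for ANOVA a `pairwise` Tukey table. See
#'   [tidy()] / [glance()].
#' @export
group_compare <- function(scores, group_col = "group", value_col = "pi") {
  stopifnot(is.data.frame(scores),
            all(c(group_col, value_col) %in% names(scores)))
  g <- factor(scores[[group_col]])
  v <- as.numeric(scores[[value_col]])
  keep <- !is.na(v) & !is.na(g)
  g <- droplevels(g[keep]); v <- v[keep]
  sizes <- table(g)
  if (length(sizes) < 2) stop("group_compare(): need at least 2 groups")
  if (any(sizes < 3)) {
    stop("group_compare(): every group needs n >= 3 (",
         paste(names(sizes)[sizes < 3], collapse = ", "), ")")
  }
  summary_tbl <- tibble::tibble(group = names(sizes), n = as.integer(sizes)) |>
    dplyr::mutate(mean = tapply(v, g, mean)[.data$group],
                  sd = tapply(v, g, stats::sd)[.data$group])
  if (length(sizes) == 2) {
    lv <- levels(g)
    tt <- stats::t.test(v[g == lv[1]], v[g == lv[2]], var.equal = TRUE)
    out <- list(test_used = "unpaired t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                group_summary = summary_tbl, pairwise = NULL)
  } else {
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    out <- list(test_used = "one-way ANOVA + Tukey",
                statistic = an$`F value`[1], df = an$Df[1:2],
                p_value = an$`Pr(>F)`[1],
                group_summary = summary_tbl,
                pairwise = tibble::tibble(
                  contrast = rownames(tk), estimate = tk[, "diff"],
                  conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                  p_adj = tk[, "p adj"]))
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test_used,
      sprintf(": statistic = %.4g, p = %.4g\n", x$statistic, x$p_value), sep = "")
  print(x$group_summary)
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}
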