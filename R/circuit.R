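#' Compartmentalized KC-to-MBON circuit state
#'
#' Rate-based model of the mushroom-body output network underlying aversive
#' memory and its extinction. Sparse Kenyon-cell (KC) odor patterns drive
#' four mushroom-body output channels through compartment-specific weight
#' vectors, initialized at 1 (a balanced network that promotes no directed
#' behavior): `gamma1pedc` (MVP2, approach), `gamma5` (M6, avoidance),
#' `betap2` (M4b', avoidance) and `approach_other` (a lumped second approach
#' channel). MVP2 inhibits the avoidance MBONs in a placement-dependent way:
#' divisively (shunting at the dendritic root) onto M6 and subtractively
#' (distal boutons) onto M4b'. Reward-coding gamma5 dopaminergic neurons
#' (DANs) receive recurrent drive from the combined M4/M6 output and gate
#' depression of CS+-active KC inputs to M6 during odor re-exposure.
#'
#' All quantitative parameters are model choices (the biology fixes only the
#' sign structure); `eta_ext` is calibrated at construction so that
#' `calibrate_trials` unreinforced CS+ re-exposures bring the M6 axonal CS+
#' response back to the CS- level.
#'
#' @param n_kc Number of Kenyon cells (default 200).
#' @param n_active Active KCs per odor (default 15, ~7.5% sparseness).
#' @param eta_train Per-trial depression rate for shock-paired training.
#' @param eta_ext Per-trial depression rate for DAN-gated extinction;
#'   `NULL` (default) calibrates it from the other parameters.
#' @param calibrate_trials Number of re-exposure trials the calibration
#'   assumes (default 2, the standard spaced protocol).
#' @param g_shunt Divisive MVP2-to-M6 inhibition gain.
#' @param s_sub Subtractive MVP2-to-M4b' inhibition gain.
#' @param dan_gain Gain from summed M4/M6 axonal output to gamma5 DAN drive.
#' @param dan_threshold gamma5 DAN drive above which extinction plasticity is
#'   recruited; sits between the naive and the post-training CS+ drive.
#' @param w_min Weight floor.
#' @param epsilon Regularizer in the model performance index.
#' @return A `circuit_state` object.
#' @export
circuit_state <- function(n_kc = 200, n_active = 15, eta_train = 0.2,
                          eta_ext = NULL, calibrate_trials = 2,
                          g_shunt = 0.5, s_sub = 0.3, dan_gain = 1,
                          dan_threshold = 1.42, w_min = 0.05,
                          epsilon = 1e-6) {
  stopifnot(n_kc >= 2, n_active >= 1, n_active <= n_kc,
            eta_train > 0, eta_train <= 1, g_shunt >= 0, s_sub >= 0,
            dan_gain >= 0, w_min >= 0, w_min < 1)
  if (is.null(eta_ext)) {
    # after training, mvp2(CS+) = 1 - eta_train while mvp2(CS-) = 1; the M6
    # shunt therefore releases the CS+ response. Choose eta_ext so that
    # calibrate_trials extinction updates shrink the CS+ dendritic drive by
    # exactly the released fraction, re-equalizing the axonal responses.
    target <- (1 + g_shunt * (1 - eta_train)) / (1 + g_shunt)
    eta_ext <- 1 - target^(1 / calibrate_trials)
  }
  stopifnot(eta_ext >= 0, eta_ext <= 1)
  comps <- c("gamma1pedc", "gamma5", "betap2", "approach_other")
  st <- list(
    n_kc = as.integer(n_kc), n_active = as.integer(n_active),
    weights = stats::setNames(rep(list(rep(1, n_kc)), length(comps)), comps),
    eta_train = eta_train, eta_ext = eta_ext,
    g_shunt = g_shunt, s_sub = s_sub, dan_gain = dan_gain,
    dan_threshold = dan_threshold, w_min = w_min, epsilon = epsilon)
  class(st) <- "circuit_state"
  st
}

#' @export
print.circuit_state <- function(x, ...) {
  cat("<circuit_state> ", x$n_kc, " KCs (", x$n_active, " active/odor)\n", sep = "")
  cat(sprintf("  eta_train %.3f, eta_ext %.4f, g_shunt %.2f, s_sub %.2f, dan_threshold %.2f\n",
              x$eta_train, x$eta_ext, x$g_shunt, x$s_sub, x$dan_threshold))
  for (cmp in names(x$weights)) {
    w <- x$weights[[cmp]]
    cat(sprintf("  w_%s: mean %.3f (min %.3f)\n", cmp, mean(w), min(w)))
  }
  invisible(x)
}

#' Sparse KC odor patterns
#'
#' `make_odor()` builds one binary KC pattern; `odor_pair()` draws the CS+
#' and CS- patterns for a protocol with a controlled number of shared active
#' KCs (default disjoint, satisfying the requirement that protocol odors
#' differ in at least half of their active cells).
#'
#' @param state A `circuit_state` (fixes `n_kc` and default `n_active`).
#' @param active Integer indices of active KCs, or `NULL` to sample.
#' @param label Odor label.
#' @param seed Seed for sampling (local to the call).
#' @param overlap Number of active KCs shared between the pair.
#' @return `make_odor()`: an `odor_pattern` (list with `kc` binary vector and
#'   `label`); `odor_pair()`: named list of two patterns.
#' @export
make_odor <- function(state, active = NULL, label = "odor", seed = NULL) {
  if (is.null(active)) {
    active <- with_local_seed(seed, sample.int(state$n_kc, state$n_active))
  }
  active <- as.integer(active)
  stopifnot(length(active) >= 1, all(active >= 1), all(active <= state$n_kc),
            !anyDuplicated(active))
  kc <- integer(state$n_kc)
  kc[active] <- 1L
  structure(list(kc = kc, label = label), class = "odor_pattern")
}

#' @rdname make_odor
#' @export
odor_pair <- function(state, seed = NULL, overlap = 0) {
  n <- state$n_active
  stopifnot(overlap >= 0, overlap <= n / 2, 2 * n - overlap <= state$n_kc)
  ids <- with_local_seed(seed, sample.int(state$n_kc, 2 * n - overlap))
  a <- ids[seq_len(n)]
  b <- c(ids[seq_len(overlap)], ids[(n + 1):(2 * n - overlap)])
  list(cs_plus = make_odor(state, a, "CS+"),
       cs_minus = make_odor(state, b, "CS-"))
}

#' Network response to an odor
#'
#' Dendritic drive in each compartment is the mean KC-to-MBON weight over the
#' odor's active KCs (so a naive network responds identically to every odor).
#' MVP2 output equals its dendritic drive; the M6 axon is shunted divisively
#' by MVP2 (`m6_dendrite / (1 + g_shunt * mvp2)`), the M4b' axon subtractively
#' (`max(0, m4_dendrite - s_sub * mvp2)`). The gamma5 DAN drive is
#' `dan_gain * (m6_axon + m4_axon)` and the behavioral valence is approach
#' minus avoidance drive.
#'
#' @param state A `circuit_state`.
#' @param odor An `odor_pattern`.
#' @return One-row tibble: `odor`, `mvp2`, `m6_dendrite`, `m6_axon`,
#'   `m4_dendrite`, `m4_axon`, `approach_other`, `dan_gamma5`, `valence`.
#' @export
respond <- function(state, odor) {
  stopifnot(inherits(state, "circuit_state"), inherits(odor, "odor_pattern"))
  act <- which(odor$kc == 1L)
  drive <- function(cmp) mean(state$weights[[cmp]][act])
  mvp2 <- drive("gamma1pedc")
  m6_d <- drive("gamma5")
  m4_d <- drive("betap2")
  other <- drive("approach_other")
  m6_a <- m6_d / (1 + state$g_shunt * mvp2)
  m4_a <- max(0, m4_d - state$s_sub * mvp2)
  tibble::tibble(
    odor = odor$label, mvp2 = mvp2, m6_dendrite = m6_d, m6_axon = m6_a,
    m4_dendrite = m4_d, m4_axon = m4_a, approach_other = other,
    dan_gamma5 = state$dan_gain * (m6_a + m4_a),
    valence = (mvp2 + other) - (m6_a + m4_a))
}

#' Apply compartment-restricted, odor-specific synaptic depression
#'
#' Coincidence of an odor with dopamine release in a compartment depresses
#' exactly the weights of that odor's active KCs in exactly the listed
#' compartments: `w <- max(w_min, w * (1 - eta))`. All other weights are
#' untouched.
#'
#' @param state A `circuit_state`.
#' @param odor An `odor_pattern`.
#' @param compartments Compartments whose DANs are active, subset of
#'   `names(state$weights)`.
#' @param eta Depression rate; defaults to `state$eta_train`.
#' @return The updated `circuit_state`.
#' @export
apply_plasticity <- function(state, odor, compartments, eta = NULL) {
  stopifnot(inherits(state, "circuit_state"), inherits(odor, "odor_pattern"))
  if (is.null(eta)) eta <- state$eta_train
  stopifnot(eta >= 0, eta <= 1)
  unknown <- setdiff(compartments, names(state$weights))
  if (length(unknown) > 0) {
    stop("apply_plasticity(): unknown compartment(s): ",
         paste(unknown, collapse = ", "))
  }
  act <- which(odor$kc == 1L)
  for (cmp in compartments) {
    w <- state$weights[[cmp]]
    w[act] <- pmax(state$w_min, w[act] * (1 - eta))
    state$weights[[cmp]] <- w
  }
  state
}

#' Model performance index for an odor pair
#'
#' `(V(CS+) - V(CS-)) / (|V(CS+)| + |V(CS-)| + epsilon)` on the valences
#' returned by [respond()]; negative values mean the model avoids the CS+.
#'
#' @param state A `circuit_state`.
#' @param odor_plus,odor_minus `odor_pattern`s.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
model_pi <- function(state, odor_plus, odor_minus) {
  vp <- respond(state, odor_plus)$valence
  vm <- respond(state, odor_minus)$valence
  (vp - vm) / (abs(vp) + abs(vm) + state$epsilon)
}

circuit_blocks <- c("PAM_gamma5_DAN", "PPL1_DAN", "M4M6_output")

#' Run a conditioning / extinction protocol through the circuit model
#'
#' Discrete-trial dynamics, one plasticity update per trial:
#' * training pairs the CS+ with PPL1 DAN activation, depressing the
#'   CS+-active KC weights in `gamma1pedc` and `approach_other`
#'   (rate `eta_train`);
#' * each unreinforced CS+ re-exposure computes the recurrent gamma5 DAN
#'   drive from the current M4/M6 axonal CS+ response; when it exceeds
#'   `dan_threshold` (and is not blocked) it depresses the CS+-active KC
#'   weights in `gamma5` (rate `eta_ext`);
#' * the test phase reports the model performance index.
#'
#' Effector blocks silence circuit elements during specific phases:
#' `"PPL1_DAN"` (training reinforcement), `"PAM_gamma5_DAN"` (extinction
#' teaching signal) and `"M4M6_output"` (zeroes the recurrent DAN drive),
#' the latter two acting during re-exposure.
#'
#' @param state A `circuit_state`, normally naive.
#' @param protocol Either a `protocol_timeline` from [build_protocol()] (the
#'   training / re-exposure / retrain phases are read off it) or a list with
#'   fields `n_reexposures` (default 2) and `retrain` (default `FALSE`).
#' @param blocks Character vector drawn from
#'   `c("PAM_gamma5_DAN", "PPL1_DAN", "M4M6_output")`.
#' @param odors Optional list with `cs_plus` and `cs_minus` patterns;
#'   defaults to a disjoint [odor_pair()] drawn with `seed`.
#' @param seed Seed for odor sampling.
#' @return A `circuit_trajectory`: `responses` (per phase x odor response
#'   table), `pi` (per-phase model PI), `final_state`.
#' @export
run_protocol <- function(state, protocol = list(n_reexposures = 2, retrain = FALSE),
                         blocks = character(), odors = NULL, seed = NULL) {
  stopifnot(inherits(state, "circuit_state"))
  unknown <- setdiff(blocks, circuit_blocks)
  if (length(unknown) > 0) {
    stop("run_protocol(): unknown block(s): ", paste(unknown, collapse = ", "),
         " (use ", paste(circuit_blocks, collapse = ", "), ")")
  }
  if (inherits(protocol, "protocol_timeline")) {
    n_reexp <- sum(protocol$phase == "reexposure" & protocol$channel == "odor" &
                     protocol$label == "CS+")
    retrain <- any(protocol$phase == "retrain")
    has_train <- any(protocol$phase == "train")
  } else {
    n_reexp <- protocol$n_reexposures %||% 2
    retrain <- isTRUE(protocol$retrain)
    has_train <- !isFALSE(protocol$train %||% TRUE)
  }
  if (is.null(odors)) odors <- odor_pair(state, seed = seed)
  cs_plus <- odors$cs_plus; cs_minus <- odors$cs_minus

  responses <- list()
  pis <- list()
  snap <- function(phase, trial = NA_integer_) {
    responses[[length(responses) + 1]] <<- dplyr::bind_rows(
      respond(state, cs_plus), respond(state, cs_minus)) |>
      dplyr::mutate(phase = phase, trial = trial, .before = 1)
    pis[[length(pis) + 1]] <<- tibble::tibble(
      phase = phase, trial = trial,
      pi_model = model_pi(state, cs_plus, cs_minus))
  }
  snap("naive")
  train_once <- function() {
    if (!("PPL1_DAN" %in% blocks)) {
      state <<- apply_plasticity(state, cs_plus,
                                 c("gamma1pedc", "approach_other"),
                                 eta = state$eta_train)
    }
  }
  if (has_train) {
    train_once()
    snap("trained")
  }
  if (n_reexp > 0) {
    for (k in seq_len(n_reexp)) {
      resp <- respond(state, cs_plus)
      dan_drive <- if ("M4M6_output" %in% blocks) 0 else resp$dan_gamma5
      if (dan_drive > state$dan_threshold && !("PAM_gamma5_DAN" %in% blocks)) {
        state <- apply_plasticity(state, cs_plus, "gamma5", eta = state$eta_ext)
      }
      snap("reexposure", k)
    }
    snap("extinguished")
  }
  if (retrain) {
    train_once()
    snap("retrained")
  }
  snap("test")
  out <- list(responses = dplyr::bind_rows(responses),
              pi = dplyr::bind_rows(pis),
              final_state = state,
              blocks = blocks, n_reexposures = n_reexp, retrain = retrain)
  class(out) <- "circuit_trajectory"
  out
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat("<circuit_trajectory> ", x$n_reexposures, " re-exposure(s)",
      if (length(x$blocks)) paste0(", blocked: ", paste(x$blocks, collapse = ", ")),
      if (x$retrain) ", retrained", "\n", sep = "")
  print(x$pi)
  invisible(x)
}

#' Model PI under the canonical protocol scenarios
#'
#' Convenience wrapper running the four scenarios used to probe the
#' extinction circuit: train-test, train + spaced CS+ re-exposure + test,
#' re-exposure with the gamma5 DAN teaching signal blocked, and re-exposure
#' with M4/M6 output blocked; optionally retraining after extinction.
#'
#' @param state A naive `circuit_state`.
#' @param n_reexposures Re-exposure trials in the extinction scenarios.
#' @param seed Seed for the odor pair (shared across scenarios).
#' @return Tibble `scenario`, `pi_model`.
#' @export
scenario_table <- function(state = circuit_state(), n_reexposures = 2, seed = 1) {
  odors <- odor_pair(state, seed = seed)
  run_pi <- function(...) {
    tr <- run_protocol(state, odors = odors, ...)
    tr$pi$pi_model[tr$pi$phase == "test"]
  }
  tibble::tibble(
    scenario = c("trained", "extinguished", "block_gamma5_dan",
                 "block_m4m6_output", "retrained"),
    pi_model = c(
      run_pi(protocol = list(n_reexposures = 0)),
      run_pi(protocol = list(n_reexposures = n_reexposures)),
      run_pi(protocol = list(n_reexposures = n_reexposures),
             blocks = "PAM_gamma5_DAN"),
      run_pi(protocol = list(n_reexposures = n_reexposures),
             blocks = "M4M6_output"),
      run_pi(protocol = list(n_reexposures = n_reexposures, retrain = TRUE))))
}
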