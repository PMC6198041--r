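# Evaluate expr under a temporary RNG state: set.seed(seed) for the duration,
# restore the caller's stream afterwards. seed = NULL uses the ambient stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synapse-class placement spec for the skeleton generator
#'
#' @param name Class label, e.g. `"MVP2_input"`, `"KC_input"`, `"output"`.
#' @param n Number of sites to plant.
#' @param side `"post"` (site on the dendrite, this neuron postsynaptic) or
#'   `"pre"` (site on the axon, this neuron presynaptic).
#' @param dist Distance distribution over geodesic distance from the planted
#'   dendritic root (nm): `list(type = "uniform", min =, max =)`,
#'   `list(type = "gaussian", mean =, sd =)` or `list(type = "bimodal",
#'   mean1 =, sd1 =, mean2 =, sd2 =, prop1 =)`.
#' @return A class-spec list for [gen_skeleton()].
#' @export
synapse_class_spec <- function(name, n, side = c("post", "pre"),
                               dist = list(type = "uniform", min = 0, max = 10000)) {
  side <- match.arg(side)
  stopifnot(n >= 0, dist$type %in% c("uniform", "gaussian", "bimodal"))
  if (dist$type == "bimodal") {
    stopifnot(dist$prop1 > 0, dist$prop1 < 1, dist$sd1 > 0, dist$sd2 > 0)
  }
  if (dist$type == "gaussian") stopifnot(dist$sd > 0)
  list(name = name, n = as.integer(n), side = side, dist = dist)
}

sample_class_distances <- function(dist, n) {
  switch(dist$type,
         uniform = stats::runif(n, dist$min, dist$max),
         gaussian = stats::rnorm(n, dist$mean, dist$sd),
         bimodal = {
           from1 <- stats::runif(n) < dist$prop1
           ifelse(from1, stats::rnorm(n, dist$mean1, dist$sd1),
                  stats::rnorm(n, dist$mean2, dist$sd2))
         })
}

# Mutable node store used while growing a synthetic arbor.
new_node_store <- function() {
  env <- new.env(parent = emptyenv())
  env$node_id <- integer(); env$parent_id <- integer()
  env$x <- env$y <- env$z <- numeric()
  env$domain <- character(); env$dist_droot <- numeric()
  env$dir <- list()
  env
}

store_add <- function(st, parent_id, seg_len, domain, dist_droot, dir = NULL) {
  id <- length(st$node_id) + 1L
  if (is.na(parent_id)) {
    pos <- c(0, 0, 0); dir <- c(0, 0, 1)
  } else {
    p <- parent_id
    prev_dir <- st$dir[[p]]
    if (is.null(dir)) {
      dir <- 0.8 * prev_dir + 0.2 * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
    }
    pos <- c(st$x[p], st$y[p], st$z[p]) + seg_len * dir
  }
  st$node_id[id] <- id; st$parent_id[id] <- parent_id
  st$x[id] <- pos[1]; st$y[id] <- pos[2]; st$z[id] <- pos[3]
  st$domain[id] <- domain; st$dist_droot[id] <- dist_droot
  st$dir[[id]] <- dir
  id
}

rand_dir <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

seg_len_draw <- function(mean, sd) {
  max(0.1 * mean, stats::rnorm(1, mean, sd))
}

# Grow one domain ("dendrite"/"axon") off an origin node: k primary chains plus
# short side twigs. Returns rows of chain bookkeeping for later placement.
grow_domain <- function(st, origin_id, n_total, k_primary, branch_prob,
                        seg_mean, seg_sd, domain) {
  if (n_total < k_primary) k_primary <- max(1L, n_total)
  n_chain <- max(k_primary, ceiling(n_total * 0.75))
  n_chain <- min(n_chain, n_total)
  n_twig <- n_total - n_chain
  sizes <- rep(n_chain %/% k_primary, k_primary)
  extra <- n_chain %% k_primary
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chain_nodes <- list()
  for (ci in seq_len(k_primary)) {
    parent <- origin_id
    d <- st$dist_droot[origin_id]
    dir <- rand_dir()
    ids <- integer(sizes[ci])
    for (j in seq_len(sizes[ci])) {
      len <- seg_len_draw(seg_mean, seg_sd)
      d <- d + len
      parent <- store_add(st, parent, len, domain, d,
                          dir = if (j == 1) dir else NULL)
      ids[j] <- parent
    }
    chain_nodes[[ci]] <- ids
  }
  all_chain <- unlist(chain_nodes)
  if (n_twig > 0 && length(all_chain) > 0) {
    n_twigs <- max(1L, stats::rbinom(1, length(all_chain), branch_prob))
    n_twigs <- min(n_twigs, n_twig)
    alloc <- rep(n_twig %/% n_twigs, n_twigs)
    extra <- n_twig %% n_twigs
    if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
    for (tw in seq_len(n_twigs)) {
      base <- sample(all_chain, 1)
      parent <- base
      d <- st$dist_droot[base]
      dir <- rand_dir()
      for (j in seq_len(alloc[tw])) {
        len <- seg_len_draw(seg_mean, seg_sd)
        d <- d + len
        parent <- store_add(st, parent, len, domain, d,
                            dir = if (j == 1) dir else NULL)
      }
    }
  }
  chain_nodes
}

#' Generate a synthetic neuron skeleton with planted ground truth
#'
#' Builds a rooted tree emulating a traced arbor: a main neurite from the
#' soma to a planted dendritic root, where the neuron branches into primary
#' dendrites (plus side twigs) and a distal axon. Synapse classes are planted
#' at prescribed geodesic distances from the dendritic root: each sampled
#' target distance is realized at the domain node nearest to it along the
#' arbor (postsynaptic classes on the dendrite, presynaptic on the axon).
#' Targets falling outside the arbor's reach are resampled (with a summary
#' warning), failing after 100 attempts per site. Optional axonlets —
#' exclusively presynaptic twigs sprouting inside the dendritic field — can
#' be planted for the axonlet-extraction analysis.
#'
#' @param n_nodes Total nodes in the core arbor (axonlets add extra nodes).
#' @param classes List of [synapse_class_spec()]s.
#' @param branch_prob Per-chain-node probability of sprouting a side twig.
#' @param seg_mean_nm,seg_sd_nm Segment-length distribution (nm).
#' @param dendritic_fraction Fraction of non-main-neurite nodes in the
#'   dendrite.
#' @param n_primary_dendrites,n_primary_axons Primary branches per domain.
#' @param main_neurite_nodes Nodes on the soma-to-dendritic-root neurite.
#' @param n_axonlets,axonlet_n_nodes,axonlet_synapses Planted axonlets.
#' @param tag_root Tag the planted dendritic root (`"dendritic_root"`), as a
#'   manual annotation would.
#' @param name Neuron name.
#' @param seed Seed (local to this call); identical arguments and seed give
#'   byte-identical output.
#' @return List with `skeleton` (a `neuron_skeleton`), `synapses` (connector
#'   table) and `truth` (planted dendritic root, per-node domains, per-site
#'   target and realized distances, axonlet roots).
#' @export
gen_skeleton <- function(n_nodes = 500, classes = list(),
                         branch_prob = 0.1, seg_mean_nm = 300, seg_sd_nm = 60,
                         dendritic_fraction = 0.6,
                         n_primary_dendrites = 4, n_primary_axons = 2,
                         main_neurite_nodes = 10,
                         n_axonlets = 0, axonlet_n_nodes = 4,
                         axonlet_synapses = 5,
                         tag_root = TRUE, name = "synthetic_neuron", seed = 1) {
  min_nodes <- main_neurite_nodes + n_primary_dendrites + n_primary_axons + 2
  if (n_nodes < min_nodes) {
    stop("gen_skeleton(): n_nodes = ", n_nodes, " too small to form a tree (need >= ",
         min_nodes, ")")
  }
  with_local_seed(seed, {
    st <- new_node_store()
    root <- store_add(st, NA_integer_, 0, "soma", NA_real_)
    parent <- root
    for (j in seq_len(main_neurite_nodes - 1)) {
      parent <- store_add(st, parent, seg_len_draw(seg_mean_nm, seg_sd_nm),
                          "main_neurite", NA_real_)
    }
    droot <- parent
    st$domain[droot] <- "dendritic_root"
    st$dist_droot[droot] <- 0
    rest <- n_nodes - main_neurite_nodes
    n_dend <- round(rest * dendritic_fraction)
    n_axon <- rest - n_dend
    dend_chains <- grow_domain(st, droot, n_dend, n_primary_dendrites,
                               branch_prob, seg_mean_nm, seg_sd_nm, "dendrite")
    grow_domain(st, droot, n_axon, n_primary_axons,
                branch_prob, seg_mean_nm, seg_sd_nm, "axon")

    # synapse placement by nearest geodesic distance within the domain
    syn <- list()
    connector <- 0L
    place_class <- function(cl) {
      cand <- which(st$domain == if (cl$side == "post") "dendrite" else "axon")
      if (length(cand) == 0) stop("gen_skeleton(): no '", cl$side,
                                  "' domain nodes to place class '", cl$name, "'")
      cand_d <- st$dist_droot[cand]
      dmax <- max(cand_d)
      rows <- vector("list", cl$n)
      n_resampled <- 0L
      for (i in seq_len(cl$n)) {
        target <- NA_real_
        for (attempt in seq_len(100)) {
          cand_target <- sample_class_distances(cl$dist, 1)
          if (cand_target >= 0 && cand_target <= dmax) {
            target <- cand_target
            break
          }
          n_resampled <- n_resampled + 1L
        }
        if (is.na(target)) {
          stop("gen_skeleton(): infeasible placement for class '", cl$name,
               "' after 100 attempts (arbor extent ", round(dmax), " nm)")
        }
        gaps <- abs(cand_d - target)
        node <- cand[which(gaps == min(gaps))][1] # candidates are id-ordered
        connector <<- connector + 1L
        rows[[i]] <- tibble::tibble(
          connector_id = connector, class = cl$name, side = cl$side,
          node_id = node, target_nm = target, realized_nm = st$dist_droot[node])
      }
      if (n_resampled > 0) {
        warning("gen_skeleton(): class '", cl$name, "': ", n_resampled,
                " target distance(s) outside the arbor resampled")
      }
      dplyr::bind_rows(rows)
    }
    truth_syn <- dplyr::bind_rows(lapply(classes, place_class))

    # axonlets: exclusively presynaptic twigs inside the dendritic field
    axonlet_roots <- integer(0)
    if (n_axonlets > 0) {
      post_nodes <- truth_syn$node_id[truth_syn$side == "post"]
      if (length(post_nodes) == 0) {
        stop("gen_skeleton(): planting axonlets requires postsynaptic classes")
      }
      # eligible attachment points: chain nodes with a postsynaptic site
      # strictly deeper in the same chain (so they sit inside the field)
      eligible <- integer(0)
      for (ids in dend_chains) {
        hit <- which(ids %in% post_nodes)
        if (length(hit) > 0 && max(hit) > 1) {
          eligible <- c(eligible, ids[seq_len(max(hit) - 1)])
        }
      }
      if (length(eligible) == 0) {
        stop("gen_skeleton(): no dendritic-field attachment point for axonlets")
      }
      for (a in seq_len(n_axonlets)) {
        base <- sample(eligible, 1)
        parent <- base
        d <- st$dist_droot[base]
        twig_ids <- integer(axonlet_n_nodes)
        dir <- rand_dir()
        for (j in seq_len(axonlet_n_nodes)) {
          len <- seg_len_draw(seg_mean_nm, seg_sd_nm)
          d <- d + len
          parent <- store_add(st, parent, len, "axonlet", d,
                              dir = if (j == 1) dir else NULL)
          twig_ids[j] <- parent
        }
        axonlet_roots <- c(axonlet_roots, twig_ids[1])
        site_nodes <- sample(twig_ids, axonlet_synapses, replace = TRUE)
        for (nd in site_nodes) {
          connector <- connector + 1L
          truth_syn <- dplyr::bind_rows(truth_syn, tibble::tibble(
            connector_id = connector, class = "axonlet_output", side = "pre",
            node_id = nd, target_nm = NA_real_, realized_nm = st$dist_droot[nd]))
        }
      }
    }

    n <- length(st$node_id)
    tags <- rep(list(character()), n)
    tags[[root]] <- "soma"
    if (tag_root) tags[[droot]] <- "dendritic_root"
    sk <- skeleton(tibble::tibble(
      node_id = st$node_id, parent_id = st$parent_id,
      x = st$x, y = st$y, z = st$z, radius = NA_real_, tags = tags),
      name = name)

    synapses <- if (nrow(truth_syn) > 0) {
      tibble::tibble(
        connector_id = truth_syn$connector_id,
        pre_neuron = ifelse(truth_syn$side == "pre", name,
                            sub("_input$", "", truth_syn$class)),
        pre_node = ifelse(truth_syn$side == "pre", truth_syn$node_id, NA_integer_),
        post_neuron = ifelse(truth_syn$side == "pre", "KC_partner", name),
        post_node = ifelse(truth_syn$side == "pre", NA_integer_, truth_syn$node_id))
    } else {
      tibble::tibble(connector_id = integer(), pre_neuron = character(),
                     pre_node = integer(), post_neuron = character(),
                     post_node = integer())
    }

    list(skeleton = sk,
         synapses = synapses,
         truth = list(
           dendritic_root = st$node_id[droot],
           domains = tibble::tibble(node_id = st$node_id, domain = st$domain),
           synapses = truth_syn,
           axonlet_roots = axonlet_roots,
           seed = seed))
  })
}

#' Write the generator's ground-truth sidecar as JSON
#'
#' @param truth The `truth` element returned by [gen_skeleton()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Random skeleton for property tests and oracles
#'
#' Uniform random recursive tree (node j attaches to a uniform earlier node)
#' with random 3-D segment geometry; no planted structure.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param seed Seed, local to the call.
#' @param seg_mean_nm Mean segment length.
#' @return A `neuron_skeleton`.
#' @export
gen_random_skeleton <- function(n_nodes, seed = 1, seg_mean_nm = 100) {
  stopifnot(n_nodes >= 2)
  with_local_seed(seed, {
    parent <- c(NA_integer_, vapply(2:n_nodes, function(j) {
      sample.int(j - 1L, 1)
    }, integer(1)))
    pos <- matrix(0, n_nodes, 3)
    for (j in 2:n_nodes) {
      pos[j, ] <- pos[parent[j], ] + rand_dir() * seg_len_draw(seg_mean_nm, seg_mean_nm / 4)
    }
    skeleton(tibble::tibble(node_id = seq_len(n_nodes), parent_id = parent,
                            x = pos[, 1], y = pos[, 2], z = pos[, 3]),
             name = paste0("random_", seed))
  })
}

#' Generate a synthetic imaging cohort with planted CS+ effects
#'
#' Emulates the post-training imaging session: each fly is sequentially
#' exposed to the CS+, the CS- and a novel odor (5 s each, 30 s of air
#' between odors) while fluorescence is sampled at 5.92 Hz. Responses follow
#' a difference-of-exponentials kernel scaled by a per-fly amplitude; the
#' CS+ amplitude is additionally scaled by `cs_plus_multiplier` (0.7 plants a
#' 30% depression, 1.3 a 30% potentiation). Noise is additive Gaussian on
#' the raw fluorescence.
#'
#' @param n_flies Flies in the cohort.
#' @param cs_plus_multiplier Planted CS+ effect (1 = none).
#' @param sampling_rate_hz Acquisition rate (default 5.92).
#' @param baseline_f Baseline fluorescence (a.u.).
#' @param peak_dff Peak response amplitude in dF/F0 units.
#' @param tau_rise_s,tau_decay_s Kernel time constants.
#' @param noise_sd Additive noise sd on F (a.u.).
#' @param fly_amp_sd Lognormal sd of the per-fly amplitude factor.
#' @param trial_amp_sd Lognormal sd of the per-odor (trial) amplitude factor
#'   (default 0: a fly's three odors share one amplitude).
#' @param air_s Air between odors (s).
#' @param odor_s Odor duration (s).
#' @param seed Seed, local to the call.
#' @return List with `traces` (tibble `fly_id`, `time_s`, `f`), `epochs`
#'   (CS+/CS-/novel onsets and durations) and `truth` (per-fly amplitudes and
#'   the planted multiplier).
#' @export
gen_imaging_cohort <- function(n_flies = 15, cs_plus_multiplier = 1,
                               sampling_rate_hz = 5.92, baseline_f = 100,
                               peak_dff = 0.8, tau_rise_s = 0.3, tau_decay_s = 4,
                               noise_sd = 3, fly_amp_sd = 0.2, trial_amp_sd = 0,
                               air_s = 30, odor_s = 5, seed = 1) {
  stopifnot(n_flies >= 1, cs_plus_multiplier > 0, sampling_rate_hz > 0,
            baseline_f > 0, noise_sd >= 0)
  odors <- c("CS+", "CS-", "novel")
  # onsets are snapped to the acquisition grid so every odor epoch samples the
  # response kernel in the same phase
  onsets <- air_s + (seq_along(odors) - 1) * (odor_s + air_s)
  onsets <- round(onsets * sampling_rate_hz) / sampling_rate_hz
  total_s <- air_s + length(odors) * (odor_s + air_s) - air_s + 10
  epochs <- tibble::tibble(label = odors, onset_s = onsets, duration_s = odor_s)
  tpk <- log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
    (tau_decay_s - tau_rise_s)
  kraw <- function(t) exp(-t / tau_decay_s) - exp(-t / tau_rise_s)
  # finite kernel support (shorter than the air gap) keeps successive odor
  # responses strictly non-overlapping; the residual tail is subtracted so the
  # kernel reaches zero continuously
  support_s <- air_s - odor_s
  ktail <- kraw(support_s)
  kernel <- function(t) {
    ifelse(t < 0 | t > support_s, 0,
           pmax(0, (kraw(t) - ktail) / (kraw(tpk) - ktail)))
  }
  t <- seq(0, total_s, by = 1 / sampling_rate_hz)
  with_local_seed(seed, {
    flies <- lapply(seq_len(n_flies), function(fly) {
      fly_factor <- exp(stats::rnorm(1, 0, fly_amp_sd))
      trial_factor <- exp(stats::rnorm(length(odors), 0, trial_amp_sd))
      amps <- peak_dff * fly_factor * trial_factor *
        ifelse(odors == "CS+", cs_plus_multiplier, 1)
      resp <- rowSums(vapply(seq_along(odors), function(i) {
        amps[i] * kernel(t - onsets[i])
      }, numeric(length(t))))
      f <- baseline_f * (1 + resp) + stats::rnorm(length(t), 0, noise_sd)
      list(trace = tibble::tibble(fly_id = fly, time_s = t, f = f),
           amps = tibble::tibble(fly_id = fly, odor = odors, amplitude = amps))
    })
    list(traces = dplyr::bind_rows(lapply(flies, `[[`, "trace")),
         epochs = epochs,
         truth = list(multiplier = cs_plus_multiplier,
                      amplitudes = dplyr::bind_rows(lapply(flies, `[[`, "amps")),
                      seed = seed))
  })
}

#' Generate binomial T-maze cohorts at a planted performance index
#'
#' Each fly independently chooses the CS+ arm with probability
#' `(1 + true_pi) / 2`, so the observed PI of a group is unbiased for
#' `true_pi` with binomial standard error `sqrt(1 - true_pi^2) / sqrt(n)`.
#'
#' @param true_pi Planted performance index in `[-1, 1]`.
#' @param n_flies Flies per group (> 0).
#' @param n_groups Number of independent groups.
#' @param seed Seed, local to the call.
#' @return Tibble `group`, `n_csplus_arm`, `n_csminus_arm`, `n_nonchoosers`.
#' @export
gen_tmaze_cohort <- function(true_pi = -0.4, n_flies = 100, n_groups = 1,
                             seed = 1) {
  if (abs(true_pi) > 1) stop("gen_tmaze_cohort(): |true_pi| > 1")
  if (n_flies <= 0) stop("gen_tmaze_cohort(): n_flies must be positive")
  stopifnot(n_groups >= 1)
  with_local_seed(seed, {
    plus <- stats::rbinom(n_groups, n_flies, (1 + true_pi) / 2)
    tibble::tibble(group = seq_len(n_groups),
                   n_csplus_arm = plus,
                   n_csminus_arm = as.integer(n_flies) - plus,
                   n_nonchoosers = 0L)
  })
}
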