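#' Read a synapse annotation table
#'
#' Connector-style table of directed synaptic contacts: each row is one
#' presynaptic site paired with one postsynaptic target. A connector with
#' several postsynaptic targets occupies several rows sharing `connector_id`.
#' Node ids may be `NA` for partners whose skeletons are not loaded.
#'
#' @param path CSV path with columns `connector_id`, `pre_neuron`, `pre_node`,
#'   `post_neuron`, `post_node`.
#' @return Tibble with those five columns, types normalized.
#' @export
read_synapses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("connector_id", "pre_neuron", "pre_node", "post_neuron", "post_node")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("read_synapses(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tibble::tibble(
    connector_id = as.integer(df$connector_id),
    pre_neuron = as.character(df$pre_neuron),
    pre_node = as.integer(df$pre_node),
    post_neuron = as.character(df$post_neuron),
    post_node = as.integer(df$post_node))
}

#' @rdname read_synapses
#' @param synapses Synapse tibble.
#' @export
write_synapses <- function(synapses, path) {
  utils::write.csv(synapses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Resolve a synapse-class label to (node ids on this skeleton):
#   "<partner>_input" -> post_node of rows post_neuron == neuron, pre_neuron == partner
#   "input"           -> all rows post_neuron == neuron
#   "output"          -> pre_node of rows pre_neuron == neuron
synapse_class_nodes <- function(synapses, neuron, synapse_class) {
  if (synapse_class == "output") {
    rows <- synapses$pre_neuron == neuron & !is.na(synapses$pre_node)
    return(synapses$pre_node[rows])
  }
  if (synapse_class == "input") {
    rows <- synapses$post_neuron == neuron & !is.na(synapses$post_node)
    return(synapses$post_node[rows])
  }
  if (grepl("_input$", synapse_class)) {
    partner <- sub("_input$", "", synapse_class)
    rows <- synapses$post_neuron == neuron & synapses$pre_neuron == partner &
      !is.na(synapses$post_node)
    return(synapses$post_node[rows])
  }
  stop("unknown synapse_class '", synapse_class,
       "': use 'output', 'input' or '<partner>_input'")
}

#' Geodesic distance profile of a synapse class
#'
#' One geodesic (along-the-arbor) distance to the dendritic root per synaptic
#' site of the class: postsynaptic nodes for input classes, presynaptic nodes
#' for outputs. This is the quantity behind proximal-vs-distal placement
#' comparisons such as inhibitory input localization on avoidance MBONs.
#'
#' @param skeleton A `neuron_skeleton`.
#' @param synapses Synapse table (see [read_synapses()]).
#' @param synapse_class `"output"`, `"input"`, or `"<partner>_input"` (e.g.
#'   `"MVP2_input"`, `"KC_input"`).
#' @param dendritic_root `node_id` of the dendritic root.
#' @return A `distance_profile` tibble with columns `neuron`, `synapse_class`,
#'   `node_id`, `distance_nm`; summary statistics via [glance()].
#' @export
distance_profile <- function(skeleton, synapses, synapse_class, dendritic_root) {
  neuron <- skeleton_name(skeleton)
  nodes <- synapse_class_nodes(synapses, neuron, synapse_class)
  if (length(nodes) == 0) {
    stop("distance_profile(): no sites of class '", synapse_class,
         "' on '", neuron, "'")
  }
  d <- geodesic_distance(skeleton, nodes, dendritic_root)
  out <- tibble::tibble(neuron = neuron, synapse_class = synapse_class,
                        node_id = as.integer(nodes), distance_nm = d)
  class(out) <- c("distance_profile", class(out))
  out
}

#' @method glance distance_profile
#' @export
glance.distance_profile <- function(x, ...) {
  q <- stats::quantile(x$distance_nm, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(neuron = x$neuron[1], synapse_class = x$synapse_class[1],
                 n = nrow(x), median_nm = q[2], q25_nm = q[1], q75_nm = q[3],
                 max_nm = max(x$distance_nm))
}

# ---- Gaussian / bimodal-Gaussian mixture selection --------------------------

# Log-likelihood of a 1-D Gaussian mixture.
gmm_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), .Machine$double.xmin)))
}

# EM for a k-component 1-D Gaussian mixture with deterministic initialization:
# component means start at evenly spaced quantiles (25th/75th for k = 2),
# shared sd at the pooled sd, equal weights.
gmm_em <- function(x, k, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  if (k == 1) {
    mu <- mean(x)
    sd_ <- stats::sd(x) * sqrt((n - 1) / n)
    ll <- gmm_loglik(x, 1, mu, sd_)
    return(list(k = 1, weights = 1, means = mu, sds = sd_, loglik = ll,
                n_params = 2, iterations = 0L))
  }
  probs <- seq_len(k) / (k + 1) # k = 2 -> 25th / 75th percentiles
  mu <- as.numeric(stats::quantile(x, probs, names = FALSE))
  sd_ <- rep(stats::sd(x) / k, k)
  w <- rep(1 / k, k)
  # component sds are floored at 5% of the pooled sd: geodesic distances are
  # realized on a discrete node grid, and without the floor EM can collapse a
  # component onto duplicated values (a likelihood singularity)
  sd_floor <- max(stats::sd(x) * 0.05, .Machine$double.eps)
  sd_ <- pmax(sd_, sd_floor)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step
    resp <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sd_[j]),
                   numeric(n))
    rs <- rowSums(resp)
    rs[rs <= 0] <- .Machine$double.xmin
    resp <- resp / rs
    # M step
    nk <- colSums(resp)
    nk[nk <= 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd_ <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sd_ <- pmax(sd_, sd_floor)
    ll <- gmm_loglik(x, w, mu, sd_)
    if (iter >= max_iter || abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(k = k, weights = w[ord], means = mu[ord], sds = sd_[ord], loglik = ll,
       n_params = 3 * k - 1, iterations = iter)
}

#' Fit a Gaussian vs bimodal-Gaussian model to a distance sample
#'
#' Fits one- and two-component Gaussian mixtures by expectation-maximization
#' (deterministic quantile-based initialization: component means start at the
#' 25th/75th percentiles) and selects the model with the smaller BIC. Used to
#' classify synapse-placement distributions along the dendritic field as
#' unimodal ("Gaussian") or bimodal ("bimodal Gaussian").
#'
#' @param distances Numeric vector of geodesic distances (nm), `n >= 10`.
#' @param seed Unused (the fit is deterministic); accepted so callers can
#'   thread one seed through an analysis uniformly.
#' @return A `mixture_fit` object: selected model label, per-component
#'   `weights`, `means`, `sds`, and the BIC of both candidates. [tidy()] gives
#'   the component table, [glance()] the model-level summary.
#' @export
fit_distance_distribution <- function(distances, seed = NULL) {
  x <- as.numeric(distances)
  if (anyNA(x)) stop("fit_distance_distribution(): NA distances")
  if (length(x) < 10) {
    stop("fit_distance_distribution(): insufficient sample (n = ", length(x),
         " < 10)")
  }
  if (stats::sd(x) == 0) stop("fit_distance_distribution(): zero variance")
  fits <- list(gmm_em(x, 1), gmm_em(x, 2))
  n <- length(x)
  bic <- vapply(fits, function(f) -2 * f$loglik + f$n_params * log(n), numeric(1))
  sel <- which.min(bic)
  out <- list(
    n = n,
    n_components = fits[[sel]]$k,
    weights = fits[[sel]]$weights,
    means = fits[[sel]]$means,
    sds = fits[[sel]]$sds,
    loglik = fits[[sel]]$loglik,
    bic = stats::setNames(bic, c("gaussian", "bimodal_gaussian")),
    selected_model = c("Gaussian", "bimodal Gaussian")[sel])
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", x$selected_model, " (n = ", x$n, ")\n", sep = "")
  cat("  BIC: 1-comp ", format(x$bic[1], digits = 6), ", 2-comp ",
      format(x$bic[2], digits = 6), "\n", sep = "")
  for (k in seq_len(x$n_components)) {
    cat(sprintf("  component %d: weight %.3f, mean %.1f, sd %.1f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  }
  invisible(x)
}

#' Compare proximal vs distal localization of two synapse classes
#'
#' Two-sided rank-sum (Mann-Whitney) test on the geodesic distance samples
#' plus the signed median difference `median(a) - median(b)`; a negative
#' difference means class `a` sits more proximally than class `b`.
#'
#' @param profile_a,profile_b `distance_profile` tibbles (or bare numeric
#'   distance vectors).
#' @return Tibble with `median_difference_nm`, `rank_statistic`, `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_localization <- function(profile_a, profile_b) {
  a <- if (is.data.frame(profile_a)) profile_a$distance_nm else as.numeric(profile_a)
  b <- if (is.data.frame(profile_b)) profile_b$distance_nm else as.numeric(profile_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("compare_localization(): empty distance sample")
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  tibble::tibble(
    median_difference_nm = stats::median(a) - stats::median(b),
    rank_statistic = unname(wt$statistic),
    p_value = if (length(a) == 1 && length(b) == 1) 1 else unname(wt$p.value),
    n_a = length(a), n_b = length(b))
}

#' Tracing detection rates
#'
#' Consensus skeleton tracing in serial-section EM finds almost all
#' presynapses but misses a fraction of postsynapses and occasionally marks a
#' false-positive postsynapse. The defaults are the published benchmark rates
#' for the tracing methodology: 99.8% of presynapses found, 91.7% of
#' postsynapses found, 2.2% false-positive postsynapses, negligible
#' false-positive presynapses.
#'
#' @param pre_found_rate,post_found_rate,post_false_positive_rate,pre_false_positive_rate
#'   Probabilities in `[0, 1]`.
#' @return A `detection_rates` list.
#' @export
detection_rates <- function(pre_found_rate = 0.998, post_found_rate = 0.917,
                            post_false_positive_rate = 0.022,
                            pre_false_positive_rate = 0) {
  r <- list(pre_found_rate = pre_found_rate, post_found_rate = post_found_rate,
            post_false_positive_rate = post_false_positive_rate,
            pre_false_positive_rate = pre_false_positive_rate)
  bad <- vapply(r, function(v) !is.numeric(v) || length(v) != 1 || v < 0 || v > 1,
                logical(1))
  if (any(bad)) {
    stop("detection_rates(): rates must be single values in [0, 1]: ",
         paste(names(r)[bad], collapse = ", "))
  }
  structure(r, class = "detection_rates")
}

round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Detection-rate-corrected synapse-count bounds
#'
#' Converts a found (annotated) synapse count into lower and upper bounds on
#' the true count. The lower bound discounts the found count by the
#' postsynaptic false-positive rate; the upper bound adds an estimate of
#' missed true synapses, `found * (1 - post_found_rate) * (1 -
#' post_false_positive_rate)`. Both are reported to one decimal
#' (half-away-from-zero). With the default rates, found counts of 17, 16 and
#' 47 give (16.6, 18.4), (15.6, 17.3) and (46.0, 50.8).
#'
#' @param found Non-negative integer count(s) of annotated synapses;
#'   vectorized.
#' @param rates A [detection_rates()] object.
#' @return Tibble with columns `found`, `lower`, `upper`.
#' @export
synapse_count_bounds <- function(found, rates = detection_rates()) {
  if (!inherits(rates, "detection_rates")) stop("rates must be detection_rates()")
  found <- as.numeric(found)
  if (any(is.na(found)) || any(found < 0) || any(found != floor(found))) {
    stop("synapse_count_bounds(): found must be non-negative integers")
  }
  fp <- rates$post_false_positive_rate
  miss <- 1 - rates$post_found_rate
  lower <- round_half_away(found * (1 - fp), 1)
  upper <- round_half_away(found * (1 + miss * (1 - fp)), 1)
  tibble::tibble(found = as.integer(found), lower = lower, upper = upper)
}

#' Directed connectivity table
#'
#' Counts synaptic contacts between named neurons: entry (i, j) is the number
#' of postsynaptic targets on neuron j whose presynaptic neuron is i. A
#' connector with several targets on the same neuron counts once per target.
#'
#' @param synapses Synapse table (see [read_synapses()]).
#' @param neurons Character vector of neuron names fixing row/column order;
#'   defaults to all names seen in the table. Names listed here but absent
#'   from the table get zero rows/columns; names in the table but not listed
#'   raise a warning and are dropped.
#' @return Integer matrix with `from` rows and `to` columns.
#' @export
connectivity_table <- function(synapses, neurons = NULL) {
  seen <- unique(c(synapses$pre_neuron, synapses$post_neuron))
  if (is.null(neurons)) {
    neurons <- sort(seen)
  } else {
    dangling <- setdiff(seen, neurons)
    if (length(dangling) > 0) {
      warning("connectivity_table(): neurons not in requested set dropped: ",
              paste(dangling, collapse = ", "))
    }
  }
  m <- matrix(0L, length(neurons), length(neurons),
              dimnames = list(from = neurons, to = neurons))
  keep <- synapses$pre_neuron %in% neurons & synapses$post_neuron %in% neurons
  if (any(keep)) {
    tab <- table(factor(synapses$pre_neuron[keep], levels = neurons),
                 factor(synapses$post_neuron[keep], levels = neurons))
    m[] <- as.integer(tab)
  }
  m
}

#' Topological dendrogram layout of an arbor
#'
#' Flattens a skeleton into the plane for dendrogram-style display: depth (y)
#' encodes topological distance from the root — neurite length is *not*
#' preserved — and leaves are spread along x in file order, internal nodes
#' centred over their children. The layout graph is isomorphic to the
#' skeleton (same parent-child edges). Synapse marks are carried along with
#' their nodes so input/output classes can be coloured.
#'
#' @param skeleton A `neuron_skeleton`.
#' @param marks Optional tibble with columns `node_id`, `mark` (class label),
#'   e.g. MVP2 inputs / KC inputs / outputs.
#' @return A `dendrogram_layout` tibble: `node_id`, `parent_id`, `x`, `y`
#'   (`y` = topological depth), plus `mark` (`NA` where unmarked; marked nodes
#'   appear once per mark).
#' @export
layout_dendrogram <- function(skeleton, marks = NULL) {
  idx <- skel_index(skeleton)
  xpos <- rep(NA_real_, idx$n)
  leaf_counter <- 0
  # depth-first in child order = file order of children
  assign_x <- function(start) {
    # iterative post-order; children visited in file order
    visited <- logical(idx$n)
    s <- c(start)
    while (length(s) > 0) {
      cur <- s[[length(s)]]
      kids <- idx$children[[cur]]
      if (!visited[cur] && length(kids) > 0) {
        visited[cur] <- TRUE
        s <- c(s, rev(kids))
      } else {
        s <- s[-length(s)]
        if (length(kids) == 0) {
          leaf_counter <<- leaf_counter + 1
          xpos[cur] <<- leaf_counter
        } else {
          xpos[cur] <<- mean(xpos[kids])
        }
      }
    }
  }
  assign_x(idx$root)
  out <- tibble::tibble(
    node_id = idx$nodes$node_id,
    parent_id = idx$nodes$parent_id,
    x = xpos,
    y = as.numeric(idx$depth))
  if (!is.null(marks) && nrow(marks) > 0) {
    stopifnot(all(c("node_id", "mark") %in% names(marks)))
    unknown <- setdiff(marks$node_id, out$node_id)
    if (length(unknown) > 0) {
      stop("layout_dendrogram(): marks reference unknown node ids: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    out <- dplyr::left_join(out,
                            tibble::tibble(node_id = as.integer(marks$node_id),
                                           mark = as.character(marks$mark)),
                            by = "node_id", relationship = "many-to-many")
  } else {
    out$mark <- NA_character_
  }
  class(out) <- c("dendrogram_layout", class(out))
  out
}
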