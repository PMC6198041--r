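#' Build a neuron skeleton from a node table
#'
#' A skeleton is a rooted tree of 3-D points traced along the centerline of a
#' neuron's profiles. It is represented as a tibble with one row per node and
#' columns `node_id`, `parent_id` (`NA` exactly for the root), `x`, `y`, `z`
#' (nanometres), `radius` (nanometres, `NA` allowed) and `tags` (list-column of
#' character vectors, e.g. `"soma"`, `"dendritic_root"`).
#'
#' @param nodes Data frame with at least `node_id`, `parent_id`, `x`, `y`, `z`.
#'   `radius` and `tags` are added (as `NA` / empty) when missing.
#' @param name Neuron name used to match this skeleton in synapse tables.
#' @param validate If `TRUE` (default), structural invariants are checked and
#'   violations raise an error.
#' @return A `neuron_skeleton` tibble (rows keep the input order).
#' @examples
#' sk <- skeleton(data.frame(node_id = 1:3, parent_id = c(NA, 1, 2),
#'                           x = c(0, 0, 0), y = c(0, 2, 5), z = 0),
#'                name = "toy")
#' total_cable_length(sk)
#' @export
skeleton <- function(nodes, name = "neuron", validate = TRUE) {
  stopifnot(is.data.frame(nodes))
  need <- c("node_id", "parent_id", "x", "y", "z")
  missing_cols <- setdiff(need, names(nodes))
  if (length(missing_cols) > 0) {
    stop("skeleton(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- tibble::as_tibble(nodes)
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (!"radius" %in% names(nodes)) nodes$radius <- NA_real_
  if (!"tags" %in% names(nodes)) nodes$tags <- rep(list(character()), nrow(nodes))
  if (!is.list(nodes$tags)) nodes$tags <- as.list(nodes$tags)
  nodes <- nodes[, c("node_id", "parent_id", "x", "y", "z", "radius", "tags")]
  out <- tibble::new_tibble(nodes, name = name, class = "neuron_skeleton")
  if (validate) {
    report <- validate_skeleton(out)
    if (nrow(report) > 0) {
      stop("invalid skeleton '", name, "': ",
           paste(unique(report$violation), collapse = "; "))
    }
  }
  out
}

#' @export
print.neuron_skeleton <- function(x, ...) {
  cat("<neuron_skeleton> ", attr(x, "name"), ": ", nrow(x), " nodes, ",
      sum(is.na(x$parent_id) == FALSE), " edges, cable ",
      format(round(total_cable_length(x), 1), big.mark = ","), " nm\n", sep = "")
  NextMethod()
}

#' @rdname skeleton
#' @param skeleton A `neuron_skeleton`.
#' @export
skeleton_name <- function(skeleton) attr(skeleton, "name") %||% "neuron"

#' Check skeleton invariants
#'
#' Verifies that node ids are unique, parent references resolve, there is
#' exactly one root, and the edge set forms a single acyclic connected tree.
#'
#' @param skeleton A `neuron_skeleton` or a plain node data frame.
#' @return A tibble with columns `violation`, `node_id`, `detail`; zero rows
#'   means the skeleton is valid.
#' @export
validate_skeleton <- function(skeleton) {
  nodes <- tibble::as_tibble(skeleton)
  bad <- list()
  add <- function(violation, node_id, detail) {
    bad[[length(bad) + 1]] <<- tibble::tibble(
      violation = violation, node_id = as.integer(node_id), detail = detail)
  }
  dup <- nodes$node_id[duplicated(nodes$node_id)]
  for (id in unique(dup)) add("duplicate node_id", id, "node_id appears more than once")
  root_rows <- which(is.na(nodes$parent_id))
  if (length(root_rows) == 0) add("no root", NA, "no node has parent_id = NA")
  if (length(root_rows) > 1) {
    for (r in root_rows) add("multiple roots", nodes$node_id[r], "more than one parent-less node")
  }
  known <- nodes$node_id
  orphan <- which(!is.na(nodes$parent_id) & !(nodes$parent_id %in% known))
  for (r in orphan) {
    add("missing parent", nodes$node_id[r],
        paste0("parent_id ", nodes$parent_id[r], " not present"))
  }
  self_ref <- which(!is.na(nodes$parent_id) & nodes$parent_id == nodes$node_id)
  for (r in self_ref) add("cycle", nodes$node_id[r], "node is its own parent")
  # reachability from the root: unreached nodes with resolvable parents sit on a
  # cycle or on a component detached from the root
  if (length(root_rows) == 1 && length(dup) == 0 && length(orphan) == 0 &&
      length(self_ref) == 0) {
    n <- nrow(nodes)
    id2row <- stats::setNames(seq_len(n), nodes$node_id)
    parent_row <- ifelse(is.na(nodes$parent_id), NA_integer_,
                         id2row[as.character(nodes$parent_id)])
    children <- split(seq_len(n), factor(parent_row, levels = seq_len(n)))
    reached <- logical(n)
    queue <- root_rows
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      reached[cur] <- TRUE
      kids <- children[[cur]]
      if (length(kids) > 0) queue <- c(queue, kids)
    }
    for (r in which(!reached)) {
      add("cycle or disconnected", nodes$node_id[r], "node not reachable from root")
    }
  }
  if (length(bad) == 0) {
    tibble::tibble(violation = character(), node_id = integer(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Read a neuron skeleton from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, `#` comments,
#' parent `-1` for the root). File row order is preserved. SWC type 1 is
#' recorded as a `"soma"` tag.
#'
#' @param path Path to an SWC file (or character vector of lines).
#' @param unit_scale Multiplier applied to positions and radii to convert the
#'   file's units to nanometres (default 1: file already in nm).
#' @param name Neuron name; defaults to the file name without extension.
#' @return A `neuron_skeleton`.
#' @export
read_swc <- function(path, unit_scale = 1, name = NULL) {
  stopifnot(is.numeric(unit_scale), unit_scale > 0)
  if (length(path) == 1 && file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    if (is.null(name)) name <- sub("\\.[sS][wW][cC]$", "", basename(path))
  } else {
    lines <- path
    if (is.null(name)) name <- "neuron"
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("read_swc(): no data rows")
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nbad <- which(lengths(fields) != 7)
  if (length(nbad) > 0) {
    stop("read_swc(): line ", keep[nbad[1]], " does not have 7 columns: '",
         lines[keep[nbad[1]]], "'")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    r <- which(apply(m, 1, anyNA))[1]
    stop("read_swc(): non-numeric field on line ", keep[r], ": '", lines[keep[r]], "'")
  }
  node_id <- as.integer(m[, 1])
  swc_type <- as.integer(m[, 2])
  parent_id <- as.integer(m[, 7])
  dup <- which(duplicated(node_id))
  if (length(dup) > 0) {
    stop("read_swc(): duplicate node_id ", node_id[dup[1]], " on line ", keep[dup[1]])
  }
  roots <- which(parent_id == -1L)
  if (length(roots) == 0) stop("read_swc(): no root (parent -1) row")
  if (length(roots) > 1) {
    stop("read_swc(): multiple roots (parent -1) on lines ",
         paste(keep[roots], collapse = ", "))
  }
  miss <- which(parent_id != -1L & !(parent_id %in% node_id))
  if (length(miss) > 0) {
    stop("read_swc(): parent ", parent_id[miss[1]], " of node ", node_id[miss[1]],
         " (line ", keep[miss[1]], ") not in file")
  }
  nodes <- tibble::tibble(
    node_id = node_id,
    parent_id = ifelse(parent_id == -1L, NA_integer_, parent_id),
    x = m[, 3] * unit_scale, y = m[, 4] * unit_scale, z = m[, 5] * unit_scale,
    radius = ifelse(m[, 6] < 0, NA_real_, m[, 6] * unit_scale),
    tags = lapply(swc_type, function(t) if (t == 1L) "soma" else character())
  )
  sk <- tryCatch(skeleton(nodes, name = name, validate = TRUE),
                 error = function(e) stop("read_swc(): ", conditionMessage(e)))
  attr(sk, "swc_type") <- swc_type
  sk
}

#' Write a neuron skeleton to an SWC file
#'
#' @param skeleton A `neuron_skeleton`.
#' @param path Output path; omit to return the lines invisibly.
#' @param unit_scale Positions are divided by this factor on the way out, so a
#'   `read_swc(..., unit_scale = s)` / `write_swc(..., unit_scale = s)` pair
#'   round-trips.
#' @return The SWC lines, invisibly.
#' @export
write_swc <- function(skeleton, path = NULL, unit_scale = 1) {
  stopifnot(inherits(skeleton, "neuron_skeleton") || is.data.frame(skeleton))
  nodes <- tibble::as_tibble(skeleton)
  swc_type <- attr(skeleton, "swc_type")
  if (is.null(swc_type)) {
    swc_type <- ifelse(vapply(nodes$tags, function(t) "soma" %in% t, logical(1)), 1L, 0L)
  }
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   nodes$node_id, swc_type,
                   nodes$x / unit_scale, nodes$y / unit_scale, nodes$z / unit_scale,
                   ifelse(is.na(nodes$radius), -1, nodes$radius / unit_scale),
                   ifelse(is.na(nodes$parent_id), -1L, nodes$parent_id))
  lines <- c("# SWC export", lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# Row-index machinery shared by the tree algorithms: children lists, a
# root-first topological order, per-node depth and cumulative path length.
skel_index <- function(skeleton) {
  nodes <- tibble::as_tibble(skeleton)
  n <- nrow(nodes)
  id2row <- stats::setNames(seq_len(n), nodes$node_id)
  parent_row <- ifelse(is.na(nodes$parent_id), NA_integer_,
                       id2row[as.character(nodes$parent_id)])
  children <- vector("list", n)
  for (r in which(!is.na(parent_row))) {
    p <- parent_row[r]
    children[[p]] <- c(children[[p]], r)
  }
  root <- which(is.na(parent_row))
  if (length(root) != 1) stop("skeleton must have exactly one root")
  order_rows <- integer(n)
  depth <- integer(n)
  dist_root <- numeric(n)
  edge_len <- numeric(n) # length of the edge to the parent; 0 at the root
  order_rows[1] <- root
  head <- 1L; tail <- 1L
  while (head <= tail) {
    cur <- order_rows[head]
    for (k in children[[cur]]) {
      tail <- tail + 1L
      order_rows[tail] <- k
      depth[k] <- depth[cur] + 1L
      edge_len[k] <- sqrt((nodes$x[k] - nodes$x[cur])^2 +
                          (nodes$y[k] - nodes$y[cur])^2 +
                          (nodes$z[k] - nodes$z[cur])^2)
      dist_root[k] <- dist_root[cur] + edge_len[k]
    }
    head <- head + 1L
  }
  if (tail != n) stop("skeleton is not a connected tree")
  list(nodes = nodes, n = n, id2row = id2row, parent_row = parent_row,
       children = children, root = root, order_rows = order_rows,
       depth = depth, dist_root = dist_root, edge_len = edge_len)
}

#' Total cable length of a skeleton
#'
#' Sum of straight-line (Euclidean) edge lengths between consecutive nodes,
#' in nanometres.
#'
#' @param skeleton A `neuron_skeleton`.
#' @return Length in nm.
#' @export
total_cable_length <- function(skeleton) {
  sum(skel_index(skeleton)$edge_len)
}

#' Strahler branch order of every node
#'
#' Leaves have order 1; a parent takes the maximum of its children's orders,
#' plus one when at least two children attain that maximum. The root carries
#' the tree's maximal order. Used to shade arbors by branch hierarchy.
#'
#' @param skeleton A `neuron_skeleton`.
#' @return Tibble with columns `node_id`, `strahler_order`.
#' @export
strahler_order <- function(skeleton) {
  idx <- skel_index(skeleton)
  if (idx$n == 0) stop("strahler_order(): empty skeleton")
  ord <- integer(idx$n)
  for (r in rev(idx$order_rows)) {
    kids <- idx$children[[r]]
    if (length(kids) == 0) {
      ord[r] <- 1L
    } else {
      mx <- max(ord[kids])
      ord[r] <- if (sum(ord[kids] == mx) >= 2L) mx + 1L else mx
    }
  }
  tibble::tibble(node_id = idx$nodes$node_id, strahler_order = ord)
}

# Lowest common ancestor by ladder-walking parent pointers (rows, not ids).
lca_rows <- function(idx, ra, rb) {
  while (idx$depth[ra] > idx$depth[rb]) ra <- idx$parent_row[ra]
  while (idx$depth[rb] > idx$depth[ra]) rb <- idx$parent_row[rb]
  while (ra != rb) {
    ra <- idx$parent_row[ra]
    rb <- idx$parent_row[rb]
  }
  ra
}

#' Geodesic (along-the-arbor) distance between nodes
#'
#' Path length along the unique tree path between two nodes, in nanometres —
#' the distance a signal travels along the neurite, not through space.
#' Vectorized over pairs (`node_a`, `node_b` are recycled to equal length).
#'
#' @param skeleton A `neuron_skeleton`.
#' @param node_a,node_b Node ids.
#' @return Numeric vector of distances in nm.
#' @export
geodesic_distance <- function(skeleton, node_a, node_b) {
  idx <- skel_index(skeleton)
  pair <- vctrs_recycle2(as.integer(node_a), as.integer(node_b))
  ra <- idx$id2row[as.character(pair[[1]])]
  rb <- idx$id2row[as.character(pair[[2]])]
  if (anyNA(ra) || anyNA(rb)) {
    bad <- c(pair[[1]][is.na(ra)], pair[[2]][is.na(rb)])
    stop("geodesic_distance(): unknown node id ", bad[1])
  }
  vapply(seq_along(ra), function(i) {
    l <- lca_rows(idx, ra[i], rb[i])
    idx$dist_root[ra[i]] + idx$dist_root[rb[i]] - 2 * idx$dist_root[l]
  }, numeric(1))
}

vctrs_recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) != n) a <- rep_len(a, n)
  if (length(b) != n) b <- rep_len(b, n)
  list(a, b)
}

# Per-node synapse counts for the skeleton's own pre/post sites, as row-indexed
# integer vectors, plus subtree totals accumulated leaves -> root.
synapse_flow_counts <- function(idx, skeleton, synapses) {
  name <- skeleton_name(skeleton)
  pre_nodes <- synapses$pre_node[!is.na(synapses$pre_node) & synapses$pre_neuron == name]
  post_nodes <- synapses$post_node[!is.na(synapses$post_node) & synapses$post_neuron == name]
  own_pre <- own_post <- integer(idx$n)
  tp <- table(factor(as.character(pre_nodes), levels = names(idx$id2row)))
  to <- table(factor(as.character(post_nodes), levels = names(idx$id2row)))
  own_pre[idx$id2row[names(tp)]] <- as.integer(tp)
  own_post[idx$id2row[names(to)]] <- as.integer(to)
  sub_pre <- own_pre
  sub_post <- own_post
  for (r in rev(idx$order_rows)) {
    p <- idx$parent_row[r]
    if (!is.na(p)) {
      sub_pre[p] <- sub_pre[p] + sub_pre[r]
      sub_post[p] <- sub_post[p] + sub_post[r]
    }
  }
  list(own_pre = own_pre, own_post = own_post,
       sub_pre = sub_pre, sub_post = sub_post,
       total_pre = sum(own_pre), total_post = sum(own_post))
}

#' Locate the dendritic root
#'
#' The dendritic root is the point at which the neuron's main neurite branches
#' into proximal dendrites and distal axon. A node carrying the annotation tag
#' (default `"dendritic_root"`) is returned directly. Without a tag the root is
#' inferred from synapse flow: for every branch point, each child subtree is
#' scored by how cleanly it separates the neuron's own postsynaptic sites from
#' its presynaptic sites — `max(post inside + pre outside, pre inside + post
#' outside) / total sites` — and the best-separating branch point wins. Ties
#' are broken toward the smallest `node_id`.
#'
#' @param skeleton A `neuron_skeleton`.
#' @param synapses Synapse table (see [read_synapses()]); required when no
#'   tagged node exists.
#' @param annotated_tag Tag that marks a manually annotated dendritic root.
#' @return The `node_id` of the dendritic root (integer scalar).
#' @export
find_dendritic_root <- function(skeleton, synapses = NULL,
                                annotated_tag = "dendritic_root") {
  nodes <- tibble::as_tibble(skeleton)
  tagged <- nodes$node_id[vapply(nodes$tags, function(t) annotated_tag %in% t, logical(1))]
  if (length(tagged) > 0) return(min(tagged))
  idx <- skel_index(skeleton)
  branch_rows <- which(lengths(idx$children) >= 2L)
  if (length(branch_rows) == 0) {
    stop("find_dendritic_root(): no branch point and no '", annotated_tag, "' tag")
  }
  if (is.null(synapses) || nrow(synapses) == 0) {
    stop("find_dendritic_root(): synapse table required to infer an untagged root")
  }
  fl <- synapse_flow_counts(idx, skeleton, synapses)
  total <- fl$total_pre + fl$total_post
  if (total == 0) {
    stop("find_dendritic_root(): no synapses on '", skeleton_name(skeleton),
         "' to infer an untagged root")
  }
  best_score <- -Inf
  best_id <- NA_integer_
  for (r in branch_rows) {
    sc <- 0
    for (k in idx$children[[r]]) {
      s1 <- fl$sub_post[k] + (fl$total_pre - fl$sub_pre[k])
      s2 <- fl$sub_pre[k] + (fl$total_post - fl$sub_post[k])
      sc <- max(sc, s1, s2)
    }
    sc <- sc / total
    id <- idx$nodes$node_id[r]
    if (sc > best_score || (sc == best_score && id < best_id)) {
      best_score <- sc
      best_id <- id
    }
  }
  best_id
}

#' Extract axonlets
#'
#' Axonlets are distal parts of neurites that originate from the dendritic
#' field yet make exclusively presynaptic connections. Operationally the
#' dendritic field is the set of nodes below the dendritic root whose subtree
#' still contains at least one of the neuron's own postsynaptic sites (the
#' dendritic root itself is excluded, so the main axon does not qualify); an
#' axonlet is a maximal subtree hanging off a field node that carries at least
#' one synaptic site, all of them presynaptic.
#'
#' @param skeleton A `neuron_skeleton`.
#' @param synapses Synapse table (see [read_synapses()]).
#' @param dendritic_root `node_id` of the dendritic root, e.g. from
#'   [find_dendritic_root()].
#' @return Tibble with one row per axonlet: `axonlet_root`, `attached_to`,
#'   `n_nodes`, `cable_length_nm`, `n_presynapses`. Zero rows when none exist.
#' @export
extract_axonlets <- function(skeleton, synapses, dendritic_root) {
  idx <- skel_index(skeleton)
  droot_row <- idx$id2row[as.character(as.integer(dendritic_root))]
  if (is.na(droot_row)) stop("extract_axonlets(): unknown dendritic_root node id")
  fl <- synapse_flow_counts(idx, skeleton, synapses)
  # nodes strictly below the dendritic root
  below <- logical(idx$n)
  below[idx$children[[droot_row]]] <- TRUE
  for (r in idx$order_rows) {
    p <- idx$parent_row[r]
    if (!is.na(p) && below[p]) below[r] <- TRUE
  }
  field <- below & (fl$sub_post > 0)
  out <- list()
  for (p in which(field)) {
    for (k in idx$children[[p]]) {
      nsites <- fl$sub_pre[k] + fl$sub_post[k]
      if (nsites >= 1 && fl$sub_post[k] == 0) {
        members <- subtree_rows(idx, k)
        out[[length(out) + 1]] <- tibble::tibble(
          axonlet_root = idx$nodes$node_id[k],
          attached_to = idx$nodes$node_id[p],
          n_nodes = length(members),
          cable_length_nm = sum(idx$edge_len[members]),
          n_presynapses = fl$sub_pre[k])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(axonlet_root = integer(), attached_to = integer(),
                          n_nodes = integer(), cable_length_nm = numeric(),
                          n_presynapses = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$axonlet_root)
}

subtree_rows <- function(idx, r) {
  acc <- integer(0)
  stack <- r
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    acc <- c(acc, cur)
    stack <- c(stack, idx$children[[cur]])
  }
  acc
}
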