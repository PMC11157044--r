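#' Multilayer node degrees
#'
#' Degrees of every ROI in the three spatial layers of one temporal layer.
#' A GM ROI inherits its MRSN's hypergraph degree (the number of hyperedges
#' the MRSN belongs to) as its layer-1 degree, takes its within-network
#' adjacency row sum as layer 2, and its WM-GM column sum as layer 3.  A WM
#' ROI participates only in layer 3 (its A2 row sum).
#'
#' @param layer A `mlfcn_spatial` from [build_spatial_fcn()].
#' @param parc The matching [parcellation()].
#' @return A tibble with columns `roi_index`, `d1`, `d2`, `d3`.
#' @export
multilayer_degrees <- function(layer, parc) {
  levs <- attr(parc, "mrsn_levels")
  mrsn_deg <- setNames(as.integer(rowSums(layer$H)), levs)
  gm <- parc$tissue == "GM"
  d1 <- integer(n_roi(parc)); d2 <- integer(n_roi(parc)); d3 <- integer(n_roi(parc))
  d1[gm] <- mrsn_deg[parc$mrsn[gm]]
  d2[gm] <- as.integer(rowSums(layer$A1))
  d3[gm] <- if (nrow(layer$A2) > 0) as.integer(colSums(layer$A2)) else 0L
  if (any(!gm)) d3[!gm] <- as.integer(rowSums(layer$A2))
  tibble(roi_index = parc$roi_index, d1 = d1, d2 = d2, d3 = d3)
}

#' Normalised multilayer degree
#'
#' Divides each ROI's summed degree across the three layers by the summed
#' theoretical maxima from [max_degrees()], giving a value in \[0, 1\] that
#' is comparable between GM nodes in differently sized networks and WM
#' nodes.
#'
#' @param degrees Tibble from [multilayer_degrees()].
#' @param dmax Tibble from [max_degrees()].
#' @return A tibble with columns `roi_index`, `norm_degree`.
#' @export
normalized_degree <- function(degrees, dmax) {
  j <- left_join(degrees, dmax[, c("roi_index", "dmax_sum")], by = "roi_index")
  if (any(j$dmax_sum <= 0)) {
    abort("degenerate parcellation: some ROI has no possible neighbours in any layer")
  }
  tibble(roi_index = j$roi_index,
         norm_degree = (j$d1 + j$d2 + j$d3) / j$dmax_sum)
}

#' Per-window core-node selection
#'
#' `select_core()` marks the `n_core` nodes with the highest normalised
#' degree as the rich-club core of one temporal layer (ties broken by
#' ascending ROI index, so selection is deterministic).  `core_assignment()`
#' applies this to every layer of a temporal network, yielding the binary
#' node x layer membership matrix on which all four rich-club metrics are
#' defined.  All ROIs — GM and WM — compete for core status.
#'
#' @param norm_degree Numeric vector of normalised degrees (ROI order).
#' @param n_core Core size (default 15, matching the 15 MRSNs of the default
#'   parcellation; scale it down with smaller parcellations).
#' @return `select_core()`: binary integer vector with exactly `n_core`
#'   ones.  `core_assignment()`: binary matrix `N_roi x T` of class
#'   `mlfcn_core` with attribute `n_core`.
#' @export
select_core <- function(norm_degree, n_core = 15) {
  n <- length(norm_degree)
  if (n_core > n) abort("n_core exceeds the number of ROIs")
  out <- integer(n)
  out[order(-norm_degree, seq_len(n))[seq_len(n_core)]] <- 1L
  out
}

#' @rdname select_core
#' @param net A `mlfcn_temporal` from [build_temporal_fcn()].
#' @export
core_assignment <- function(net, n_core = 15) {
  parc <- net$parcellation
  dmax <- max_degrees(parc)
  r <- vapply(net$layers, function(l) {
    nd <- normalized_degree(multilayer_degrees(l, parc), dmax)
    select_core(nd$norm_degree, n_core)
  }, integer(n_roi(parc)))
  structure(r, n_core = as.integer(n_core), class = c("mlfcn_core", "matrix"))
}

#' Temporal centrality
#'
#' The fraction of temporal layers in which each node is a rich-club core
#' node.  Summed over nodes it always equals the core size, since every
#' layer contributes exactly `n_core` memberships.
#'
#' @param r Binary core-assignment matrix (`N_roi x T`), e.g. from
#'   [core_assignment()].
#' @return Numeric vector of length `N_roi` in \[0, 1\].
#' @export
temporal_centrality <- function(r) {
  if (ncol(r) < 1) abort("temporal centrality needs at least one layer")
  rowMeans(unclass(r))
}

#' Temporal stability
#'
#' How persistently a node keeps its core/peripheral identity between
#' consecutive temporal layers.  Two readings are provided:
#' `mode = "prose"` (default) scores a node by the fraction of the `T - 1`
#' consecutive-layer transitions at which its identity is unchanged, so a
#' never-switching node scores 1; `mode = "literal"` is the complementary
#' transition frequency (1 minus the prose value), under which a perfectly
#' stable node scores 0.  The two modes always sum to 1 elementwise.
#'
#' @inheritParams temporal_centrality
#' @param mode `"prose"` or `"literal"`.
#' @return Numeric vector of length `N_roi` in \[0, 1\].
#' @export
temporal_stability <- function(r, mode = c("prose", "literal")) {
  mode <- match.arg(mode)
  r <- unclass(r)
  t_n <- ncol(r)
  if (t_n < 2) abort("temporal stability needs at least two layers")
  consistent <- r[, -1, drop = FALSE] == r[, -t_n, drop = FALSE]
  literal <- 1 - rowMeans(consistent)
  if (mode == "literal") literal else 1 - literal
}

# Union connectivity graph over all ROIs at one temporal layer.
# GM-GM: within-network adjacency, plus (policy "union_clique") hypergraph
# clique expansion — two GM ROIs are connected when their MRSNs co-occur in
# at least one hyperedge (including both belonging to one MRSN that sits in
# any hyperedge).  WM-GM: bipartite adjacency.  WM-WM: never.
union_graph <- function(layer, parc,
                        connectivity = c("union_clique", "adjacency_only")) {
  connectivity <- match.arg(connectivity)
  n <- n_roi(parc)
  gm_idx <- parc$roi_index[parc$tissue == "GM"]
  wm_idx <- parc$roi_index[parc$tissue == "WM"]
  u <- matrix(0L, n, n)
  a1 <- layer$A1
  u[gm_idx, gm_idx] <- a1
  if (connectivity == "union_clique") {
    co <- (layer$H %*% t(layer$H)) > 0   # MRSN pairs sharing >= 1 hyperedge
    levs <- attr(parc, "mrsn_levels")
    mpos <- match(parc$mrsn[gm_idx], levs)
    u[gm_idx, gm_idx] <- u[gm_idx, gm_idx] | co[mpos, mpos]
  }
  if (length(wm_idx) > 0 && nrow(layer$A2) > 0) {
    u[wm_idx, gm_idx] <- layer$A2
    u[gm_idx, wm_idx] <- t(layer$A2)
  }
  diag(u) <- 0L
  mode(u) <- "integer"
  u
}

#' Pairwise shared-core matrix
#'
#' For each temporal layer, counts for every pair of peripheral nodes the
#' number of core nodes to which both are concurrently connected in the
#' union graph of that layer (pairs involving a core node contribute zero),
#' then normalises the sum over layers by `T * n_core`.  This matrix `P`
#' underlies both local and joint functionality.
#'
#' Cross-layer "connected to" is resolved by the `connectivity` policy:
#' `"union_clique"` (default) unions the within-network adjacency, the
#' hypergraph clique expansion at MRSN level, and the WM-GM adjacency;
#' `"adjacency_only"` drops the hypergraph term.  `p_sum_mode = "t_minus_1"`
#' restricts the layer sum to the first `T - 1` layers while keeping the
#' `T * n_core` normaliser.
#'
#' @param net A `mlfcn_temporal`.
#' @param r Core assignment matrix from [core_assignment()].
#' @param connectivity Connectivity policy, see Details.
#' @param p_sum_mode `"all_t"` (default) or `"t_minus_1"`.
#' @return Symmetric `N_roi x N_roi` numeric matrix with zero diagonal,
#'   entries in \[0, 1\].
#' @export
shared_core_matrix <- function(net, r,
                               connectivity = c("union_clique", "adjacency_only"),
                               p_sum_mode = c("all_t", "t_minus_1")) {
  connectivity <- match.arg(connectivity)
  p_sum_mode <- match.arg(p_sum_mode)
  parc <- net$parcellation
  r <- unclass(r)
  t_n <- length(net$layers)
  stopifnot(ncol(r) == t_n)
  n_c <- attr(r, "n_core") %||% max(colSums(r))
  layers_used <- if (p_sum_mode == "all_t") seq_len(t_n) else seq_len(t_n - 1)
  acc <- matrix(0, n_roi(parc), n_roi(parc))
  for (t in layers_used) {
    u <- union_graph(net$layers[[t]], parc, connectivity)
    core <- which(r[, t] == 1)
    b <- u[, core, drop = FALSE]
    beta <- b %*% t(b)            # shared-core counts for all pairs
    beta[core, ] <- 0             # only peripheral pairs count
    beta[, core] <- 0
    acc <- acc + beta
  }
  p <- acc / (t_n * n_c)
  diag(p) <- 0
  p
}

#' Local and joint functionality
#'
#' Aggregate each node's shared-core frequencies within its own functional
#' network (`local_functionality`) and towards all other networks
#' (`joint_functionality`).  WM nodes use the single WM group as their
#' network.  The local sum runs over same-network partners (excluding the
#' node itself) and is divided by the network size `n_S`; the joint sum runs
#' over out-of-network partners and is divided by `N - n_S`.
#'
#' @param p Shared-core matrix from [shared_core_matrix()].
#' @param parc The matching [parcellation()].
#' @param denominator For the local metric: `"n_s"` (default) or
#'   `"n_s_minus_1"` to divide by the number of summed partners instead.
#' @return Numeric vector of length `N_roi`.
#' @export
local_functionality <- function(p, parc, denominator = c("n_s", "n_s_minus_1")) {
  denominator <- match.arg(denominator)
  vapply(seq_len(n_roi(parc)), function(i) {
    same <- which(parc$mrsn == parc$mrsn[i])
    n_s <- length(same)
    den <- if (denominator == "n_s") n_s else max(n_s - 1, 1)
    sum(p[i, setdiff(same, i)]) / den
  }, numeric(1))
}

#' @rdname local_functionality
#' @export
joint_functionality <- function(p, parc) {
  n <- n_roi(parc)
  vapply(seq_len(n), function(i) {
    same <- which(parc$mrsn == parc$mrsn[i])
    if (length(same) == n) {
      abort("joint functionality undefined: all ROIs share one network")
    }
    sum(p[i, -same]) / (n - length(same))
  }, numeric(1))
}

#' Dynamic rich-club metrics of a temporal multilayer network
#'
#' End-to-end metric computation: per-layer normalised degrees and top-`n_core`
#' core selection, then the four node-level metrics — temporal centrality
#' (TC), temporal stability (TS, both readings), local functionality (LF)
#' and joint functionality (JF).
#'
#' @param net A `mlfcn_temporal` from [build_temporal_fcn()].
#' @param n_core Rich-club core size per layer (default 15).
#' @inheritParams shared_core_matrix
#' @param lf_denominator Passed to [local_functionality()].
#' @param ts_mode Which stability reading fills the `ts` column (both are
#'   always reported as `ts_prose` / `ts_literal`).
#' @return A tibble of class `mlfcn_richclub` with one row per ROI and
#'   columns `roi_index`, `label`, `tissue`, `mrsn`, `tc`, `ts`,
#'   `ts_prose`, `ts_literal`, `lf`, `jf`.  The core-assignment matrix and
#'   shared-core matrix are attached as attributes `core` and `P`.
#' @examples
#' parc <- toy_parcellation()
#' ts <- simulate_subject(sim_config(parcellation = parc, seed = 1), "s1")
#' net <- build_temporal_fcn(ts, parc, window = 200, stride = 100)
#' m <- richclub_metrics(net, n_core = 5)
#' dplyr::arrange(m, dplyr::desc(tc))
#' @export
richclub_metrics <- function(net, n_core = 15,
                             connectivity = c("union_clique", "adjacency_only"),
                             p_sum_mode = c("all_t", "t_minus_1"),
                             lf_denominator = c("n_s", "n_s_minus_1"),
                             ts_mode = c("prose", "literal")) {
  ts_mode <- match.arg(ts_mode)
  lf_denominator <- match.arg(lf_denominator)
  parc <- net$parcellation
  if (length(net$layers) < 2) {
    abort("rich-club metrics need at least two temporal layers")
  }
  r <- core_assignment(net, n_core)
  p <- shared_core_matrix(net, r, connectivity = connectivity,
                          p_sum_mode = p_sum_mode)
  ts_lit <- temporal_stability(r, "literal")
  out <- tibble(
    roi_index = parc$roi_index,
    label = parc$label,
    tissue = parc$tissue,
    mrsn = parc$mrsn,
    tc = temporal_centrality(r),
    ts = if (ts_mode == "literal") ts_lit else 1 - ts_lit,
    ts_prose = 1 - ts_lit,
    ts_literal = ts_lit,
    lf = local_functionality(p, parc, lf_denominator),
    jf = joint_functionality(p, parc)
  )
  structure(out, core = r, P = p, n_core = as.integer(n_core),
            ts_mode = ts_mode,
            class = c("mlfcn_richclub", class(tibble())))
}

#' Aggregate rich-club metrics to MRSN or whole-brain scale
#'
#' Unweighted means of the node-level metrics over each network's member
#' ROIs (`scale = "mrsn"`, with the 48 WM ROIs forming one `WM` unit) or
#' over all ROIs (`scale = "whole_brain"`).  Whole-brain temporal centrality
#' is reported but is constant by construction (its node sum always equals
#' the core size), so it carries no between-subject information.
#'
#' @param metrics A `mlfcn_richclub` tibble (or compatible data frame with
#'   `mrsn` and metric columns).
#' @param scale `"roi"`, `"mrsn"` or `"whole_brain"`.
#' @param cols Metric columns to aggregate.
#' @return A tibble keyed by `unit` with one column per metric.
#' @export
aggregate_metrics <- function(metrics, scale = c("roi", "mrsn", "whole_brain"),
                              cols = c("tc", "ts", "ts_prose", "ts_literal",
                                       "lf", "jf")) {
  scale <- match.arg(scale)
  df <- as_tibble(metrics)
  cols <- intersect(cols, names(df))
  if (scale == "roi") {
    out <- df[, c("roi_index", cols)]
    out <- dplyr::rename(out, unit = "roi_index")
    out$unit <- as.character(out$unit)
    return(out)
  }
  if (scale == "mrsn") {
    out <- df |>
      group_by(unit = .data$mrsn) |>
      summarise(across(all_of(cols), mean), .groups = "drop")
    return(out)
  }
  summarise(df, across(all_of(cols), mean)) |>
    mutate(unit = "whole_brain", .before = 1)
}
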