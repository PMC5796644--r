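# Directed-graph characterizations of estimated effective connectivity:
# signed in/out-strengths, symmetric/antisymmetric split, network-level
# down-sampling, group binarized averages, and graph exports.

#' Nodal in- and out-strengths of a directed coupling matrix
#'
#' With the convention `A[i, j]` = influence of region `j` on region `i`,
#' the in-strength of node `i` is the signed sum of its incoming couplings
#' (row sum excluding the self-connection) and the out-strength of node `j`
#' the sum of its outgoing couplings (column sum, likewise).  Nodes with
#' larger out- than in-strength are net senders ("sources"), the reverse
#' are net receivers ("sinks").  Signed weights are used by default;
#' `absolute = TRUE` sums magnitudes instead.
#'
#' @param A Square coupling matrix.
#' @param labels Optional node labels.
#' @param absolute Sum absolute weights instead of signed weights.
#' @return Data frame with `node`, `in_strength`, `out_strength`, `role`
#'   (`"source"`, `"sink"`, or `"balanced"`).
#' @export
strengths <- function(A, labels = NULL, absolute = FALSE) {
  .stop_if_not_square(A, "A")
  n <- nrow(A)
  W <- if (absolute) abs(A) else A
  diag(W) <- 0
  s_in <- rowSums(W)
  s_out <- colSums(W)
  role <- ifelse(s_out > s_in, "source",
                 ifelse(s_out < s_in, "sink", "balanced"))
  data.frame(node = labels %||% rownames(A) %||% paste0("R", seq_len(n)),
             in_strength = s_in, out_strength = s_out, role = role,
             row.names = NULL)
}

#' Symmetric and antisymmetric parts of a coupling matrix
#'
#' Splits `A` by transposition: `S = (A + t(A))/2` and `N = (A - t(A))/2`
#' by default, so that `S + N` reconstructs `A` exactly and the two parts
#' are Frobenius-orthogonal.  `scale = "unnormalized"` returns the plain
#' sum and difference (no 1/2 factor).
#'
#' @param A Square matrix.
#' @param scale `"half"` (default, reconstructing) or `"unnormalized"`.
#' @return List with `S` (symmetric) and `N` (antisymmetric).
#' @export
sym_antisym <- function(A, scale = c("half", "unnormalized")) {
  .stop_if_not_square(A, "A")
  scale <- match.arg(scale)
  fac <- if (scale == "half") 0.5 else 1
  list(S = fac * (A + t(A)), N = fac * (A - t(A)))
}

#' Down-sample a coupling matrix to network-level nodes
#'
#' Averages coupling strengths among the sets of regions constituting each
#' network: entry `(p, q)` with `p != q` is the mean of `A[i, j]` over
#' `i` in network `p` and `j` in network `q`; diagonal blocks are averaged
#' excluding the self-connections (set `exclude_self = FALSE` to include
#' them).
#'
#' @param A Square region-level matrix.
#' @param partition Character (or factor) vector mapping every region to a
#'   network label.
#' @param exclude_self Drop `A[i, i]` from diagonal-block averages.
#' @return `k` x `k` network-level matrix (networks in first-appearance
#'   order).
#' @export
downsample_to_networks <- function(A, partition, exclude_self = TRUE) {
  .stop_if_not_square(A, "A")
  n <- nrow(A)
  if (length(partition) != n || anyNA(partition))
    stop("every region must carry exactly one network label", call. = FALSE)
  nets <- unique(as.character(partition))
  k <- length(nets)
  out <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  for (p in seq_len(k)) for (q in seq_len(k)) {
    ii <- which(partition == nets[p])
    jj <- which(partition == nets[q])
    M <- A[ii, jj, drop = FALSE]
    if (p == q && exclude_self) {
      keep <- outer(ii, jj, `!=`)
      out[p, q] <- if (any(keep)) mean(M[keep]) else NA_real_
    } else {
      out[p, q] <- mean(M)
    }
  }
  out
}

#' Group summaries of pruned adjacencies
#'
#' For a set of subject-level pruned coupling matrices, computes the
#' fraction-present matrix (each subject's adjacency binarized to edge
#' existence -- BMR retention, no magnitude threshold -- then averaged, so
#' entries reflect how often a connection is evident over subjects) and the
#' mean-weight matrix over subjects in which the edge was retained.
#'
#' @param pruned List of `dcm_pruned` objects, or of coupling matrices
#'   (with `masks` supplied separately).
#' @param masks Optional list of logical retention masks matching `pruned`.
#' @return List with `fraction` (entries in `[0, 1]`) and `mean_weight`
#'   (`NA` where an edge was never retained); diagonals follow the masks.
#' @export
group_binarize_average <- function(pruned, masks = NULL) {
  if (!length(pruned)) stop("empty subject list", call. = FALSE)
  As <- lapply(pruned, function(x) if (inherits(x, "dcm_pruned")) x$A else x)
  masks <- masks %||% lapply(pruned, function(x)
    if (inherits(x, "dcm_pruned")) x$mask else stop(
      "masks must be supplied for plain matrices", call. = FALSE))
  dims <- unique(lapply(As, dim))
  if (length(dims) != 1L) stop("matrices differ in size", call. = FALSE)
  n <- dims[[1]][1]
  frac <- Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks)
  wsum <- Reduce(`+`, lapply(seq_along(As), function(s)
    As[[s]] * (masks[[s]] * 1)))
  cnt <- frac * length(masks)
  mean_w <- ifelse(cnt > 0, wsum / cnt, NA_real_)
  list(fraction = frac, mean_weight = mean_w)
}

#' Read a region table (name, network, MNI coordinates)
#'
#' CSV with columns `name`, `network`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param path CSV path.
#' @return Data frame with those columns.
#' @export
read_region_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "network", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("region table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Export a signed weighted directed graph
#'
#' `write_graphml()` writes GraphML via igraph (edge attributes `weight`
#' and `sign`); `write_edge_list()` writes a CSV with columns `source`,
#' `target`, `weight`, `sign`.  Self-connections are not exported as edges.
#'
#' @param A Coupling matrix (entries of zero are absent edges); recall
#'   `A[i, j]` couples source `j` to target `i`.
#' @param path Output path.
#' @param labels Optional node labels.
#' @export
write_graphml <- function(A, path, labels = NULL) {
  g <- .as_igraph(A, labels)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(A, path, labels = NULL) {
  .stop_if_not_square(A, "A")
  labels <- labels %||% rownames(A) %||% paste0("R", seq_len(nrow(A)))
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  df <- data.frame(source = labels[idx[, "col"]],
                   target = labels[idx[, "row"]],
                   weight = A[idx],
                   sign = ifelse(A[idx] > 0, "excitatory", "inhibitory"))
  write.csv(df[order(df$source, df$target), ], path, row.names = FALSE)
  invisible(path)
}

.as_igraph <- function(A, labels = NULL) {
  .stop_if_not_square(A, "A")
  labels <- labels %||% rownames(A) %||% paste0("R", seq_len(nrow(A)))
  W <- A
  diag(W) <- 0
  # igraph's adjacency is from-row-to-column; our convention is column ->
  # row, so transpose.
  g <- igraph::graph_from_adjacency_matrix(t(W != 0) * 1, mode = "directed")
  igraph::V(g)$name <- labels
  idx <- which(W != 0, arr.ind = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- W[cbind(el[, 2], el[, 1])]
  igraph::E(g)$weight <- w
  igraph::E(g)$sign <- ifelse(w > 0, "excitatory", "inhibitory")
  g
}
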