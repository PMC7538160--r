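# Reciprocity and clustering analyses across tracing experiments:
# input-output correlation, fold-difference maps, pairwise Pearson
# correlation matrices and complete-linkage clustering with starter-center
# ranking.

#' Per-mouse region vectors from a connectivity table
#'
#' Extracts percent-of-total vectors (one per mouse) over a fixed region
#' order, the representation on which correlation and clustering operate.
#'
#' @param ctable a `connectivity_table` (typically at major-region
#'   granularity).
#' @param region_order optional fixed region order; default sorted codes.
#' @return matrix, mice in rows, regions in columns.
#' @export
region_vectors <- function(ctable, region_order = NULL) {
  ok <- !ctable$excluded
  regions <- region_order %||% sort(unique(ctable$region_code[ok]))
  mice <- unique(ctable$mouse_id[ok])
  out <- matrix(0, length(mice), length(regions),
                dimnames = list(mice, regions))
  for (m in mice) {
    sel <- ok & ctable$mouse_id == m
    v <- tapply(ctable$percent_total[sel], ctable$region_code[sel], sum)
    out[m, names(v)] <- v
  }
  out
}

#' Input-output reciprocity correlation
#'
#' Pearson correlation between a region-wise input vector and output
#' vector, over the regions where input and output are not both zero.
#'
#' @param inputs,outputs numeric vectors in identical region order.
#' @return Pearson's r.
#' @export
io_reciprocity <- function(inputs, outputs) {
  if (length(inputs) != length(outputs))
    stop("input and output vectors must have the same region order")
  keep <- !(inputs == 0 & outputs == 0)
  if (sum(keep) < 3)
    stop("fewer than 3 regions with signal; correlation undefined")
  if (stats::sd(inputs[keep]) == 0 || stats::sd(outputs[keep]) == 0)
    stop("constant vector; correlation undefined")
  stats::cor(inputs[keep], outputs[keep])
}

#' Input/output fold-difference map
#'
#' Per region, the ratio of input share to output share with a small
#' pseudo-floor keeping one-sided zeros finite. Regions with neither input
#' nor output are omitted.
#'
#' @param inputs,outputs percent-of-total vectors, identical region order
#'   (names taken from `inputs`).
#' @param floor pseudo-count added to both sides (percentage points).
#' @return data.frame with `region`, `input`, `output`, `ratio`,
#'   `dominance` (input-dominated / output-dominated / balanced); omitted
#'   regions are absent.
#' @export
fold_difference <- function(inputs, outputs, floor = 0.01) {
  if (length(inputs) != length(outputs))
    stop("mismatched vectors")
  keep <- !(inputs == 0 & outputs == 0)
  ratio <- (inputs[keep] + floor) / (outputs[keep] + floor)
  data.frame(
    region = if (!is.null(names(inputs))) names(inputs)[keep] else
      which(keep),
    input = inputs[keep], output = outputs[keep], ratio = ratio,
    dominance = ifelse(ratio > 1, "input-dominated",
                       ifelse(ratio < 1, "output-dominated", "balanced")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise Pearson correlation matrix of tracing vectors
#'
#' @param vectors matrix with one tracing per row (e.g. from
#'   [region_vectors()]).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vectors) {
  if (nrow(vectors) < 2) stop("need at least 2 vectors")
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds == 0))
    stop("constant vector(s): ",
         paste(rownames(vectors)[sds == 0], collapse = ", "),
         "; correlation undefined")
  r <- stats::cor(t(vectors))
  diag(r) <- 1
  r
}

#' Complete-linkage clustering of a correlation matrix
#'
#' Distances are `1 - r`. Agglomeration is complete linkage (inter-cluster
#' distance = maximum pairwise distance); ties merge the pair with the
#' lowest leaf indices. The result is convertible to `hclust` so the usual
#' `cutree`/dendrogram tooling applies.
#'
#' @param corr symmetric correlation matrix.
#' @return a `cluster_result`: list with `corr`, `merge`, `height`,
#'   `order`, `labels` and `hclust` (an equivalent `stats::hclust`
#'   object).
#' @export
cluster_complete_linkage <- function(corr) {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  n <- nrow(corr)
  d <- 1 - corr
  labels <- rownames(corr) %||% as.character(seq_len(n))
  # active cluster distance matrix, complete-linkage (max) update
  cd <- d; diag(cd) <- Inf
  id <- -seq_len(n)             # hclust convention: negatives are leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(n)) {
      if (!active[i]) next
      for (j in seq_len(n)) {
        if (j <= i || !active[j]) next
        if (cd[i, j] < best - 1e-12) { best <- cd[i, j]; bi <- i; bj <- j }
      }
    }
    merge[step, ] <- c(id[bi], id[bj])
    height[step] <- best
    # merged cluster lives in slot bi; complete-linkage distance update
    for (k in seq_len(n)) if (active[k] && k != bi && k != bj)
      cd[bi, k] <- cd[k, bi] <- max(cd[bi, k], cd[bj, k])
    active[bj] <- FALSE
    id[bi] <- step
  }
  hc <- structure(list(merge = merge, height = height,
                       order = .dendrogram_order(merge),
                       labels = labels, method = "complete",
                       dist.method = "1 - Pearson r",
                       call = match.call()),
                  class = "hclust")
  structure(list(corr = corr, merge = merge, height = height,
                 order = hc$order, labels = labels, hclust = hc),
            class = "cluster_result")
}

# Leaf order by left-to-right traversal of the merge tree.
.dendrogram_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Cut a cluster result into k groups
#'
#' @param result a `cluster_result`.
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cut_clusters <- function(result, k) {
  stopifnot(inherits(result, "cluster_result"))
  stats::cutree(result$hclust, k = k)
}

#' Rank starter-cell centers from rostral to caudal
#'
#' Dense ranks of the starter-count-weighted center bregma; the most
#' rostral (largest bregma) center gets rank 1 and ties share a rank.
#'
#' @param centers numeric vector of center bregma values (mm), optionally
#'   named by mouse.
#' @return integer vector of dense ranks.
#' @export
starter_center_ranks <- function(centers) {
  u <- sort(unique(centers), decreasing = TRUE)
  out <- match(centers, u)
  names(out) <- names(centers)
  out
}
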