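#' Best-seed F1 protocol
#'
#' Runs a local clustering algorithm from every node of a ground-truth
#' community and reports the evaluation of the seed that yields the best F1
#' score against that community — the standard protocol for scoring local
#' community detection when any member may serve as the query node.
#'
#' @param x the input structure the algorithm runs on (a [hypergraph()] or
#'   an [igraph::igraph] graph)
#' @param community nonempty vector of ground-truth node labels
#' @param algo a function `algo(x, seed, params, ...)` returning a
#'   `crd_cluster`-like object with a `cluster` field, e.g. [hgcrd()],
#'   [crd()], or [crd_m()] wrapped to fix its motif
#' @param params passed to `algo`
#' @param ... further arguments passed to `algo`
#' @return a one-row [tibble::tibble] with `seed`, `precision`, `recall`,
#'   `f1`; seeds on which the algorithm fails (e.g. no motif instance at the
#'   seed) are skipped, and an error is raised only when every seed fails
#' @export
best_seed_f1 <- function(x, community, algo, params, ...) {
  tab <- seed_distribution(x, community, algo, params, ...)
  ok <- !is.na(tab$f1)
  if (!any(ok)) stop("protocol error: the algorithm failed from every seed")
  best <- which(ok)[which.max(tab$f1[ok])]
  tibble::tibble(seed = tab$seed[best], precision = tab$precision[best],
                 recall = tab$recall[best], f1 = tab$f1[best])
}

#' Per-seed robustness distribution
#'
#' Runs the algorithm from every community node and tabulates, per seed, the
#' returned cluster's size, motif conductance and precision/recall/F1
#' against the community. Medians (lower-middle element for even counts, see
#' [median_low()]) are attached as the `"medians"` attribute and shown by
#' `print`.
#'
#' @inheritParams best_seed_f1
#' @return a [tibble::tibble] with one row per seed (`seed`, `size`, `phi`,
#'   `precision`, `recall`, `f1`; failed seeds carry `NA`s) with attribute
#'   `medians`
#' @export
seed_distribution <- function(x, community, algo, params, ...) {
  community <- unique(as.character(community))
  if (length(community) == 0L) stop("community must be nonempty")
  rows <- lapply(community, function(s) {
    res <- tryCatch(algo(x, seed = s, params = params, ...),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(seed = s, size = NA_integer_, phi = NA_real_,
                            precision = NA_real_, recall = NA_real_,
                            f1 = NA_real_))
    }
    ev <- cluster_eval(res$cluster, community)
    tibble::tibble(seed = s, size = length(res$cluster),
                   phi = if (!is.null(res$phi)) res$phi else NA_real_,
                   precision = ev$precision, recall = ev$recall, f1 = ev$f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "medians") <- list(f1 = median_low(out$f1[!is.na(out$f1)]),
                               phi = median_low(out$phi[!is.na(out$phi)]))
  out
}

#' Lower median
#'
#' The lower middle element for even-length inputs (a deterministic,
#' always-attained median), the ordinary middle element otherwise.
#'
#' @param x numeric vector (NAs removed by the caller)
#' @return a single value; `NA` for empty input
#' @export
median_low <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sort(x)[floor((length(x) + 1) / 2)]
}
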