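#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a diffusion cluster result
#'
#' One row per node of the best sweep ordering: its level and flow at the
#' iteration that produced the returned cluster, the running prefix motif
#' conductance, and whether it made the returned cluster.
#'
#' @param x a `crd_cluster` from [hgcrd()], [crd()] or [crd_m()]
#' @param ... unused
#' @return a [tibble::tibble] with columns `node`, `level`, `node_flow`,
#'   `phi`, `in_cluster`
#' @export
tidy.crd_cluster <- function(x, ...) {
  pr <- x$sweep$profile
  pr$in_cluster <- pr$node %in% x$cluster
  pr
}

#' One-row summary of a diffusion cluster result
#'
#' @inheritParams tidy.crd_cluster
#' @return a one-row [tibble::tibble]: `algorithm`, `seed`, `size`, `phi`,
#'   `cut`, `volume`, `iterations_run`, `terminated_by`
#' @export
glance.crd_cluster <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, seed = x$seed,
                 size = length(x$cluster), phi = x$phi, cut = x$cut,
                 volume = x$volume, iterations_run = x$iterations_run,
                 terminated_by = x$terminated_by)
}

#' Sweep-conductance profile plot
#'
#' Prefix motif conductance along the level-ordered sweep of the iteration
#' that produced the returned cluster; the chosen prefix is marked.
#'
#' @param object a `crd_cluster`
#' @param ... unused
#' @return a [ggplot2::ggplot]
#' @export
autoplot.crd_cluster <- function(object, ...) {
  pr <- tidy(object)
  pr$rank <- seq_len(nrow(pr))
  best <- length(object$cluster)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$rank, y = .data$phi)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_cluster), na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "sweep prefix size", y = "motif conductance",
                  colour = "in cluster",
                  title = sprintf("%s sweep from seed %s: phi* = %.3g",
                                  object$algorithm, object$seed, object$phi)) +
    ggplot2::theme_minimal()
}

#' Per-iteration diffusion history plot
#'
#' Best sweep conductance and retained flow per outer doubling iteration.
#'
#' @param x a `crd_cluster`
#' @return a [ggplot2::ggplot]
#' @export
plot_history <- function(x) {
  stopifnot(inherits(x, "crd_cluster"))
  h <- tibble::as_tibble(x$history)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$sweep_phi)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "outer iteration", y = "best sweep motif conductance") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
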