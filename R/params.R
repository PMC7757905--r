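`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diffusion parameters
#'
#' Controls for the capacity-releasing diffusion. `phi` is the target
#' conductance scale: when `C` (per-hyperedge capacity) or `h` (maximum node
#' level) are not given explicitly they default to `ceiling(1/phi)` and
#' `ceiling(3 * log(total initial flow) / phi)` respectively (natural log;
#' the flow total is taken at the start of each inner run). Explicit `C`/`h`
#' win over `phi`-derived values. `tau` (> 1) sets the excess-removal
#' stopping rule: the outer loop stops once the flow retained after excess
#' truncation drops to `1/tau` of the amount doubling alone would have
#' produced — i.e. more than a `1 - 1/tau` fraction of the flow piled up as
#' excess, signalling a bottleneck. `t` caps the number of outer doubling
#' iterations (the loop runs `j = 0..t`) and `alpha` is the number of
#' strictly-lower-level co-members a hyperedge needs to be eligible for a
#' push.
#'
#' @param phi target conductance in `(0, 1]`; optional when both `C` and `h`
#'   are given
#' @param C positive integer hyperedge capacity
#' @param h positive integer maximum node level
#' @param tau excess-removal stopping factor, `> 1`
#' @param t non-negative integer outer iteration cap
#' @param alpha integer eligibility count, `>= 1` (at most hyperedge size - 1)
#' @return an object of class `crd_params`
#' @export
crd_params <- function(phi = NULL, C = NULL, h = NULL, tau = 2, t = 20,
                       alpha = 1) {
  if (is.null(phi) && (is.null(C) || is.null(h))) {
    stop("supply phi, or both C and h")
  }
  if (!is.null(phi) && (phi <= 0 || phi > 1)) stop("phi must be in (0, 1]")
  if (!is.null(C) && C < 1) stop("C must be >= 1")
  if (!is.null(h) && h < 1) stop("h must be >= 1")
  if (tau <= 1) stop("tau must be > 1")
  if (t < 0) stop("t must be >= 0")
  if (alpha < 1) stop("alpha must be >= 1")
  structure(list(phi = phi,
                 C = if (!is.null(C)) as.integer(ceiling(C)),
                 h = if (!is.null(h)) as.integer(ceiling(h)),
                 tau = tau, t = as.integer(t), alpha = as.integer(alpha)),
            class = "crd_params")
}

#' @exportS3Method base::print
print.crd_params <- function(x, ...) {
  cat("diffusion parameters:\n")
  cat(sprintf("  phi = %s, C = %s, h = %s, tau = %g, t = %d, alpha = %d\n",
              x$phi %||% "-", x$C %||% "auto", x$h %||% "auto",
              x$tau, x$t, x$alpha))
  invisible(x)
}

# resolve capacity / level cap for one inner run
params_C <- function(params) {
  params$C %||% as.integer(ceiling(1 / params$phi))
}

params_h <- function(params, total_flow) {
  params$h %||% max(1L, as.integer(ceiling(3 * log(max(total_flow, 2)) / params$phi)))
}
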