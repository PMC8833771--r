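#' Wendland C2 kernel
#'
#' The compactly supported radial kernel \eqn{\psi(r) = (1-r)^4 (4r+1)} for
#' \eqn{r \in [0, 1]} and 0 otherwise. It is positive definite in up to
#' three dimensions and twice continuously differentiable, which makes it a
#' convenient minimal-smoothness choice for expanding coefficient
#' trajectories over landmark time.
#'
#' @param r Nonnegative scaled distances.
#' @return Kernel values, same length as `r`.
#' @examples
#' wendland_c2(c(0, 0.5, 1, 2))
#' @export
wendland_c2 <- function(r) {
  out <- numeric(length(r))
  inside <- r >= 0 & r < 1
  ri <- r[inside]
  out[inside] <- (1 - ri)^4 * (4 * ri + 1)
  out
}

#' Spline basis specification for dynamic coefficients
#'
#' Describes the basis \eqn{\phi_1(s), \ldots, \phi_k(s)} through which each
#' time-dependent covariate effect \eqn{\beta(s) = \sum_i \alpha_i \phi_i(s)}
#' varies over landmark time `s` (months). The default family places
#' Wendland C2 kernels at `nodes` with a common `support_radius`, optionally
#' preceded by a constant function so that a time-constant effect lies
#' exactly in the span.
#'
#' @param nodes Kernel node locations in landmark time (months).
#' @param support_radius Support radius of each kernel (months, > 0).
#' @param include_constant Add a constant basis function `phi_0(s) = 1`
#'   (default `TRUE`). Required by [wald_test_time_varying()].
#' @param family Kernel family; only `"wendland_c2"` is built in.
#' @param transform Optional invertible k x k matrix `A` replacing the
#'   basis by the reparameterization `phi(s)' A`. The span -- and hence
#'   fitted trajectories, likelihood and predictions -- is unchanged;
#'   individual coefficients lose their named interpretation, so
#'   [wald_test_time_varying()] refuses transformed bases.
#' @return An object of class `basis_spec`.
#' @seealso [default_basis()], [evaluate_basis()]
#' @export
basis_spec <- function(nodes, support_radius, include_constant = TRUE,
                       family = "wendland_c2", transform = NULL) {
  if (!identical(family, "wendland_c2")) {
    abort_config("unknown basis family '%s'", family)
  }
  nodes <- as.numeric(nodes)
  if (length(nodes) < 1L && !include_constant) {
    abort_config("basis must contain at least one function")
  }
  if (!is.numeric(support_radius) || length(support_radius) != 1L ||
      !is.finite(support_radius) || support_radius <= 0) {
    abort_config("support_radius must be a single positive number")
  }
  if (is.unsorted(nodes, strictly = TRUE)) {
    abort_config("basis nodes must be strictly increasing")
  }
  k <- length(nodes) + as.integer(include_constant)
  names_k <- c(if (include_constant) "const",
               if (length(nodes)) paste0("w", seq_along(nodes)))
  if (!is.null(transform)) {
    transform <- as.matrix(transform)
    if (nrow(transform) != k || ncol(transform) != k) {
      abort_config("transform must be a %d x %d matrix", k, k)
    }
    if (abs(det(transform)) < 1e-12) abort_config("transform must be invertible")
    names_k <- paste0("b", seq_len(k))
  }
  structure(
    list(family = family, nodes = nodes, support_radius = support_radius,
         include_constant = include_constant, k = k, names = names_k,
         transform = transform),
    class = "basis_spec"
  )
}

#' Default basis over a landmark grid
#'
#' Places `n_nodes` Wendland kernels equally spaced over the landmark range
#' with support radius `radius_factor` times the node spacing, plus a
#' constant function. With the default four nodes on a 0--12 month grid this
#' gives k = 5 basis functions, nodes at 0, 4, 8, 12 and radius 8 months.
#'
#' @param landmarks Landmark grid the model will be fitted on (months).
#' @param n_nodes Number of kernel nodes (default 4).
#' @param radius_factor Support radius as a multiple of node spacing
#'   (default 2).
#' @return A [basis_spec()].
#' @export
default_basis <- function(landmarks, n_nodes = 4, radius_factor = 2) {
  landmarks <- as.numeric(landmarks)
  lo <- min(landmarks); hi <- max(landmarks)
  if (hi <= lo) {
    # single landmark: constant-only basis (static special case)
    return(basis_spec(nodes = numeric(0), support_radius = 1,
                      include_constant = TRUE))
  }
  nodes <- seq(lo, hi, length.out = n_nodes)
  spacing <- nodes[2L] - nodes[1L]
  basis_spec(nodes = nodes, support_radius = radius_factor * spacing,
             include_constant = TRUE)
}

#' Evaluate a basis at landmark times
#'
#' @param spec A [basis_spec()].
#' @param s Landmark times (months); may be a vector.
#' @return A `length(s) x k` matrix with one column per basis function.
#'   Kernel columns are zero outside their support; the constant column is
#'   identically 1.
#' @examples
#' b <- basis_spec(nodes = c(0, 6, 12), support_radius = 6)
#' evaluate_basis(b, c(0, 3, 12))
#' @export
evaluate_basis <- function(spec, s) {
  stopifnot(inherits(spec, "basis_spec"))
  s <- as.numeric(s)
  if (any(!is.finite(s))) abort_data("landmark times must be finite")
  cols <- list()
  if (spec$include_constant) cols$const <- rep(1, length(s))
  for (i in seq_along(spec$nodes)) {
    r <- abs(s - spec$nodes[i]) / spec$support_radius
    cols[[paste0("w", i)]] <- wendland_c2(r)
  }
  out <- do.call(cbind, cols)
  if (!is.null(spec$transform)) {
    out <- out %*% spec$transform
    colnames(out) <- spec$names
  }
  rownames(out) <- NULL
  out
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("Basis: %s, k = %d%s\n", x$family, x$k,
              if (x$include_constant) " (incl. constant)" else ""))
  if (length(x$nodes)) {
    cat("  nodes:", paste(format(x$nodes), collapse = ", "),
        "  support radius:", format(x$support_radius), "months\n")
  }
  invisible(x)
}
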