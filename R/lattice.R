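#' Dual lattice on the unit square
#'
#' The scheme discretizes the unit square on two staggered grids with spacing
#' `h = 1/N`: the *main* lattice of cell centers \eqn{((i-1/2)h, (j-1/2)h)},
#' `i, j = 1..N`, where the tip density and the transport velocity live, and
#' the *sub* lattice of cell corners \eqn{(ih, jh)}, `i, j = 0..N`, where the
#' chemotactic potential and the fluxes live. The velocity stencil at a main
#' point averages difference quotients of the potential at the four
#' surrounding corners, so the full `(N+1) x (N+1)` corner set is carried.
#'
#' Matrix convention throughout the package: rows index `i` (along x), columns
#' index `j` (along y), 1-based, origin at the lower-left corner.
#'
#' @param N cells per side (positive integer).
#' @return An object of class `dual_lattice`: list with `N`, `h`, `x_main`
#'   (the N cell-center coordinates) and `x_sub` (the N+1 corner coordinates).
#' @export
dual_lattice <- function(N = 100) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2, N == as.integer(N))
  N <- as.integer(N)
  h <- 1 / N
  structure(list(N = N, h = h,
                 x_main = (seq_len(N) - 0.5) * h,
                 x_sub = (0:N) * h),
            class = "dual_lattice")
}

#' @export
print.dual_lattice <- function(x, ...) {
  cat(sprintf("Dual lattice: N = %d, h = %g (main %dx%d centers, sub %dx%d corners)\n",
              x$N, x$h, x$N, x$N, x$N + 1L, x$N + 1L))
  invisible(x)
}
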