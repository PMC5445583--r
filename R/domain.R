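#' Define a rectangular lattice domain
#'
#' The simulation runs on an `Lx` by `Ly` square lattice. A site is addressed
#' as `(i, j)` where `i` (1..Lx) is the column and `j` (1..Ly) the row, both
#' 1-based. The top and bottom of the domain (the y direction) are always
#' periodic: rows 1 and `Ly` are neighbours. The left and right edges (the x
#' direction) never wrap; they are either reflecting (`"no_flux"`, moves off
#' the domain carry no probability) or open (`"flux"`, an agent stepping off
#' the domain leaves the simulation).
#'
#' @param Lx Number of sites per row (columns); at least 2.
#' @param Ly Number of sites per column (rows); at least 1.
#' @param delta Physical lattice spacing in micrometres. Metadata only: one
#'   site is one cell diameter (26 um in the motivating assay).
#' @param x_boundary `"no_flux"` or `"flux"`.
#'
#' @return An object of class `abm_domain`.
#' @examples
#' abm_domain(100, 100)
#' abm_domain(23, 23, x_boundary = "flux")
#' @export
abm_domain <- function(Lx, Ly, delta = 26, x_boundary = c("no_flux", "flux")) {
  x_boundary <- match.arg(x_boundary)
  Lx <- as.integer(Lx)
  Ly <- as.integer(Ly)
  if (is.na(Lx) || Lx < 2) abort("`Lx` must be an integer >= 2.")
  if (is.na(Ly) || Ly < 1) abort("`Ly` must be an integer >= 1.")
  if (!is.numeric(delta) || delta <= 0) abort("`delta` must be positive.")
  structure(
    list(Lx = Lx, Ly = Ly, delta = as.numeric(delta), x_boundary = x_boundary),
    class = "abm_domain"
  )
}

#' @export
print.abm_domain <- function(x, ...) {
  cat(sprintf(
    "<abm_domain> %d x %d sites (delta = %g um), x boundary: %s, y periodic\n",
    x$Lx, x$Ly, x$delta, x$x_boundary
  ))
  invisible(x)
}

is_abm_domain <- function(x) inherits(x, "abm_domain")
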