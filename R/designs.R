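#' Experiment designs
#'
#' An experiment design bundles everything needed to regenerate a synthetic
#' dataset: the lattice domain, the initial-condition rule, the boundary and
#' replenishment behaviour, the sampling times and the replicate count.
#'
#' Three presets mirror the study conditions:
#' * `"unrealistic"` — 100 x 100 lattice, deterministic double-sided wound
#'   (columns 1-10 and 91-100 occupied), no-flux x boundaries, 10 replicates.
#' * `"realistic_small"` — 23 x 23 lattice (a 597.24 um field of view at
#'   26 um per site), single-sided initial condition drawn from per-column
#'   densities, open (flux) x boundaries with the left column kept at or
#'   above its initial density, 5 replicates.
#' * `"realistic_large"` — the same per-column densities on a 23 x 184
#'   lattice (the y extent scaled by 8), 5 replicates.
#'
#' @param name One of `"unrealistic"`, `"realistic_small"`,
#'   `"realistic_large"`.
#' @return An object of class `experiment_design`.
#' @examples
#' design_preset("realistic_small")
#' @export
design_preset <- function(name = c("unrealistic", "realistic_small",
                                   "realistic_large")) {
  name <- match.arg(name)
  switch(name,
    unrealistic = design_unrealistic(),
    realistic_small = design_realistic(),
    realistic_large = scale_design(design_realistic(), 8)
  )
}

#' @rdname design_preset
#' @param Lx,Ly Lattice size.
#' @param n_replicates Replicates used when generating synthetic data.
#' @param times Sampling times in minutes.
#' @param block_width Width of each occupied block in the double-sided
#'   initial condition.
#' @export
design_unrealistic <- function(Lx = 100, Ly = 100, n_replicates = 10,
                               times = c(240, 480, 720), block_width = 10) {
  new_design(
    name = "unrealistic",
    domain = abm_domain(Lx, Ly, x_boundary = "no_flux"),
    init = list(type = "unrealistic", block_width = block_width),
    replenish = NULL, times = times, n_replicates = n_replicates
  )
}

#' @rdname design_preset
#' @param column_densities Initial per-column densities (length `Lx`);
#'   defaults to [default_column_densities()].
#' @param replenish_density Minimum density maintained in column 1
#'   (default: the initial density of column 1).
#' @export
design_realistic <- function(Lx = 23, Ly = 23,
                             column_densities = default_column_densities(Lx),
                             replenish_density = column_densities[[1]],
                             n_replicates = 5, times = c(240, 480, 720)) {
  if (length(column_densities) != Lx)
    abort("`column_densities` must have length Lx.")
  new_design(
    name = sprintf("realistic_%dx%d", Lx, Ly),
    domain = abm_domain(Lx, Ly, x_boundary = "flux"),
    init = list(type = "column_densities", densities = column_densities),
    replenish = replenish_density, times = times, n_replicates = n_replicates
  )
}

new_design <- function(name, domain, init, replenish, times, n_replicates) {
  structure(
    list(name = name, domain = domain, init = init, replenish = replenish,
         times = as.numeric(times), n_replicates = as.integer(n_replicates)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %s: %d x %d (%s x), %s initial condition, %d replicates, t = %s\n",
    x$name, x$domain$Lx, x$domain$Ly, x$domain$x_boundary, x$init$type,
    x$n_replicates, paste(x$times, collapse = ", ")))
  if (!is.null(x$replenish))
    cat(sprintf("  left column kept at density >= %g\n", x$replenish))
  invisible(x)
}

#' Default single-sided initial column densities
#'
#' A stand-in for the averaged initial frame of the assay: the `width`
#' left-most columns fully occupied, a linear ramp to zero over the next
#' `ramp` columns, and empty space (the wound) beyond. With the defaults on
#' a 23-column lattice, columns 1-6 have density 1, columns 7-9 have 0.75,
#' 0.5, 0.25, and columns 10-23 are empty. Measured profiles can be supplied
#' to [design_realistic()] instead.
#'
#' @param Lx Number of columns.
#' @param width Number of fully occupied columns.
#' @param ramp Number of columns over which density ramps to zero.
#' @return A numeric vector of length `Lx`.
#' @export
default_column_densities <- function(Lx, width = 6, ramp = 3) {
  if (width + ramp > Lx) abort("`width + ramp` exceeds Lx.")
  c(rep(1, width),
    seq(1, 0, length.out = ramp + 2)[-c(1, ramp + 2)],
    rep(0, Lx - width - ramp))
}

#' Scale a design's domain in the y direction
#'
#' Multiplies `Ly` by an integer factor while keeping the initial per-column
#' densities (and everything else) unchanged. Growing the domain this way is
#' the simulation analogue of widening the microscope field of view: the
#' expected initial density profile is identical but the agent count grows
#' with the domain.
#'
#' @param design An `experiment_design` with a column-density initial
#'   condition, or the unrealistic preset (whose blocks are full columns).
#' @param y_factor Positive integer scale factor.
#' @return The scaled `experiment_design`.
#' @examples
#' scale_design(design_realistic(), 8)$domain$Ly # 184
#' @export
scale_design <- function(design, y_factor) {
  stopifnot(inherits(design, "experiment_design"))
  if (!is.numeric(y_factor) || length(y_factor) != 1 ||
      y_factor != round(y_factor) || y_factor < 1)
    abort("`y_factor` must be a positive integer.")
  d <- design$domain
  design$domain <- abm_domain(d$Lx, d$Ly * as.integer(y_factor),
                              delta = d$delta, x_boundary = d$x_boundary)
  design$name <- sprintf("%s_y%d", design$name, as.integer(y_factor))
  design
}

#' Domain area (site count) of a design
#' @param design An `experiment_design`.
#' @return `Lx * Ly`.
#' @export
design_area <- function(design) design$domain$Lx * design$domain$Ly

#' Draw the initial state of a design
#'
#' Deterministic for the unrealistic preset; random (per-column binomial-free
#' placement of `round(density * Ly)` agents) for column-density designs.
#' Uses the current RNG state unless `seed` is given.
#'
#' @param design An `experiment_design`.
#' @param seed Optional integer seed.
#' @return An [occupancy_state()].
#' @export
initial_state <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- design$domain
  switch(design$init$type,
    unrealistic = initialize_unrealistic(d$Lx, d$Ly, delta = d$delta,
                                         block_width = design$init$block_width),
    column_densities = initialize_from_column_densities(
      design$init$densities, d$Ly, delta = d$delta,
      x_boundary = d$x_boundary),
    abort("unknown initial-condition type.")
  )
}

#' Generate a synthetic dataset from a design
#'
#' Runs `n_replicates` independent simulations of the design at the given
#' parameters, computes the requested summary statistics at every sampling
#' time, and returns both the per-replicate values and their ensemble
#' average. Replicate `r` uses seed `seed + r`, so datasets are reproducible
#' and replicates independent.
#'
#' @param design An `experiment_design`.
#' @param params An [abm_params()].
#' @param n_replicates Number of replicates (default: the design's).
#' @param seed Integer base seed.
#' @param statistics Which statistics to compute.
#' @return An object of class `summary_dataset`: a list with `replicates`
#'   (long tibble with a `rep` column), `ensemble` (long tibble of means),
#'   `params`, `design`, `n_replicates`, `seed`.
#' @examples
#' \donttest{
#' ds <- generate_synthetic_data(design_realistic(), abm_params(0.5, 0.25, "B"),
#'                               seed = 1)
#' head(ds$ensemble)
#' }
#' @export
generate_synthetic_data <- function(design, params,
                                    n_replicates = design$n_replicates,
                                    seed = 1,
                                    statistics = c("displacement",
                                                   "density_profile", "pcf")) {
  stopifnot(inherits(design, "experiment_design"))
  statistics <- match.arg(statistics,
                          c("displacement", "density_profile", "pcf"),
                          several.ok = TRUE)
  template <- stat_template(design, statistics)
  vals <- vapply(seq_len(n_replicates), function(rep_idx) {
    set.seed(seed + rep_idx)
    replicate_stat_values(design, params, statistics)
  }, numeric(nrow(template)))
  vals <- matrix(vals, nrow = nrow(template))
  reps <- tibble(
    rep = rep(seq_len(n_replicates), each = nrow(template)),
    statistic = rep(template$statistic, n_replicates),
    t = rep(template$t, n_replicates),
    r = rep(template$r, n_replicates),
    value = as.vector(vals)
  )
  structure(
    list(replicates = reps, ensemble = ensemble_average(reps),
         params = params, design = design,
         n_replicates = as.integer(n_replicates), seed = seed),
    class = "summary_dataset"
  )
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf(
    "<summary_dataset> %s, model %s (Pm = %g, alpha = %g), %d replicates\n",
    x$design$name, x$params$model, x$params$pm, x$params$alpha,
    x$n_replicates))
  print(x$ensemble)
  invisible(x)
}

#' @export
tidy.summary_dataset <- function(x, ...) x$ensemble

#' @export
glance.summary_dataset <- function(x, ...) {
  tibble(design = x$design$name, model = x$params$model, pm = x$params$pm,
         alpha = x$params$alpha, n_replicates = x$n_replicates,
         seed = x$seed)
}
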