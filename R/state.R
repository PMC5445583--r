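#' Occupancy states
#'
#' An occupancy state couples a lattice domain with an agent registry: one
#' row per agent with its id, current column `col`, current row `row`, and
#' the column it started in (`init_col`, used for displacement bookkeeping).
#' At most one agent may occupy a site (exclusion).
#'
#' @param agents A data frame with integer columns `id`, `col`, `row`,
#'   `init_col`.
#' @param domain An [abm_domain()].
#' @return An object of class `occupancy_state`.
#' @export
occupancy_state <- function(agents, domain) {
  stopifnot(is_abm_domain(domain))
  agents <- as_tibble(agents)
  required <- c("id", "col", "row", "init_col")
  if (!all(required %in% names(agents)))
    abort("`agents` needs columns id, col, row, init_col.")
  agents <- agents[required]
  agents[] <- lapply(agents, as.integer)
  if (nrow(agents)) {
    if (any(agents$col < 1 | agents$col > domain$Lx |
            agents$row < 1 | agents$row > domain$Ly))
      abort("agent positions outside the lattice.")
    if (anyDuplicated(agents[c("col", "row")]))
      abort("exclusion violated: two agents share a lattice site.")
    if (anyDuplicated(agents$id)) abort("duplicated agent ids.")
  }
  structure(list(agents = agents, domain = domain), class = "occupancy_state")
}

#' @export
print.occupancy_state <- function(x, ...) {
  cat(sprintf("<occupancy_state> %d agents on a %d x %d lattice\n",
              nrow(x$agents), x$domain$Lx, x$domain$Ly))
  invisible(x)
}

#' @export
as_tibble.occupancy_state <- function(x, ...) x$agents

n_agents <- function(state) nrow(state$agents)

#' Convert an occupancy state to / from a 0-1 grid matrix
#'
#' The grid has `Ly` rows and `Lx` columns; entry `[j, i]` is 1 when site
#' `(i, j)` is occupied.
#'
#' @param state An [occupancy_state()].
#' @return For `as_grid()`, an integer `Ly x Lx` matrix.
#' @export
as_grid <- function(state) {
  d <- state$domain
  g <- matrix(0L, nrow = d$Ly, ncol = d$Lx)
  if (nrow(state$agents))
    g[cbind(state$agents$row, state$agents$col)] <- 1L
  g
}

#' @rdname as_grid
#' @param grid An `Ly x Lx` 0/1 matrix.
#' @param domain An [abm_domain()] consistent with `dim(grid)`.
#' @export
state_from_grid <- function(grid, domain) {
  stopifnot(is_abm_domain(domain))
  if (nrow(grid) != domain$Ly || ncol(grid) != domain$Lx)
    abort("grid dimensions do not match the domain.")
  if (!all(grid %in% c(0L, 1L))) abort("grid entries must be 0 or 1.")
  occ <- which(grid == 1L, arr.ind = TRUE)
  occupancy_state(
    tibble(id = seq_len(nrow(occ)), col = occ[, 2], row = occ[, 1],
           init_col = occ[, 2]),
    domain
  )
}

#' Double-sided wound initial condition
#'
#' Deterministic idealised scratch: the 10 left-most and 10 right-most
#' columns are fully occupied and the space between them is the wound. With
#' the default 100 x 100 lattice this places 2000 agents. The geometry is
#' deliberately uniform; no real assay starts this cleanly, which is why the
#' companion single-sided generator exists ([initialize_from_column_densities()]).
#'
#' @param Lx,Ly Lattice size; `Lx` must be at least 20 so both occupied
#'   blocks fit.
#' @param delta Lattice spacing in micrometres (metadata).
#' @param block_width Width of each occupied block (default 10 columns).
#' @return An [occupancy_state()] on a no-flux domain.
#' @examples
#' st <- initialize_unrealistic()
#' nrow(st$agents) # 2000
#' @export
initialize_unrealistic <- function(Lx = 100, Ly = 100, delta = 26,
                                   block_width = 10) {
  if (Lx < 2 * block_width) abort("`Lx` too small for two occupied blocks.")
  domain <- abm_domain(Lx, Ly, delta = delta, x_boundary = "no_flux")
  cols <- c(seq_len(block_width), seq(Lx - block_width + 1, Lx))
  agents <- tidyr::expand_grid(col = as.integer(cols), row = seq_len(Ly))
  agents <- mutate(agents, id = row_number(), init_col = .data$col)
  occupancy_state(agents, domain)
}

#' Single-sided initial condition from per-column densities
#'
#' Emulates the averaged initial frame of a scratch assay: column `i`
#' receives `round(density_i * Ly)` agents placed uniformly at random
#' without replacement among that column's sites.
#'
#' @param column_densities Numeric vector of length `Lx` with values in
#'   \[0, 1\].
#' @param Ly Number of rows.
#' @param seed Optional integer seed (`set.seed()` is called when supplied).
#' @param delta Lattice spacing in micrometres (metadata).
#' @param x_boundary Boundary behaviour of the resulting domain
#'   (default `"flux"`, as in the realisable experiment).
#' @return An [occupancy_state()].
#' @examples
#' initialize_from_column_densities(c(1, 0.5, 0), Ly = 4, seed = 1)
#' @export
initialize_from_column_densities <- function(column_densities, Ly, seed = NULL,
                                             delta = 26, x_boundary = "flux") {
  if (any(is.na(column_densities)) ||
      any(column_densities < 0 | column_densities > 1))
    abort("column densities must lie in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  Lx <- length(column_densities)
  domain <- abm_domain(Lx, Ly, delta = delta, x_boundary = x_boundary)
  counts <- as.integer(round(column_densities * Ly))
  rows <- purrr::map(counts, function(k) {
    if (k == 0) integer(0) else sort(sample.int(Ly, k))
  })
  agents <- tibble(
    col = rep.int(seq_len(Lx), lengths(rows)),
    row = unlist(rows, use.names = FALSE)
  )
  agents <- mutate(agents, id = row_number(), init_col = .data$col)
  occupancy_state(agents, domain)
}

#' Top up the left-most column to a target density
#'
#' Adds agents (fresh ids, `init_col = 1`) to empty sites of column 1,
#' chosen uniformly at random, until its density is at or above
#' `target_density`. A column already at or above the target is returned
#' unchanged. During a simulation with an open left boundary this rule keeps
#' the monolayer side of the wound supplied with cells; this helper exposes
#' the same rule for standalone use.
#'
#' @param state An [occupancy_state()].
#' @param target_density Required minimum density of column 1, in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The topped-up [occupancy_state()].
#' @export
replenish_left_column <- function(state, target_density, seed = NULL) {
  if (target_density < 0 || target_density > 1)
    abort("`target_density` must lie in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  Ly <- state$domain$Ly
  need <- ceiling(target_density * Ly - 1e-9)
  in_col1 <- state$agents$col == 1L
  have <- sum(in_col1)
  if (have >= need) return(state)
  empty_rows <- setdiff(seq_len(Ly), state$agents$row[in_col1])
  add_rows <- if (length(empty_rows) == 1) empty_rows else
    sample(empty_rows, need - have)
  next_id <- if (nrow(state$agents)) max(state$agents$id) + 1L else 1L
  new_agents <- tibble(
    id = seq.int(next_id, length.out = length(add_rows)),
    col = 1L, row = as.integer(add_rows), init_col = 1L
  )
  occupancy_state(bind_rows(state$agents, new_agents), state$domain)
}
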