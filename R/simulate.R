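#' Simulate the exclusion-process agent-based model
#'
#' Exact continuous-time simulation (Gillespie direct method) of agents on a
#' lattice with volume exclusion. Each agent carries attempt rate `pm`; at
#' each event one agent is chosen uniformly and moves to one of its
#' neighbour sites with the per-direction probability of
#' [transition_probability()] (model A or B). Moves into occupied sites are
#' aborted, which is equivalent to the event being a no-op. The y boundary
#' is periodic; the x boundary is reflecting (`"no_flux"`) or open
#' (`"flux"`, agents stepping off the domain leave the simulation). With an
#' open boundary the left-most column can be topped up to a minimum density
#' after every event that vacates one of its sites (`replenish`).
#'
#' @param domain An [abm_domain()].
#' @param params An [abm_params()].
#' @param init An [occupancy_state()] on the same domain geometry.
#' @param times Sorted, non-negative sampling times (minutes) at which
#'   snapshots are recorded. The state at `t = 0` is always retained as the
#'   record's `initial`.
#' @param seed Optional integer seed; when supplied the run is fully
#'   reproducible.
#' @param replenish `NULL` (off), `TRUE` (target density = the initial
#'   density of column 1), or a number in \[0, 1\] giving the target density.
#'   Requires a flux x boundary.
#'
#' @return An object of class `abm_record` with elements `snapshots` (one
#'   [occupancy_state()] per requested time), `times`, `initial`, `params`,
#'   `domain`, `seed`, and event counters `n_events`, `n_exited`, `n_added`.
#' @examples
#' dom <- abm_domain(10, 10)
#' st <- state_from_grid(matrix(rbinom(100, 1, 0.3), 10, 10), dom)
#' rec <- simulate_abm(dom, abm_params(0.5, 0.1, "A"), st,
#'                     times = c(60, 120), seed = 1)
#' @export
simulate_abm <- function(domain, params, init, times = c(240, 480, 720),
                         seed = NULL, replenish = NULL) {
  stopifnot(is_abm_domain(domain), inherits(params, "abm_params"),
            inherits(init, "occupancy_state"))
  if (init$domain$Lx != domain$Lx || init$domain$Ly != domain$Ly)
    abort("initial state and domain have different lattice sizes.")
  times <- as.numeric(times)
  if (length(times) == 0 || is.unsorted(times, strictly = FALSE) ||
      any(times < 0))
    abort("`times` must be non-negative and sorted ascending.")
  target <- NULL
  if (isTRUE(replenish)) {
    target <- sum(init$agents$col == 1L) / domain$Ly
  } else if (is.numeric(replenish)) {
    if (replenish < 0 || replenish > 1)
      abort("replenishment target density must lie in [0, 1].")
    target <- replenish
  } else if (!is.null(replenish) && !isFALSE(replenish)) {
    abort("`replenish` must be NULL, TRUE/FALSE, or a density in [0, 1].")
  }
  if (!is.null(target) && domain$x_boundary != "flux")
    abort("replenishment requires a flux x boundary.")
  if (!is.null(seed)) set.seed(seed)

  agents0 <- cbind(init$agents$col, init$agents$row, init$agents$init_col)
  storage.mode(agents0) <- "integer"
  res <- abm_gillespie_cpp(
    domain$Lx, domain$Ly, agents0,
    model = if (params$model == "A") 0L else 1L,
    pm = params$pm, alpha = params$alpha,
    flux_x = domain$x_boundary == "flux",
    replenish = !is.null(target),
    replenish_density = if (is.null(target)) 0 else target,
    times = times
  )
  # ids in the C++ core are slot ids 1..n; map the initial block back to the
  # caller's ids so displacement joins work against `init`.
  id_map <- init$agents$id
  snapshots <- purrr::map(res$snapshots, function(m) {
    colnames(m) <- c("id", "col", "row", "init_col")
    a <- as_tibble(m)
    inside <- a$id <= length(id_map)
    a$id[inside] <- id_map[a$id[inside]]
    if (any(!inside) && length(id_map))
      a$id[!inside] <- a$id[!inside] - length(id_map) + max(id_map)
    occupancy_state(a, domain)
  })
  names(snapshots) <- format(times, trim = TRUE)
  structure(
    list(snapshots = snapshots, times = times, initial = init,
         params = params, domain = domain, seed = seed,
         replenish = target,
         n_events = res$n_events, n_exited = res$n_exited,
         n_added = res$n_added),
    class = "abm_record"
  )
}

#' @export
print.abm_record <- function(x, ...) {
  cat(sprintf(
    "<abm_record> %d x %d lattice, model %s (Pm = %g, alpha = %g)\n",
    x$domain$Lx, x$domain$Ly, x$params$model, x$params$pm, x$params$alpha))
  cat(sprintf("  snapshots at t = %s min; %g events, %g exited, %g added\n",
              paste(x$times, collapse = ", "), x$n_events, x$n_exited,
              x$n_added))
  invisible(x)
}

#' @export
as_tibble.abm_record <- function(x, ...) {
  purrr::map2(x$times, x$snapshots,
              function(t, s) mutate(s$agents, time = t, .before = 1)) %>%
    bind_rows()
}

#' Extract a snapshot from a simulation record
#'
#' @param record An `abm_record` from [simulate_abm()].
#' @param t A recorded time, or 0 for the initial state.
#' @return An [occupancy_state()].
#' @export
snapshot_state <- function(record, t) {
  if (t == 0 && !any(record$times == 0)) return(record$initial)
  idx <- which(record$times == t)
  if (length(idx) != 1)
    abort(sprintf("time %g was not recorded (available: %s).",
                  t, paste(record$times, collapse = ", ")))
  record$snapshots[[idx]]
}
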