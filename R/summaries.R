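#' Column density profile
#'
#' Fraction of occupied sites per lattice column,
#' `C_t(i) = (# agents in column i) / Ly`. This is the macroscopic shape of
#' the cell front as it invades the wound.
#'
#' @param state An [occupancy_state()].
#' @return A tibble with columns `i` (1..Lx) and `density`.
#' @export
density_profile <- function(state) {
  d <- state$domain
  tibble(i = seq_len(d$Lx),
         density = tabulate(state$agents$col, nbins = d$Lx) / d$Ly)
}

#' Horizontal pair counts
#'
#' Number of unordered agent pairs at each horizontal (column) separation
#' `m = 1..Lx-1`. Distances never wrap the x boundary and same-column pairs
#' (`m = 0`) are excluded; [same_column_pairs()] reports them separately.
#' Computed from the per-column occupancy counts `k_i` as
#' `c(m) = sum_i k_i * k_(i+m)`.
#'
#' @param state An [occupancy_state()].
#' @return A tibble with columns `m` and `count`.
#' @export
pair_counts <- function(state) {
  d <- state$domain
  k <- tabulate(state$agents$col, nbins = d$Lx)
  m <- seq_len(d$Lx - 1)
  counts <- vapply(m, function(mm) {
    sum(k[seq_len(d$Lx - mm)] * k[seq_len(d$Lx - mm) + mm])
  }, numeric(1))
  tibble(m = m, count = counts)
}

#' @rdname pair_counts
#' @return For `same_column_pairs()`, the number of unordered agent pairs
#'   sharing a column.
#' @export
same_column_pairs <- function(state) {
  k <- tabulate(state$agents$col, nbins = state$domain$Lx)
  sum(k * (k - 1) / 2)
}

#' Pair-count expectation under complete spatial randomness
#'
#' Expected number of occupied horizontal pairs at separation `m` when `N`
#' agents are placed uniformly at random on the `Lx x Ly` lattice (without
#' double occupancy): `Ly^2 (Lx - m) rho rho_hat` with
#' `rho = N/(Lx Ly)` and `rho_hat = (N-1)/(Lx Ly - 1)`. This normalisation
#' accounts for volume exclusion.
#'
#' @param Lx,Ly Lattice dimensions.
#' @param N Agent count; at least 2.
#' @return A tibble with columns `m` and `expected`.
#' @export
pcf_normalisation <- function(Lx, Ly, N) {
  if (N < 2) abort("the PCF is undefined for fewer than 2 agents.")
  m <- seq_len(Lx - 1)
  rho <- N / (Lx * Ly)
  rho_hat <- (N - 1) / (Lx * Ly - 1)
  tibble(m = m, expected = Ly^2 * (Lx - m) * rho * rho_hat)
}

#' Horizontal pair-correlation function
#'
#' Ratio of observed to expected horizontal pair counts,
#' `q_t(m) = c_t(m) / c_hat_t(m)`. Values of 1 indicate no horizontal
#' spatial structure beyond what random placement at the same density would
#' give; adhesion pushes short-range `q` up, repulsion pushes it down.
#'
#' @param state An [occupancy_state()] with at least 2 agents.
#' @return A tibble with columns `m`, `count`, `expected`, `q`.
#' @examples
#' dom <- abm_domain(3, 1)
#' st <- occupancy_state(
#'   tibble::tibble(id = 1:2, col = c(1L, 3L), row = 1L, init_col = c(1L, 3L)),
#'   dom)
#' pcf(st)$q # (0, 3)
#' @export
pcf <- function(state) {
  d <- state$domain
  norm <- pcf_normalisation(d$Lx, d$Ly, n_agents(state))
  counts <- pair_counts(state)
  mutate(left_join(counts, norm, by = "m"),
         q = .data$count / .data$expected)
}

#' Average horizontal displacement of agents
#'
#' Mean absolute column displacement between two recorded times,
#' over the agents present at both (agents that left through an open
#' boundary, or were added by replenishment after `t_i`, are excluded).
#' Units are lattice sites.
#'
#' @param record An `abm_record` from [simulate_abm()].
#' @param t_i Start time (default 0, the initial state).
#' @param t_f End time (default the last recorded time).
#' @return A single number.
#' @export
average_horizontal_displacement <- function(record, t_i = 0,
                                            t_f = max(record$times)) {
  if (t_i >= t_f) abort("`t_i` must precede `t_f`.")
  a0 <- snapshot_state(record, t_i)$agents
  a1 <- snapshot_state(record, t_f)$agents
  both <- inner_join(a0, a1, by = "id", suffix = c("_i", "_f"))
  if (nrow(both) == 0)
    abort("no agent is present at both times; displacement undefined.")
  mean(abs(both$col_i - both$col_f))
}

#' Summary statistics of a simulation record, in long form
#'
#' Computes any of the three summary statistics at every recorded time and
#' stacks them as a tidy table: `statistic`, `t`, `r` (position within the
#' statistic vector: 1 for displacement, the column `i` for the density
#' profile, the separation `m` for the PCF), and `value`.
#'
#' @param record An `abm_record`.
#' @param statistics Subset of `c("displacement", "density_profile", "pcf")`.
#' @param t_i Reference time for the displacement statistic.
#' @return A tibble with columns `statistic`, `t`, `r`, `value`.
#' @export
summarise_record <- function(record,
                             statistics = c("displacement", "density_profile",
                                            "pcf"),
                             t_i = 0) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  purrr::map(record$times, function(t) {
    st <- snapshot_state(record, t)
    parts <- list()
    if ("displacement" %in% statistics)
      parts$displacement <- tibble(
        statistic = "displacement", t = t, r = 1L,
        value = average_horizontal_displacement(record, t_i = t_i, t_f = t))
    if ("density_profile" %in% statistics) {
      dp <- density_profile(st)
      parts$density_profile <- tibble(
        statistic = "density_profile", t = t, r = dp$i, value = dp$density)
    }
    if ("pcf" %in% statistics) {
      qq <- pcf(st)
      parts$pcf <- tibble(statistic = "pcf", t = t, r = qq$m, value = qq$q)
    }
    bind_rows(parts)
  }) %>% bind_rows()
}

#' Ensemble average and variance of replicate summary statistics
#'
#' Operates on a long replicate table (columns `rep`, `statistic`, `t`, `r`,
#' `value`), e.g. the `replicates` element of a [generate_synthetic_data()]
#' result. The average is the elementwise arithmetic mean over replicates;
#' the variance is the elementwise unbiased (n - 1) sample variance, chosen
#' because replicate counts are small (typically 5).
#'
#' @param replicates A long tibble of per-replicate statistic values.
#' @return A tibble with columns `statistic`, `t`, `r` and `value`
#'   (`ensemble_average()`) or `variance` (`statistic_variance()`).
#' @export
ensemble_average <- function(replicates) {
  check_replicate_table(replicates)
  replicates %>%
    group_by(.data$statistic, .data$t, .data$r) %>%
    summarise(value = mean(.data$value), .groups = "drop")
}

#' @rdname ensemble_average
#' @export
statistic_variance <- function(replicates) {
  check_replicate_table(replicates)
  counts <- dplyr::count(replicates, .data$statistic, .data$t, .data$r)
  if (any(counts$n < 2))
    abort("variance needs at least two replicates per statistic element.")
  replicates %>%
    group_by(.data$statistic, .data$t, .data$r) %>%
    summarise(variance = var(.data$value), .groups = "drop")
}

check_replicate_table <- function(replicates) {
  need <- c("statistic", "t", "r", "value")
  if (!all(need %in% names(replicates)))
    abort("expected a long table with columns statistic, t, r, value.")
  lens <- replicates %>%
    group_by(.data$statistic, .data$t) %>%
    summarise(k = dplyr::n_distinct(.data$r), .groups = "drop_last") %>%
    summarise(ok = dplyr::n_distinct(.data$k) == 1, .groups = "drop")
  if (!all(lens$ok))
    abort("replicates of the same statistic have inconsistent lengths.")
  invisible(replicates)
}
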