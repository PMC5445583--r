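# Internal fast path for synthetic-data generation: computes the summary
# statistics directly on the integer snapshot matrices returned by the C++
# core, bypassing per-snapshot tibble construction. Used by
# generate_synthetic_data(); the user-facing equivalents are
# summarise_record() and friends, which share the same formulas.

# fixed element layout of one replicate's statistics
stat_template <- function(design, statistics) {
  Lx <- design$domain$Lx
  parts <- list()
  for (t in design$times) {
    if ("displacement" %in% statistics)
      parts[[length(parts) + 1]] <-
        list(statistic = "displacement", t = t, r = 1L)
    if ("density_profile" %in% statistics)
      parts[[length(parts) + 1]] <-
        list(statistic = "density_profile", t = t, r = seq_len(Lx))
    if ("pcf" %in% statistics)
      parts[[length(parts) + 1]] <-
        list(statistic = "pcf", t = t, r = seq_len(Lx - 1))
  }
  tibble(
    statistic = unlist(purrr::map(parts, function(p)
      rep(p$statistic, length(p$r)))),
    t = unlist(purrr::map(parts, function(p) rep(p$t, length(p$r)))),
    r = unlist(purrr::map(parts, "r"))
  )
}

# one replicate: simulate and return values aligned with stat_template()
replicate_stat_values <- function(design, params, statistics) {
  d <- design$domain
  init <- initial_state(design)
  target <- design$replenish
  agents0 <- cbind(init$agents$col, init$agents$row, init$agents$init_col)
  storage.mode(agents0) <- "integer"
  res <- abm_gillespie_cpp(
    d$Lx, d$Ly, agents0,
    model = if (params$model == "A") 0L else 1L,
    pm = params$pm, alpha = params$alpha,
    flux_x = d$x_boundary == "flux",
    replenish = !is.null(target),
    replenish_density = if (is.null(target)) 0 else target,
    times = design$times
  )
  init_ids <- seq_len(nrow(agents0)) # core ids for the initial block
  init_cols <- init$agents$col
  Lx <- d$Lx; Ly <- d$Ly
  out <- numeric(0)
  for (snap in res$snapshots) {
    ids <- snap[, 1]; cols <- snap[, 2]
    if ("displacement" %in% statistics) {
      idx <- match(init_ids, ids)
      present <- !is.na(idx)
      if (!any(present))
        abort("no agent is present at both times; displacement undefined.")
      out <- c(out, mean(abs(init_cols[present] - cols[idx[present]])))
    }
    k <- tabulate(cols, nbins = Lx)
    if ("density_profile" %in% statistics) out <- c(out, k / Ly)
    if ("pcf" %in% statistics) {
      N <- length(ids)
      if (N < 2) abort("the PCF is undefined for fewer than 2 agents.")
      m <- seq_len(Lx - 1)
      cm <- vapply(m, function(mm)
        sum(k[seq_len(Lx - mm)] * k[seq_len(Lx - mm) + mm]), numeric(1))
      chat <- Ly^2 * (Lx - m) * (N / (Lx * Ly)) * ((N - 1) / (Lx * Ly - 1))
      out <- c(out, cm / chat)
    }
  }
  out
}
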