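# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (dense scans, full enumeration, closed forms) and never
# call the code paths they check.

# brute-force first-crossing time of a piecewise-linear trace: dense scan of
# the interpolated amplitude at resolution dt_scan.
oracle_first_crossing <- function(times, amplitudes, threshold,
                                  dt_scan = 0.01) {
  grid <- seq(min(times), max(times), by = dt_scan)
  amp <- approx(times, amplitudes, xout = grid)$y
  hit <- which(amp >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  grid[hit[1L]]
}

# full-enumeration two-sided Mann-Whitney p: U over every assignment of the
# pooled values into groups of the observed sizes; two-sided p as
# 2 * min(P(U <= u), P(U >= u)) capped at 1, the exact-test convention.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(length(pooled), m), 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# random strictly monotone (non-decreasing amplitude) trace
random_monotone_trace <- function(n = 20, tmax = 2400) {
  times <- sort(runif(n, 0, tmax))
  times[1] <- 0
  amps <- cumsum(c(0, runif(n - 1, 0, 4)))
  rotem_trace(times, amps)
}

# closed forms for the simulator's exponential-approach model, used as
# parameter-recovery oracles against noise-free simulated traces.
closed_plateau <- function(params, condition) {
  phi <- params$fibrinogen_fraction
  g <- function(v) v / (v + params$agglutination_k_pct)
  m <- params$mcf_total_mm
  switch(condition,
    extem = list(m_eff = m, add = 0),
    fibtem = list(m_eff = phi * m, add = 0),
    rico = list(m_eff = m * (phi + (1 - phi) * (1 - g(params$vwf_activity_pct))),
                add = 0),
    rico_haemate = list(
      m_eff = m * (phi + (1 - phi) *
        (1 - g(params$vwf_activity_pct + params$haemate_increment_pct))),
      add = params$haemate_procoagulant_mm))
}

closed_amplitude <- function(params, condition, t) {
  cp <- closed_plateau(params, condition)
  ifelse(t >= params$lag_s,
         cp$m_eff * (1 - exp(-(t - params$lag_s) / params$tau_s)) + cp$add, 0)
}

# time at which the closed-form amplitude first reaches `thr` (add term
# included); NA if the plateau never reaches it.
closed_crossing <- function(params, condition, thr) {
  cp <- closed_plateau(params, condition)
  top <- cp$m_eff + cp$add
  if (top <= thr) return(NA_real_)
  params$lag_s + params$tau_s * log(cp$m_eff / (top - thr))
}

# noise-free Ricotem+ straight from the closed-form 30-min amplitudes
closed_ricotem_plus <- function(params) {
  a <- vapply(c("extem", "rico", "rico_haemate"),
              function(cc) closed_amplitude(params, cc, 1800), numeric(1))
  (a[["rico"]] - a[["rico_haemate"]]) / a[["extem"]] * 100
}
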