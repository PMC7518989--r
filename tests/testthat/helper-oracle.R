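# Independent straight-line re-implementation of the stock-flow equations
# (affected inflow, treated outflow, climate-amplified death outflow,
# forward Euler at 1 day), used as the brute-force oracle for the engine.
# Table functions are interpolated manually, not via the package.

oracle_interp <- function(xs, ys, x) {
  if (x <= xs[1]) return(ys[1])
  k <- length(xs)
  if (x >= xs[k]) return(ys[k])
  i <- max(which(xs <= x))
  if (xs[i] == x) return(ys[i])
  ys[i] + (ys[i + 1] - ys[i]) * (x - xs[i]) / (xs[i + 1] - xs[i])
}

oracle_simulate <- function(tmax, prof, p) {
  ex <- p$exposure; ad <- p$adaptation; ref <- ad$reference
  w <- ad$weights
  clamp <- function(v) max(min(v, ad$factor_cap), ad$factor_floor)
  cd <- function(v, r, wt) {
    if (wt == 0) 1 else max(v / r, ad$factor_floor)^wt
  }
  ec <- clamp(cd(prof$ac_rate, ref$ac_rate, w$ac) *
                cd(prof$income, ref$income, w$income))
  hf <- clamp(cd(prof$staff, ref$staff, w$staff) *
                cd(prof$beds, ref$beds, w$beds) *
                cd(prof$hospitals, ref$hospitals, w$hospitals))
  gf <- clamp(cd(prof$allowance, ref$allowance, w$allowance) *
                cd(prof$insurance, ref$insurance, w$insurance))
  af <- min(ad$af_cap, ad$af0 * ec * hf * gf)
  tot <- prof$pop_under14 + prof$pop_15_64 + prof$pop_over65
  pop <- tot * (1 + ex$vuln_over65 * prof$pop_over65 / tot)
  ap <- p$initial_ap
  n <- length(tmax)
  deaths <- tpf_v <- ap_v <- numeric(n)
  run <- 0
  for (t in seq_len(n)) {
    run <- if (tmax[t] > 35) run + 1 else 0
    apf <- pop / 1e7 * (ex$r_base + ex$beta_morb * max(0, tmax[t] - ex$t_morb))
    cf <- oracle_interp(p$ma$x, p$ma$y, tmax[t]) *
      oracle_interp(p$hdaf$x, p$hdaf$y, run)
    tpf <- ap * af
    d <- ap * ex$mu * cf
    if (tpf + d > ap + apf && tpf + d > 0) {
      s <- (ap + apf) / (tpf + d)
      tpf <- tpf * s; d <- d * s
    }
    ap <- max(ap + apf - tpf - d, 0)
    deaths[t] <- d; tpf_v[t] <- tpf; ap_v[t] <- ap
  }
  list(deaths = deaths, tpf = tpf_v, ap = ap_v)
}
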