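# Inter-protein non-bonded interaction energy (shifted Lennard-Jones +
# shifted Coulomb) and the two-threshold bound/unbound state machine.

COULOMB_CONST <- 138.935458   # kJ mol^-1 nm e^-2

# Shift-function coefficients for an inverse-power potential r^-p with the
# force and its derivative vanishing at the cutoff rc (switch region starts
# at r1). Solved from the two boundary conditions rather than hard-coded.
shift_coefficients <- function(p, r1, rc) {
  d <- rc - r1
  M <- matrix(c(d^2, d^3,
                2 * d, 3 * d^2), 2, 2, byrow = TRUE)
  rhs <- c(-p / rc^(p + 1), p * (p + 1) / rc^(p + 2))
  ab <- solve(M, rhs)
  list(A = ab[1], B = ab[2],
       # potential offset making V(rc) = 0
       C = 1 / rc^p - (ab[1] / 3) * d^3 - (ab[2] / 4) * d^4)
}

# Shifted inverse-power potential phi_p(r); exactly 0 for r >= rc.
phi_shifted <- function(r, p, r1, rc) {
  co <- shift_coefficients(p, r1, rc)
  v <- numeric(length(r))
  inside <- r < rc
  rin <- r[inside]
  core <- rin^(-p) - co$C
  sw <- rin > r1
  core[sw] <- core[sw] - (co$A / 3) * (rin[sw] - r1)^3 -
    (co$B / 4) * (rin[sw] - r1)^4
  v[inside] <- core
  v
}

# Plain truncated-and-shifted potential (documented fallback scheme).
phi_truncated <- function(r, p, rc) {
  v <- numeric(length(r))
  inside <- r < rc
  v[inside] <- r[inside]^(-p) - rc^(-p)
  v
}

#' Inter-set non-bonded pair energy
#'
#' Sum over all bead pairs (one from each set, minimum image) within the
#' cutoff of the shifted 12-6 Lennard-Jones potential (switch region
#' `r_switch`..`r_cut`) plus the shifted Coulomb potential (shifted over
#' 0..`r_cut`) with relative permittivity `epsilon_r`. Pairs beyond the
#' cutoff contribute exactly zero; both terms vanish smoothly at the cutoff.
#'
#' @param frame a `cg_frame`.
#' @param beads_A,beads_B disjoint bead index sets.
#' @param topology a `cg_topology` carrying type keys, charges and the
#'   non-bonded C6/C12 table.
#' @param r_cut cutoff in nm (default 1.2).
#' @param r_switch start of the Lennard-Jones switch region in nm (0.9).
#' @param epsilon_r relative permittivity (default 15).
#' @param scheme `"shift"` (engine-standard shift function) or
#'   `"truncate"` (truncated-and-shifted fallback).
#' @return energy in kJ/mol.
#' @export
pair_energy <- function(frame, beads_A, beads_B, topology,
                        r_cut = 1.2, r_switch = 0.9, epsilon_r = 15,
                        scheme = c("shift", "truncate")) {
  scheme <- match.arg(scheme)
  if (length(intersect(beads_A, beads_B)))
    stop("bead sets must be disjoint")
  A <- frame$coordinates[beads_A, , drop = FALSE]
  B <- frame$coordinates[beads_B, , drop = FALSE]
  r <- pair_distances(A, B, frame$box)
  within <- which(r < r_cut)
  if (!length(within)) return(0)
  ri <- r[within]
  ij <- arrayInd(within, dim(r))
  ti <- topology$beads$type_key[beads_A][ij[, 1]]
  tj <- topology$beads$type_key[beads_B][ij[, 2]]
  par <- nonbonded_params(topology, ti, tj)
  if (scheme == "shift") {
    p12 <- phi_shifted(ri, 12, r_switch, r_cut)
    p6 <- phi_shifted(ri, 6, r_switch, r_cut)
  } else {
    p12 <- phi_truncated(ri, 12, r_cut)
    p6 <- phi_truncated(ri, 6, r_cut)
  }
  e <- sum(par$C12 * p12 - par$C6 * p6)
  qi <- topology$beads$charge[beads_A][ij[, 1]]
  qj <- topology$beads$charge[beads_B][ij[, 2]]
  qq <- qi * qj
  if (any(qq != 0)) {
    pc <- if (scheme == "shift") phi_shifted(ri, 1, 0, r_cut)
          else phi_truncated(ri, 1, r_cut)
    e <- e + sum(COULOMB_CONST * qq / epsilon_r * pc)
  }
  e
}

#' Interaction-energy time series between two bead sets
#'
#' Evaluates [pair_energy()] for every frame of a run; the default bead
#' sets are the transmembrane domains of the two protein molecules, the
#' sets on which the dimerization criterion is defined.
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param beads_A,beads_B bead index sets; default TM beads of molecules
#'   1 and 2.
#' @param ... passed on to [pair_energy()].
#' @return data.frame of class `energy_series` with columns `time` (ns) and
#'   `E` (kJ/mol).
#' @export
energy_series <- function(run, topology,
                          beads_A = tm_beads(topology, 1L),
                          beads_B = tm_beads(topology, 2L), ...) {
  n <- length(run$times)
  E <- numeric(n)
  for (i in seq_len(n)) {
    E[i] <- pair_energy(get_frame(run, i), beads_A, beads_B, topology, ...)
  }
  structure(data.frame(time = run$times, E = E),
            class = c("energy_series", "data.frame"))
}

#' Bound/unbound classification of an energy series
#'
#' Two-threshold hysteresis automaton: the pair becomes bound when the
#' interaction energy drops below `bind_threshold` and unbound (a
#' dissociation event) when, from the bound state, it exceeds
#' `unbind_threshold`. Frames with energies between the thresholds keep the
#' previous state; the initial state is unbound. Monomer lifetimes are
#' measured from each dissociation to the next binding; a terminal monomer
#' interval is reported as censored.
#'
#' @param series an `energy_series` (columns `time`, `E`).
#' @param bind_threshold binding threshold, kJ/mol (default -50).
#' @param unbind_threshold dissociation threshold, kJ/mol (default -1).
#' @param smooth_width optional running-mean width (frames, odd) applied to
#'   the energies before classification; 1 = instantaneous (default).
#' @return object of class `binding_timeline`: list with `times`, `bound`
#'   (per-frame flag), `binding_events`, `dissociation_events` (ns),
#'   `monomer_lifetimes` (data.frame: lifetime ns, censored),
#'   `dimer_time`, `post_dissociation_monomer_time`, `run_length` (ns).
#' @export
classify_states <- function(series, bind_threshold = -50,
                            unbind_threshold = -1, smooth_width = 1L) {
  if (!nrow(series)) stop("empty energy series")
  if (bind_threshold >= unbind_threshold)
    stop("bind_threshold must lie below unbind_threshold")
  E <- series$E
  if (smooth_width > 1L) {
    k <- rep(1 / smooth_width, smooth_width)
    E <- as.numeric(stats::filter(E, k, sides = 2))
    E[is.na(E)] <- series$E[is.na(E)]
  }
  s <- ifelse(E < bind_threshold, 1L, ifelse(E > unbind_threshold, 0L, NA))
  if (is.na(s[1])) s[1] <- 0L          # between thresholds before first
  # crossing: unbound by definition
  filled <- s
  for (i in seq_along(filled)[-1]) {
    if (is.na(filled[i])) filled[i] <- filled[i - 1]
  }
  bound <- filled == 1L
  tr <- diff(filled)
  binding_events <- series$time[which(tr == 1L) + 1L]
  if (filled[1] == 1L) binding_events <- c(series$time[1], binding_events)
  dissociation_events <- series$time[which(tr == -1L) + 1L]

  # lifetimes: each dissociation to next binding (or run end, censored)
  lifetimes <- data.frame(lifetime = numeric(0), censored = logical(0))
  t_end <- series$time[length(series$time)]
  for (td in dissociation_events) {
    nxt <- binding_events[binding_events > td]
    if (length(nxt)) {
      lifetimes <- rbind(lifetimes,
                         data.frame(lifetime = nxt[1] - td, censored = FALSE))
    } else {
      lifetimes <- rbind(lifetimes,
                         data.frame(lifetime = t_end - td, censored = TRUE))
    }
  }

  # time attribution: frame i covers [t_i, t_{i+1})
  dt <- diff(series$time)
  st <- filled[-length(filled)]
  dimer_time <- sum(dt[st == 1L])
  # post-dissociation monomer time: unbound stretches after the first
  # dissociation (censored terminal stretches included)
  post_mono <- 0
  if (length(dissociation_events)) {
    t0 <- series$time[-length(series$time)]
    after <- t0 >= dissociation_events[1]
    post_mono <- sum(dt[st == 0L & after])
  }
  structure(list(times = series$time, bound = bound,
                 binding_events = binding_events,
                 dissociation_events = dissociation_events,
                 monomer_lifetimes = lifetimes,
                 dimer_time = dimer_time,
                 post_dissociation_monomer_time = post_mono,
                 run_length = t_end - series$time[1]),
            class = "binding_timeline")
}

#' @export
print.binding_timeline <- function(x, ...) {
  cat(sprintf(
    "binding_timeline: %d frames, %d binding / %d dissociation events\n",
    length(x$times), length(x$binding_events), length(x$dissociation_events)))
  cat(sprintf("  dimer time %.4g ns, post-dissociation monomer time %.4g ns\n",
              x$dimer_time, x$post_dissociation_monomer_time))
  invisible(x)
}

#' Fraction of runs ever dimerized by a horizon
#'
#' @param timelines list of `binding_timeline`s.
#' @param horizon time horizon in ns.
#' @return fraction in `[0, 1]`, monotone non-decreasing in `horizon`.
#' @export
ensemble_dimer_counts <- function(timelines, horizon) {
  if (!length(timelines)) stop("at least one timeline is required")
  ever <- vapply(timelines, function(tl) {
    length(tl$binding_events) > 0 && min(tl$binding_events) <= horizon
  }, logical(1))
  mean(ever)
}

#' First binding time of each run
#'
#' @param timelines list of `binding_timeline`s.
#' @return numeric vector, `Inf` for runs that never bind.
#' @export
first_binding_times <- function(timelines) {
  vapply(timelines, function(tl) {
    if (length(tl$binding_events)) min(tl$binding_events) else Inf
  }, numeric(1))
}
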