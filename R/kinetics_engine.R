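## Homogeneous-phase kinetics: the ODE system dC/dt = S r(C) + inj(t),
## integrated with a stiff-capable solver (lsoda) over pulse trains, with
## G-value bookkeeping normalized to the energy imparted by the full pulse.

#' Convert a G value to a concentration
#'
#' C = G * dose * rho / (100 eV * N_A) with rho = 1 kg/L, i.e.
#' C = 1.0364e-7 * G * dose mol/L. This is the bridge between radiation-
#' chemical yields (entities per 100 eV) and molarities at a given dose.
#'
#' @param G Yield, entities per 100 eV (scalar or named vector).
#' @param dose Dose, Gy.
#' @return Concentration(s), mol/L.
#' @examples
#' concentration_from_g(1, 1)  # 1.0364e-7
#' @export
concentration_from_g <- function(G, dose) {
  stopifnot(all(G >= 0), dose >= 0)
  G * dose * .MOLAR_PER_G_PER_GY
}

#' Convert a concentration to a G value
#'
#' Exact inverse of [concentration_from_g()] at the same dose. During a
#' pulse the divisor is the energy imparted by the entire pulse, not the
#' dose delivered so far — the normalization convention used for all
#' in-pulse yields here.
#'
#' @param C Concentration, mol/L.
#' @param total_dose Total dose of the pulse (train), Gy; must be > 0.
#' @return Yield, entities per 100 eV.
#' @export
g_from_concentration <- function(C, total_dose) {
  if (total_dose <= 0) stop("total_dose must be > 0")
  C / (total_dose * .MOLAR_PER_G_PER_GY)
}

#' Primary-yield set constructor
#'
#' @param ... Named G values (entities per 100 eV), e.g. `OH = 2.72`.
#' @return Named numeric vector of class `primary_yields`.
#' @export
primary_yields <- function(...) {
  g <- unlist(list(...))
  stopifnot(all(g >= 0))
  names(g) <- vapply(names(g), .canon_species, "")
  structure(g, class = "primary_yields")
}

#' Pre-irradiation background water state
#'
#' Neutral water at 25 C: [H3O+] = [OH-] = 1e-7 M (or as implied by `pH`,
#' with [OH-] = Kw / [H3O+]), plus a configured dissolved-oxygen
#' concentration. All other dynamic species start at zero; constant species
#' sit at their reservoir values.
#'
#' @param network A `reaction_network`.
#' @param O2 Dissolved O2, mol/L. Default 1.25e-5 M, i.e. 1 percent of
#'   O2-saturated water.
#' @param pH Negative log10 of [H3O+]; default 7 (neutral).
#' @return A `concentration_state` (named concentrations + time 0).
#' @export
background_state <- function(network, O2 = 1.25e-5, pH = 7) {
  conc <- c("H3O+" = 10^(-pH), "OH-" = 1e-14 / 10^(-pH))
  if ("O2" %in% network$species$name) conc <- c(conc, O2 = O2)
  concentration_state(state_vector(network, conc), time = 0)
}

#' Concentration state at a time point
#'
#' @param conc Named concentrations, mol/L (full or partial; resolved by the
#'   integrator against the network).
#' @param time Time, s.
#' @return Object of class `concentration_state`.
#' @export
concentration_state <- function(conc, time = 0) {
  structure(list(conc = conc, time = time), class = "concentration_state")
}

#' Initialize the solver state at the hand-off time
#'
#' Builds the state handed to the homogeneous solver when the early
#' inhomogeneous track chemistry is summarized by per-species yields: the
#' background water composition plus [concentration_from_g()] of each yield
#' at the pulse dose. The default hand-off time of 5e-6 s reflects the point
#' where track chemistry has relaxed to spatial homogeneity.
#'
#' @param network A `reaction_network`.
#' @param yields A `primary_yields` (G per 100 eV at hand-off).
#' @param dose Delivered dose, Gy (> 0).
#' @param background A `concentration_state` (default
#'   [background_state()]).
#' @param time Hand-off time, s.
#' @return A `concentration_state` with the background recorded in
#'   attribute `reference` (used for delta-based G reporting).
#' @export
handoff_initialize <- function(network, yields, dose,
                               background = background_state(network),
                               time = 5e-6) {
  stopifnot(dose > 0, inherits(background, "concentration_state"))
  conc <- state_vector(network, background$conc)
  add <- concentration_from_g(unclass(yields), dose)
  conc[names(add)] <- conc[names(add)] + add
  st <- concentration_state(conc, time = time)
  attr(st, "reference") <- state_vector(network, background$conc)
  st
}

#' Build the ODE right-hand side of a reaction network
#'
#' Returns a derivative function in the `deSolve` contract:
#' `function(t, y, parms)` yielding `list(dy)` with
#' dC/dt = S r(C) + inj(t). Rows of constant-concentration species are
#' forced to zero. Concentrations are clamped at zero for rate evaluation
#' (guards against harmless solver undershoot).
#'
#' @param network A `reaction_network`.
#' @param inj `NULL`, a named numeric vector of constant injection rates
#'   (mol/L/s), or a function `f(t)` returning one.
#' @return Function usable with [deSolve::lsoda()].
#' @examples
#' net <- parse_reaction_table("1a, OH + OH -> H2O2, 5.50e9, M-1s-1")
#' f <- build_rhs(net)
#' f(0, state_vector(net, c(OH = 1e-5)), NULL)
#' @export
build_rhs <- function(network, inj = NULL) {
  ki <- .kinetics_index(network)
  S <- network$S
  const_row <- !is.na(network$species$const_conc)
  sp_names <- network$species$name
  inj_vec <- NULL
  if (!is.null(inj) && !is.function(inj)) {
    inj_vec <- numeric(length(sp_names))
    names(inj_vec) <- sp_names
    inj_vec[names(inj)] <- as.numeric(inj)
  }
  i1 <- pmax(ki$i1, 1L); use1 <- ki$i1 > 0
  i2 <- pmax(ki$i2, 1L); use2 <- ki$i2 > 0
  keff <- ki$keff
  function(t, y, parms) {
    yc <- pmax(y, 0)
    r <- keff * ifelse(use1, yc[i1], 1) * ifelse(use2, yc[i2], 1)
    dy <- as.vector(S %*% r)
    if (!is.null(inj_vec)) {
      dy <- dy + inj_vec
    } else if (is.function(inj)) {
      add <- inj(t)
      full <- numeric(length(dy))
      names(full) <- sp_names
      full[names(add)] <- as.numeric(add)
      dy <- dy + full
    }
    dy[const_row] <- 0
    list(dy)
  }
}

#' Logarithmic output time grid with in-pulse refinement
#'
#' Log-spaced points between `from` and `to`, plus linearly spaced points
#' inside every finite-width pulse window of `train` (where the chemistry
#' source term switches on and off).
#'
#' @param from,to Grid limits, s.
#' @param points_per_decade Density of the log grid.
#' @param train Optional `pulse_train` for refinement.
#' @param pulse_points Linear points per pulse window.
#' @return Sorted numeric vector of times.
#' @export
log_time_grid <- function(from = 1e-9, to = 1e2, points_per_decade = 20,
                          train = NULL, pulse_points = 25) {
  n <- ceiling(log10(to / from) * points_per_decade) + 1
  grid <- 10^seq(log10(from), log10(to), length.out = n)
  if (!is.null(train) && train$width > 0) {
    for (s in train$starts) {
      grid <- c(grid, seq(s, s + train$width, length.out = pulse_points))
    }
  }
  grid <- sort(unique(grid[grid >= min(from, 0) & grid <= to]))
  grid[grid > 0 | grid == 0]
}

#' Integrate the radiolysis kinetics over a pulse train
#'
#' Solves the homogeneous reaction network with the stiff-capable `lsoda`
#' integrator, restarting at every pulse boundary. Finite-width pulses
#' inject primary species continuously at rate
#' `concentration_from_g(G, 1) * dose_rate(t)`; instantaneous (zero-width)
#' pulses are applied as discrete concentration increments at the pulse
#' time. With `train` or `yields` absent the network evolves freely from
#' the initial state.
#'
#' @param network A `reaction_network`.
#' @param initial A `concentration_state` (or named concentration vector,
#'   taken at time 0).
#' @param t_grid Output times, s (strictly increasing, all >=
#'   `initial$time`).
#' @param train Optional `pulse_train` driving injection.
#' @param yields Optional `primary_yields` injected by the train.
#' @param rtol,atol Relative / absolute solver tolerances. The defaults
#'   (1e-8, 1e-16 mol/L) accommodate concentrations spanning 1e-12 to
#'   1e-3 M; atol sits well below the smallest meaningful concentration so
#'   that near-depleted species are still resolved rather than allowed to
#'   drift around zero.
#' @param maxsteps Maximum internal steps per segment.
#' @return Object of class `conc_series`: data.frame with column `time_s`
#'   and one concentration column per species (mol/L). Attributes:
#'   `total_dose` (Gy, 0 when no train), `species`, `reference` (background
#'   used for delta-based G values), `mode`.
#' @seealso [g_values()] for the G-value view of a series.
#' @examples
#' net <- parse_reaction_table("1a, OH + OH -> H2O2, 5.50e9, M-1s-1")
#' s <- integrate_kinetics(net, c(OH = 1e-5), t_grid = 10^seq(-9, -1))
#' @export
integrate_kinetics <- function(network, initial, t_grid, train = NULL,
                               yields = NULL, rtol = 1e-8, atol = 1e-16,
                               maxsteps = 100000) {
  if (!inherits(initial, "concentration_state")) {
    initial <- concentration_state(initial, time = 0)
  }
  t0 <- initial$time
  t_grid <- sort(unique(as.numeric(t_grid)))
  if (any(t_grid < t0)) {
    stop("t_grid must start at or after the initial state's time")
  }
  y <- state_vector(network, initial$conc)
  reference <- attr(initial, "reference")
  if (is.null(reference)) reference <- y

  inject <- !is.null(train) && !is.null(yields)
  total_dose <- if (!is.null(train)) train$n_pulses * train$dose_per_pulse else 0

  # Segment boundaries: pulse starts/ends (finite width) or event times
  # (zero width), within [t0, max(t_grid)].
  t_end <- max(t_grid)
  events <- numeric(0)    # discrete deposits
  breaks <- numeric(0)
  if (inject) {
    if (train$width > 0) {
      breaks <- c(train$starts, train$starts + train$width)
    } else {
      events <- train$starts
      breaks <- events
    }
  }
  breaks <- sort(unique(c(t0, breaks[breaks > t0 & breaks < t_end], t_end)))

  g_per_gray <- if (inject) concentration_from_g(unclass(yields), 1) else NULL
  out_t <- numeric(0)
  out_y <- NULL
  floor_tol <- 100 * atol

  record <- function(tt, yy) {
    keep <- t_grid[t_grid >= tt[1] & t_grid <= tt[length(tt)]]
    keep <- setdiff(keep, out_t)
    if (length(keep)) {
      idx <- match(keep, tt)
      out_t <<- c(out_t, keep)
      out_y <<- rbind(out_y, yy[idx, , drop = FALSE])
    }
  }

  apply_event <- function(y, tt) {
    add <- g_per_gray * train$dose_per_pulse
    y[names(add)] <- y[names(add)] + add
    y
  }

  cur_t <- t0
  if (length(events) && any(events == t0)) y <- apply_event(y, t0)
  if (t0 %in% t_grid) {
    out_t <- t0
    out_y <- matrix(y, nrow = 1)
  }

  for (i in seq_len(length(breaks) - 1)) {
    seg <- c(breaks[i], breaks[i + 1])
    # constant injection rate within the segment (rectangular pulses)
    inj_vec <- NULL
    if (inject && train$width > 0) {
      mid <- (seg[1] + seg[2]) / 2
      rate <- dose_rate_profile(train, mid)
      if (rate > 0) inj_vec <- g_per_gray * rate
    }
    rhs <- build_rhs(network, inj_vec)
    times <- sort(unique(c(seg, t_grid[t_grid > seg[1] & t_grid < seg[2]])))
    sol <- deSolve::lsoda(y, times, rhs, parms = NULL, rtol = rtol,
                          atol = atol, maxsteps = maxsteps)
    reached <- sol[nrow(sol), 1]
    if (abs(reached - seg[2]) > 1e-12 * max(1, seg[2])) {
      ylast <- sol[nrow(sol), -1]
      worst <- names(y)[which.min(ylast)]
      stop(sprintf(
        "integration failed at t = %.4g s (target %.4g s); suspect species: %s",
        reached, seg[2], worst))
    }
    ymat <- sol[, -1, drop = FALSE]
    # Undershoot floor: negatives below the solver's per-species error scale
    # (100 atol, or 1e-3 of the species' peak in this segment) are numerical
    # noise from steep decays and are clipped; anything larger aborts.
    span <- apply(abs(ymat), 2, max)
    neg_tol <- pmax(floor_tol, 1e-3 * span)
    worst_neg <- apply(ymat, 2, min)
    if (any(worst_neg < -neg_tol)) {
      bad <- which.min(worst_neg / neg_tol)
      stop(sprintf(
        "negative concentration %.3g beyond tolerance for %s near t = %.4g s",
        worst_neg[bad], network$species$name[bad], seg[2]))
    }
    ymat[ymat < 0] <- 0
    record(sol[, 1], ymat)
    y <- ymat[nrow(ymat), ]
    names(y) <- network$species$name
    cur_t <- seg[2]
    if (length(events) && any(abs(events - cur_t) < 1e-18 + 1e-12 * cur_t)) {
      y <- apply_event(y, cur_t)
      # re-record the post-event state at this grid time, if sampled
      if (cur_t %in% out_t) out_y[match(cur_t, out_t), ] <- y
    }
  }

  ord <- order(out_t)
  df <- data.frame(time_s = out_t[ord])
  ymat <- out_y[ord, , drop = FALSE]
  colnames(ymat) <- network$species$name
  df <- cbind(df, as.data.frame(ymat))
  structure(df,
            class = c("conc_series", "data.frame"),
            total_dose = total_dose,
            species = network$species$name,
            reference = reference,
            mode = if (inject) {
              if (train$width > 0) "per_pulse_injection" else "instantaneous"
            } else "free")
}

#' G-value view of a concentration time series
#'
#' G_X(t) = (C_X(t) - C_X(reference)) normalized by the energy imparted by
#' the entire pulse train: the "changed per 100 eV" bookkeeping. The
#' reference is the pre-irradiation background recorded in the series (so
#' reservoir-like species such as O2 report their net change, not their
#' absolute level).
#'
#' @param series A `conc_series`.
#' @param total_dose Normalization dose, Gy; defaults to the dose of the
#'   train that produced the series.
#' @return data.frame `time_s` + per-species G values (per 100 eV).
#' @export
g_values <- function(series, total_dose = attr(series, "total_dose")) {
  if (is.null(total_dose) || total_dose <= 0) {
    stop("total_dose must be > 0 (series was produced without a pulse train?)")
  }
  ref <- attr(series, "reference")
  sp <- attr(series, "species")
  out <- data.frame(time_s = series$time_s)
  for (s in sp) {
    out[[s]] <- g_from_concentration(series[[s]] - ref[[s]], total_dose)
  }
  out
}

#' Time for a species to decay to a fraction of its peak
#'
#' Finds the post-`after` maximum of the species trace, then the first
#' crossing of `frac * peak` after the peak, located by linear interpolation
#' between grid points. Returns NA if the trace never falls that far.
#'
#' @param series A `conc_series`.
#' @param species Species name.
#' @param frac Fraction of the peak (e.g. 0.5 for the half-maximum time).
#' @param after Ignore times before this, s.
#' @return Crossing time, s (absolute).
#' @export
time_to_fraction_of_peak <- function(series, species, frac, after = 0) {
  t <- series$time_s
  c_ <- series[[species]]
  keep <- t >= after
  t <- t[keep]; c_ <- c_[keep]
  ip <- which.max(c_)
  target <- frac * c_[ip]
  for (i in seq(ip, length(t) - 1)) {
    if (c_[i] >= target && c_[i + 1] < target) {
      w <- (c_[i] - target) / (c_[i] - c_[i + 1])
      return(t[i] + w * (t[i + 1] - t[i]))
    }
  }
  NA_real_
}

#' Maximum relative difference between two series
#'
#' Pointwise relative difference |a - b| / max(|a|, |b|, floor) over the
#' common time grid, for the given species and times at or after `t_min`.
#' The floor (default 1e-13 M) excludes concentrations below the solver's
#' resolution, where a relative comparison carries no information.
#'
#' @param a,b `conc_series` objects on the same grid.
#' @param species Species to compare (default: all shared dynamic species).
#' @param t_min Compare only times >= t_min, s.
#' @param floor Absolute concentration floor, mol/L.
#' @return Maximum relative difference (scalar).
#' @export
series_max_rel_diff <- function(a, b, species = NULL, t_min = 0,
                                floor = 1e-13) {
  if (is.null(species)) species <- intersect(attr(a, "species"),
                                             attr(b, "species"))
  tt <- intersect(a$time_s, b$time_s)
  tt <- tt[tt >= t_min]
  ia <- match(tt, a$time_s)
  ib <- match(tt, b$time_s)
  worst <- 0
  for (s in species) {
    xa <- a[[s]][ia]; xb <- b[[s]][ib]
    denom <- pmax(abs(xa), abs(xb), floor)
    worst <- max(worst, max(abs(xa - xb) / denom))
  }
  worst
}
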