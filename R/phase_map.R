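# One-clock-cycle iterated map for the network-vs-clock phase, built from a
# measured fmPRC.
#
# With Phi_n the network phase relative to the n-th clock pulse (arrival
# convention, normalized by the clock period) and dphi the persistent phase
# response of the rhythm, one clock cycle advances the phase by
#   Phi_{n+1} = G(Phi_n) = Phi_n + 1 - (T_nat / T_clock) (1 - dphi(phi_n)),
# where phi_n = wrap(Phi_n T_clock / T_nat) is the pulse phase within the
# network cycle. Discontinuities of the measured fmPRC (volley suppression
# under strong pulses) are carried into the map; interpolation never crosses
# them.

#' Periodic interpolant of an fmPRC with discontinuity flags
#'
#' Monotone piecewise-cubic interpolation within continuous segments of the
#' phase grid; jumps larger than `disc_tol` are treated as discontinuities
#' and interpolation is clamped to the segment edges up to the jump midpoint.
#'
#' @param prc an `fmprc` (or data frame with `phi`, `dphi`).
#' @param disc_tol jump size flagged as a discontinuity (phase units).
#' @return list with `fun` (vectorized `phi -> dphi`), `disc` (phase
#'   locations of the jump midpoints), `segments`.
#' @export
fmprc_interpolant <- function(prc, disc_tol = 0.04) {
  ok <- !is.na(prc$dphi)
  if (sum(ok) < 4) stop("too few valid fmPRC entries")
  phi <- prc$phi[ok]; dphi <- prc$dphi[ok]
  o <- order(phi); phi <- phi[o]; dphi <- dphi[o]
  n <- length(phi)
  if (any(diff(phi) > 2.5 * median(diff(phi)))) {
    stop("fmPRC has gaps wider than 2 grid steps; interpolation refused")
  }
  # unwrap modulo 1: the measured shift lives in [-0.5, 0.5), but the
  # physical volley-time shift is continuous in the pulse phase; strong
  # resetting pulses wind around the circle (winding number -1)
  u <- dphi[1] + c(0, cumsum(wrap_phase(diff(dphi))))
  jump_in <- abs(wrap_phase(diff(dphi)))          # residual (true) jumps
  bnd_jump <- wrap_phase(dphi[1] - dphi[n])       # closure step
  winding <- round(u[n] + bnd_jump - u[1])        # integer by construction
  # grid extended by the periodic closure point
  phi_x <- c(phi, phi[1] + 1)
  u_x <- c(u, u[n] + bnd_jump)
  # a discontinuity is an outlier jump: merely steep (smooth) stretches have
  # many steps of comparable size
  all_jumps <- c(jump_in, abs(bnd_jump))
  thr <- max(disc_tol, 4 * median(all_jumps))
  is_disc <- all_jumps > thr
  disc_mid <- (phi_x[-length(phi_x)] + phi_x[-1])[is_disc] / 2
  cuts <- which(is_disc)
  starts <- c(1, cuts + 1)
  ends <- c(cuts, length(phi_x))
  segs <- Map(function(s, e) s:e, starts, ends)
  funs <- lapply(segs, function(ix) {
    if (length(ix) == 1) {
      v <- u_x[ix]; function(x) rep(v, length(x))
    } else splinefun(phi_x[ix], u_x[ix], method = "monoH.FC")
  })
  seg_lo <- vapply(segs, function(ix) phi_x[ix[1]], 0)
  seg_hi <- vapply(segs, function(ix) phi_x[ix[length(ix)]], 0)
  n_seg <- length(segs)
  fun <- function(x) {
    x <- wrap_phase(x - phi[1]) + phi[1]      # into [phi1, phi1+1)
    x[x < phi[1]] <- x[x < phi[1]] + 1
    if (n_seg == 1) return(funs[[1]](pmin(pmax(x, seg_lo), seg_hi)))
    out <- numeric(length(x))
    # segment assignment; points inside a flagged jump clamp to the nearer
    # segment edge
    idx <- findInterval(x, seg_lo)
    idx[idx < 1] <- 1
    up <- idx < n_seg & x > seg_hi[idx] &
      x >= (seg_hi[idx] + seg_lo[pmin(idx + 1, n_seg)]) / 2
    idx[up] <- idx[up] + 1
    xx <- pmin(pmax(x, seg_lo[idx]), seg_hi[idx])
    for (k in unique(idx)) {
      m <- idx == k
      out[m] <- funs[[k]](xx[m])
    }
    out
  }
  # discontinuities of the unwrapped response within the base interval,
  # plus the period-boundary branch step when the response winds
  disc <- wrap_phase(disc_mid)
  if (winding != 0 && !(abs(bnd_jump) > disc_tol)) {
    disc <- c(disc, wrap_phase(phi[1]))
  }
  list(fun = fun, disc = disc, n_seg = length(segs),
       winding = winding, phi0 = phi[1])
}

#' Build the one-clock-cycle phase map
#'
#' @param prc an `fmprc` measured with the clock's pulse shape.
#' @param f_clock clock frequency (Hz).
#' @param T_nat natural period of the network (ms); defaults to the period
#'   stored in `prc`.
#' @param use_first use the first-cycle shift instead of the persistent one.
#' @param disc_tol passed to [fmprc_interpolant()].
#' @param n_grid tabulation grid size.
#' @return object of class `phase_map`: tabulated `Phi`, `G`, map closure
#'   `G_fun`, discontinuity locations `disc_Phi` (in the clock-phase
#'   coordinate), `T_nat`, `T_clock`, `delta_f`.
#' @export
build_map <- function(prc, f_clock, T_nat = NULL, use_first = FALSE,
                      disc_tol = 0.04, n_grid = 2048) {
  stopifnot(f_clock > 0)
  T_nat <- T_nat %||% attr(prc, "period")
  if (use_first) {
    prc <- within(as.data.frame(prc), dphi <- dphi_first)
  }
  itp <- fmprc_interpolant(prc, disc_tol)
  T_clock <- 1000 / f_clock
  ratio <- T_nat / T_clock
  G_fun <- function(Phi) {
    phi <- wrap_phase(Phi / ratio)
    Phi + 1 - ratio * (1 - itp$fun(phi))
  }
  Phi <- seq(0, 1 - 1 / n_grid, length.out = n_grid)
  # preimages of the response discontinuities under phi = Phi / ratio mod 1
  disc_Phi <- sort(unlist(lapply(itp$disc, function(pd) {
    cand <- (pd + (-3:3)) * ratio
    cand[cand >= 0 & cand < 1]
  })))
  # wrap points of the mod-1 map: branch boundaries of the return map drawn
  # on the unit square (G crosses an integer)
  Gtab <- G_fun(Phi)
  fl <- floor(Gtab + 1e-12)
  chg <- which(diff(fl) != 0)
  wraps <- vapply(chg, function(i) {
    k <- max(fl[i], fl[i + 1])
    tryCatch(stats::uniroot(function(x) G_fun(x) - k,
                            c(Phi[i], Phi[i + 1]))$root,
             error = function(e) (Phi[i] + Phi[i + 1]) / 2)
  }, 0)
  disc_Phi <- sort(unique(c(disc_Phi, wrap_unit(wraps))))
  structure(list(Phi = Phi, G = Gtab, G_fun = G_fun,
                 disc_Phi = disc_Phi, T_nat = T_nat, T_clock = T_clock,
                 delta_f = f_clock - 1000 / T_nat, f_clock = f_clock),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map: T_nat=%.2f ms, T_clock=%.2f ms, df=%.2f Hz, %d discontinuities>\n",
              x$T_nat, x$T_clock, x$delta_f, length(x$disc_Phi)))
  invisible(x)
}

#' Iterate a phase map
#'
#' @param map a `phase_map`.
#' @param Phi0 initial phase.
#' @param n_transient iterates discarded.
#' @param n_keep iterates kept.
#' @return numeric vector of kept iterates, wrapped into `[0, 1)`.
#' @export
iterate_map <- function(map, Phi0 = 0.5, n_transient = 1024, n_keep = 4096) {
  Phi <- wrap_unit(Phi0)
  for (i in seq_len(n_transient)) Phi <- wrap_unit(map$G_fun(Phi))
  out <- numeric(n_keep)
  for (i in seq_len(n_keep)) {
    Phi <- wrap_unit(map$G_fun(Phi))
    out[i] <- Phi
  }
  out
}

#' Fixed points of a phase map
#'
#' Diagonal crossings `G(Phi) = Phi (mod 1)` located by sign change and
#' bisection on continuous stretches, with the local slope and stability.
#'
#' @param map a `phase_map`.
#' @param n_scan scan resolution.
#' @return data frame `Phi`, `slope`, `stable`; zero rows when none exist.
#'   Attribute `degenerate` is TRUE for an identity map.
#' @export
fixed_points <- function(map, n_scan = 4096) {
  Phi <- seq(0, 1 - 1 / n_scan, length.out = n_scan)
  H <- wrap_phase(map$G_fun(Phi) - Phi)
  if (all(abs(H) < 1e-12)) {
    out <- data.frame(Phi = numeric(0), slope = numeric(0),
                      stable = logical(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # avoid spanning a map discontinuity
  near_disc <- function(a, b) {
    any(vapply(map$disc_Phi, function(d) {
      dd <- wrap_unit(d)
      (a <= dd & dd <= b)
    }, TRUE))
  }
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1)) {
    if (is.na(H[i]) || is.na(H[i + 1])) next
    if (sign(H[i]) == sign(H[i + 1]) || abs(H[i] - H[i + 1]) > 0.5) next
    if (length(map$disc_Phi) && near_disc(Phi[i], Phi[i + 1])) next
    f <- function(x) wrap_phase(map$G_fun(x) - x)
    r <- tryCatch(stats::uniroot(f, c(Phi[i], Phi[i + 1]))$root,
                  error = function(e) NA_real_)
    if (!is.na(r)) roots <- c(roots, r)
  }
  if (!length(roots)) {
    out <- data.frame(Phi = numeric(0), slope = numeric(0),
                      stable = logical(0))
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  roots <- unique(round(roots, 8))
  h <- 1e-5
  slope <- vapply(roots, function(r)
    (map$G_fun(r + h) - map$G_fun(r - h)) / (2 * h), 0)
  out <- data.frame(Phi = roots, slope = slope, stable = abs(slope) < 1)
  attr(out, "degenerate") <- FALSE
  out
}

segment_of <- function(Phi, disc) {
  # index of the continuity segment (arcs between discontinuities on the circle)
  if (!length(disc)) return(rep(1L, length(Phi)))
  d <- sort(wrap_unit(disc))
  findInterval(wrap_unit(Phi), d) %% length(d) + 1L
}

circ_arc <- function(points) {
  # smallest circular arc containing all points: (start, width)
  p <- sort(wrap_unit(points))
  if (length(p) == 1) return(list(start = p, width = 0))
  gaps <- diff(c(p, p[1] + 1))
  i <- which.max(gaps)
  list(start = p[i %% length(p) + 1], width = 1 - gaps[i])
}

arc_contains <- function(x, arc, strict = TRUE) {
  d <- wrap_unit(x - arc$start)
  if (strict) d > 1e-9 & d < arc$width - 1e-9 else d <= arc$width
}

classify_orbit <- function(orb, period_max = 64, tol = 1e-4) {
  n <- length(orb)
  for (p in seq_len(min(period_max, n - 1))) {
    d <- abs(wrap_phase(orb[(p + 1):n] - orb[1:(n - p)]))
    if (max(d) < tol) return(p)
  }
  NA_integer_  # aperiodic / chaotic
}

#' Bifurcation diagram of the phase map over detuning
#'
#' Sweeps the clock detuning, iterating the map at each step with
#' continuation of the attractor, classifying the attractor (fixed point /
#' period-k / aperiodic) and flagging whether it includes points on both
#' sides of a map discontinuity.
#'
#' @param prc fmPRC measured with the clock pulse shape.
#' @param df_grid detuning grid (Hz).
#' @param f_nat natural frequency (Hz); defaults to the period stored in the
#'   fmPRC.
#' @param n_transient,n_keep iteration counts per detuning.
#' @param Phi0 initial phase at the first detuning.
#' @param disc_tol passed to [build_map()].
#' @return list with `table` (per detuning: `df`, `period` (NA = aperiodic),
#'   `straddles`, `on_fp_branch`, `n_segments`), `orbits` (list of kept
#'   iterates), `single_branch_end` (largest detuning up to which the
#'   attractor stays on the single branch holding the fixed point),
#'   `straddle_start` (smallest detuning whose attractor straddles a
#'   discontinuity).
#' @export
bifurcation_diagram <- function(prc, df_grid, f_nat = NULL,
                                n_transient = 1024, n_keep = 4096,
                                Phi0 = NULL, disc_tol = 0.04) {
  T_nat <- attr(prc, "period")
  f_nat <- f_nat %||% (1000 / T_nat)
  tab <- data.frame(df = df_grid, period = NA_integer_, straddles = NA,
                    on_fp_branch = NA, n_segments = NA_integer_)
  orbits <- vector("list", length(df_grid))
  Phi <- Phi0
  for (i in seq_along(df_grid)) {
    map <- build_map(prc, f_nat + df_grid[i], T_nat = 1000 / f_nat,
                     disc_tol = disc_tol)
    if (is.null(Phi)) {
      fp <- fixed_points(map)
      Phi <- if (nrow(fp)) fp$Phi[which.max(fp$stable)] else 0.5
    }
    orb <- iterate_map(map, Phi, n_transient, n_keep)
    Phi <- orb[length(orb)]  # continuation
    fp <- fixed_points(map)
    tab$period[i] <- classify_orbit(orb)
    arc <- circ_arc(orb)
    tab$n_segments[i] <- length(unique(segment_of(orb, map$disc_Phi)))
    # the attractor straddles a discontinuity when the smallest arc
    # containing it holds a discontinuity in its interior
    tab$straddles[i] <- length(map$disc_Phi) > 0 &&
      any(arc_contains(map$disc_Phi, arc))
    # single branch holding the fixed point: the arc spanned by attractor
    # and fixed point is free of discontinuities
    tab$on_fp_branch[i] <- if (nrow(fp) == 0) FALSE else {
      any(vapply(fp$Phi, function(pf) {
        arc2 <- circ_arc(c(orb, pf))
        !length(map$disc_Phi) || !any(arc_contains(map$disc_Phi, arc2))
      }, TRUE))
    }
    orbits[[i]] <- orb
  }
  ok <- which(tab$on_fp_branch)
  single_branch_end <- if (length(ok)) {
    brk <- which(!tab$on_fp_branch & seq_along(df_grid) > min(ok))
    if (length(brk)) tab$df[min(brk) - 1] else tab$df[max(ok)]
  } else NA_real_
  st <- which(tab$straddles)
  straddle_start <- if (length(st)) tab$df[min(st)] else NA_real_
  list(table = tab, orbits = orbits,
       single_branch_end = single_branch_end,
       straddle_start = straddle_start)
}
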