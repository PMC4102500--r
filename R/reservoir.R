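#' Reservoir pressure from measured aortic pressure
#'
#' Integrates the three-element Windkessel reservoir equation
#' \deqn{dP_{res}/dt = (P_{ao} - P_{res})/(R_{prox}C) - (P_{res} - P_{msf})/(RC)}
#' whose analytic solution is
#' \deqn{P_{res}(t) = e^{-\beta t}\left[P_{res}(0) +
#'   \int_0^t \left(\frac{P_{ao}}{R_{prox}C} + \frac{P_{msf}}{RC}\right)
#'   e^{\beta s}\,ds\right], \qquad \beta = \frac{1}{R_{prox}C} + \frac{1}{RC}.}
#' The quadrature is exact for aortic pressure piecewise linear between
#' samples (closed-form per-interval exponential update), which removes
#' grid-dependent bias at 200 Hz sampling.
#'
#' @param t Sample times (s), uniform grid.
#' @param p Aortic pressure (mmHg).
#' @param rc Diastolic time constant \eqn{RC} (s), positive.
#' @param rproxc Proximal time constant \eqn{R_{prox}C} (s), positive.
#' @param p_msf Mean systemic filling pressure (mmHg).
#' @param p_res0 Initial reservoir pressure at `t[1]`. Defaults to `p[1]`:
#'   the beat starts at end-diastole where inflow, hence excess pressure, is
#'   essentially zero.
#' @return Numeric vector of reservoir pressure on the sample grid.
#' @export
solve_reservoir_pressure <- function(t, p, rc, rproxc, p_msf, p_res0 = p[1]) {
  if (!is.finite(rc) || !is.finite(rproxc) || rc <= 0 || rproxc <= 0) {
    stop("time constants rc and rproxc must be positive", call. = FALSE)
  }
  dt <- t[2] - t[1]
  beta <- 1 / rproxc + 1 / rc
  g <- p / rproxc + p_msf / rc
  expint_lin(g, dt, beta, p_res0)
}

#' Identify the diastolic time constant and filling pressure from one beat
#'
#' With the aortic valve closed, inflow is zero and the reservoir equation
#' reduces to a mono-exponential relaxation towards the mean systemic
#' filling pressure:
#' \deqn{P(t) = (P(t_d) - P_{msf})\,e^{-(t - t_d)/RC} + P_{msf}.}
#' `RC` and `P_msf` are identified by nonlinear least squares over the
#' diastolic window. The decay amplitude at `t_d` is a fitted quantity
#' rather than the raw sample: the minimum-slope rule can place `t_d` a
#' sample or two before true valve closure, where the measured pressure
#' still contains excess pressure, and anchoring there biases both `RC`
#' and `P_msf`. The first 20 ms after `t_d` are trimmed to avoid
#' valve-closure ringing. Bounds: `RC` in \[0.1, 10\] s, `P_msf` in
#' \[0, min diastolic pressure\]; start values come from a log-linear
#' regression of the decay.
#'
#' When `p_msf_fixed` is supplied only `RC` and the amplitude are fitted.
#' Over a single sub-second diastole, `RC` and `P_msf` trade off strongly
#' under measurement noise; the filling pressure is a slowly varying
#' volume-state quantity, so [decompose_beats()] pools it across
#' neighbouring beats and refits each beat's `RC` with `P_msf` held fixed,
#' which restores near-noiseless `RC` precision.
#'
#' @param t,p One beat's sample times (s) and pressure (mmHg).
#' @param t_d Diastole-onset time (s) from [detect_diastole_onset()].
#' @param trim_s Initial portion of diastole to drop (s); default 0.02.
#' @param p_msf_fixed Optional known/pooled mean systemic filling pressure
#'   (mmHg); when given it is not re-estimated.
#' @return List with `rc` (s), `p_msf` (mmHg), `p_td_fit` (fitted pressure
#'   at `t_d`, mmHg), `rmse` (mmHg), and logical `ok`. Degenerate windows
#'   (non-decaying, too short, or a fit pinned at its bounds) return
#'   `ok = FALSE`.
#' @export
fit_diastolic_decay <- function(t, p, t_d, trim_s = 0.02,
                                p_msf_fixed = NULL) {
  bad <- list(rc = NA_real_, p_msf = NA_real_, p_td_fit = NA_real_,
              rmse = NA_real_, ok = FALSE)
  i_d <- which.min(abs(t - t_d))
  p_td <- p[i_d]
  win <- which(t >= t_d + trim_s)
  if (length(win) < 10) return(bad)
  tw <- t[win] - t_d
  pw <- p[win]
  if (pw[length(pw)] >= pw[1] || stats::sd(pw) < 1e-9) return(bad)

  p_min <- min(pw)
  pmsf_hi <- p_min
  # log-linear start values: subtract a provisional asymptote below the
  # window minimum, then regress the log-residual on time
  pmsf0 <- max(0, p_min - 0.05 * max(p_td - p_min, 1e-6))
  resid0 <- pmax(pw - pmsf0, 1e-6)
  sl <- stats::coef(stats::lm(log(resid0) ~ tw))[2]
  rc0 <- if (is.finite(sl) && sl < 0) min(max(-1 / sl, 0.1), 10) else 1
  a0 <- max(p_td - pmsf0, 1e-3)

  fit <- tryCatch(
    if (is.null(p_msf_fixed)) {
      minpack.lm::nlsLM(
        pw ~ pmsf + a * exp(-tw / rc),
        start = list(rc = rc0, pmsf = pmsf0, a = a0),
        lower = c(rc = 0.1, pmsf = 0, a = 1e-6),
        upper = c(rc = 10, pmsf = pmsf_hi, a = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        pw ~ p_msf_fixed + a * exp(-tw / rc),
        start = list(rc = rc0, a = max(p_td - p_msf_fixed, 1e-3)),
        lower = c(rc = 0.1, a = 1e-6),
        upper = c(rc = 10, a = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    },
    error = function(e) NULL
  )
  if (is.null(fit)) return(bad)
  est <- stats::coef(fit)
  rc <- unname(est["rc"])
  p_msf <- if (is.null(p_msf_fixed)) unname(est["pmsf"]) else p_msf_fixed
  rmse <- sqrt(mean(stats::resid(fit)^2))
  at_bound <- rc <= 0.1 + 1e-9 || rc >= 10 - 1e-9
  if (!is.finite(rmse) || at_bound) return(bad)
  list(rc = rc, p_msf = p_msf, p_td_fit = p_msf + unname(est["a"]),
       rmse = rmse, ok = TRUE)
}

#' Identify the proximal time constant from the zero-net-flow condition
#'
#' Between the systolic pressure peak and valve closure there is a time
#' \eqn{\tau} at which aortic inflow equals outflow, i.e. net compartment
#' flow is zero and the reservoir pressure is stationary
#' (\eqn{dP_{res}/dt(\tau) = 0}). Given `RC` and `P_msf` from the diastolic
#' fit, \eqn{R_{prox}C} is the value for which the reservoir curve computed
#' by [solve_reservoir_pressure()] has that stationary point.
#'
#' For each candidate \eqn{\tau} on the sample grid inside the window, an
#' inner bisection on \eqn{R_{prox}C} in \[1e-3, 0.9 RC\] (terminating at
#' relative width 1e-6) enforces \eqn{dP_{res}/dt(\tau) = 0}; among
#' candidates whose reservoir curve is stationary at its own in-window
#' maximum (self-consistency within one sample), the one whose reservoir
#' pressure best rides the fitted diastolic decay curve over the trimmed
#' diastolic window is returned, then polished by a continuous 1-D
#' minimisation of the same mismatch. A stationary point alone does not pin
#' the solution — distinct \eqn{(\tau, R_{prox}C)} pairs can each be
#' stationary at their own maximum — so continuity with the diastolic curve
#' after `t_d` is what selects the physical one.
#'
#' @param t,p One beat's sample times (s) and pressure (mmHg).
#' @param t_peak,t_d Systolic peak and diastole-onset times (s).
#' @param rc,p_msf Diastolic identification from [fit_diastolic_decay()].
#' @param p_td Value of the diastolic decay curve at `t_d` used for the
#'   continuity criterion; defaults to the measured sample, and
#'   [decompose_beats()] passes the fitted value.
#' @param bracket Optional `c(lo, hi)` search bounds (s) intersected with
#'   the default \[1e-3, 0.9 RC\]; [decompose_beats()] uses this to
#'   re-identify beats whose estimate falls far from the across-beat
#'   rolling median.
#' @return List with `rproxc` (s), `tau` (s), `continuity_mmhg` (absolute
#'   reservoir-vs-decay mismatch at `t_d`) and logical `converged`. Beats
#'   with no stationary point in the window are flagged non-converged.
#' @export
identify_rproxc <- function(t, p, t_peak, t_d, rc, p_msf, p_td = NULL,
                            bracket = NULL) {
  bad <- list(rproxc = NA_real_, tau = NA_real_, continuity_mmhg = NA_real_,
              converged = FALSE)
  if (!is.finite(rc) || rc <= 0) return(bad)
  win <- which(t > t_peak & t < t_d)
  if (length(win) < 2) return(bad)
  i_d <- which.min(abs(t - t_d))
  p_td <- p_td %||% p[i_d]
  # continuity anchor: the first sample of the trimmed diastolic window.
  # The minimum-slope rule can fire a sample or two before true valve
  # closure, so at t_d itself the fitted decay extrapolates; 20 ms in, the
  # decay curve interpolates the fit window and inflow is safely zero,
  # while the reservoir solution still remembers its diastole entry state.
  dia <- which(t >= t_d + 0.02)
  if (length(dia) < 2) return(bad)
  i_star <- dia[1]
  decay_star <- p_msf + (p_td - p_msf) * exp(-(t[i_star] - t_d) / rc)

  lo <- max(1e-3, bracket[1] %||% 0)
  hi <- min(0.9 * rc, bracket[2] %||% Inf)
  if (hi <= lo) return(bad)
  grid <- exp(seq(log(lo), log(hi), length.out = 48))
  # dP_res/dt at sample i, from the ODE right-hand side
  dpres_at <- function(rpc, i) {
    pr <- solve_reservoir_pressure(t, p, rc, rpc, p_msf)
    (p[i] - pr[i]) / rpc - (pr[i] - p_msf) / rc
  }

  best <- NULL
  for (tau_i in win) {
    fg <- vapply(grid, dpres_at, numeric(1), i = tau_i)
    ok <- is.finite(fg)
    # rising sign change: the physical root has dP_res/dt increasing in rproxc
    sc <- which(ok[-1] & ok[-length(ok)] & fg[-length(fg)] <= 0 & fg[-1] >= 0)
    if (!length(sc)) next
    a <- grid[sc[1]]
    b <- grid[sc[1] + 1]
    fa <- fg[sc[1]]
    while ((b - a) / b > 1e-6) {
      m <- 0.5 * (a + b)
      fm <- dpres_at(m, tau_i)
      if (fa * fm <= 0) b <- m else {
        a <- m
        fa <- fm
      }
    }
    rpc <- 0.5 * (a + b)
    pr <- solve_reservoir_pressure(t, p, rc, rpc, p_msf)
    if (abs(win[which.max(pr[win])] - tau_i) > 1) next  # not its own maximum
    miss <- abs(pr[i_d] - p_td)
    if (is.null(best) || miss < best$continuity_mmhg) {
      best <- list(rproxc = rpc, tau = t[tau_i], continuity_mmhg = miss,
                   converged = TRUE)
    }
  }
  if (is.null(best)) return(bad)

  # continuous refinement: the discrete tau grid quantises the root, so
  # polish rproxc by a signed root-find on the continuity mismatch at the
  # diastolic anchor, in a bracket around the selected candidate
  m_fn <- function(x) {
    pr <- solve_reservoir_pressure(t, p, rc, x, p_msf)
    pr[i_star] - decay_star
  }
  br <- c(max(lo, best$rproxc / 1.5), min(hi, best$rproxc * 1.5))
  rpc <- best$rproxc
  if (m_fn(br[1]) * m_fn(br[2]) < 0) {
    rpc <- stats::uniroot(m_fn, br, tol = 1e-10)$root
  }
  pr <- solve_reservoir_pressure(t, p, rc, rpc, p_msf)
  if (abs(win[which.max(pr[win])] - win[which.min(abs(t[win] - best$tau))]) > 2) {
    return(best)  # refinement moved the stationary point; keep the grid solution
  }

  # tau = interpolated zero crossing of net inflow (q_in - q_out) in the window
  qn <- (p - pr) / rpc - (pr - p_msf) / rc
  tau <- best$tau
  ii <- win
  crossing <- which(qn[ii[-length(ii)]] > 0 & qn[ii[-1]] <= 0)
  if (length(crossing)) {
    i1 <- ii[crossing[1]]
    frac <- qn[i1] / (qn[i1] - qn[i1 + 1])
    tau <- t[i1] + frac * (t[2] - t[1])
  }
  list(rproxc = rpc, tau = tau,
       continuity_mmhg = abs(pr[i_star] - decay_star), converged = TRUE)
}

#' Decompose beats into reservoir and excess pressure
#'
#' Runs the full per-beat identification chain: diastolic decay fit (`RC`,
#' `P_msf`), zero-net-flow identification (`R_prox C`, `tau`), reservoir
#' pressure solution, and excess pressure `p_ex = P_ao - p_res` (exact by
#' construction). Beats whose fit or identification fails are kept in the
#' table but flagged `converged = FALSE` with the reason, and carry no
#' decomposition.
#'
#' By default the filling pressure is pooled across beats: a first pass
#' fits each beat's decay freely, `P_msf` is replaced by its centered
#' rolling median over `pool_window` beats (it is a slowly varying
#' volume-state quantity, while over one sub-second diastole it trades off
#' strongly against `RC` under noise), and a second pass refits `RC` with
#' `P_msf` held fixed. On noiseless data the two passes coincide.
#'
#' @param beats Beat table from [split_beats()].
#' @param pool_pmsf Pool the filling pressure across beats (default `TRUE`).
#' @param pool_window Rolling-median window (beats) for the pooling.
#' @return `beats` with added columns `rc_s`, `rproxc_s`, `pmsf_mmhg`,
#'   `beta_1s` (\eqn{1/R_{prox}C + 1/RC}), `tau_s`, `fit_rmse_mmhg`,
#'   `converged`, `flag_reason`, and a list-column `decomposition` of
#'   tibbles `time_s`, `p_ao`, `p_res`, `p_ex`.
#' @export
decompose_beats <- function(beats, pool_pmsf = TRUE, pool_window = 15L) {
  decompose_one <- function(d, t_peak, t_d, p_msf_fixed = NULL,
                            rpc_bracket = NULL) {
    t <- d$time_s
    p <- d$pressure_mmhg
    dec <- fit_diastolic_decay(t, p, t_d, p_msf_fixed = p_msf_fixed)
    if (!dec$ok) {
      return(list(rc = dec$rc, rproxc = NA_real_, pmsf = dec$p_msf,
                  tau = NA_real_, rmse = dec$rmse, conv = FALSE,
                  reason = "diastolic fit failed", dcmp = list(NULL)))
    }
    idf <- identify_rproxc(t, p, t_peak, t_d, dec$rc, dec$p_msf,
                           p_td = dec$p_td_fit, bracket = rpc_bracket)
    if (!idf$converged) {
      return(list(rc = dec$rc, rproxc = NA_real_, pmsf = dec$p_msf,
                  tau = NA_real_, rmse = dec$rmse, conv = FALSE,
                  reason = "rproxc identification failed", dcmp = list(NULL)))
    }
    p_res <- solve_reservoir_pressure(t, p, dec$rc, idf$rproxc, dec$p_msf)
    dcmp <- tibble::tibble(time_s = t, p_ao = p, p_res = p_res,
                           p_ex = p - p_res)
    list(rc = dec$rc, rproxc = idf$rproxc, pmsf = dec$p_msf,
         tau = idf$tau, rmse = dec$rmse, conv = TRUE, reason = "",
         dcmp = list(dcmp))
  }

  pmsf_fixed <- rep(list(NULL), nrow(beats))
  if (pool_pmsf && nrow(beats) > 1) {
    free_pmsf <- purrr::pmap_dbl(
      list(beats$data, beats$t_d),
      function(d, t_d) fit_diastolic_decay(d$time_s, d$pressure_mmhg,
                                           t_d)$p_msf)
    pooled <- rolling_median(free_pmsf, pool_window)
    pmsf_fixed <- lapply(pooled, function(x) if (is.finite(x)) x else NULL)
  }
  res <- purrr::pmap(
    list(beats$data, beats$t_peak, beats$t_d, pmsf_fixed),
    decompose_one
  )
  if (pool_pmsf && nrow(beats) > 1) {
    # a beat whose proximal time constant lands far from its neighbours'
    # has been caught by the degenerate small-RproxC branch (or a missed
    # closure notch); re-identify it inside a bracket around the
    # across-beat rolling median, flagging it if no root lives there
    rpc <- purrr::map_dbl(res, "rproxc")
    pooled_rpc <- rolling_median(rpc, pool_window)
    redo <- which(is.finite(rpc) & is.finite(pooled_rpc) &
                    (rpc < 0.5 * pooled_rpc | rpc > 2 * pooled_rpc))
    for (i in redo) {
      res[[i]] <- decompose_one(beats$data[[i]], beats$t_peak[i],
                                beats$t_d[i], pmsf_fixed[[i]],
                                rpc_bracket = pooled_rpc[i] * c(0.5, 2))
    }
  }
  dplyr::mutate(
    beats,
    rc_s = purrr::map_dbl(res, "rc"),
    rproxc_s = purrr::map_dbl(res, "rproxc"),
    pmsf_mmhg = purrr::map_dbl(res, "pmsf"),
    beta_1s = 1 / .data$rproxc_s + 1 / .data$rc_s,
    tau_s = purrr::map_dbl(res, "tau"),
    fit_rmse_mmhg = purrr::map_dbl(res, "rmse"),
    converged = purrr::map_lgl(res, "conv"),
    flag_reason = purrr::map_chr(res, "reason"),
    decomposition = purrr::map(res, ~ .x$dcmp[[1]])
  )
}

#' Aortic inflow and outflow from a decomposition
#'
#' Under the three-element Windkessel, inflow is proportional to excess
#' pressure and outflow to the reservoir pressure above the filling
#' pressure: `q_in = p_ex / R_prox`, `q_out = (p_res - P_msf) / R`. This
#' needs the full parameter triple, i.e. a closure of the one-parameter
#' ambiguity (see [close_parameters()]).
#'
#' @param decomposition Tibble `time_s`, `p_ao`, `p_res`, `p_ex` from
#'   [decompose_beats()].
#' @param params Parameter list from [windkessel_params()].
#' @return The decomposition tibble with added `q_in`, `q_out` (ml/s).
#' @export
compute_flows <- function(decomposition, params) {
  if (params$R_prox <= 0 || params$R <= 0) {
    stop("R and R_prox must be positive", call. = FALSE)
  }
  dplyr::mutate(decomposition,
                q_in = .data$p_ex / params$R_prox,
                q_out = (.data$p_res - params$P_msf) / params$R)
}
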