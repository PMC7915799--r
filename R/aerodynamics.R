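#' Hydraulic (equivalent) diameter
#'
#' `dh = 4 S / P` for a duct of cross-sectional area `S` and wetted
#' perimeter `P`; reduces to the diameter for a circular section.
#'
#' @param S area, m^2.
#' @param P perimeter, m.
#' @return Hydraulic diameter, m.
#' @export
hydraulic_diameter <- function(S, P) {
  if (any(S <= 0) || any(P <= 0)) stop("S and P must be positive")
  4 * S / P
}

#' Reynolds number of duct flow
#'
#' `Re = rho * (Q/S) * dh / mu` with mean velocity `Q/S`.
#'
#' @param Q volumetric flow, m^3/s.
#' @param S section area, m^2.
#' @param dh hydraulic diameter, m.
#' @param rho fluid density, kg/m^3 (air: 1.205).
#' @param mu dynamic viscosity, Pa s (air: 1.81e-5).
#' @return Reynolds number (dimensionless).
#' @export
reynolds <- function(Q, S, dh, rho = 1.205, mu = 1.81e-5) {
  if (any(c(Q, S, dh, rho, mu) <= 0)) stop("all inputs must be positive")
  rho * (Q / S) * dh / mu
}

#' Darcy friction coefficient
#'
#' `64/Re` in the laminar regime and `0.32/Re^0.25` in the turbulent
#' regime (the turbulent constant is configurable; 0.3164 gives the
#' classical Blasius form).
#'
#' @param Re Reynolds number, > 0.
#' @param regime `"laminar"` or `"turbulent"`.
#' @param turbulent_coef numerator of the turbulent formula.
#' @return Friction coefficient (dimensionless).
#' @export
darcy_lambda <- function(Re, regime = c("laminar", "turbulent"),
                         turbulent_coef = 0.32) {
  regime <- match.arg(regime)
  if (any(Re <= 0)) stop("Re must be positive")
  if (regime == "laminar") 64 / Re else turbulent_coef / Re^0.25
}

#' Channel section
#'
#' One computational section of a sectioned duct: area, perimeter (or a
#' directly supplied hydraulic diameter), length and a local-loss
#' coefficient attributed to the section's transition.
#'
#' @param S area, m^2.
#' @param P perimeter, m (used to derive `dh = 4S/P` unless `dh` given).
#' @param dl section length, m.
#' @param xi dimensionless local hydraulic-loss coefficient (>= 0).
#' @param dh optional hydraulic diameter, m.
#' @return List of class `channel_section`.
#' @export
channel_section <- function(S, P = NULL, dl, xi = 0, dh = NULL) {
  if (S <= 0 || dl <= 0) stop("S and dl must be positive")
  if (xi < 0) stop("xi must be >= 0")
  if (is.null(dh)) {
    if (is.null(P)) stop("supply either P or dh")
    dh <- hydraulic_diameter(S, P)
  } else if (dh <= 0) stop("dh must be positive")
  structure(list(S = S, P = if (is.null(P)) 4 * S / dh else P,
                 dh = dh, dl = dl, xi = xi),
            class = "channel_section")
}

#' Sectioned channel model of a nasal passage
#'
#' @param sections list of [channel_section()]s (>= 1), ordered along
#'   the duct.
#' @param rho air density, kg/m^3 (default 1.205).
#' @param mu dynamic viscosity, Pa s (default 1.81e-5).
#' @param re_threshold laminar/turbulent transition Reynolds number
#'   (default 2300, the classical pipe-flow value).
#' @param turbulent_coef turbulent friction numerator (default 0.32).
#' @return List of class `channel_model`.
#' @export
channel_model <- function(sections, rho = 1.205, mu = 1.81e-5,
                          re_threshold = 2300, turbulent_coef = 0.32) {
  if (inherits(sections, "channel_section")) sections <- list(sections)
  if (length(sections) < 1L) stop("need at least one section")
  if (!all(vapply(sections, inherits, logical(1), "channel_section")))
    stop("all elements must be channel_section objects")
  if (rho <= 0 || mu <= 0) stop("rho and mu must be positive")
  structure(list(sections = sections, rho = rho, mu = mu,
                 re_threshold = re_threshold,
                 turbulent_coef = turbulent_coef),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("channel_model: %d section(s), rho %.3f kg/m^3, mu %.3g Pa s\n",
              length(x$sections), x$rho, x$mu))
  for (s in x$sections)
    cat(sprintf("  S %.3g m^2, dh %.3g m, dl %.3g m, xi %g\n",
                s$S, s$dh, s$dl, s$xi))
  invisible(x)
}

#' Build channel geometry from a preset or an explicit section series
#'
#' Presets: `"circular_tube"` (single section with `S = pi d^2/4`,
#' `dh = d`) and `"two_identical_passages"` (a list of two equal
#' circular tubes, e.g. the two nasal passages of a symmetric airway).
#' An explicit series is a data frame with columns `S_mm2`, `P_mm`,
#' `dl_mm` and optionally `xi` (one row per section, converted to SI).
#'
#' @param profile preset name or a data frame of sections.
#' @param d tube diameter, m (presets).
#' @param L tube length, m (presets).
#' @param xi local-loss coefficient per section.
#' @param ... passed on to [channel_model()] (fluid constants).
#' @return A `channel_model`, or a list of two for
#'   `"two_identical_passages"`.
#' @export
make_channel_geometry <- function(profile = "circular_tube", d = 0.008,
                                  L = 0.1, xi = 0, ...) {
  if (is.data.frame(profile)) {
    need <- c("S_mm2", "P_mm", "dl_mm")
    if (!all(need %in% names(profile)))
      stop("section table needs columns ", paste(need, collapse = ", "))
    if (any(profile$S_mm2 <= 0) || any(profile$P_mm <= 0) ||
        any(profile$dl_mm <= 0))
      stop("section areas, perimeters and lengths must be positive")
    xi_col <- if ("xi" %in% names(profile)) profile$xi else
      rep(xi, nrow(profile))
    secs <- lapply(seq_len(nrow(profile)), function(i)
      channel_section(S = profile$S_mm2[i] * 1e-6,
                      P = profile$P_mm[i] * 1e-3,
                      dl = profile$dl_mm[i] * 1e-3, xi = xi_col[i]))
    return(channel_model(secs, ...))
  }
  profile <- match.arg(profile, c("circular_tube", "two_identical_passages"))
  tube <- function() channel_model(
    channel_section(S = pi * d^2 / 4, P = pi * d, dl = L, xi = xi), ...)
  if (profile == "circular_tube") tube() else list(tube(), tube())
}

# per-section diagnostics at flow Q: Re, regime, lambda, dp contribution
section_diagnostics <- function(channel, Q) {
  do.call(rbind, lapply(channel$sections, function(s) {
    Re <- reynolds(Q, s$S, s$dh, channel$rho, channel$mu)
    regime <- if (Re < channel$re_threshold) "laminar" else "turbulent"
    lam <- darcy_lambda(Re, regime, channel$turbulent_coef)
    dp <- (lam * s$dl / s$dh + s$xi) * channel$rho * Q^2 / (2 * s$S^2)
    data.frame(S = s$S, dh = s$dh, dl = s$dl, xi = s$xi, Re = Re,
               regime = regime, lambda = lam, dp = dp)
  }))
}

#' Pressure drop across a sectioned channel
#'
#' `dp = sum over sections of [lambda(Re) rho dl/dh + xi rho] Q^2/(2 S^2)`,
#' friction plus local losses, with the friction coefficient evaluated
#' at the section Reynolds number. In the laminar regime
#' `lambda = 64/Re` makes the drop linear in Q; turbulent sections scale
#' as `Q^1.75`.
#'
#' @param channel a [channel_model()].
#' @param Q volumetric flow, m^3/s, > 0.
#' @param details if `TRUE`, attach the per-section diagnostics table as
#'   attribute `"sections"`.
#' @return Pressure drop, Pa.
#' @export
pressure_drop <- function(channel, Q, details = FALSE) {
  stopifnot(inherits(channel, "channel_model"))
  if (Q <= 0) stop("Q must be positive")
  diag <- section_diagnostics(channel, Q)
  dp <- sum(diag$dp)
  if (details) attr(dp, "sections") <- diag
  dp
}

#' Aerodynamic drag constant of a channel
#'
#' The constant `A` with `dp = Q^2 A`, evaluated with the friction
#' coefficient at the given flow, in SI units (Pa s^2 / m^6).
#'
#' @inheritParams pressure_drop
#' @return Drag constant A.
#' @export
channel_resistance_A <- function(channel, Q) {
  pressure_drop(channel, Q) / Q^2
}

#' Flow split between two parallel channels
#'
#' Solves the parallel-duct network: continuity `Q1 + Q2 = Q_total`
#' with equal pressure drop across both channels (common inlet and
#' outlet). The drop is strictly increasing in flow, so the split is
#' unique; it is found by root bracketing to a relative tolerance of
#' 1e-8.
#'
#' @param channel1,channel2 [channel_model()]s for the two passages.
#' @param q_total total flow, m^3/s, > 0.
#' @return Object of class `flow_result`: `q1`, `q2`, `q_total` (m^3/s),
#'   `q1_lps`, `q2_lps` (L/s), `dp` (Pa), `dp_kpa`, drag constants `A1`,
#'   `A2` (SI) and per-channel section diagnostics.
#' @export
split_flow <- function(channel1, channel2, q_total) {
  stopifnot(inherits(channel1, "channel_model"),
            inherits(channel2, "channel_model"))
  if (q_total <= 0) stop("q_total must be positive")
  f <- function(q1) pressure_drop(channel1, q1) -
    pressure_drop(channel2, q_total - q1)
  eps <- q_total * 1e-12
  lo <- eps; hi <- q_total - eps
  if (f(lo) >= 0 || f(hi) <= 0)
    stop("failed to bracket the flow split (degenerate geometry)")
  root <- stats::uniroot(f, c(lo, hi), tol = q_total * 1e-9)
  q1 <- root$root; q2 <- q_total - q1
  dp1 <- pressure_drop(channel1, q1, details = TRUE)
  dp2 <- pressure_drop(channel2, q2, details = TRUE)
  dp <- (as.numeric(dp1) + as.numeric(dp2)) / 2
  structure(list(q1 = q1, q2 = q2, q_total = q_total,
                 q1_lps = q1 * 1e3, q2_lps = q2 * 1e3,
                 dp = dp, dp_kpa = dp * 1e-3,
                 dp_imbalance = abs(as.numeric(dp1) - as.numeric(dp2)) /
                   max(dp, .Machine$double.eps),
                 A1 = as.numeric(dp1) / q1^2, A2 = as.numeric(dp2) / q2^2,
                 sections1 = attr(dp1, "sections"),
                 sections2 = attr(dp2, "sections")),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: Q1 %.4g L/s + Q2 %.4g L/s = %.4g L/s\n",
              x$q1_lps, x$q2_lps, x$q_total * 1e3))
  cat(sprintf("  dp %.4g Pa (imbalance %.2g); A1 %.4g, A2 %.4g Pa s^2/m^6\n",
              x$dp, x$dp_imbalance, x$A1, x$A2))
  invisible(x)
}

#' Aerodynamic nasal drag coefficient from rhinomanometric data
#'
#' `A = dp / Q` in kPa/(L/s), the unit of the diagnostic indicator x5;
#' computable from a directly measured pressure-flow pair or from the
#' hydraulic model's predicted drop at a given flow.
#'
#' @param dp_kpa pressure drop, kPa (>= 0).
#' @param q_lps airflow, L/s, > 0.
#' @return Drag coefficient, kPa/(L/s).
#' @export
drag_coefficient <- function(dp_kpa, q_lps) {
  if (any(q_lps <= 0)) stop("Q must be positive")
  if (any(dp_kpa < 0)) stop("dp must be >= 0")
  dp_kpa / q_lps
}
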