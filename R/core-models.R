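#' @include AllClasses.R
NULL

#' Lea-Catcheside protraction factor for a single repair time
#'
#' Dose-protraction factor of the quadratic survival term for a constant
#' dose rate delivered over `theta` minutes when sub-lethal damage is
#' repaired with a single first-order characteristic time `t0`:
#' \deqn{G(\theta, t_0) = \frac{2 t_0}{\theta}\left[1 - \frac{t_0}{\theta}
#'   \left(1 - e^{-\theta/t_0}\right)\right].}
#' `theta = 0` encodes the acute limit and returns exactly 1 (the
#' closed form is continuous there). For `theta >> t0` the factor tends to
#' `2 t0 / theta`.
#'
#' @param theta Delivery time (min), `>= 0`; vectorized.
#' @param t0 Characteristic repair time (min), `> 0`.
#' @return G in (0, 1].
#' @examples
#' gSingle(10, 91)
#' gSingle(0, 91)     # acute limit
#' @export
gSingle <- function(theta, t0) {
  if (length(t0) != 1L || !is.finite(t0) || t0 <= 0)
    stop("'t0' must be a finite scalar > 0")
  if (anyNA(theta) || any(theta < 0))
    stop("'theta' must be >= 0")
  x <- theta / t0
  out <- numeric(length(x))
  acute <- x == 0
  out[acute] <- 1
  # series for small theta/t0 avoids catastrophic cancellation in the
  # closed form (1 - (1 - e^-x)/x ~ x/2 - x^2/6 + ...)
  small <- !acute & x < 1e-4
  if (any(small)) {
    xs <- x[small]
    out[small] <- 1 - xs / 3 + xs^2 / 12
  }
  big <- !acute & !small
  if (any(big)) {
    xb <- x[big]
    out[big] <- (2 / xb) * (1 - (1 - exp(-xb)) / xb)
  }
  out
}

#' Dual-kinetics protraction factor
#'
#' Convex combination of [gSingle()] at the fast and slow repair times with
#' the LET-class-specific proportions:
#' \deqn{G_R(\theta) = a_f\, G(\theta, t_{0f}) + (1 - a_f)\, G(\theta, t_{0s}).}
#'
#' @param protocol An [IrradiationProtocol], or a numeric delivery time in
#'   minutes.
#' @param kinetics A [RepairKinetics] object.
#' @param letClass `"low"` or `"high"`; selects the fast proportion.
#' @param fracFastOverride Optional explicit fast proportion in \[0, 1\]
#'   (used e.g. for cross-component terms); overrides `letClass`.
#' @return G in (0, 1].
#' @examples
#' k <- RepairKinetics()
#' gDual(10, k, "high")   # the 10-min reactor protocol
#' gDual(10, k, "low")
#' @export
gDual <- function(protocol, kinetics = RepairKinetics(),
                  letClass = c("low", "high"), fracFastOverride = NULL) {
  theta <- if (is(protocol, "IrradiationProtocol")) protocol@duration
           else as.numeric(protocol)
  af <- if (is.null(fracFastOverride)) {
    fracFast(kinetics, match.arg(letClass))
  } else {
    if (fracFastOverride < 0 || fracFastOverride > 1)
      stop("'fracFastOverride' must lie in [0, 1]")
    fracFastOverride
  }
  af * gSingle(theta, kinetics@t0Fast) +
    (1 - af) * gSingle(theta, kinetics@t0Slow)
}

#' G factors for every term of the mixed-field survival model
#'
#' Computes the six protraction factors of the mixed-field quadratic terms:
#' the three like-component factors (boron, neutron, photon) and the three
#' cross factors (boron-neutron, boron-photon, photon-neutron). All
#' components are delivered simultaneously over the same protocol, so each
#' factor uses the shared duration; a cross term between components of
#' different LET class uses the arithmetic mean of the two components' fast
#' proportions (at the short durations typical of BNCT every factor is
#' within a few percent of 1, so the combination rule has negligible
#' numerical impact).
#'
#' @param protocol [IrradiationProtocol] or numeric duration (min).
#' @param kinetics [RepairKinetics].
#' @return Named list with elements `gB`, `gN`, `gGamma`, `gBN`, `gBGamma`,
#'   `gGammaN`, each in (0, 1].
#' @examples
#' mixedFieldGFactors(10, RepairKinetics())
#' @export
mixedFieldGFactors <- function(protocol, kinetics = RepairKinetics()) {
  afLow <- fracFast(kinetics, "low")
  afHigh <- fracFast(kinetics, "high")
  afCross <- (afLow + afHigh) / 2
  list(
    gB = gDual(protocol, kinetics, "high"),
    gN = gDual(protocol, kinetics, "high"),
    gGamma = gDual(protocol, kinetics, "low"),
    gBN = gDual(protocol, kinetics, fracFastOverride = afHigh),
    gBGamma = gDual(protocol, kinetics, fracFastOverride = afCross),
    gGammaN = gDual(protocol, kinetics, fracFastOverride = afCross)
  )
}

#' Reference-radiation MLQ survival
#'
#' Surviving fraction after a photon reference dose under the modified
#' linear-quadratic model,
#' \deqn{S_R = \exp\left[-(\alpha_R D + \beta_R G_R(\theta) D^2)\right],}
#' where the protraction factor G scales the quadratic term.
#'
#' @param dose Absorbed dose (Gy), `>= 0`; vectorized.
#' @param params [LQParameters] of the reference radiation.
#' @param gFactor Protraction factor in (0, 1] (default 1, acute).
#' @return Surviving fraction in (0, 1].
#' @examples
#' co60 <- LQParameters(0.21, 0.02, "low")
#' survivalReference(5, co60)
#' @export
survivalReference <- function(dose, params, gFactor = 1) {
  stopifnot(is(params, "LQParameters"))
  if (anyNA(dose) || any(dose < 0)) stop("'dose' must be >= 0")
  if (anyNA(gFactor) || any(gFactor <= 0) || any(gFactor > 1))
    stop("'gFactor' must lie in (0, 1]")
  exp(-(params@alpha * dose + params@beta * gFactor * dose^2))
}

#' Mixed-field MLQ survival
#'
#' Surviving fraction for the BNCT mixed field (boron capture products,
#' neutron-induced charged particles, photons). The log-survival is the sum
#' of each component's linear and protraction-scaled quadratic term plus the
#' synergistic quadratic cross terms:
#' \deqn{-\ln S = \alpha_B D_B + \alpha_n D_n + \alpha_\gamma D_\gamma
#'   + G_B \beta_B D_B^2 + G_n \beta_n D_n^2 + G_\gamma \beta_\gamma D_\gamma^2
#'   + M_Q,}
#' \deqn{M_Q = 2 G_{Bn}\sqrt{\beta_B\beta_n} D_B D_n
#'   + 2 G_{B\gamma}\sqrt{\beta_B\beta_\gamma} D_B D_\gamma
#'   + 2 G_{\gamma n}\sqrt{\beta_\gamma\beta_n} D_\gamma D_n.}
#' With exactly one nonzero component and the matching G this reduces
#' exactly to [survivalReference()].
#'
#' @param dose A [MixedFieldDose] (components may be vectors).
#' @param params A [RadiobiologicalParameterSet].
#' @param protocol [IrradiationProtocol] or numeric duration (min); used to
#'   compute the G factors when `g` is not supplied.
#' @param g Optional list of explicit factors as returned by
#'   [mixedFieldGFactors()].
#' @return Surviving fraction(s) in (0, 1].
#' @examples
#' survivalMixedField(MixedFieldDose(boron = 1, neutron = 1, photon = 1),
#'                    gbmParameters(), protocol = 10)
#' @export
survivalMixedField <- function(dose, params, protocol = 0, g = NULL) {
  stopifnot(is(dose, "MixedFieldDose"),
            is(params, "RadiobiologicalParameterSet"))
  validObject(dose)
  if (is.null(g)) g <- mixedFieldGFactors(protocol, params@kinetics)
  exp(-mixedFieldLogEffect(
    dB = dose@boron, dN = dose@neutron, dG = dose@photon,
    aB = params@boron@alpha, bB = params@boron@beta,
    aN = params@neutron@alpha, bN = params@neutron@beta,
    aG = params@photon@alpha, bG = params@photon@beta,
    g = g))
}

# Shared exponent of the mixed-field model: -ln S as a function of raw
# component doses and parameters. Vectorized over doses. Internal: the
# survival, fitting and isoeffective-dose code all call this one kernel.
mixedFieldLogEffect <- function(dB, dN, dG, aB, bB, aN, bN, aG, bG, g) {
  aB * dB + aN * dN + aG * dG +
    g$gB * bB * dB^2 + g$gN * bN * dN^2 + g$gGamma * bG * dG^2 +
    2 * g$gBN * sqrt(bB * bN) * dB * dN +
    2 * g$gBGamma * sqrt(bB * bG) * dB * dG +
    2 * g$gGammaN * sqrt(bG * bN) * dG * dN
}

#' Bi-exponential DNA-repair (foci) decay
#'
#' Normalized radiation-induced foci intensity at time `t` after
#' irradiation, modelled as the sum of a fast and a slow exponential repair
#' component:
#' \deqn{I(t) = c\, e^{-t/t_{0f}} + (1 - c)\, e^{-t/t_{0s}}.}
#' `I(0) = 1` and the curve decreases monotonically to 0.
#'
#' @param t Time after irradiation (min), `>= 0`; vectorized.
#' @param fracFast Proportion `c` repaired with the fast kinetics, in
#'   \[0, 1\].
#' @param t0Fast,t0Slow Characteristic repair times (min), `> 0`.
#' @return Normalized intensity in (0, 1].
#' @examples
#' fociIntensity(c(0, 91, 1440), 0.77, 91, 1238)
#' @export
fociIntensity <- function(t, fracFast, t0Fast, t0Slow) {
  if (t0Fast <= 0 || t0Slow <= 0)
    stop("repair times must be > 0")
  if (fracFast < 0 || fracFast > 1)
    stop("'fracFast' must lie in [0, 1]")
  if (anyNA(t) || any(t < 0)) stop("'t' must be >= 0")
  fracFast * exp(-t / t0Fast) + (1 - fracFast) * exp(-t / t0Slow)
}
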