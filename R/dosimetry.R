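#' @include core-models.R
NULL

#' Invert the MLQ survival model for a dose
#'
#' Dose producing a target surviving fraction under the (protracted) LQ
#' model, i.e. the positive root of
#' `alpha D + beta G D^2 = -log(S)`:
#' \deqn{D = \frac{-\alpha + \sqrt{\alpha^2 + 4\beta G\,(-\ln S)}}{2\beta G},}
#' with the linear branch `D = -log(S)/alpha` when `beta = 0`.
#'
#' @param targetS Target surviving fraction in (0, 1]; vectorized.
#' @param params [LQParameters].
#' @param gFactor Protraction factor in (0, 1].
#' @return Dose in Gy.
#' @examples
#' doseAtSurvival(0.01, LQParameters(0.21, 0.02, "low"))   # ~10.8 Gy
#' @export
doseAtSurvival <- function(targetS, params, gFactor = 1) {
  stopifnot(is(params, "LQParameters"))
  if (anyNA(targetS) || any(targetS <= 0) || any(targetS > 1))
    stop("'targetS' must lie in (0, 1]")
  a <- params@alpha
  bg <- params@beta * gFactor
  if (a == 0 && bg == 0)
    stop("no solution: alpha and beta are both zero")
  e <- -log(targetS)
  if (bg == 0) e / a
  else (-a + sqrt(a^2 + 4 * bg * e)) / (2 * bg)
}

#' RBE at a survival endpoint
#'
#' Relative biological effectiveness of a test radiation versus a reference
#' radiation at a survival endpoint: the ratio of the reference dose to the
#' test dose that each produce the target surviving fraction, each dose
#' obtained by inverting its own (protracted) MLQ curve. The default
#' endpoint is 1% survival, the convention for BNCT RBE/CBE factors.
#'
#' @param reference,test [LQParameters] of the two radiations.
#' @param targetS Survival endpoint in (0, 1) (default 0.01).
#' @param kinetics [RepairKinetics] used to compute each radiation's
#'   dual-kinetics G factor from its protocol.
#' @param referenceProtocol,testProtocol [IrradiationProtocol] or numeric
#'   duration in minutes (default acute, G = 1).
#' @return Dimensionless dose ratio.
#' @examples
#' co60 <- LQParameters(0.21, 0.02, "low")
#' neutron <- LQParameters(0.5, 0.5, "high")
#' rbeAtEndpoint(co60, neutron, testProtocol = 10)   # 10-min irradiation
#' @export
rbeAtEndpoint <- function(reference, test, targetS = 0.01,
                          kinetics = RepairKinetics(),
                          referenceProtocol = 0, testProtocol = 0) {
  gRef <- gDual(referenceProtocol, kinetics, reference@letClass)
  gTest <- gDual(testProtocol, kinetics, test@letClass)
  doseAtSurvival(targetS, reference, gRef) /
    doseAtSurvival(targetS, test, gTest)
}

#' CBE at a survival endpoint
#'
#' Compound biological effectiveness of the boron dose component: the RBE
#' of the isolated boron-capture contribution versus the photon reference,
#' at the survival endpoint. Identical to [rbeAtEndpoint()] with the boron
#' component as the test radiation; provided as its own verb because CBE is
#' carrier-dependent and reported separately in practice.
#'
#' @param reference Photon reference [LQParameters].
#' @param boron Boron-component [LQParameters].
#' @inheritParams rbeAtEndpoint
#' @param boronProtocol Protocol of the boron irradiation (default acute).
#' @return Dimensionless dose ratio.
#' @examples
#' cbeAtEndpoint(LQParameters(0.21, 0.02, "low"),
#'               LQParameters(3.0, 0, "high"))
#' @export
cbeAtEndpoint <- function(reference, boron, targetS = 0.01,
                          kinetics = RepairKinetics(),
                          referenceProtocol = 0, boronProtocol = 0) {
  rbeAtEndpoint(reference, boron, targetS, kinetics,
                referenceProtocol, boronProtocol)
}

#' Photon isoeffective dose of a mixed-field irradiation
#'
#' The photon dose that produces the same cell survival as the given
#' combination of BNCT dose components, under the mixed-field MLQ model with
#' synergy and dual-kinetics sub-lethal damage repair. Solving the survival
#' equality for the reference dose gives the closed form
#' \deqn{D_{IsoE} = \frac{-\alpha_R + \sqrt{\alpha_R^2 + 4\beta_R G_R\, E}}
#'   {2\beta_R G_R},}
#' where E is the mixed-field log-effect (the exponent of
#' [survivalMixedField()]).
#'
#' In `"acute"` reference mode `G_R = 1` and the closed form applies
#' directly. In `"fixed_rate"` mode the reference irradiation is itself
#' protracted at `referenceDoseRate`, so `G_R` depends on the reference
#' delivery time `D_IsoE / rate`; the equation is then solved
#' self-consistently by fixed-point iteration to relative tolerance 1e-8.
#'
#' @param dose [MixedFieldDose] (vector components allowed).
#' @param params [RadiobiologicalParameterSet].
#' @param protocol [IrradiationProtocol] or numeric duration (min) of the
#'   BNCT delivery, used for the mixed-field G factors.
#' @param referenceMode `"acute"` (default) or `"fixed_rate"`.
#' @param referenceDoseRate Gy/min for `"fixed_rate"` mode.
#' @return Photon isoeffective dose(s), Gy(IsoE).
#' @examples
#' isoeffectiveDose(MixedFieldDose(boron = 10), gbmParameters())  # ~33.8
#' @export
isoeffectiveDose <- function(dose, params, protocol = 0,
                             referenceMode = c("acute", "fixed_rate"),
                             referenceDoseRate = 1) {
  referenceMode <- match.arg(referenceMode)
  stopifnot(is(dose, "MixedFieldDose"),
            is(params, "RadiobiologicalParameterSet"))
  validObject(dose)
  g <- mixedFieldGFactors(protocol, params@kinetics)
  effect <- mixedFieldLogEffect(
    dB = dose@boron, dN = dose@neutron, dG = dose@photon,
    aB = params@boron@alpha, bB = params@boron@beta,
    aN = params@neutron@alpha, bN = params@neutron@beta,
    aG = params@photon@alpha, bG = params@photon@beta, g = g)
  aR <- params@photon@alpha
  bR <- params@photon@beta

  invert <- function(gR) {
    if (bR == 0) effect / aR
    else (-aR + sqrt(aR^2 + 4 * bR * gR * effect)) / (2 * bR * gR)
  }
  if (referenceMode == "acute" || bR == 0) return(invert(1))

  # self-consistent reference protraction: G_R depends on the returned dose
  d <- invert(1)
  for (i in 1:200) {
    thetaR <- d / referenceDoseRate
    gR <- vapply(thetaR, gDual, numeric(1), kinetics = params@kinetics,
                 letClass = "low")
    dNew <- invert(gR)
    if (all(abs(dNew - d) <= 1e-8 * pmax(dNew, 1e-12))) return(dNew)
    d <- dNew
  }
  stop("fixed-rate isoeffective dose iteration did not converge")
}

#' Fixed-factor RBE-weighted dose
#'
#' The conventional photon-equivalent dose: each physical dose component in
#' Gy multiplied by its fixed RBE/CBE factor and summed,
#' `w_B D_B + w_n D_n + w_gamma D_gamma`. Linear and additive in the
#' components, unlike the isoeffective dose.
#'
#' @param dose [MixedFieldDose] (vector components allowed).
#' @param weights [RBEWeights].
#' @return Gy(RBE) value(s).
#' @examples
#' rbeWeightedDose(MixedFieldDose(1, 1, 1), RBEWeights())   # 8 Gy(RBE)
#' @export
rbeWeightedDose <- function(dose, weights = RBEWeights()) {
  stopifnot(is(dose, "MixedFieldDose"), is(weights, "RBEWeights"))
  validObject(dose)
  validObject(weights)
  weights@boron * dose@boron + weights@neutron * dose@neutron +
    weights@photon * dose@photon
}
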