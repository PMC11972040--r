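# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: the G factor comes from brute-force numerical
# integration of the constant-dose-rate Lea-Catcheside double integral, and
# dose inversions come from bisection on the survival function itself.

# G(theta, t0) = (2/theta^2) int_0^theta dt int_0^t du exp(-(t-u)/t0),
# evaluated by nested adaptive quadrature.
gLeaCatchesideNumeric <- function(theta, t0) {
  inner <- function(t) vapply(t, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(function(u) exp(-(ti - u) / t0), 0, ti,
                     rel.tol = 1e-11)$value
  }, numeric(1))
  (2 / theta^2) * stats::integrate(inner, 0, theta, rel.tol = 1e-10)$value
}

# Bisection root of SR(D) = targetS for the reference MLQ curve.
bisectDoseAtSurvival <- function(targetS, alpha, beta, g = 1, hi = 1e4) {
  f <- function(d) exp(-(alpha * d + beta * g * d^2)) - targetS
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Bisection root of the survival-equality equation SR(D) = S_BNCT for a
# given mixed-field log-effect (acute reference).
bisectIsoeffective <- function(effect, alphaR, betaR, gR = 1, hi = 1e4) {
  f <- function(d) alphaR * d + betaR * gR * d^2 - effect
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Noise-free survival table computed straight from the model (the generator
# truth serves as the oracle for recovery tests).
exactSurvivalTable <- function(truth, design, sfSigmaRel = 0.05) {
  s <- survivalMixedField(
    MixedFieldDose(design@doses$boron, design@doses$neutron,
                   design@doses$photon),
    truth, protocol = design@durationMin)
  data.frame(
    condition = design@condition,
    d_boron = design@doses$boron,
    d_neutron = design@doses$neutron,
    d_photon = design@doses$photon,
    d_boron_sigma = 0,
    surviving_fraction = s,
    sf_sigma = sfSigmaRel * s,
    duration_min = design@durationMin
  )
}

# Printed reference/component parameter values used throughout:
co60Params <- function() LQParameters(0.21, 0.02, "low")
xrayParams <- function() LQParameters(0.46, 0.03, "low")
neutronCo60Params <- function() LQParameters(0.5, 0.5, "high")
neutronXrayParams <- function() LQParameters(0.1, 0.5, "high")
boronParams <- function() LQParameters(3.0, 0.0, "high")
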