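#' @include AllGenerics.R
NULL

.dipoleEnergyJ <- function(muA, muB, theta, r, dielectric) {
  if (any(r <= 0)) stop("separation r must be positive")
  k <- physicalConstants()
  muA_SI <- muA * k$debye_Cm
  muB_SI <- muB * k$debye_Cm
  ang <- 1 - 3 * cos(theta * pi / 180)^2
  muA_SI * muB_SI * ang /
    (4 * pi * k$eps0_F_m * dielectric * (r * 1e-10)^3)
}

#' Scalar dipole-dipole interaction energy
#'
#' Energy per molecule of two point dipoles in a dielectric continuum,
#' \deqn{E = \mu_A \mu_B (1 - 3\cos^2\theta) / (4\pi\varepsilon_0 D r^3),}
#' with a single inter-dipole angle \eqn{\theta} (a scalar reduction of the
#' full two-angle dipole tensor). Negative values are attractive; the
#' interaction vanishes at the magic angle (\eqn{\theta \approx 54.74}
#' degrees, where \eqn{1 - 3\cos^2\theta = 0}).
#'
#' @param state a \linkS4class{DipolePairState}, or the dipole magnitude
#'   \code{muA} in Debye when using the numeric interface.
#' @param muB second dipole magnitude, Debye (numeric interface; defaults to
#'   \code{state}).
#' @param theta inter-dipole angle, degrees.
#' @param r separation, Angstrom.
#' @param dielectric relative dielectric constant (default 78, bulk water).
#' @param ... unused.
#' @return Energy per molecule in joules (vectorized); negative =
#'   attractive.
#' @examples
#' dipoleEnergy(DipolePairState(300, 300, theta = 135, r = 50))  # ~ -4.6e-22 J
#' @rdname dipoleEnergy
#' @export
setMethod("dipoleEnergy", "DipolePairState", function(state, ...) {
  .dipoleEnergyJ(state@muA, state@muB, state@theta, state@r, state@dielectric)
})

#' @rdname dipoleEnergy
#' @export
setMethod("dipoleEnergy", "numeric",
          function(state, muB = state, theta, r, dielectric = 78, ...) {
  .dipoleEnergyJ(state, muB, theta, r, dielectric)
})

#' Scalar dipole-dipole force per molecule
#'
#' The radial derivative of the scalar dipole-dipole energy: since
#' \eqn{E \propto r^{-3}}, the force magnitude is \eqn{|F| = 3|E|/r},
#' reported per molecule in piconewtons together with an attractive flag
#' (sign of E).
#'
#' @inheritParams dipoleEnergy
#' @return data.frame with columns \code{force_pN} (magnitude) and
#'   \code{attractive} (logical), one row per input state.
#' @examples
#' dipoleForce(DipolePairState(300, 300, theta = 135, r = 50))  # ~0.277 pN
#' @rdname dipoleForce
#' @export
setMethod("dipoleForce", "DipolePairState", function(state, ...) {
  E <- dipoleEnergy(state)
  data.frame(force_pN = 3 * abs(E) / (state@r * 1e-10) * 1e12,
             attractive = E < 0)
})

#' @rdname dipoleForce
#' @export
setMethod("dipoleForce", "numeric",
          function(state, muB = state, theta, r, dielectric = 78, ...) {
  dipoleForce(DipolePairState(state, muB, theta, r, dielectric))
})

#' Arrhenius conversion of a free-energy barrier to a timescale
#'
#' \deqn{\tau = \exp(\Delta G / RT) / k_0} — the characteristic escape time
#' over a barrier \eqn{\Delta G} at temperature T with attempt frequency
#' \eqn{k_0}. With the default 1 per microsecond prefactor, barriers of
#' 5--20 kcal/mol map to dissociation timescales of about 1e-2 to 1e9
#' seconds.
#'
#' @param spec a \linkS4class{BarrierSpec}, or the barrier height in
#'   kcal/mol (numeric interface).
#' @param temperature temperature, K (numeric interface; default 300).
#' @param prefactor attempt frequency, 1/s (numeric interface; default 1e6).
#' @param ... unused.
#' @return Timescale in seconds (vectorized).
#' @examples
#' arrheniusTimescale(0)    # 1e-6 s: the bare attempt time
#' arrheniusTimescale(20)   # ~3.7e8 s
#' @rdname arrheniusTimescale
#' @export
setMethod("arrheniusTimescale", "BarrierSpec", function(spec, ...) {
  RT <- physicalConstants()$R_kcal_mol_K * spec@temperature
  exp(spec@deltaG / RT) / spec@prefactor
})

#' @rdname arrheniusTimescale
#' @export
setMethod("arrheniusTimescale", "numeric",
          function(spec, temperature = 300, prefactor = 1e6, ...) {
  arrheniusTimescale(BarrierSpec(spec, temperature, prefactor))
})

#' Evaluate dipole-dipole energy and force on a parameter grid
#'
#' Expands the full grid of the supplied dipole magnitudes, angles and
#' separations and evaluates energy and force at each point — the tabular
#' form behind quick sensitivity scans.
#'
#' @param mu dipole magnitudes, Debye (applied to both dipoles).
#' @param theta angles, degrees.
#' @param r separations, Angstrom.
#' @param dielectric relative dielectric constant.
#' @return data.frame with columns \code{mu_D}, \code{theta_deg},
#'   \code{r_A}, \code{dielectric}, \code{energy_J}, \code{force_pN},
#'   \code{attractive}.
#' @export
dipoleGrid <- function(mu = c(200, 300), theta = seq(0, 180, by = 15),
                       r = seq(20, 80, by = 5), dielectric = 78) {
  g <- expand.grid(mu_D = mu, theta_deg = theta, r_A = r,
                   dielectric = dielectric, KEEP.OUT.ATTRS = FALSE)
  st <- DipolePairState(g$mu_D, g$mu_D, g$theta_deg, g$r_A, g$dielectric)
  f <- dipoleForce(st)
  cbind(g, energy_J = dipoleEnergy(st), f)
}
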