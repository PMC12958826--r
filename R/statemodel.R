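# Eight-state, seven-reaction equilibrium model of receptor signalling.
#
# The receptor cycles through four alternating-access conformations
# (outward open, occluded, inward-facing occluded, inward open), each with
# or without bound ligand: states A..H. Seven reversible reactions connect
# them --
#   E1: A + L_out <-> B   (K1, per-uM association)
#   E2: B <-> C, E3: C <-> D                (extracellular-side closure)
#   E4: A <-> E, E5: E <-> F, E6: F <-> G   (ligand-free pathway)
#   E7: G + L_in <-> H    (K7, per-uM association with cytosolic ligand)
# -- and the D <-> H interconversion present in true transporters is
# structurally absent, so the reaction graph is a spanning tree over the 8
# states. Equilibrium populations are therefore plain path products of the
# edge constants, normalized; no cycle consistency condition arises. The
# inward-facing occluded states D (ligand-bound) and F (ligand-free) are
# the signalling states; the signalling fraction is f_D + f_F.
#
# In closed form the signalling fraction is a hyperbola in L_out,
#   S(L) = (a L + b) / (c L + d), with
#   a = K1 K2 K3, b = K4 K5,
#   c = K1 (1 + K2 + K2 K3), d = 1 + K4 (1 + K5 + K5 K6 + K5 K6 K7 L_in),
# giving basal = b/d, plateau = a/c and EC50 = d/c (the half point of a
# hyperbola through basal and plateau).

#' Default equilibrium parameters
#'
#' Constructs the parameter set of the 8-state model. The defaults place
#' the receptor in a low-basal, ligand-responsive regime: K4 (spontaneous
#' occlusion without ligand) is small, so the basal signal comes from a
#' small population of the ligand-free signalling state F, while K2 and K3
#' make the ligand-bound pathway to the signalling state D productive.
#' K1 defaults to 0.00492 per uM so that the wild-type EC50 is ~12 uM, a
#' typical potency for the strongest-sensed amino acid (leucine).
#'
#' @param K1 Association constant of extracellular ligand (per uM).
#' @param K2,K3 Extracellular-closure and inward-occlusion equilibrium
#'   constants on the ligand-bound path (dimensionless).
#' @param K4,K5,K6 Ligand-free pathway equilibrium constants
#'   (dimensionless).
#' @param K7 Association constant of intracellular ligand (per uM).
#' @param L_out,L_in Extra-/intracellular ligand concentrations (uM).
#' @return An object of class `sps_state_params` (named list).
#' @export
state_params <- function(K1 = 0.00492, K2 = 3, K3 = 5, K4 = 0.002,
                         K5 = 10, K6 = 5, K7 = 0.05,
                         L_out = 0, L_in = 0) {
  p <- list(K1 = K1, K2 = K2, K3 = K3, K4 = K4, K5 = K5, K6 = K6,
            K7 = K7, L_out = L_out, L_in = L_in)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                   is.na(v) || v < 0, logical(1)))) {
    stop("all equilibrium constants and concentrations must be single non-negative numbers",
         call. = FALSE)
  }
  structure(p, class = "sps_state_params")
}

#' @export
print.sps_state_params <- function(x, ...) {
  cat("<sps_state_params> K1..K7 =",
      paste(signif(unlist(x[paste0("K", 1:7)]), 4), collapse = ", "),
      " L_out =", x$L_out, "uM  L_in =", x$L_in, "uM\n")
  invisible(x)
}

# unnormalized state weights as path products from state A
#' @noRd
.state_weights <- function(p) {
  with(p, c(
    A = 1,
    B = K1 * L_out,
    C = K1 * K2 * L_out,
    D = K1 * K2 * K3 * L_out,
    E = K4,
    F = K4 * K5,
    G = K4 * K5 * K6,
    H = K4 * K5 * K6 * K7 * L_in
  ))
}

#' Solve the 8-state equilibrium
#'
#' @param p Parameters from [state_params()].
#' @return List of class `sps_state_distribution`: `fractions` (named
#'   vector over states A..H, summing to 1) and `signaling_fraction`
#'   (`f_D + f_F`).
#' @examples
#' solve_equilibrium(state_params(L_out = 10))
#' @export
solve_equilibrium <- function(p) {
  stopifnot(inherits(p, "sps_state_params"))
  w <- .state_weights(p)
  f <- w / sum(w)
  structure(list(fractions = f, signaling_fraction = unname(f["D"] + f["F"])),
            class = "sps_state_distribution")
}

#' @export
print.sps_state_distribution <- function(x, ...) {
  print(round(x$fractions, 4))
  cat("signaling fraction (f_D + f_F):", signif(x$signaling_fraction, 4), "\n")
  invisible(x)
}

# hyperbola coefficients S(L) = (aL + b)/(cL + d)
#' @noRd
.hyperbola_coef <- function(p) {
  with(p, list(
    a = K1 * K2 * K3,
    b = K4 * K5,
    c = K1 * (1 + K2 + K2 * K3),
    d = 1 + K4 * (1 + K5 + K5 * K6 + K5 * K6 * K7 * L_in)
  ))
}

#' Closed-form EC50 of the dose-response curve
#'
#' The signalling fraction is a hyperbola `(aL+b)/(cL+d)` in extracellular
#' ligand, so the ligand concentration giving the response midway between
#' basal and plateau is `d/c`:
#' `EC50 = [1 + K4 (1 + K5 + K5 K6 + K5 K6 K7 L_in)] / [K1 (1 + K2 + K2 K3)]`.
#'
#' @param p Parameters from [state_params()].
#' @return EC50 in uM, or `NA` when plateau equals basal.
#' @export
ec50_closed_form <- function(p) {
  h <- .hyperbola_coef(p)
  if (h$c == 0) return(NA_real_)
  basal <- h$b / h$d
  plateau <- h$a / h$c
  if (isTRUE(all.equal(basal, plateau))) return(NA_real_)
  h$d / h$c
}

#' Dose-response of the signalling fraction
#'
#' Evaluates the signalling fraction over a grid of extracellular ligand
#' concentrations and finds the EC50 numerically: the concentration where
#' the curve crosses midway between basal (`L_out = 0`) and plateau
#' (`L_out -> Inf`), located by bisection to relative tolerance 1e-9.
#'
#' @param p Parameters from [state_params()] (its `L_out` is ignored).
#' @param grid Non-negative `L_out` values (uM).
#' @return List of class `sps_dose_response`: `grid`, `signaling`,
#'   `basal`, `plateau`, `ec50` (`NA` when the curve is flat).
#' @export
dose_response <- function(p, grid = 10^seq(-2, 4, length.out = 200)) {
  stopifnot(all(grid >= 0))
  sig_at <- function(L) {
    q <- p; q$L_out <- L
    solve_equilibrium(q)$signaling_fraction
  }
  signaling <- vapply(grid, sig_at, numeric(1))
  h <- .hyperbola_coef(p)
  basal <- h$b / h$d
  plateau <- if (h$c > 0) h$a / h$c else basal
  ec50 <- NA_real_
  if (!isTRUE(all.equal(basal, plateau))) {
    half <- (basal + plateau) / 2
    # bracket the crossing, then bisect
    lo <- 0; hi <- 1
    gap <- function(L) sig_at(L) - half
    s0 <- sign(gap(lo))
    while (sign(gap(hi)) == s0 && hi < 1e18) hi <- hi * 10
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (sign(gap(mid)) == s0) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-9 * max(hi, 1e-300)) break
    }
    ec50 <- (lo + hi) / 2
  }
  structure(list(grid = grid, signaling = signaling, basal = basal,
                 plateau = plateau, ec50 = ec50),
            class = "sps_dose_response")
}

#' @export
print.sps_dose_response <- function(x, ...) {
  cat("<sps_dose_response> basal =", signif(x$basal, 4),
      " plateau =", signif(x$plateau, 4),
      " EC50 =", if (is.na(x$ec50)) "undefined" else paste(signif(x$ec50, 4), "uM"),
      "\n")
  invisible(x)
}

#' Named mutant-class perturbation presets
#'
#' Multiplicative factors on equilibrium constants emulating the mutant
#' classes discussed for the sensor: `"extracellular-gate"` (K2 x5, K4 x5;
#' mutations easing closure of the extracellular gate, the
#' constitutive/hyper-responsive class) and `"TM1-loop-block"` (K2 /100,
#' K4 /100; mutations disfavouring occlusion, the hypo-responsive class
#' with strongly reduced basal signal and an EC50 raised by orders of
#' magnitude).
#'
#' @return Named list of named factor vectors.
#' @export
state_presets <- function() {
  list(
    "extracellular-gate" = c(K2 = 5, K4 = 5),
    "TM1-loop-block" = c(K2 = 1 / 100, K4 = 1 / 100)
  )
}

#' Perturb parameters and compare signalling phenotype
#'
#' Applies multiplicative factors to selected equilibrium constants,
#' solves both parameterizations, and flags the phenotype of the change:
#' `constitutive` (basal up), `hyper_responsive` (EC50 down),
#' `hypo_responsive` (EC50 up).
#'
#' @param p Baseline parameters from [state_params()].
#' @param perturbation Named numeric vector of positive factors, e.g.
#'   `c(K2 = 5, K4 = 5)`. Ignored when `preset` is given.
#' @param preset Optional preset name, see [state_presets()].
#' @return List of class `sps_perturbation`: `before`/`after` (each with
#'   `basal`, `plateau`, `ec50`), `factors` and logical flags
#'   `constitutive`, `hyper_responsive`, `hypo_responsive`.
#' @export
perturb_and_compare <- function(p, perturbation = NULL, preset = NULL) {
  if (!is.null(preset)) {
    presets <- state_presets()
    if (!preset %in% names(presets)) stop("unknown preset: ", preset, call. = FALSE)
    perturbation <- presets[[preset]]
  }
  if (is.null(perturbation)) perturbation <- numeric(0)
  if (length(perturbation) && (is.null(names(perturbation)) ||
      !all(names(perturbation) %in% paste0("K", 1:7)))) {
    stop("perturbation must be named with K1..K7", call. = FALSE)
  }
  if (any(perturbation <= 0)) stop("factors must be > 0", call. = FALSE)
  q <- p
  for (nm in names(perturbation)) q[[nm]] <- q[[nm]] * perturbation[[nm]]
  class(q) <- class(p)
  summarize <- function(pp) {
    h <- .hyperbola_coef(pp)
    list(basal = h$b / h$d,
         plateau = if (h$c > 0) h$a / h$c else h$b / h$d,
         ec50 = ec50_closed_form(pp))
  }
  before <- summarize(p)
  after <- summarize(q)
  tol <- 1e-12
  structure(list(
    before = before, after = after, factors = perturbation,
    constitutive = after$basal > before$basal * (1 + tol),
    hyper_responsive = !is.na(after$ec50) && !is.na(before$ec50) &&
      after$ec50 < before$ec50 * (1 - tol),
    hypo_responsive = !is.na(after$ec50) && !is.na(before$ec50) &&
      after$ec50 > before$ec50 * (1 + tol)
  ), class = "sps_perturbation")
}

#' @export
print.sps_perturbation <- function(x, ...) {
  cat("<sps_perturbation>",
      if (length(x$factors)) paste(names(x$factors), "x", signif(x$factors, 4),
                                   collapse = ", ") else "(identity)", "\n")
  cat("  basal:  ", signif(x$before$basal, 4), "->", signif(x$after$basal, 4), "\n")
  cat("  EC50:   ", signif(x$before$ec50, 4), "->", signif(x$after$ec50, 4), "uM\n")
  flags <- c("constitutive", "hyper_responsive", "hypo_responsive")
  on <- flags[vapply(flags, function(f) isTRUE(x[[f]]), logical(1))]
  cat("  flags:  ", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}
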