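# Material registry: isotropic linear-elastic tissue properties.

#' Define an isotropic linear-elastic material
#'
#' @param E elastic modulus in GPa (converted to MPa inside the solver so that
#'   mm/N units yield stresses in MPa).
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return an object of class `material`.
#' @export
material <- function(E, nu) {
  if (!is.numeric(E) || length(E) != 1 || !is.finite(E) || E <= 0) {
    stop("material: E must be a positive finite scalar (GPa)")
  }
  if (!is.numeric(nu) || length(nu) != 1 || nu <= -1 || nu >= 0.5) {
    stop("material: nu must lie in (-1, 0.5)")
  }
  structure(list(E = E, nu = nu), class = "material")
}

#' Default tissue properties
#'
#' Literature values for human dental and periodontal tissues as used in
#' dental finite-element work: enamel 84.1 GPa / 0.3, dentine 18.6 / 0.31,
#' pulp 0.002 / 0.45, periodontal ligament 0.0689 / 0.45, alveolar bone
#' 11.5 / 0.3. Trabecular and cortical bone are collapsed into the single
#' BONE entry.
#'
#' @return named list of [material()] objects keyed by tissue region
#'   (ENAMEL, DENTINE, PULP, PDL, BONE).
#' @export
default_materials <- function() {
  list(
    ENAMEL  = material(84.1,   0.30),
    DENTINE = material(18.6,   0.31),
    PULP    = material(0.002,  0.45),
    PDL     = material(0.0689, 0.45),
    BONE    = material(11.5,   0.30)
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("material: E = %g GPa, nu = %g\n", x$E, x$nu))
  invisible(x)
}
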