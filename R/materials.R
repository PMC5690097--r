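#' Photon interaction coefficient table
#'
#' Returns the bundled elemental photon mass-coefficient table: total mass
#' attenuation coefficient (mu/rho), mass energy-absorption coefficient
#' (mu_en/rho), and the photoelectric / incoherent / coherent split, all in
#' cm^2/g on an energy grid covering 1-150 keV.  Absorption edges are
#' represented by grid-point pairs just below/above the edge energy, so
#' log-log interpolation never crosses an edge.
#'
#' @return A data.frame with columns `element`, `Z`, `A`, `energy_kev`,
#'   `mu_rho`, `muen_rho`, `photo`, `incoh`, `coh`.
#' @export
coefficient_table <- function() {
  if (is.null(.froi$coeff)) {
    path <- system.file("extdata", "photon_mass_coefficients.csv",
                        package = "froidose", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .froi$coeff <- tab
    .froi$coeff_split <- split(tab, tab$element)
  }
  .froi$coeff
}

.element_table <- function(element) {
  coefficient_table()
  et <- .froi$coeff_split[[element]]
  if (is.null(et)) stop("unknown element: ", element)
  et
}

#' Elemental mass coefficient at given energies
#'
#' Log-log interpolation of the bundled table for a single element.
#'
#' @param element element symbol, e.g. `"C"`.
#' @param energy_kev photon energies in keV (vector), within 1-150 keV.
#' @param kind one of `"attenuation"`, `"energy_absorption"`, `"photo"`,
#'   `"incoh"`, `"coh"`.
#' @return numeric vector of coefficients, cm^2/g.
#' @export
element_mu <- function(element, energy_kev,
                       kind = c("attenuation", "energy_absorption",
                                "photo", "incoh", "coh")) {
  kind <- match.arg(kind)
  et <- .element_table(element)
  col <- switch(kind, attenuation = "mu_rho",
                energy_absorption = "muen_rho", kind)
  if (any(energy_kev < min(et$energy_kev) - 1e-9) ||
      any(energy_kev > max(et$energy_kev) + 1e-9))
    stop("energy out of table range for ", element, " (",
         min(et$energy_kev), "-", max(et$energy_kev), " keV)")
  e <- pmin(pmax(energy_kev, min(et$energy_kev)), max(et$energy_kev))
  exp(stats::approx(log(et$energy_kev), log(et[[col]]), xout = log(e),
                    ties = "ordered")$y)
}

#' Define a material
#'
#' A material is a named elemental composition by mass fraction plus a bulk
#' density.  Mass fractions must be strictly positive and sum to one within
#' 1e-6 (set `normalize = TRUE` to renormalize, used by the built-ins for
#' stoichiometric compounds).
#'
#' @param name material name.
#' @param composition named numeric vector of elemental mass fractions,
#'   names are element symbols present in [coefficient_table()].
#' @param density bulk density in g/cm^3, > 0.
#' @param normalize renormalize mass fractions to sum exactly to 1.
#' @return an object of class `froi_material`.
#' @export
material <- function(name, composition, density, normalize = FALSE) {
  if (!is.numeric(composition) || is.null(names(composition)))
    stop("composition must be a named numeric vector")
  if (any(composition <= 0)) stop("mass fractions must be strictly positive")
  if (normalize) composition <- composition / sum(composition)
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 within 1e-6 (got ",
         format(sum(composition), digits = 10), ")")
  if (!is.numeric(density) || length(density) != 1 || density <= 0)
    stop("density must be a single positive number")
  coefficient_table()
  unknown <- setdiff(names(composition), names(.froi$coeff_split))
  if (length(unknown)) stop("unknown element(s): ",
                            paste(unknown, collapse = ", "))
  structure(list(name = name, composition = composition, density = density),
            class = "froi_material")
}

#' @export
print.froi_material <- function(x, ...) {
  cat("<froi_material>", x$name, " rho =", x$density, "g/cm3\n")
  print(round(x$composition, 5))
  invisible(x)
}

# Built-in material registry.  Tissue compositions are ICRU-44-style mass
# fractions; Gd2O2S fractions are stoichiometric; densities are standard
# handbook values (Gd2O2S: 7.32 g/cm3).
.builtin_materials <- function() {
  list(
    water = list(c(H = 0.111894, O = 0.888106), 0.998),
    air = list(c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827),
               0.0012047),
    soft_tissue = list(c(H = 0.102, C = 0.143, N = 0.034, O = 0.708,
                         Na = 0.002, P = 0.003, S = 0.003, Cl = 0.002,
                         K = 0.003), 1.05),
    brain = list(c(H = 0.107, C = 0.145, N = 0.022, O = 0.712, Na = 0.002,
                   P = 0.004, S = 0.002, Cl = 0.003, K = 0.003), 1.04),
    bone_cortical = list(c(H = 0.034, C = 0.155, N = 0.042, O = 0.435,
                           Na = 0.001, Mg = 0.002, P = 0.103, S = 0.003,
                           Ca = 0.225), 1.92),
    skin = list(c(H = 0.100, C = 0.204, N = 0.042, O = 0.645, Na = 0.002,
                  P = 0.001, S = 0.002, Cl = 0.003, K = 0.001), 1.09),
    eye_lens = list(c(H = 0.096, C = 0.195, N = 0.057, O = 0.646,
                      Na = 0.001, P = 0.001, S = 0.003, Cl = 0.001), 1.07),
    salivary = list(c(H = 0.102, C = 0.143, N = 0.034, O = 0.708,
                      Na = 0.002, P = 0.003, S = 0.003, Cl = 0.002,
                      K = 0.003), 1.03),
    spinal_cord = list(c(H = 0.107, C = 0.145, N = 0.022, O = 0.712,
                         Na = 0.002, P = 0.004, S = 0.002, Cl = 0.003,
                         K = 0.003), 1.04),
    carbon = list(c(C = 1), 2.267),
    aluminium = list(c(Al = 1), 2.699),
    copper = list(c(Cu = 1), 8.96),
    tungsten = list(c(W = 1), 19.30),
    gadolinium_oxysulfide = list(c(Gd = 314.5, O = 31.998, S = 32.06), 7.32)
  )
}

#' Built-in materials
#'
#' @param name one of `names(froi_materials())`, e.g. `"water"`, `"air"`,
#'   `"carbon"`, `"gadolinium_oxysulfide"`, or the ICRU-44-style tissues
#'   used by the synthetic head phantom.
#' @param density override the default density (g/cm^3), e.g. the fitted
#'   effective density of the patient table.
#' @return a [material()] object.
#' @export
froi_material <- function(name, density = NULL) {
  reg <- .builtin_materials()
  if (!name %in% names(reg)) stop("unknown built-in material: ", name)
  m <- reg[[name]]
  material(name, m[[1]], if (is.null(density)) m[[2]] else density,
           normalize = TRUE)
}

#' @rdname froi_material
#' @export
froi_materials <- function() names(.builtin_materials())

#' Mass coefficient of a material mixture
#'
#' Mass-fraction-weighted sum of elemental coefficients (mixture rule),
#' log-log interpolated in energy.
#'
#' @param mat a [material()].
#' @param energy_kev photon energies, keV.
#' @param kind `"attenuation"` (mu/rho) or `"energy_absorption"`
#'   (mu_en/rho); the interaction-split kinds of [element_mu()] are also
#'   accepted.
#' @return numeric vector, cm^2/g.
#' @export
mixture_mu <- function(mat, energy_kev, kind = "attenuation") {
  stopifnot(inherits(mat, "froi_material"))
  out <- numeric(length(energy_kev))
  for (el in names(mat$composition))
    out <- out + mat$composition[[el]] * element_mu(el, energy_kev, kind)
  out
}
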