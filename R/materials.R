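#' Physical constants used by the transport model
#'
#' CODATA-style values, fixed at package build time: electron and proton
#' rest energies (MeV), the Bethe-Bloch prefactor K = 4 pi N_A r_e^2 m_e c^2
#' (MeV mol^-1 cm^2), the Coulomb constant e^2 = alpha hbar c (MeV fm),
#' the atomic mass unit (MeV) and the Bohr straggling constant
#' (MeV^2 cm^2 g^-1).
#'
#' @return Named list of constants.
#' @export
physics_constants <- function() {
  list(
    me_mev   = 0.51099895,
    mp_mev   = 938.2720882,
    K_bb     = 0.307075,
    e2_mevfm = 1.43996,
    amu_mev  = 931.4941024,
    bohr_straggling = 0.1569
  )
}

#' Material registry
#'
#' Effective single-element description of each material the phantoms and
#' detectors use: mass density (g/cm^3), effective atomic number Z,
#' effective mass number A (g/mol, chosen so Z/A matches the compound) and
#' mean excitation energy I (eV). Densities of water, hydroxyapatite and
#' glass follow the phantom definitions (1.0, 3.076 and 1.8 g/cm^3).
#'
#' @return data.frame with columns name, density, Z, A, I.
#' @export
material_registry <- function() {
  data.frame(
    name    = c("water", "air", "hydroxyapatite", "glass", "lead",
                "scintillator"),
    density = c(1.0, 0.0012041, 3.076, 1.8, 11.35, 1.032),
    Z       = c(7.42, 7.37, 15.60, 10.80, 82.0, 5.61),
    A       = c(13.37, 14.78, 31.35, 21.63, 207.2, 10.36),
    I       = c(75.0, 85.7, 130.0, 139.2, 823.0, 64.7),
    stringsAsFactors = FALSE
  )
}

#' Look up one material from the registry
#'
#' @param name Material name, or a one-row data.frame from a registry
#'   (passed through after validation).
#' @param registry Registry data.frame; defaults to [material_registry()].
#' @return One-row data.frame (name, density, Z, A, I).
#' @export
get_material <- function(name, registry = material_registry()) {
  if (is.data.frame(name)) {
    m <- name
    if (nrow(m) != 1L ||
        !all(c("name", "density", "Z", "A", "I") %in% names(m)))
      stop("material must be a single registry row", call. = FALSE)
  } else {
    if (!is.character(name) || length(name) != 1L)
      stop("material name must be a single string", call. = FALSE)
    i <- match(name, registry$name)
    if (is.na(i))
      stop(sprintf("unknown material '%s'", name), call. = FALSE)
    m <- registry[i, , drop = FALSE]
  }
  stopifnot(m$density > 0, m$Z >= 1, m$A >= m$Z, m$I > 0)
  m
}

#' Write / read the material registry as a plain-text config
#'
#' Tab-separated table with a header row; round-trips exactly through
#' [read_material_registry()].
#'
#' @param registry Registry data.frame.
#' @param path File path.
#' @return `path`, invisibly (writer); the registry (reader).
#' @export
write_material_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_material_registry
#' @export
read_material_registry <- function(path) {
  reg <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "density", "Z", "A", "I") %in% names(reg)))
  reg
}
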