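#' Discrete spectral model
#'
#' Bundles the discretized physics of a multispectral acquisition: an energy
#' grid of `E` nodes (keV), per-material mass-attenuation curves sampled on
#' that grid (`E x M` matrix, one column per material), and the effective
#' spectrum of each energy bin (`B x E` matrix, one row per bin; the product
#' of incident spectral density and detector bin sensitivity, with any
#' quadrature weights absorbed).
#'
#' @param energies Numeric vector of `E` energy nodes in keV, strictly
#'   increasing and positive.
#' @param attenuations `E x M` matrix of nonnegative attenuation values.
#' @param spectra `B x E` matrix of nonnegative effective spectra; every row
#'   must have a positive sum.
#' @param materials Optional character vector of `M` material names.
#' @return An object of class `spectral_model`.
#' @export
spectral_model <- function(energies, attenuations, spectra, materials = NULL) {
  energies <- as.numeric(energies)
  attenuations <- as.matrix(attenuations)
  spectra <- as.matrix(spectra)
  E <- length(energies)
  if (E < 1L) stop("need at least one energy node", call. = FALSE)
  if (any(!is.finite(energies)) || any(energies <= 0) ||
      is.unsorted(energies, strictly = TRUE)) {
    stop("energies must be positive, finite and strictly increasing",
         call. = FALSE)
  }
  if (nrow(attenuations) != E) {
    stop("attenuations must have one row per energy node", call. = FALSE)
  }
  if (ncol(spectra) != E) {
    stop("spectra must have one column per energy node", call. = FALSE)
  }
  if (any(!is.finite(attenuations)) || any(attenuations < 0)) {
    stop("attenuations must be finite and nonnegative", call. = FALSE)
  }
  if (any(!is.finite(spectra)) || any(spectra < 0)) {
    stop("spectra must be finite and nonnegative", call. = FALSE)
  }
  if (any(rowSums(spectra) <= 0)) {
    stop("every spectrum row must have a positive sum", call. = FALSE)
  }
  M <- ncol(attenuations)
  if (is.null(materials)) materials <- paste0("material_", seq_len(M))
  if (length(materials) != M) {
    stop("materials must name each attenuation column", call. = FALSE)
  }
  attenuations <- unname(attenuations)
  colnames(attenuations) <- materials
  structure(
    list(
      energies = energies,
      attenuations = attenuations,
      spectra = unname(spectra),
      materials = as.character(materials)
    ),
    class = "spectral_model"
  )
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf(
    "<spectral_model> M=%d materials (%s), B=%d bins, E=%d energies in [%g, %g] keV%s\n",
    n_materials(x), paste(x$materials, collapse = ", "),
    n_bins(x), length(x$energies),
    min(x$energies), max(x$energies),
    if (is_normalized(x)) " [normalized]" else ""
  ))
  invisible(x)
}

n_materials <- function(model) ncol(model$attenuations)

n_bins <- function(model) nrow(model$spectra)

is_normalized <- function(model) {
  all(abs(rowSums(model$spectra) - 1) < 1e-12)
}

#' Normalize effective spectra to unit sum
#'
#' Rescales each bin's effective spectrum to sum to one. Under the
#' recalibrated (logarithmic) model this is equivalent to dividing raw
#' measurements by the blank scan `F(0)`, so the normalized model satisfies
#' `F(0) = 1` identically. Idempotent; attenuations are untouched.
#'
#' @param model A [spectral_model()].
#' @return The model with row-normalized `spectra`.
#' @export
normalize_spectra <- function(model) {
  stopifnot(inherits(model, "spectral_model"))
  rs <- rowSums(model$spectra)
  if (any(rs <= 0)) stop("zero spectrum row sum", call. = FALSE)
  model$spectra <- model$spectra / rs
  model
}

#' Read attenuation curves or spectra from CSV
#'
#' Both tables share the layout: first column `energy_keV`, then one column
#' per material (attenuations) or per bin (spectra, stored transposed as
#' energy rows for readability).
#'
#' @param attenuation_csv Path to the attenuation table.
#' @param spectra_csv Path to the spectra table.
#' @return A [spectral_model()].
#' @export
read_spectral_model_csv <- function(attenuation_csv, spectra_csv) {
  att <- utils::read.csv(attenuation_csv, check.names = FALSE)
  spc <- utils::read.csv(spectra_csv, check.names = FALSE)
  if (names(att)[1] != "energy_keV" || names(spc)[1] != "energy_keV") {
    stop("first CSV column must be energy_keV", call. = FALSE)
  }
  if (!isTRUE(all.equal(att$energy_keV, spc$energy_keV))) {
    stop("attenuation and spectra tables use different energy grids",
         call. = FALSE)
  }
  spectral_model(
    energies = att$energy_keV,
    attenuations = as.matrix(att[, -1, drop = FALSE]),
    spectra = t(as.matrix(spc[, -1, drop = FALSE])),
    materials = names(att)[-1]
  )
}

#' Write a spectral model to CSV tables
#'
#' @param model A [spectral_model()].
#' @param attenuation_csv,spectra_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_spectral_model_csv <- function(model, attenuation_csv, spectra_csv) {
  att <- data.frame(energy_keV = model$energies,
                    model$attenuations, check.names = FALSE)
  spc <- data.frame(energy_keV = model$energies,
                    t(model$spectra), check.names = FALSE)
  names(spc)[-1] <- paste0("bin_", seq_len(n_bins(model)))
  write_full_precision_csv(att, attenuation_csv)
  write_full_precision_csv(spc, spectra_csv)
  invisible(c(attenuation_csv, spectra_csv))
}
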