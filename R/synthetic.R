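#' Phantom specification
#'
#' Describes a piecewise-constant multichannel phantom on the unit field of
#' view: coordinates of primitives are in `[-0.5, 0.5]^2` regardless of the
#' grid size. Each primitive is a disk or ellipse assigning one material a
#' density; where primitives overlap, the last one listed wins (it
#' overwrites all channels at the covered pixels).
#'
#' @param n Grid side length (image is `n x n`).
#' @param primitives List of lists with fields `center` (length-2),
#'   `radii` (scalar for a disk or length-2 for an ellipse), `rotation`
#'   (radians, default 0), `material` (1-based index), `density`
#'   (nonnegative).
#' @param background_material,background_density Fill for uncovered pixels
#'   (defaults: material 1, density 0).
#' @param n_materials Number of material channels (default: largest
#'   material index referenced).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n, primitives = list(),
                         background_material = 1L,
                         background_density = 0,
                         n_materials = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  for (p in primitives) {
    stopifnot(length(p$center) == 2L, all(abs(p$center) <= 0.5),
              all(p$radii > 0), length(p$radii) %in% 1:2,
              p$material >= 1L, p$density >= 0)
    if (max(abs(p$center)) + max(p$radii) > 0.5 + 1e-9) {
      stop("primitive does not fit in the unit field of view", call. = FALSE)
    }
  }
  if (is.null(n_materials)) {
    n_materials <- max(c(background_material,
                         vapply(primitives, function(p) p$material, 1)))
  }
  stopifnot(background_density >= 0)
  structure(
    list(n = n, primitives = primitives,
         background_material = as.integer(background_material),
         background_density = background_density,
         n_materials = as.integer(n_materials)),
    class = "phantom_spec"
  )
}

#' Rasterize a phantom into a material image
#'
#' Pixel centres on the unit field of view are tested against each
#' primitive in order; the image is deterministic given the spec (`seed` is
#' accepted for interface symmetry but unused by the deterministic
#' rasterizer).
#'
#' @param spec A [phantom_spec()].
#' @param seed Unused; kept so all generators share a signature.
#' @return `Nx x M` material image matrix (pixel index x fastest, matching
#'   the projector's vectorization).
#' @export
make_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  h <- 1 / n
  centres <- (seq_len(n) - 0.5) * h - 0.5
  px <- rep(centres, times = n)
  py <- rep(centres, each = n)
  M <- spec$n_materials
  X <- matrix(0, n * n, M)
  X[, spec$background_material] <- spec$background_density
  for (p in spec$primitives) {
    radii <- if (length(p$radii) == 1L) rep(p$radii, 2L) else p$radii
    rot <- if (is.null(p$rotation)) 0 else p$rotation
    dx <- px - p$center[1]
    dy <- py - p$center[2]
    u <- cos(rot) * dx + sin(rot) * dy
    v <- -sin(rot) * dx + cos(rot) * dy
    inside <- (u / radii[1])^2 + (v / radii[2])^2 <= 1
    X[inside, ] <- 0
    X[inside, p$material] <- p$density
  }
  X
}

#' Default three-material phantom
#'
#' A water disk containing three inserts — an iodine-like disk (left), a
#' gadolinium-like disk (middle), and a denser water disk (right) — scaled
#' to the unit field of view. Emulates a contrast-agent phantom with
#' spatially disjoint high-attenuation inserts.
#'
#' @param n Grid side length.
#' @return A [phantom_spec()] with `M = 3` channels
#'   (water, iodine, gadolinium).
#' @export
default_phantom_spec <- function(n) {
  phantom_spec(
    n,
    primitives = list(
      list(center = c(0, 0), radii = 0.42, material = 1L, density = 1),
      list(center = c(-0.22, 0), radii = 0.11, material = 2L, density = 0.6),
      list(center = c(0, 0.1), radii = 0.11, material = 3L, density = 0.6),
      list(center = c(0.22, -0.05), radii = 0.11, material = 1L, density = 1.8)
    ),
    n_materials = 3L
  )
}

# Continuous parametric spectral family emulating a filtered clinical
# photon-counting acquisition: attenuation curves are a photoelectric-like
# decaying power law plus a Compton-like floor, with a K-edge step for the
# contrast materials; the source envelope is a Kramers tube spectrum behind
# aluminium-like filtration; bins are near-contiguous with smoothly rolled
# (sigmoid) thresholds. Magnitudes are scaled so a unit-density object of
# unit diameter has optical depth of order one in the softest bin — the
# working regime of clinical spectral CT. Evaluable on any energy grid,
# which is what makes the inverse-crime finer data grid possible.
spectral_family <- function(M, B, e_max, seed) {
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  edge_energies <- c(33.2, 50.2)  # iodine / gadolinium K-edges, keV
  materials <- character(M)
  mats <- vector("list", M)
  for (m in seq_len(M)) {
    if (m == 1L) {
      # water-like base material: no K-edge
      mats[[m]] <- list(a = 1.2 * stats::runif(1, 0.9, 1.1),
                        c = 0.30 * stats::runif(1, 0.9, 1.1),
                        e_ref = 40, edge = NA_real_, jump = 0)
      materials[m] <- "water"
    } else {
      edge <- if (m - 1L <= length(edge_energies)) {
        edge_energies[m - 1L]
      } else {
        stats::runif(1, 0.25, 0.5) * e_max
      }
      mats[[m]] <- list(a = 1.5 * stats::runif(1, 0.8, 1.2),
                        c = 0.2 * stats::runif(1, 0.9, 1.1),
                        e_ref = 40, edge = edge,
                        jump = 4.0 * stats::runif(1, 0.8, 1.2))
      materials[m] <- c("iodine", "gadolinium",
                        paste0("material_", seq_len(max(0, M - 3L)) + 3L))[m - 1L]
    }
  }
  lo <- max(25, 0.15 * e_max)  # lowest counting threshold, keV
  thresholds <- seq(lo, 0.95 * e_max, length.out = B + 1L)
  bins <- lapply(seq_len(B), function(b) {
    list(lo = thresholds[b] * stats::runif(1, 0.99, 1.01),
         hi = thresholds[b + 1L] * stats::runif(1, 0.99, 1.01),
         roll = 4)  # threshold roll-off width, keV (charge sharing)
  })
  list(materials = materials, mats = mats, bins = bins, e_max = e_max,
       filter_cut = 28)  # ~2-3 mm Al equivalent filtration
}

# Evaluate the continuous family on an E-cell grid. Each node represents
# one energy cell: the attenuation value is the spectrum-weighted cell mean
# and the spectrum value the cell integral, both computed by sub-sampling
# the continuous curves. Cell averaging keeps grids of different resolution
# consistent approximations of the same continuous physics (point sampling
# across K-edges and bin thresholds would make coarse and fine grids
# disagree at first order in the cell width).
eval_spectral_family <- function(family, E, n_sub = 16L) {
  e_max <- family$e_max
  de <- e_max / E
  edges <- (0:E) * de
  nodes <- (seq_len(E) - 0.5) * de
  # sub-sampled continuous curves
  es <- as.vector(vapply(seq_len(E), function(i) {
    edges[i] + (seq_len(n_sub) - 0.5) * de / n_sub
  }, numeric(n_sub)))
  cell <- rep(seq_len(E), each = n_sub)
  mu_cont <- vapply(family$mats, function(p) {
    ec <- pmax(es, 15)  # floor below 15 keV so low-energy tails stay bounded
    mu <- p$a * (ec / p$e_ref)^(-3) + p$c
    if (is.finite(p$edge)) {
      mu <- mu + p$jump * (ec / p$edge)^(-3) * (es >= p$edge)
    }
    mu
  }, numeric(length(es)))
  # Kramers tube spectrum behind power-law (aluminium-like) filtration
  envelope <- pmax((e_max - es) / es, 0) *
    exp(-(family$filter_cut / pmax(es, 5))^3)
  weight <- envelope + 1e-12  # weighting for the attenuation cell means
  wsum <- tapply(weight, cell, sum)
  att <- apply(mu_cont, 2L, function(mu) {
    as.numeric(tapply(mu * weight, cell, sum)) / as.numeric(wsum)
  })
  spectra <- t(vapply(family$bins, function(b) {
    resp <- stats::plogis((es - b$lo) / b$roll) *
      stats::plogis((b$hi - es) / b$roll)
    as.numeric(tapply(pmax(envelope * resp, 0), cell, sum)) * de / n_sub
  }, numeric(E)))
  spectral_model(nodes, att, spectra, materials = family$materials)
}

#' Generate a parametric spectral model
#'
#' Builds smooth, strictly positive attenuation curves (decaying power law
#' with a constant floor; K-edge steps at the iodine and gadolinium edges
#' for the contrast materials) and bell-shaped effective bin spectra under
#' a tube-like envelope, sampled on `E` uniform midpoint nodes in
#' `(0, e_max]` keV. The defaults `M = 3, B = 5, E = 150, e_max = 150`
#' match a three-material, five-bin photon-counting acquisition. The
#' resulting channel matrix must be well conditioned (`cond(U) < 1e6`);
#' otherwise the curves are re-drawn with a perturbed seed, up to 10 times.
#'
#' @param M Number of materials (`>= 1`).
#' @param B Number of energy bins (`>= M`).
#' @param E Number of energy nodes.
#' @param e_max Upper end of the energy range in keV.
#' @param seed Integer seed for the curve parameters.
#' @return A [spectral_model()]; the continuous generating family is
#'   attached as attribute `"family"` so the same physics can be resampled
#'   on a finer grid.
#' @export
make_spectral_model <- function(M = 3L, B = 5L, E = 150L, e_max = 150,
                                seed = 1L) {
  stopifnot(M >= 1L, B >= M, E >= 1L, e_max > 0)
  for (attempt in 0:9) {
    family <- spectral_family(M, B, e_max, seed + 1000L * attempt)
    model <- eval_spectral_family(family, E)
    cond <- tryCatch(build_channel_matrix(model)$condition,
                     error = function(e) Inf)
    if (cond < 1e6) {
      attr(model, "family") <- family
      return(model)
    }
  }
  stop("could not generate a well-conditioned spectral model in 10 attempts",
       call. = FALSE)
}

#' Acquisition specification
#'
#' @param I0 Expected photon count per ray and bin for a blank scan
#'   (photon budget); must be positive.
#' @param E_data Number of energy nodes used to *generate* data; must be at
#'   least the reconstruction grid size `E`. Using a finer grid (the
#'   default pipeline uses `2 E`) avoids the inverse crime.
#' @param noise Draw Poisson counts (`TRUE`) or return noiseless expected
#'   data (`FALSE`).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(I0 = 1e6, E_data, noise = TRUE) {
  stopifnot(is.finite(I0), I0 > 0, E_data >= 1)
  structure(list(I0 = I0, E_data = as.integer(E_data), noise = isTRUE(noise)),
            class = "acquisition_spec")
}

#' Simulate multispectral measurements
#'
#' Evaluates the forward model for the ground-truth image on the (usually
#' finer) `E_data` energy grid of the model's generating family, scales
#' each bin to expected photon counts `I0 * F(X) / <S_b, 1>`, draws Poisson
#' counts, and rescales back to the measurement units of the reconstruction
#' model. Reproducible given `seed`.
#'
#' @param X_true Ground-truth `Nx x M` image.
#' @param model A [make_spectral_model()] result (needs the `"family"`
#'   attribute unless `E_data` equals the model's own grid).
#' @param projector A [build_projector()] result.
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed for the Poisson draw.
#' @return `Ny x B` matrix of (noisy) spectral measurements `Y`.
#' @export
simulate_data <- function(X_true, model, projector, acq, seed = 1L) {
  stopifnot(inherits(acq, "acquisition_spec"))
  E <- length(model$energies)
  if (acq$E_data < E) {
    stop("E_data must be at least the reconstruction energy grid size",
         call. = FALSE)
  }
  data_model <- if (acq$E_data == E) {
    model
  } else {
    family <- attr(model, "family")
    if (is.null(family)) {
      stop("model carries no generating family; cannot resample a finer grid",
           call. = FALSE)
    }
    eval_spectral_family(family, acq$E_data)
  }
  F_fine <- forward_F(data_model, projector, X_true)
  if (!acq$noise) return(F_fine)
  bin_sums <- rowSums(data_model$spectra)
  lambda <- acq$I0 * sweep(F_fine, 2L, bin_sums, "/")
  if (any(lambda > .Machine$integer.max)) {
    stop("expected counts overflow; lower I0", call. = FALSE)
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda))
  sweep(counts / acq$I0, 2L, bin_sums, "*")
}
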