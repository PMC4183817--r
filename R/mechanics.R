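# Mechanical element models: wormlike chain (WLC), rigid folded domains, and
# the helix-coil constant-force element that represents a SAH domain in
# series with the rest of the construct.

#' Thermal parameters
#'
#' Bundles absolute temperature with the thermal energy scale `kBT` in
#' pN nm, the unit system used throughout the package.
#'
#' @param temperature_K Absolute temperature in kelvin. Default 298 K
#'   (room temperature); kBT = 4.114 pN nm.
#' @return An object of class `thermo` with fields `temperature_K` and
#'   `kBT` (pN nm).
#' @examples
#' thermo()          # 298 K
#' thermo(300)$kBT
#' @export
thermo <- function(temperature_K = 298) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1 ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    stop("temperature_K must be a single positive number")
  }
  # Boltzmann constant, pN nm / K
  kB <- 1.380649e-2 / 1000 * 1000  # 1.380649e-23 J/K = 1.380649e-2 pN nm / K
  structure(
    list(temperature_K = temperature_K, kBT = kB * temperature_K),
    class = "thermo"
  )
}

#' Wormlike-chain parameters
#'
#' @param persistence_length Persistence length p in nm (> 0).
#' @param contour_length Contour length l_c in nm (> 0).
#' @return An object of class `wlc_params`.
#' @export
wlc_params <- function(persistence_length, contour_length) {
  if (!is.numeric(persistence_length) || length(persistence_length) != 1 ||
      !is.finite(persistence_length) || persistence_length <= 0) {
    stop("persistence_length must be a single positive number")
  }
  if (!is.numeric(contour_length) || length(contour_length) != 1 ||
      !is.finite(contour_length) || contour_length <= 0) {
    stop("contour_length must be a single positive number")
  }
  structure(
    list(persistence_length = persistence_length,
         contour_length = contour_length),
    class = "wlc_params"
  )
}

#' Wormlike-chain force at a given extension
#'
#' Interpolation form of the WLC force-extension relation,
#' F = (kBT/p) * (1/(4 (1 - x/lc)^2) - 1/4 + x/lc),
#' exact in both the low-force entropic limit and the high-force
#' divergence as x approaches the contour length.
#'
#' @param x Extension in nm; vectorised. Must satisfy 0 <= x < contour length.
#' @param params A [wlc_params()] object.
#' @param thermo A [thermo()] object.
#' @return Force in pN (same length as `x`).
#' @examples
#' wlc_force(14, wlc_params(0.4, 28))   # ~12.86 pN
#' @export
wlc_force <- function(x, params, thermo = default_thermo()) {
  stopifnot(inherits(params, "wlc_params"), inherits(thermo, "thermo"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("extension x must be finite and >= 0")
  }
  if (any(x >= params$contour_length)) {
    stop("extension x must be strictly less than the contour length")
  }
  s <- x / params$contour_length
  (thermo$kBT / params$persistence_length) *
    (1 / (4 * (1 - s)^2) - 0.25 + s)
}

# Dimensionless inverse of the WLC interpolation formula: given
# fhat = F p / kBT, return s = x / lc in [0, 1).  Safeguarded Newton
# iteration; h(s) = 1/(4(1-s)^2) - 1/4 + s is increasing and convex so
# Newton converges monotonically after the first step.  Vectorised.
wlc_inv_scaled <- function(fhat, tol = 1e-12, maxit = 60) {
  s <- ifelse(fhat < 1, 2 * fhat / 3, 1 - 0.5 / sqrt(fhat))
  s <- pmin(pmax(s, 0), 1 - 1e-12)
  for (i in seq_len(maxit)) {
    one_m <- 1 - s
    h <- 1 / (4 * one_m^2) - 0.25 + s - fhat
    hp <- 1 / (2 * one_m^3) + 1
    step <- h / hp
    s_new <- pmin(pmax(s - step, 0), 1 - 1e-12)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s
}

#' Wormlike-chain extension at a given force (numerical inverse)
#'
#' Inverts [wlc_force()]; the round trip is accurate to better than 1e-6
#' relative tolerance over the working force range.
#'
#' @param F Force in pN (>= 0); vectorised.
#' @inheritParams wlc_force
#' @return Extension in nm, in `[0, contour_length)`.
#' @export
wlc_extension <- function(F, params, thermo = default_thermo()) {
  stopifnot(inherits(params, "wlc_params"), inherits(thermo, "thermo"))
  if (any(!is.finite(F)) || any(F < 0)) {
    stop("force F must be finite and >= 0")
  }
  fhat <- F * params$persistence_length / thermo$kBT
  params$contour_length * wlc_inv_scaled(fhat)
}

#' Helix-coil element parameters
#'
#' Two-state (helix/coil) description of a single alpha-helix domain
#' under force.  Residues convert between helix and coil in cooperative
#' blocks (default four residues, about one helical turn); each block is
#' an independent two-state unit whose coil state is a short wormlike
#' chain.  The model produces an extension plateau at nearly constant
#' force, the signature mechanical behaviour of a SAH domain, without a
#' discrete unfolding peak.
#'
#' @param n_residues Number of residues in the helix (>= 1).
#' @param rise_per_residue_helix Helical rise, nm per residue (default
#'   0.15, canonical alpha-helix).
#' @param contour_per_residue_coil Contour length of an unfolded residue,
#'   nm (default 0.38).
#' @param coil_persistence_length Persistence length of the coil state,
#'   nm (default 0.4).
#' @param delta_g_per_residue Helix-minus-coil free energy per residue in
#'   units of kBT; negative favours helix at zero force.  The default
#'   -0.4 kBT/residue places the half-unfolding (plateau) force near
#'   20 pN, inside the < 30 pN band observed for SAH domains.
#' @param cooperativity_block Residues that convert together (default 4).
#'   `n_residues` is split into `floor(n/block)` full blocks plus one
#'   remainder block of `n %% block` residues when the division is not
#'   exact.
#' @return An object of class `helix_coil_params`.
#' @export
helix_coil_params <- function(n_residues,
                              rise_per_residue_helix = 0.15,
                              contour_per_residue_coil = 0.38,
                              coil_persistence_length = 0.4,
                              delta_g_per_residue = -0.4,
                              cooperativity_block = 4) {
  if (!is.numeric(n_residues) || length(n_residues) != 1 || n_residues < 1) {
    stop("n_residues must be >= 1")
  }
  if (rise_per_residue_helix >= contour_per_residue_coil) {
    stop("rise_per_residue_helix must be smaller than contour_per_residue_coil")
  }
  if (coil_persistence_length <= 0) stop("coil_persistence_length must be > 0")
  if (cooperativity_block < 1) stop("cooperativity_block must be >= 1")
  structure(
    list(n_residues = as.integer(n_residues),
         rise_per_residue_helix = rise_per_residue_helix,
         contour_per_residue_coil = contour_per_residue_coil,
         coil_persistence_length = coil_persistence_length,
         delta_g_per_residue = delta_g_per_residue,
         cooperativity_block = as.integer(cooperativity_block)),
    class = "helix_coil_params"
  )
}

# Residue counts of the independent blocks (full blocks + remainder).
hc_blocks <- function(params) {
  b <- params$cooperativity_block
  n <- params$n_residues
  nb <- n %/% b
  rem <- n %% b
  c(rep.int(b, nb), if (rem > 0) rem)
}

#' Helix-coil element extension and helix fraction at a given force
#'
#' For each block of `m` residues the coil state gains stretching energy
#' F * dx(F) relative to the helix state, where dx(F) is the extension
#' difference between the coil wormlike chain (contour m * 0.38 nm) at
#' force F and the rigid helical rise m * 0.15 nm.  The block helix
#' probability is the two-state Boltzmann factor
#' 1 / (1 + exp((F * dx(F) - dG_unfold) / kBT)) with
#' dG_unfold = -m * delta_g_per_residue * kBT.  The element extension is
#' the probability-weighted sum of helix and coil block extensions.
#'
#' @param F Force in pN (>= 0); vectorised.
#' @param params A [helix_coil_params()] object.
#' @param thermo A [thermo()] object.
#' @return A list with `extension` (nm) and `helix_fraction` (residue-
#'   weighted, in `[0, 1]`), each the same length as `F`.
#' @export
helix_coil_extension <- function(F, params, thermo = default_thermo()) {
  stopifnot(inherits(params, "helix_coil_params"), inherits(thermo, "thermo"))
  if (any(!is.finite(F)) || any(F < 0)) {
    stop("force F must be finite and >= 0")
  }
  kBT <- thermo$kBT
  blocks <- hc_blocks(params)
  fhat <- F * params$coil_persistence_length / kBT
  s <- wlc_inv_scaled(fhat)          # shared by all blocks (same p)
  ext <- numeric(length(F))
  n_helix <- numeric(length(F))
  for (m in unique(blocks)) {
    k <- sum(blocks == m)
    x_coil <- m * params$contour_per_residue_coil * s
    x_helix <- m * params$rise_per_residue_helix
    dx <- x_coil - x_helix
    dg_unfold <- -m * params$delta_g_per_residue * kBT  # pN nm, > 0 if helix favoured
    w_coil <- exp((F * dx - dg_unfold) / kBT)
    f_helix <- 1 / (1 + w_coil)
    ext <- ext + k * (f_helix * x_helix + (1 - f_helix) * x_coil)
    n_helix <- n_helix + k * m * f_helix
  }
  list(extension = ext, helix_fraction = n_helix / params$n_residues)
}

#' Plateau force of the helix-coil element
#'
#' The force at which a full cooperativity block is half helix, half
#' coil, i.e. where the stretching energy gain F * dx(F) of a block
#' equals its unfolding free energy.  This is the (approximately
#' constant) force at which the element lengthens.
#'
#' @inheritParams helix_coil_extension
#' @param f_max Upper bracket for the root search in pN (default 200).
#' @return Plateau force in pN.
#' @export
plateau_force <- function(params, thermo = default_thermo(), f_max = 200) {
  stopifnot(inherits(params, "helix_coil_params"))
  if (params$delta_g_per_residue == 0) return(0)
  if (params$delta_g_per_residue > 0) {
    stop("plateau_force requires delta_g_per_residue < 0 (helix favoured)")
  }
  kBT <- thermo$kBT
  m <- params$cooperativity_block
  dg_unfold <- -m * params$delta_g_per_residue * kBT
  g <- function(F) {
    s <- wlc_inv_scaled(F * params$coil_persistence_length / kBT)
    dx <- m * params$contour_per_residue_coil * s -
      m * params$rise_per_residue_helix
    F * dx - dg_unfold
  }
  if (g(f_max) < 0) {
    stop("no plateau force found in (0, ", f_max, "] pN for these parameters")
  }
  stats::uniroot(g, lower = 0, upper = f_max, tol = 1e-10)$root
}

# --- series mechanics -------------------------------------------------------

#' Mechanical elements for series constructions
#'
#' Constructors for the three element kinds used to assemble a construct:
#' a rigid (force-independent) length such as a folded I27 domain, a
#' wormlike chain such as an unfolded polypeptide, and a helix-coil
#' element.  Elements in series share the same force and their
#' extensions add.
#'
#' @param length Rigid length in nm.
#' @return An object of class `mech_element`.
#' @export
el_rigid <- function(length) {
  stopifnot(is.numeric(length), length >= 0)
  structure(list(kind = "rigid", length = length), class = "mech_element")
}

#' @rdname el_rigid
#' @param params For `el_wlc` a [wlc_params()] object; for
#'   `el_helix_coil` a [helix_coil_params()] object.
#' @export
el_wlc <- function(params) {
  stopifnot(inherits(params, "wlc_params"))
  structure(list(kind = "wlc", params = params), class = "mech_element")
}

#' @rdname el_rigid
#' @export
el_helix_coil <- function(params) {
  stopifnot(inherits(params, "helix_coil_params"))
  structure(list(kind = "helix_coil", params = params), class = "mech_element")
}

element_extension <- function(el, F, thermo) {
  switch(el$kind,
    rigid = rep.int(el$length, length(F)),
    wlc = wlc_extension(F, el$params, thermo),
    helix_coil = helix_coil_extension(F, el$params, thermo)$extension,
    stop("unknown element kind: ", el$kind)
  )
}

#' Total extension of mechanical elements in series
#'
#' All elements experience the same force; extensions add, so the result
#' is independent of element order.
#'
#' @param F Force in pN (>= 0); vectorised.
#' @param elements List of `mech_element` objects.
#' @param thermo A [thermo()] object.
#' @return Total extension in nm.
#' @export
series_extension <- function(F, elements, thermo = default_thermo()) {
  if (length(elements) == 0) {
    warning("empty element list; extension is 0")
    return(numeric(length(F)))
  }
  stopifnot(all(vapply(elements, inherits, logical(1), "mech_element")))
  ext <- numeric(length(F))
  for (el in elements) ext <- ext + element_extension(el, F, thermo)
  ext
}

# Default thermal state (room temperature).  Used as the default for every
# `thermo` argument; a plain `thermo()` default would be shadowed by the
# argument name itself.
default_thermo <- function() thermo(298)
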