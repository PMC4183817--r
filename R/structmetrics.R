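# Coordinate-based structure metrics: end-to-end distance (r_NC), distance-
# matrix RMSD (DRMSD), a helicity assignment proxy, running averages, and a
# backbone builder for ideal helices and extended/random chains.

#' Coordinate set container
#'
#' Minimal atom table for backbone metrics: one row per atom with the
#' atom name (`N`, `CA`, `C`, `O`), residue index and xyz position in
#' nm.
#'
#' @param atoms data.frame with columns `name`, `resno`, `x`, `y`, `z`
#'   (nm); residue indices non-decreasing.
#' @return An object of class `coordset`.
#' @export
coordset <- function(atoms) {
  need <- c("name", "resno", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns ", paste(need, collapse = ", "))
  }
  if (is.unsorted(atoms$resno)) stop("residue indices must be non-decreasing")
  structure(list(atoms = atoms), class = "coordset")
}

#' Read a PDB file into coordinate sets
#'
#' Thin wrapper around `bio3d::read.pdb` converting backbone atoms to
#' [coordset()] objects (coordinates converted from Angstrom to nm).
#' Multi-model files yield one coordinate set per model.
#'
#' @param path PDB file path.
#' @param backbone_only Keep only N, CA, C, O atoms (default TRUE).
#' @return A list of `coordset` objects (length 1 for single-model
#'   files).
#' @export
read_coordsets <- function(path, backbone_only = TRUE) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  a <- pdb$atom
  keep <- if (backbone_only) a$elety %in% c("N", "CA", "C", "O") else
    rep(TRUE, nrow(a))
  n_models <- dim(pdb$xyz)[1]
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    coordset(data.frame(
      name = a$elety[keep], resno = a$resno[keep],
      x = xyz[keep, 1] / 10, y = xyz[keep, 2] / 10, z = xyz[keep, 3] / 10,
      stringsAsFactors = FALSE))
  })
}

atom_xyz <- function(cs, name, resno) {
  a <- cs$atoms
  i <- which(a$name == name & a$resno == resno)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' End-to-end distance (r_NC)
#'
#' Euclidean distance between the N-terminal backbone nitrogen and the
#' C-terminal carbonyl carbon.
#'
#' @param cs A [coordset()].
#' @return Distance in nm.
#' @export
end_to_end <- function(cs) {
  stopifnot(inherits(cs, "coordset"))
  r <- range(cs$atoms$resno)
  n1 <- atom_xyz(cs, "N", r[1])
  c2 <- atom_xyz(cs, "C", r[2])
  if (is.null(n1) || is.null(c2)) {
    stop("terminal N or C atom missing")
  }
  sqrt(sum((n1 - c2)^2))
}

backbone_matrix <- function(cs) {
  a <- cs$atoms[cs$atoms$name %in% c("N", "CA", "C", "O"), ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Distance-matrix RMSD between two structures
#'
#' Root mean square deviation over all unique backbone atom pairs
#' (i < j) of the internal distances of `cs` from those of `ref`.
#' Invariant under rigid-body rotation and translation of either
#' structure; no superposition is performed.
#'
#' @param cs,ref [coordset()] objects with matching backbone atom sets.
#' @return DRMSD in nm.
#' @export
drmsd <- function(cs, ref) {
  m1 <- backbone_matrix(cs)
  m2 <- backbone_matrix(ref)
  if (nrow(m1) != nrow(m2)) stop("backbone atom sets do not match")
  d1 <- stats::dist(m1)
  d2 <- stats::dist(m2)
  sqrt(mean((d1 - d2)^2))
}

# Dihedral angle (degrees) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Helical fraction of a backbone structure
#'
#' Binary helix assignment per residue: a residue is helical when its
#' carbonyl oxygen lies within `on_cutoff` of the backbone nitrogen four
#' residues downstream (hydrogen-bond proxy for the i, i+4 contact) and
#' its phi/psi angles fall in the alpha basin (phi in `[-100, -30]`, psi
#' in `[-80, -5]` degrees).  The fraction is over assignable residues
#' (those with defined phi/psi and an i+4 partner).  This is a
#' simplified stand-in for a full DSSP-style assignment and will differ
#' from continuous assignments by a few percent.
#'
#' @param cs A [coordset()] with N, CA, C, O atoms per residue.
#' @param on_cutoff O(i)-N(i+4) distance cutoff, nm (default 0.35).
#' @return Helical fraction in `[0, 1]`.
#' @export
helicity <- function(cs, on_cutoff = 0.35) {
  stopifnot(inherits(cs, "coordset"))
  res <- sort(unique(cs$atoms$resno))
  if (length(res) < 5) {
    warning("chain shorter than 5 residues; helicity 0")
    return(0)
  }
  helical <- logical(0)
  for (i in seq_len(length(res) - 4)) {
    r <- res[i]
    o <- atom_xyz(cs, "O", r)
    n4 <- atom_xyz(cs, "N", res[i + 4])
    # phi(i) needs C(i-1); psi(i) needs N(i+1)
    cprev <- if (i > 1) atom_xyz(cs, "C", res[i - 1]) else NULL
    nn <- atom_xyz(cs, "N", r)
    ca <- atom_xyz(cs, "CA", r)
    cc <- atom_xyz(cs, "C", r)
    nnext <- atom_xyz(cs, "N", res[i + 1])
    if (is.null(o) || is.null(n4) || is.null(cprev) || is.null(nn) ||
        is.null(ca) || is.null(cc) || is.null(nnext)) {
      next
    }
    phi <- dihedral(cprev, nn, ca, cc)
    psi <- dihedral(nn, ca, cc, nnext)
    hbond <- sqrt(sum((o - n4)^2)) < on_cutoff
    basin <- phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5
    helical <- c(helical, hbond && basin)
  }
  if (length(helical) == 0) return(0)
  mean(helical)
}

#' Centered running average
#'
#' Moving mean with shrinking windows at the edges; output length equals
#' input length.
#'
#' @param series Numeric vector.
#' @param window Window size in samples (>= 1; also accepts even sizes).
#' @return Smoothed vector.
#' @export
running_average <- function(series, window) {
  if (window < 1) stop("window must be >= 1")
  if (window > length(series)) stop("window exceeds series length")
  smooth_force(series, window)
}

# --- backbone builders ------------------------------------------------------

# Place atom D given A, B, C and internal coordinates: bond |CD|, angle
# B-C-D (degrees) and dihedral A-B-C-D (degrees).  Standard NeRF step.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # match the IUPAC dihedral sign convention
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a backbone from phi/psi angles
#'
#' Constructs N, CA, C, O backbone coordinates (nm) for a chain with the
#' given torsion angles using standard bond lengths and angles
#' (N-CA 0.1458, CA-C 0.1525, C-N 0.1329, C=O 0.1231 nm; omega fixed at
#' 180 degrees).  `ideal_helix()` uses the canonical alpha-helical
#' torsions (phi = -57, psi = -47); `extended_chain()` a beta-strand-like
#' geometry; `random_coil()` draws torsions uniformly (seeded).
#'
#' @param phi,psi Torsion angles in degrees, recycled to `n_residues`.
#' @param n_residues Chain length.
#' @return A [coordset()].
#' @export
build_backbone <- function(n_residues, phi, psi) {
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)
  b_nca <- 0.1458; b_cac <- 0.1525; b_cn <- 0.1329; b_co <- 0.1231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7; a_caco <- 120.8
  # first residue
  atoms <- list()
  n1 <- c(0, 0, 0)
  ca1 <- c(b_nca, 0, 0)
  c1 <- ca1 + b_cac * c(cos(pi * (180 - a_ncac) / 180),
                        sin(pi * (180 - a_ncac) / 180), 0)
  pos <- list(list(N = n1, CA = ca1, C = c1))
  for (i in 2:n_residues) {
    prev <- pos[[i - 1]]
    ni <- place_atom(prev$N, prev$CA, prev$C, b_cn, a_cacn, psi[i - 1])
    cai <- place_atom(prev$CA, prev$C, ni, b_nca, a_cnca, 180)
    ci <- place_atom(prev$C, ni, cai, b_cac, a_ncac, phi[i])
    pos[[i]] <- list(N = ni, CA = cai, C = ci)
  }
  # carbonyl oxygens: in the peptide plane, anti to the next N
  rows <- list()
  for (i in seq_len(n_residues)) {
    p <- pos[[i]]
    o <- place_atom(p$N, p$CA, p$C, b_co, a_caco, psi[i] - 180)
    rows[[i]] <- data.frame(
      name = c("N", "CA", "C", "O"), resno = i,
      x = c(p$N[1], p$CA[1], p$C[1], o[1]),
      y = c(p$N[2], p$CA[2], p$C[2], o[2]),
      z = c(p$N[3], p$CA[3], p$C[3], o[3]),
      stringsAsFactors = FALSE)
  }
  coordset(do.call(rbind, rows))
}

#' @rdname build_backbone
#' @export
ideal_helix <- function(n_residues) {
  build_backbone(n_residues, phi = -57, psi = -47)
}

#' @rdname build_backbone
#' @export
extended_chain <- function(n_residues) {
  build_backbone(n_residues, phi = -120, psi = 120)
}

#' @rdname build_backbone
#' @param seed Seed for the torsion draws.
#' @export
random_coil <- function(n_residues, seed = 1) {
  set.seed(seed)
  build_backbone(n_residues,
                 phi = stats::runif(n_residues, -180, 180),
                 psi = stats::runif(n_residues, -180, 180))
}

#' Apply a rigid-body transform to a coordinate set
#'
#' @param cs A [coordset()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector, nm.
#' @return Transformed [coordset()].
#' @export
transform_coordset <- function(cs, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  m <- as.matrix(cs$atoms[, c("x", "y", "z")])
  m <- m %*% t(rotation)
  m <- sweep(m, 2, translation, "+")
  out <- cs
  out$atoms$x <- m[, 1]
  out$atoms$y <- m[, 2]
  out$atoms$z <- m[, 3]
  out
}

#' Random rotation matrix (uniform over SO(3))
#'
#' @param seed Seed for the draw.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}
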