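# Backbone geometry. Ideal bond lengths (Angstrom) and angles (deg) for
# N-CA-C backbones; only Calpha-level RMSD/Rg statistics are consumed
# downstream, so fixed ideal geometry is adequate.
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  omega = 180
)

deg2rad <- function(x) x * pi / 180

# Place atom D given positions A, B, C, the bond length |C-D|, the angle
# B-C-D and the torsion A-B-C-D (natural extension reference frame).
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- deg2rad(angle_deg); chi <- deg2rad(torsion_deg)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma::cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi),
          bond * sin(th) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an N-CA-C backbone from dihedral angles
#'
#' Constructs Cartesian coordinates (nm) for an n-residue backbone with
#' ideal bond lengths and angles, trans peptide bonds (omega = 180), and
#' the supplied phi/psi angles. phi of the first residue and psi of the
#' last are undefined and ignored.
#'
#' @param phi,psi Numeric vectors of length n_residues (degrees).
#' @return Matrix (3 * n_residues) x 3 of coordinates in nm, with
#'   attributes \code{atom} ("N", "CA", "C") and \code{residue_index}.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 3)
  xyz <- matrix(NA_real_, 3 * n, 3)
  # seed residue 1 in the xy-plane
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(.bb$b_n_ca, 0, 0)
  th <- deg2rad(.bb$a_n_ca_c)
  xyz[3, ] <- xyz[2, ] + .bb$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    iN <- 3 * (i - 1) + 1
    pN <- 3 * (i - 2) + 1
    xyz[iN, ] <- place_atom(xyz[pN, ], xyz[pN + 1, ], xyz[pN + 2, ],
                            .bb$b_c_n, .bb$a_ca_c_n, psi[i - 1])
    xyz[iN + 1, ] <- place_atom(xyz[pN + 1, ], xyz[pN + 2, ], xyz[iN, ],
                                .bb$b_n_ca, .bb$a_c_n_ca, .bb$omega)
    xyz[iN + 2, ] <- place_atom(xyz[pN + 2, ], xyz[iN, ], xyz[iN + 1, ],
                                .bb$b_ca_c, .bb$a_n_ca_c, phi[i])
  }
  xyz <- xyz / 10  # Angstrom -> nm
  attr(xyz, "atom") <- rep(c("N", "CA", "C"), n)
  attr(xyz, "residue_index") <- rep(seq_len(n), each = 3)
  xyz
}

#' Torsion angle over four points
#'
#' IUPAC sign convention (clockwise positive looking from p2 to p3), as
#' used for protein phi/psi angles.
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Torsion angle in degrees, in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
  m1 <- pracma::cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

frame_selection <- function(frame, selection) {
  if (is.null(attr(frame, "atom")) || is.null(selection)) return(frame)
  frame[attr(frame, "atom") %in% selection, , drop = FALSE]
}

#' Radius of gyration of a conformation
#'
#' Mass-uniform Rg: the root-mean-square distance of the selected atoms
#' from their centroid. Cα-only selection is the default for backbone
#' ensembles.
#'
#' @param frame Coordinate matrix (n_atoms x 3, nm), optionally carrying an
#'   \code{atom} attribute.
#' @param selection Atom names to keep (default "CA"; NULL for all rows).
#' @return Rg in the input length unit.
#' @export
radius_of_gyration <- function(frame, selection = "CA") {
  x <- frame_selection(frame, selection)
  if (nrow(x) < 2) stop("need at least 2 atoms")
  ctr <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, ctr)^2)))
}

#' RMSD after optimal superposition
#'
#' Minimum root-mean-square deviation between two conformations over rigid
#' motions (translation plus proper rotation), computed by the Kabsch
#' SVD construction with the determinant correction that excludes
#' reflections.
#'
#' @param frame,reference Coordinate matrices with matching atom sets.
#' @param selection Atom names to superpose (default "CA").
#' @return RMSD in the input length unit.
#' @export
rmsd_to_reference <- function(frame, reference, selection = "CA") {
  x <- frame_selection(frame, selection)
  y <- frame_selection(reference, selection)
  if (nrow(x) != nrow(y)) stop("mismatched atom sets")
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((yc - xc %*% t(R))^2)))
}

#' An ideal alpha-helix backbone
#'
#' Reference conformation with phi = -60, psi = -45 at every residue,
#' standing in for the helical bound form of the peptide.
#'
#' @param n_residues Number of residues, >= 3.
#' @return Backbone coordinate matrix (nm), as [build_backbone()].
#' @export
ideal_helix <- function(n_residues) {
  build_backbone(rep(-60, n_residues), rep(-45, n_residues))
}

#' Build a 2D free-energy surface over (RMSD, Rg)
#'
#' Computes, for every frame, the Cα RMSD to the reference conformation and
#' the Cα radius of gyration, bins the pairs on a regular 2D grid, and
#' converts the histogram to a free-energy surface
#' \eqn{F = -\ln(\mathrm{population})}, shifted so the occupied minimum is
#' 0. Unsampled bins carry NA (a distinguished marker, not a numeric
#' level), so downstream statistics must handle missingness explicitly.
#'
#' @param ensemble A [generate_ensemble()] result, or a list with
#'   \code{frames} (list of coordinate matrices) and \code{reference}.
#' @param reference Reference conformation (default
#'   \code{ensemble$reference}).
#' @param n_bins_rmsd,n_bins_rg Bin counts (default 50 x 50).
#' @return Object of class \code{"fes_grid"}: list with \code{rmsd_edges},
#'   \code{rg_edges} (nm), \code{free_energy} and \code{populations}
#'   matrices (rmsd x rg), and the per-frame \code{rmsd}, \code{rg}.
#' @export
build_fes <- function(ensemble, reference = ensemble$reference,
                      n_bins_rmsd = 50, n_bins_rg = 50) {
  frames <- ensemble$frames
  if (length(frames) < 100) {
    warning("fewer than 100 frames: populations will be noisy")
  }
  rmsd <- vapply(frames, rmsd_to_reference, numeric(1),
                 reference = reference)
  rg <- vapply(frames, radius_of_gyration, numeric(1))

  edges <- function(v, k) {
    r <- range(v)
    if (diff(r) == 0) {  # degenerate: all frames identical on this axis
      r <- r + c(-1, 1) * max(abs(r[1]) * 1e-9, 1e-9)
      k <- 1
    }
    seq(r[1], r[2], length.out = k + 1)
  }
  re <- edges(rmsd, n_bins_rmsd)
  ge <- edges(rg, n_bins_rg)
  ir <- findInterval(rmsd, re, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ig <- findInterval(rg, ge, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(re) - 1, length(ge) - 1)
  for (i in seq_along(ir)) counts[ir[i], ig[i]] <- counts[ir[i], ig[i]] + 1L
  pop <- counts / length(frames)
  fe <- -log(pop)          # empty bins -> Inf for now
  fe[counts == 0] <- NA    # unsampled marker
  fe <- fe - min(fe, na.rm = TRUE)
  structure(list(rmsd_edges = re, rg_edges = ge, free_energy = fe,
                 populations = pop, rmsd = rmsd, rg = rg),
            class = "fes_grid")
}

#' Per-residue helix propensity of an ensemble
#'
#' Fraction of frames in which each residue is helical, a residue-frame
#' being helical iff phi lies in [-100, -30] and psi in [-67, -7] degrees.
#' Terminal residues, whose phi or psi is undefined, are reported NA. The
#' dihedral window is configurable; it is one plausible helicity criterion
#' among several (DSSP-like assignments will differ near basin edges).
#'
#' @param ensemble A [generate_ensemble()] result (frames must carry N, CA,
#'   C atoms).
#' @param phi_range,psi_range Helical windows in degrees.
#' @return Named numeric vector of per-residue propensities in [0, 1]
#'   (NA at termini).
#' @export
helix_propensity <- function(ensemble, phi_range = c(-100, -30),
                             psi_range = c(-67, -7)) {
  frames <- ensemble$frames
  dih <- lapply(frames, backbone_dihedrals)
  n_res <- nrow(dih[[1]])
  helical <- sapply(dih, function(d) {
    ifelse(is.na(d$phi) | is.na(d$psi), NA,
           d$phi >= phi_range[1] & d$phi <= phi_range[2] &
             d$psi >= psi_range[1] & d$psi <= psi_range[2])
  })
  prop <- rowMeans(helical)       # NA propagates at termini
  names(prop) <- rownames(dih[[1]])
  prop
}

#' Backbone dihedrals of one conformation
#'
#' @param frame Backbone coordinate matrix from [build_backbone()] (atoms
#'   N, CA, C per residue, in order).
#' @return data.frame with \code{phi}, \code{psi} per residue (degrees; NA
#'   where undefined at the termini).
#' @export
backbone_dihedrals <- function(frame) {
  atoms <- attr(frame, "atom")
  if (is.null(atoms) || !all(c("N", "CA", "C") %in% atoms)) {
    stop("frame must carry N, CA, C atoms")
  }
  n <- nrow(frame) / 3
  phi <- psi <- rep(NA_real_, n)
  at <- function(i, name) frame[3 * (i - 1) + match(name, c("N", "CA", "C")), ]
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- torsion_angle(at(i - 1, "C"), at(i, "N"), at(i, "CA"),
                              at(i, "C"))
    }
    if (i < n) {
      psi[i] <- torsion_angle(at(i, "N"), at(i, "CA"), at(i, "C"),
                              at(i + 1, "N"))
    }
  }
  out <- data.frame(phi = phi, psi = psi)
  rownames(out) <- seq_len(n)
  out
}
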