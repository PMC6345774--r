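#' Conformational shifts from a chemical-shift table
#'
#' Computes the conformational (secondary) shift
#' \eqn{\Delta\delta = \delta_{obs} - \delta_{RC}} per (residue, atom) row.
#' Random-coil reference shifts are caller-supplied (for phosphorylated
#' residues the references should come from phosphorylated model random-coil
#' peptides). Rows with a missing reference are kept and flagged rather than
#' dropped.
#'
#' @param table data.frame with columns \code{residue_index},
#'   \code{residue_code}, \code{atom}, \code{delta_obs_ppm},
#'   \code{delta_rc_ppm}, and optionally \code{phospho}.
#' @return The input with added columns \code{delta_ppm}
#'   (\eqn{\Delta\delta}, NA where no reference) and \code{missing_ref}.
#' @export
conformational_shifts <- function(table) {
  req <- c("residue_index", "residue_code", "atom", "delta_obs_ppm",
           "delta_rc_ppm")
  stopifnot(is.data.frame(table), all(req %in% names(table)))
  key <- paste(table$residue_index, table$atom)
  if (anyDuplicated(key)) stop("duplicate (residue_index, atom) rows")
  out <- table
  out$delta_ppm <- out$delta_obs_ppm - out$delta_rc_ppm
  out$missing_ref <- is.na(out$delta_rc_ppm)
  if (any(out$missing_ref)) {
    warning(sum(out$missing_ref),
            " row(s) lack a random-coil reference; flagged, not dropped")
  }
  out
}

#' Classify residues as random coil from conformational shifts
#'
#' A residue is random coil iff \eqn{|\Delta\delta| \le} the threshold
#' (0.1 ppm, the commonly accepted band for random-coil peptides); the
#' boundary is inclusive.
#'
#' @param shifts Output of [conformational_shifts()] (or any data.frame with
#'   \code{delta_ppm}).
#' @param threshold_ppm Band half-width in ppm (default 0.1).
#' @return Logical vector, one element per row (NA where the shift is NA).
#' @export
classify_random_coil <- function(shifts,
                                 threshold_ppm = p53_constants()$random_coil_band_ppm) {
  dd <- if (is.data.frame(shifts)) shifts$delta_ppm else shifts
  abs(dd) <= threshold_ppm
}

#' Helical population of a residue window from H-alpha shifts
#'
#' Estimates the helix percentage over a residue window as the mean of the
#' negative conformational shifts in the window divided by the full-helix
#' reference shift (-0.39 ppm), times 100. Only negative (upfield, helical)
#' shifts enter the mean; positive shifts are excluded, and 0 is returned if
#' the window contains no negative shift. The estimate is clamped to
#' [0, 100] with a warning. Note the usual ambiguity: x\% can mean x\% of
#' residues fully helical all of the time or all residues helical x\% of the
#' time.
#'
#' @param shifts Output of [conformational_shifts()].
#' @param window Integer vector of residue indices (e.g. \code{20:25}).
#' @param full_helix_ppm Full-helix reference shift (default -0.39 ppm).
#' @param atom Atom whose shifts are used (default "HA").
#' @return Helix percentage in [0, 100].
#' @export
helix_percent_from_shifts <- function(shifts, window,
                                      full_helix_ppm = p53_constants()$halpha_full_helix_ppm,
                                      atom = "HA") {
  stopifnot(length(window) >= 1)
  rows <- shifts$residue_index %in% window & shifts$atom == atom
  dd <- shifts$delta_ppm[rows]
  dd <- dd[!is.na(dd) & dd < 0]
  if (length(dd) == 0) return(0)
  pct <- 100 * mean(dd) / full_helix_ppm
  if (pct < 0 || pct > 100) {
    warning("helix percentage clamped to [0, 100]")
  }
  min(max(pct, 0), 100)
}

#' Downfield NH check for phosphorylated residues
#'
#' Phosphorylation shifts the backbone amide proton downfield; this boolean
#' report (\eqn{\delta_{obs}(HN) - \delta_{RC}(HN) > 0} per phospho-marked
#' residue) is the qualitative check used to confirm phosphorylation. No
#' quantitative threshold is imposed.
#'
#' @param shifts Output of [conformational_shifts()] containing HN rows and
#'   a \code{phospho} column.
#' @return data.frame with \code{residue_index} and \code{nh_downfield}.
#' @export
phospho_nh_downfield <- function(shifts) {
  stopifnot("phospho" %in% names(shifts))
  rows <- shifts$phospho & shifts$atom == "HN"
  data.frame(
    residue_index = shifts$residue_index[rows],
    nh_downfield = shifts$delta_ppm[rows] > 0
  )
}
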