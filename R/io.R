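#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, backbone atoms only, coordinates
#' converted from nm to Angstrom. Residues are written as GLY since only
#' backbone geometry is represented.
#'
#' @param ensemble A [generate_ensemble()] result.
#' @param path Output file path.
#' @param first_residue Residue number of the first residue (default 17).
#' @return \code{path}, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path, first_residue = 17L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[j]]
    atoms <- attr(fr, "atom")
    resid <- attr(fr, "residue_index") + first_residue - 1L
    writeLines(sprintf("MODEL     %4d", j), con)
    for (i in seq_len(nrow(fr))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, atoms[i], "GLY", resid[i],
        fr[i, 1] * 10, fr[i, 2] * 10, fr[i, 3] * 10), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a backbone ensemble from a multi-model PDB file
#'
#' Counterpart of [write_ensemble_pdb()]: reads MODEL blocks of N/CA/C
#' ATOM records into coordinate matrices in nm (Angstrom input assumed;
#' set \code{angstrom = FALSE} if the file is already in nm).
#'
#' @param path PDB file path.
#' @param angstrom Input coordinates are Angstrom (default TRUE).
#' @return List with \code{frames}, as in [generate_ensemble()].
#' @export
read_ensemble_pdb <- function(path, angstrom = TRUE) {
  lines <- readLines(path)
  frames <- list()
  cur <- NULL; atoms <- NULL; resid <- NULL
  scale <- if (angstrom) 0.1 else 1
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") {
      cur <- matrix(numeric(0), 0, 3); atoms <- character(0)
      resid <- integer(0)
    } else if (tag == "ENDMDL") {
      attr(cur, "atom") <- atoms
      attr(cur, "residue_index") <- resid - min(resid) + 1L
      frames[[length(frames) + 1]] <- cur
    } else if (tag == "ATOM  ") {
      cur <- rbind(cur, scale * c(as.numeric(substr(ln, 31, 38)),
                                  as.numeric(substr(ln, 39, 46)),
                                  as.numeric(substr(ln, 47, 54))))
      atoms <- c(atoms, trimws(substr(ln, 13, 16)))
      resid <- c(resid, as.integer(substr(ln, 23, 26)))
    }
  }
  list(frames = frames)
}

#' Write a ground-truth sidecar in YAML
#'
#' Records the generating parameters, noise level and seed of a synthetic
#' data set next to the data file, so any downstream recovery check can
#' find its truth.
#'
#' @param truth A [ground_truth()].
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  yaml::write_yaml(list(kind = truth$kind, params = truth$params,
                        noise_sd = truth$noise_sd, seed = truth$seed),
                   path)
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path YAML path written by [write_ground_truth_yaml()].
#' @return A [ground_truth()].
#' @export
read_ground_truth_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  ground_truth(x$kind, x$params, x$noise_sd, x$seed)
}
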