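# Format readers and writers: multi-frame PDB trajectories (via bio3d),
# structures for pore profiling, grayscale PNG class images with JSON
# sidecar metadata, and CSV helpers for curves and traces. Coordinates are
# Angstrom throughout; DEER distances and ring axes are reported in nm.

# segment label <-> PDB residue-name tag used by the toy trajectories
SEGMENT_RESNAMES <- c(tail = "TAL", core = "COR", partner = "PTR",
                      phosphate = "PHO", acyl = "ACY")

#' Write a trajectory as a multi-frame PDB file
#'
#' Frames become MODEL/ENDMDL blocks; residue numbering is 1-based and
#' coordinates are Angstrom (PDB fixed-format, 3 decimals). Toy-segment
#' labels are stored as residue names (TAL/COR/PTR/PHO/ACY).
#'
#' @param traj an [md_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$atoms
  resname <- ifelse(a$segment %in% names(SEGMENT_RESNAMES),
                    SEGMENT_RESNAMES[a$segment], a$resname)
  xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
  if (n_frames(traj) == 1L) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resid %% 10000L, resid = resname,
                   elety = a$name, chain = rep("A", nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Read a multi-frame PDB file as a trajectory
#'
#' MODEL blocks become frames. All frames must contain the same atoms; a
#' mismatch is reported with the offending model number.
#'
#' @param path PDB file path.
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) == length(model_starts)) {
      counts <- vapply(seq_along(model_starts), function(k)
        sum(grepl("^(ATOM|HETATM)",
                  lines[model_starts[k]:ends[k]])), integer(1))
      if (length(unique(counts)) > 1L) {
        bad <- which(counts != counts[1])[1]
        stop_invalid("inconsistent atom count in MODEL ", bad, " (",
                     counts[bad], " vs ", counts[1], " atoms)")
      }
    }
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE),
                  error = function(e)
                    stop_invalid("PDB parse error in ", path, ": ",
                                 conditionMessage(e)))
  at <- pdb$atom
  nf <- nrow(pdb$xyz)
  n_atoms <- nrow(at)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  seg_map <- stats::setNames(names(SEGMENT_RESNAMES), SEGMENT_RESNAMES)
  seg <- ifelse(at$resid %in% names(seg_map), seg_map[at$resid], "core")
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(trimws(at$elety), 1, 1), trimws(at$elesy))
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      resid = at$resno, resname = at$resid, segment = seg,
                      element = elem,
                      heavy = toupper(elem) != "H",
                      stringsAsFactors = FALSE)
  md_trajectory(atoms, coords)
}

#' Read a PDB structure for pore profiling
#'
#' Waters, ions and other hetero records are stripped by default; van der
#' Waals radii are assigned from the Bondi set by element (override with
#' `vdw_table`).
#'
#' @param path PDB file path.
#' @param keep_hetero keep HETATM records (default FALSE).
#' @param vdw_table optional named vector element -> radius (Angstrom).
#' @return A [pore_structure()].
#' @export
read_structure <- function(path, keep_hetero = FALSE, vdw_table = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e)
                    stop_invalid("PDB parse error in ", path, ": ",
                                 conditionMessage(e)))
  at <- pdb$atom
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop_invalid("no atoms after filtering: ", path)
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(trimws(at$elety), 1, 1), trimws(at$elesy))
  vdw <- if (is.null(vdw_table)) bondi_radius(elem) else {
    r <- unname(vdw_table[toupper(elem)]); r[is.na(r)] <- 1.7; r
  }
  pore_structure(as.matrix(at[, c("x", "y", "z")]), element = elem,
                 vdw = vdw, resid = at$resno, chain = at$chain)
}

#' Write a class image as 8-bit grayscale PNG with JSON sidecar
#'
#' Intensities are clipped to `[0, 1]`. The sidecar (`<path>.json`) records
#' the pixel size and any ground-truth metadata.
#'
#' @param image a `class_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_class_image <- function(image, path) {
  m <- pmin(pmax(image$pixels, 0), 1)
  png::writePNG(m, path)
  meta <- list(pixel_size = image$pixel_size, truth = image$truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a grayscale PNG class image (+ JSON sidecar if present)
#'
#' @param path PNG path; `<path>.json` supplies `pixel_size` when present.
#' @param pixel_size nm/px override.
#' @param n_particles optional particle count for weighting.
#' @return A `class_image` list.
#' @export
read_class_image <- function(path, pixel_size = NULL, n_particles = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  sidecar <- paste0(path, ".json")
  truth <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% meta$pixel_size
    truth <- meta$truth
    n_particles <- n_particles %||% meta$n_particles
  }
  if (is.null(pixel_size)) stop_invalid("pixel_size not given and no sidecar found")
  structure(list(pixels = m, pixel_size = pixel_size, truth = truth,
                 n_particles = n_particles), class = "class_image")
}

#' Write a time series / curve as CSV
#'
#' Comma-delimited with a header row, UTF-8.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a curve CSV written by [write_curve_csv()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  utils::read.csv(path, fileEncoding = "UTF-8")
}
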