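## Coordinate file IO: GRO, PDB, XYZ. In-memory coordinates are always in
## Angstrom; GRO files are nm on disk (exact factor-10 conversion). Species
## map to residue names LAU/MYR/PLM/STE. Protonation is encoded as an
## "H"/"-" residue-name suffix in GRO and XYZ; PDB keeps 3-character
## residue names and uses chain ID P (protonated) / D (deprotonated).

species_to_res <- function(species) {
  map <- c(LA = "LAU", MA = "MYR", PA = "PLM", SA = "STE")
  out <- unname(map[species])
  out[is.na(out)] <- toupper(substr(species[is.na(out)], 1, 3))
  out
}

res_to_species <- function(res) {
  map <- c(LAU = "LA", MYR = "MA", PLM = "PA", STE = "SA")
  out <- unname(map[res])
  if (anyNA(out)) {
    warning("unknown residue name(s): ",
            paste(unique(res[is.na(out)]), collapse = ", "),
            "; assigning species 'other'", call. = FALSE)
    out[is.na(out)] <- "other"
  }
  out
}

frame_from_atoms <- function(molecule_id, species, protonated, x, y, z, box) {
  leaflet <- ifelse(z > box[3] / 2, "upper", "lower")
  monolayer_frame(data.frame(molecule_id = molecule_id, species = species,
                             protonated = protonated, x = x, y = y, z = z,
                             leaflet = leaflet, present = TRUE,
                             stringsAsFactors = FALSE), box)
}

present_rows <- function(frame) frame[frame$present, , drop = FALSE]

## ---- GRO ----

write_gro_block <- function(frame, title = "monolayer frame") {
  fr <- present_rows(frame)
  box <- frame_box(frame)
  res <- paste0(species_to_res(fr$species), ifelse(fr$protonated, "H", "-"))
  c(title,
    sprintf("%5d", nrow(fr)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            fr$molecule_id %% 100000L, res, "C1",
            seq_len(nrow(fr)) %% 100000L,
            fr$x / 10, fr$y / 10, fr$z / 10),
    sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10))
}

read_gro_block <- function(lines, start) {
  natoms <- as.integer(trimws(lines[start + 1L]))
  if (is.na(natoms)) stop("malformed GRO atom count at line ", start + 1L,
                          call. = FALSE)
  al <- lines[start + 1L + seq_len(natoms)]
  resname <- trimws(substr(al, 6, 10))
  suppressWarnings({
    resno <- as.integer(substr(al, 1, 5))
    x <- as.numeric(substr(al, 21, 28)) * 10
    y <- as.numeric(substr(al, 29, 36)) * 10
    z <- as.numeric(substr(al, 37, 44)) * 10
  })
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record at line ", start + 1L + bad[1], call. = FALSE)
  box <- as.numeric(strsplit(trimws(lines[start + 2L + natoms]), "\\s+")[[1]])[1:3] * 10
  prot <- !grepl("-$", resname)
  base <- sub("[H-]$", "", resname)
  list(frame = frame_from_atoms(resno, res_to_species(base), prot, x, y, z, box),
       next_line = start + 3L + natoms)
}

## ---- XYZ ----

write_xyz_block <- function(frame) {
  fr <- present_rows(frame)
  box <- frame_box(frame)
  res <- paste0(species_to_res(fr$species), ifelse(fr$protonated, "H", "-"))
  c(sprintf("%d", nrow(fr)),
    sprintf("box %.6f %.6f %.6f", box[1], box[2], box[3]),
    sprintf("%-6s %12.6f %12.6f %12.6f", res, fr$x, fr$y, fr$z))
}

read_xyz_block <- function(lines, start) {
  natoms <- as.integer(trimws(lines[start]))
  if (is.na(natoms)) stop("malformed XYZ atom count at line ", start,
                          call. = FALSE)
  comment <- strsplit(trimws(lines[start + 1L]), "\\s+")[[1]]
  if (length(comment) < 4L || comment[1] != "box")
    stop("XYZ comment line must be 'box Lx Ly Lz' (line ", start + 1L, ")",
         call. = FALSE)
  box <- as.numeric(comment[2:4])
  al <- strsplit(trimws(lines[start + 1L + seq_len(natoms)]), "\\s+")
  if (any(lengths(al) < 4L))
    stop("malformed XYZ record near line ", start + 2L, call. = FALSE)
  nm <- vapply(al, `[`, "", 1L)
  x <- as.numeric(vapply(al, `[`, "", 2L))
  y <- as.numeric(vapply(al, `[`, "", 3L))
  z <- as.numeric(vapply(al, `[`, "", 4L))
  prot <- !grepl("-$", nm)
  base <- sub("[H-]$", "", nm)
  list(frame = frame_from_atoms(seq_len(natoms), res_to_species(base),
                                prot, x, y, z, box),
       next_line = start + 2L + natoms)
}

## ---- PDB (atom records via bio3d) ----

write_pdb_frames <- function(frames, path) {
  box <- frame_box(frames[[1]])
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   box[1], box[2], box[3], 90, 90, 90)
  lines <- cryst
  multi <- length(frames) > 1L
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  for (i in seq_along(frames)) {
    fr <- present_rows(frames[[i]])
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(rbind(fr$x, fr$y, fr$z)),
                     resno = fr$molecule_id,
                     resid = species_to_res(fr$species),
                     elety = rep("C1", nrow(fr)),
                     chain = ifelse(fr$protonated, "P", "D"))
    body <- grep("^ATOM", readLines(tmp), value = TRUE)
    if (multi) body <- c(sprintf("MODEL     %4d", i), body, "ENDMDL")
    lines <- c(lines, body)
  }
  writeLines(c(lines, "END"), path)
}

read_pdb_frames <- function(path) {
  lines <- readLines(path)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) stop("PDB file has no CRYST1 box record: ", path,
                        call. = FALSE)
  box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts)) {
    ends <- grep("^ENDMDL", lines)
    lapply(seq_along(starts), function(i) lines[(starts[i] + 1L):(ends[i] - 1L)])
  } else list(grep("^ATOM", lines, value = TRUE))
  frames <- lapply(blocks, function(bl) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(c(bl, "END"), tmp)
    at <- bio3d::read.pdb(tmp)$atom
    frame_from_atoms(at$resno, res_to_species(at$resid),
                     at$chain != "D", at$x, at$y, at$z, box)
  })
  frames
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("gro", "pdb", "xyz")) ext
  else stop("cannot infer format from extension '", ext,
            "'; pass 'format' explicitly", call. = FALSE)
}

#' Read a monolayer trajectory from a coordinate file
#'
#' Supports GRO (nm on disk, converted exactly to \enc{Å}{Angstrom}), PDB
#' and XYZ; multi-frame files (concatenated GRO/XYZ blocks or PDB MODEL
#' records) become multi-frame trajectories. Species and protonation are
#' recovered from residue naming (see package IO conventions); leaflet is
#' assigned by z relative to the box midplane.
#'
#' @param path input file.
#' @param format \code{"gro"}, \code{"pdb"}, \code{"xyz"} or \code{"auto"}
#'   (by extension).
#' @return A \code{monolayer_trajectory}.
#' @export
read_frames <- function(path, format = c("auto", "gro", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  frames <- if (format == "pdb") {
    read_pdb_frames(path)
  } else {
    lines <- readLines(path)
    lines <- lines[seq_len(max(which(nzchar(trimws(lines)))))]
    out <- list(); pos <- 1L
    reader <- if (format == "gro") read_gro_block else read_xyz_block
    while (pos <= length(lines)) {
      blk <- reader(lines, pos)
      out[[length(out) + 1L]] <- blk$frame
      pos <- blk$next_line
    }
    out
  }
  structure(list(frames = frames, dt_ps = NA_real_),
            class = "monolayer_trajectory")
}

#' Write a frame or trajectory to a coordinate file
#'
#' Inverse of [read_frames()]. Desorbed molecules (\code{present = FALSE})
#' are omitted from the file; the desorption flag is an in-memory analysis
#' state.
#'
#' @param x a [monolayer_frame()] or trajectory.
#' @param path output file.
#' @param format \code{"gro"}, \code{"pdb"}, \code{"xyz"} or \code{"auto"}.
#' @return \code{path}, invisibly.
#' @export
write_frames <- function(x, path, format = c("auto", "gro", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  traj <- as_trajectory(x)
  if (format == "pdb") {
    write_pdb_frames(traj$frames, path)
  } else {
    writer <- if (format == "gro") write_gro_block else write_xyz_block
    writeLines(unlist(lapply(traj$frames, writer)), path)
  }
  invisible(path)
}
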