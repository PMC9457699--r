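# Minimal structure/trajectory data model.
#
# Coordinates are Angstrom, times ps, boxes orthorhombic (edge lengths only).
# Atom and residue indexing is 0-free: plain 1-based R indices internally;
# PDB serial numbers are regenerated on output.

#' Construct a trajectory object
#'
#' @param coords numeric array frames x atoms x 3, Angstrom
#' @param box per-frame orthorhombic edge lengths: vector of length 3
#'   (constant box), or frames x 3 matrix, or NULL for non-periodic
#' @param times per-frame times in ps (default 0,1,2,...)
#' @param wrapped logical: are coordinates wrapped into the primary box?
#' @return object of class \code{ff_trajectory}
#' @export
ff_trajectory <- function(coords, box = NULL, times = NULL, wrapped = FALSE) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 1L) stop("need at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  nf <- dim(coords)[1]
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    stopifnot(nrow(box) == nf, ncol(box) == 3)
    if (any(box <= 0)) stop("box edges must be positive")
  }
  if (is.null(times)) times <- seq_len(nf) - 1
  stopifnot(length(times) == nf)
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 wrapped = isTRUE(wrapped)),
            class = "ff_trajectory")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms%s%s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (!is.null(x$box)) sprintf(", box %.2f x %.2f x %.2f A",
                                           x$box[1, 1], x$box[1, 2], x$box[1, 3]) else "",
              if (x$wrapped) " (wrapped)" else ""))
  invisible(x)
}

#' Number of frames / atoms
#' @param t \code{ff_trajectory}
#' @return integer
#' @export
n_frames <- function(t) dim(t$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(t) dim(t$coords)[2]

#' Construct a topology
#'
#' @param atom_name,element,res_index,res_name,chain per-atom vectors
#' @return object of class \code{ff_topology}; the backbone map (per-residue
#'   indices of N, CA, C, O and amide H when present) is built for residues
#'   where all four heavy atoms exist
#' @export
ff_topology <- function(atom_name, element, res_index, res_name,
                        chain = rep("A", length(atom_name))) {
  n <- length(atom_name)
  stopifnot(length(element) == n, length(res_index) == n,
            length(res_name) == n, length(chain) == n)
  if (is.unsorted(res_index)) stop("residue indices must be non-decreasing")
  atoms <- data.frame(atom_name = atom_name, element = element,
                      res_index = res_index, res_name = res_name,
                      chain = chain, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, backbone = .backbone_map(atoms)),
            class = "ff_topology")
}

.backbone_map <- function(atoms) {
  res <- unique(atoms$res_index)
  bb <- lapply(res, function(r) {
    sel <- which(atoms$res_index == r)
    nm <- atoms$atom_name[sel]
    idx <- function(a) { i <- sel[match(a, nm)]; if (is.na(i)) NA_integer_ else i }
    out <- c(N = idx("N"), CA = idx("CA"), C = idx("C"), O = idx("O"),
             H = idx("H"))
    if (anyNA(out[c("N", "CA", "C", "O")])) NULL else out
  })
  names(bb) <- as.character(res)
  bb[!vapply(bb, is.null, TRUE)]
}

#' Residue indices with a complete backbone
#' @param top \code{ff_topology}
#' @return integer vector
#' @export
backbone_residues <- function(top) as.integer(names(top$backbone))

#' Indices of one named backbone atom per backbone residue
#' @param top \code{ff_topology}
#' @param atom one of "N","CA","C","O","H"
#' @return integer vector (NA where absent)
#' @export
backbone_atom <- function(top, atom = "CA")
  vapply(top$backbone, `[[`, 0L, atom)

# ---- PDB --------------------------------------------------------------------

#' Read a (multi-model) PDB text into topology + trajectory
#'
#' Parsing of ATOM records is delegated to \pkg{bio3d}; MODEL/ENDMDL blocks
#' become frames and an optional CRYST1 record populates the box edges.
#'
#' @param text character scalar/vector of PDB lines, or a file path
#' @return list with \code{top} (\code{ff_topology}) and \code{traj}
#'   (\code{ff_trajectory})
#' @export
read_pdb_traj <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else lines <- as.character(text)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)

  nat <- nrow(pdb$atom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (ncol(xyz) != 3L * nat)
    stop("inconsistent atom count across MODEL blocks")
  coords <- array(NA_real_, c(nf, nat, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)

  box <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl)) {
    a <- as.numeric(substr(cl[1], 7, 15))
    b <- as.numeric(substr(cl[1], 16, 24))
    c3 <- as.numeric(substr(cl[1], 25, 33))
    if (all(is.finite(c(a, b, c3)))) box <- c(a, b, c3)
  }
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(pdb$atom$elety), 1, 1)
  top <- ff_topology(trimws(pdb$atom$elety), trimws(elem),
                     pdb$atom$resno, trimws(pdb$atom$resid),
                     ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain))
  list(top = top, traj = ff_trajectory(coords, box = box, wrapped = FALSE))
}

#' Write topology + trajectory as multi-model PDB text
#'
#' @param top \code{ff_topology}
#' @param traj \code{ff_trajectory}
#' @param file optional output path
#' @return character vector of lines, invisibly when \code{file} given
#' @export
write_pdb_traj <- function(top, traj, file = NULL) {
  stopifnot(inherits(top, "ff_topology"), inherits(traj, "ff_trajectory"))
  nat <- nrow(top$atoms)
  stopifnot(n_atoms(traj) == nat)
  out <- character(0)
  if (!is.null(traj$box))
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      traj$box[1, 1], traj$box[1, 2], traj$box[1, 3], 90, 90, 90))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    if (nf > 1L) out <- c(out, sprintf("MODEL     %4d", f))
    rec <- sprintf(
      "ATOM  %5d %-4s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nat) %% 100000L,
      ifelse(nchar(top$atoms$atom_name) < 4L,
             paste0(" ", top$atoms$atom_name), top$atoms$atom_name),
      top$atoms$res_name, substr(top$atoms$chain, 1, 1),
      top$atoms$res_index %% 10000L,
      traj$coords[f, , 1], traj$coords[f, , 2], traj$coords[f, , 3],
      1, 0, top$atoms$element)
    out <- c(out, rec)
    if (nf > 1L) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

# ---- XYZ --------------------------------------------------------------------

#' Read a plain multi-frame XYZ trajectory
#'
#' Whitespace-separated frames: a count line, a comment line, then
#' \code{name x y z} rows; constant atom count across frames.
#'
#' @param text character scalar/vector of lines or file path
#' @param box orthorhombic edge lengths (length 3 or scalar), or NULL
#' @param dt frame spacing in ps
#' @param wrapped whether coordinates are wrapped
#' @return \code{ff_trajectory} with times \code{(0:(nf-1)) * dt}
#' @export
read_xyz_traj <- function(text, box = NULL, dt = 1, wrapped = FALSE) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else lines <- as.character(text)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %in% integer(0)]

  i <- 1L
  frames <- list()
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) stop("bad atom-count line at line ", i)
    if (i + 1L + nat > length(lines)) stop("truncated frame starting line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    m <- t(vapply(block, function(ln) {
      tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
      if (length(tok) < 4L) stop("ragged XYZ row: ", ln)
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(v)) stop("malformed coordinate in row: ", ln)
      v
    }, numeric(3)))
    dimnames(m) <- NULL
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + nat
  }
  nat <- nrow(frames[[1L]])
  if (any(vapply(frames, nrow, 0L) != nat))
    stop("atom count varies across frames")
  coords <- array(NA_real_, c(length(frames), nat, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  if (!is.null(box) && length(box) == 1L) box <- rep(box, 3)
  ff_trajectory(coords, box = box,
                times = (seq_along(frames) - 1) * dt, wrapped = wrapped)
}

#' Write a plain multi-frame XYZ trajectory
#' @param traj \code{ff_trajectory}
#' @param names per-atom names (default "X")
#' @param file optional output path
#' @return lines, invisibly when \code{file} given
#' @export
write_xyz_traj <- function(traj, names = NULL, file = NULL) {
  nat <- n_atoms(traj)
  if (is.null(names)) names <- rep("X", nat)
  out <- character(0)
  for (f in seq_len(n_frames(traj))) {
    out <- c(out, as.character(nat), sprintf("frame %d t= %.6f ps", f,
                                             traj$times[f]),
             sprintf("%-4s %14.8f %14.8f %14.8f", names,
                     traj$coords[f, , 1], traj$coords[f, , 2],
                     traj$coords[f, , 3]))
  }
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

# ---- periodic boundaries ----------------------------------------------------

#' Unwrap periodic-boundary jumps (minimum-image accumulation)
#'
#' Assumes every true per-step displacement is below L/2 per axis; under
#' that assumption the minimum-image increment between consecutive frames
#' recovers the continuous displacement needed for MSD analysis.  The first
#' frame is unchanged.
#'
#' @param t wrapped \code{ff_trajectory} with a box
#' @return unwrapped \code{ff_trajectory} (\code{wrapped = FALSE})
#' @export
unwrap_pbc <- function(t) {
  stopifnot(inherits(t, "ff_trajectory"))
  if (!t$wrapped) return(t)
  if (is.null(t$box)) stop("cannot unwrap without box dimensions")
  out <- t$coords
  nf <- n_frames(t)
  for (f in seq_len(nf)[-1L]) {
    d <- t$coords[f, , , drop = FALSE] - t$coords[f - 1L, , , drop = FALSE]
    for (ax in 1:3) {
      L <- t$box[f, ax]
      d[1, , ax] <- d[1, , ax] - L * round(d[1, , ax] / L)
    }
    out[f, , ] <- out[f - 1L, , ] + d[1, , ]
  }
  ff_trajectory(out, box = t$box, times = t$times, wrapped = FALSE)
}

#' Wrap coordinates into the primary box [0, L)
#' @param t \code{ff_trajectory} with a box
#' @return wrapped \code{ff_trajectory}
#' @export
wrap_pbc <- function(t) {
  stopifnot(!is.null(t$box))
  out <- t$coords
  for (ax in 1:3) {
    L <- t$box[, ax]
    out[, , ax] <- out[, , ax] - outer(L, rep(1, n_atoms(t))) *
      floor(out[, , ax] / outer(L, rep(1, n_atoms(t))))
  }
  ff_trajectory(out, box = t$box, times = t$times, wrapped = TRUE)
}
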