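# Readers and writers: plain-text HILLS dialect, PDB (via bio3d), GRO, XYZ
# multi-frame, OpenDX scalar fields, TSV profiles with metadata headers.
# Internal units on read: angstrom, ps, e, amu (GRO nm -> angstrom).

#' Deposited-hill series
#'
#' Validated container for metadynamics hill records: deposition time,
#' Gaussian center in (d, theta), widths, height and the (single) bias
#' factor. Time must be strictly increasing, widths positive, heights
#' non-negative.
#'
#' @param records tibble with columns `time`, `cv1` (d, nm), `cv2` (theta,
#'   rad, periodic), `sigma1`, `sigma2`, `height` (kJ/mol), `biasf`.
#' @return tibble of class `ha_hills`.
#' @export
hill_series <- function(records) {
  records <- as_tibble(records)
  need <- c("time", "cv1", "cv2", "sigma1", "sigma2", "height", "biasf")
  if (!all(need %in% names(records))) {
    abort("hill series needs columns time, cv1, cv2, sigma1, sigma2, height, biasf",
          class = "ha_format_error")
  }
  if (nrow(records) > 0) {
    if (any(diff(records$time) <= 0)) {
      abort("hill times must be strictly increasing", class = "ha_corrupt_file")
    }
    if (any(records$sigma1 <= 0) || any(records$sigma2 <= 0)) {
      abort("hill widths must be positive", class = "ha_corrupt_file")
    }
    if (any(records$height < 0)) {
      abort("hill heights must be non-negative", class = "ha_corrupt_file")
    }
    if (length(unique(records$biasf)) > 1) {
      abort("a hill series must carry a single bias factor", class = "ha_corrupt_file")
    }
  }
  structure(records, class = c("ha_hills", class(records)))
}

#' Write a hill series to a plain-text HILLS file
#'
#' Whitespace-separated records preceded by a `#! FIELDS ...` header line
#' (the de-facto metadynamics convention).
#'
#' @param hills a [hill_series()].
#' @param path output file.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2 sigma1 sigma2 height biasf", con)
  if (nrow(hills) > 0) {
    lines <- sprintf("%.6f %.9f %.9f %.9f %.9f %.9f %.6f",
                     hills$time, hills$cv1, hills$cv2, hills$sigma1,
                     hills$sigma2, hills$height, hills$biasf)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a plain-text HILLS file
#'
#' Expects a `#!` header naming at least two CV columns; the second CV is
#' interpreted as the periodic azimuthal angle. Non-monotone times raise a
#' corrupt-file error. A missing bias-factor column falls back to the
#' non-tempered interpretation (`biasf = Inf`) with a warning. Unknown
#' columns are preserved.
#'
#' @param path HILLS file.
#' @return a [hill_series()].
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!", lines, value = TRUE)
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- NULL
  if (length(hdr) > 0) {
    toks <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1])), "\\s+")[[1]]
    fields <- toks[nzchar(toks)]
  }
  if (is.null(fields)) {
    abort("HILLS file lacks a '#! FIELDS' header", class = "ha_format_error")
  }
  if (length(fields) < 6) {
    abort("HILLS header must declare two CV columns with widths and height",
          class = "ha_format_error")
  }
  if (length(data_lines) == 0) {
    return(hill_series(tibble(time = numeric(0), cv1 = numeric(0), cv2 = numeric(0),
                              sigma1 = numeric(0), sigma2 = numeric(0),
                              height = numeric(0), biasf = numeric(0))))
  }
  vals <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(vals)
  if (any(nf != length(fields))) {
    abort(sprintf("HILLS record %d has %d fields, header declares %d",
                  which(nf != length(fields))[1], nf[nf != length(fields)][1],
                  length(fields)), class = "ha_corrupt_file")
  }
  m <- matrix(as.numeric(unlist(vals)), ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  tb <- as_tibble(m)
  std <- c("time", "cv1", "cv2", "sigma1", "sigma2", "height")
  if (!all(std %in% names(tb))) {
    # positional fallback: time, cv1, cv2, sigma1, sigma2, height[, biasf]
    names(tb)[1:6] <- std
  }
  if (!"biasf" %in% names(tb)) {
    warn("HILLS file has no bias-factor column; interpreting as non-tempered (biasf = Inf)",
         class = "ha_missing_biasf")
    tb$biasf <- Inf
  }
  hill_series(tb)
}

# ---- structure / trajectory formats ----------------------------------------

# infer group labels from residue and atom names (read-back of our writers
# and conventional PDB naming)
.infer_groups <- function(resname, name) {
  grp <- rep("other", length(name))
  grp[resname %in% c("HOH", "SOL", "WAT", "TIP3")] <- "water"
  grp[name == "P" | name %in% c("O1P", "O2P", "OP1", "OP2")] <- "phosphate"
  grp[name == "GM"] <- "major_groove"
  grp[name == "Gm"] <- "minor_groove"
  ion <- resname %in% c("ION", "MG", "NA", "K", "CL", "SPM")
  grp[ion] <- paste0("ion:", ifelse(resname[ion] == "ION", name[ion], resname[ion]))
  grp
}

#' Write a structure as PDB
#'
#' Atom records are written with bio3d; the box is recorded on a CRYST1
#' line. Occupancy carries the partial charge and B-factor the mass so the
#' reduced topology round-trips.
#'
#' @param structure an `ha_structure`.
#' @param path output file.
#' @export
write_structure_pdb <- function(structure, path) {
  box <- ha_box(structure)
  xyz <- as.numeric(t(structure_coords(structure)))
  chain <- ifelse(is.na(structure$helix), "W",
                  ifelse(structure$helix == 1L, "A", "B"))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = structure$resid, resid = structure$resname,
                   eleno = structure$atom, elety = structure$name,
                   chain = chain, o = structure$charge, b = structure$mass)
  lines <- readLines(path)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   box[1], box[2], box[3], 90, 90, 90)
  writeLines(c(cryst, lines), path)
  invisible(path)
}

#' Read a PDB structure
#'
#' @param path PDB file.
#' @param box optional 3-vector overriding the CRYST1 record.
#' @return an `ha_structure`; groups inferred from residue/atom names.
#' @export
read_structure_pdb <- function(path, box = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(box)) {
    lines <- readLines(path, n = 50)
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (length(cl) > 0) {
      box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                          substr(cl[1], 25, 33)))
    } else {
      abort("PDB has no CRYST1 record; supply box=", class = "ha_format_error")
    }
  }
  helix <- ifelse(at$chain == "A", 1L, ifelse(at$chain == "B", 2L, NA_integer_))
  atoms <- tibble(atom = seq_len(nrow(at)), name = at$elety, resname = at$resid,
                  resid = at$resno, helix = helix,
                  group = .infer_groups(at$resid, at$elety),
                  x = at$x, y = at$y, z = at$z,
                  charge = at$o, mass = at$b)
  labeled_structure(atoms, box)
}

#' Write a structure (optionally with velocities) as GRO
#'
#' GROMACS coordinate file: positions in nm, velocities in nm/ps.
#'
#' @param structure an `ha_structure`; if columns `vx`,`vy`,`vz` are present
#'   (angstrom/ps) they are written as velocities.
#' @param path output file.
#' @param title title line.
#' @export
write_gro <- function(structure, path, title = "helixatmos fixture") {
  box <- ha_box(structure) / 10
  has_v <- all(c("vx", "vy", "vz") %in% names(structure))
  lines <- c(title, sprintf("%5d", nrow(structure)))
  body <- if (has_v) {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
            structure$resid %% 100000L, substr(structure$resname, 1, 5),
            substr(structure$name, 1, 5), structure$atom %% 100000L,
            structure$x / 10, structure$y / 10, structure$z / 10,
            structure$vx / 10, structure$vy / 10, structure$vz / 10)
  } else {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            structure$resid %% 100000L, substr(structure$resname, 1, 5),
            substr(structure$name, 1, 5), structure$atom %% 100000L,
            structure$x / 10, structure$y / 10, structure$z / 10)
  }
  lines <- c(lines, body, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO file
#'
#' Positions are converted nm -> angstrom and velocities nm/ps ->
#' angstrom/ps when present.
#'
#' @param path GRO file.
#' @return an `ha_structure` (with velocity columns when present).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("truncated GRO file", class = "ha_format_error")
  n <- as.integer(trimws(lines[2]))
  if (length(lines) < n + 3) {
    abort(sprintf("GRO file truncated: %d atom lines expected, %d present",
                  n, length(lines) - 3L), class = "ha_format_error")
  }
  body <- lines[3:(2 + n)]
  num <- function(from, to) as.numeric(substr(body, from, to))
  has_v <- all(nchar(body) >= 68)
  atoms <- tibble(
    atom = seq_len(n),
    name = trimws(substr(body, 11, 15)),
    resname = trimws(substr(body, 6, 10)),
    resid = as.integer(substr(body, 1, 5)),
    x = num(21, 28) * 10, y = num(29, 36) * 10, z = num(37, 44) * 10
  )
  if (has_v) {
    atoms$vx <- num(45, 52) * 10; atoms$vy <- num(53, 60) * 10; atoms$vz <- num(61, 68) * 10
  }
  atoms$helix <- NA_integer_
  atoms$group <- .infer_groups(atoms$resname, atoms$name)
  atoms$charge <- 0; atoms$mass <- 1
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3] * 10
  labeled_structure(atoms[, c(.structure_cols, if (has_v) c("vx", "vy", "vz"))], box)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Concatenated XYZ frames; the comment line records the box and frame time.
#'
#' @param window an `ha_trajectory`.
#' @param path output file.
#' @export
write_xyz <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- window$atoms$name[order(window$atoms$atom)]
  for (i in frame_indices(window)) {
    xyz <- frame_coords(window, i)
    writeLines(as.character(nrow(xyz)), con)
    writeLines(sprintf("box %.6f %.6f %.6f t= %.6f", window$box[1],
                       window$box[2], window$box[3], (i - 1) * window$dt), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", nm, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path XYZ file.
#' @param topology an `ha_structure` supplying atom metadata (names, groups,
#'   charges, masses); atom counts are checked per frame.
#' @param dt frame spacing, ps.
#' @return an `ha_trajectory`.
#' @export
read_xyz <- function(path, topology, dt = 1) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  fi <- 0L
  n_top <- nrow(topology)
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    fi <- fi + 1L
    if (is.na(n)) {
      abort(sprintf("frame %d: malformed atom-count line", fi), class = "ha_format_error")
    }
    if (n != n_top) {
      abort(sprintf("frame %d: %d atoms in file, topology has %d", fi, n, n_top),
            class = "ha_format_error")
    }
    if (pos + 1L + n > length(lines)) {
      abort(sprintf("frame %d: truncated (expected %d atom lines)", fi, n),
            class = "ha_format_error")
    }
    body <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    m <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3, byrow = TRUE)
    if (anyNA(m)) {
      abort(sprintf("frame %d: malformed coordinate line", fi), class = "ha_format_error")
    }
    frames[[fi]] <- tibble(frame = fi, atom = seq_len(n),
                           x = m[, 1], y = m[, 2], z = m[, 3])
    pos <- pos + 2L + n
  }
  if (length(frames) == 0) abort("empty XYZ file", class = "ha_format_error")
  trajectory_window(topology, bind_rows(frames), box = ha_box(topology), dt = dt)
}

#' Load a trajectory from standard formats
#'
#' Dispatches on file extension: `.pdb` and `.gro` give single-frame windows
#' (GRO velocities attached and unit-converted), `.xyz` gives multi-frame
#' windows and requires `topology`. Atom counts are validated against the
#' topology; truncated files are rejected rather than partially read.
#'
#' @param paths one or more files (frames are concatenated in order).
#' @param topology an `ha_structure` (required for XYZ; overrides metadata
#'   for other formats when given).
#' @param dt frame spacing, ps.
#' @return an `ha_trajectory` in internal units (angstrom, ps).
#' @export
load_trajectory <- function(paths, topology = NULL, dt = 1) {
  windows <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    switch(ext,
      pdb = as_trajectory(read_structure_pdb(p)),
      gro = as_trajectory(read_gro(p)),
      xyz = {
        if (is.null(topology)) abort("XYZ input requires topology=", class = "ha_format_error")
        read_xyz(p, topology, dt = dt)
      },
      abort(paste0("unsupported trajectory format: .", ext), class = "ha_format_error")
    )
  })
  if (length(windows) == 1) {
    w <- windows[[1]]
    if (!is.null(topology) && tolower(tools::file_ext(paths[1])) != "xyz") {
      w$atoms <- as_tibble(topology)
    }
    w$dt <- dt
    return(w)
  }
  counts <- vapply(windows, function(w) nrow(w$atoms), integer(1))
  if (length(unique(counts)) > 1) {
    abort("atom counts differ across input files", class = "ha_format_error")
  }
  frames <- list()
  off <- 0L
  for (w in windows) {
    f <- w$frames
    f$frame <- f$frame + off
    off <- max(f$frame)
    frames[[length(frames) + 1L]] <- f
  }
  at <- topology %||% windows[[1]]$atoms
  trajectory_window(at, bind_rows(frames), box = windows[[1]]$box, dt = dt)
}

# ---- tabular / field exports -----------------------------------------------

#' Write a profile or table as TSV with a metadata header
#'
#' Metadata is written as leading `# key: value` comment lines so the file
#' stays a valid TSV for any reader that skips comments.
#'
#' @param x data frame.
#' @param path output file.
#' @param metadata named list written into the header.
#' @export
write_profile_tsv <- function(x, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k, paste(format(metadata[[k]]), collapse = " ")), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(x, format, trim = TRUE, scientific = FALSE), sep = "\t"))
  if (nrow(x) > 0) writeLines(body, con)
  invisible(path)
}

#' Export a 3D scalar field as OpenDX
#'
#' Regular-grid OpenDX text format readable by VMD/PyMOL.
#'
#' @param field an `ha_field` from [number_density()] or [charge_density()].
#' @param path output file.
#' @export
write_opendx <- function(field, path) {
  dims <- dim(field$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("origin %.6f %.6f %.6f", field$origin[1], field$origin[2], field$origin[3]),
    sprintf("delta %.6f 0 0", field$spacing),
    sprintf("delta 0 %.6f 0", field$spacing),
    sprintf("delta 0 0 %.6f", field$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(dims))
  ), con)
  vals <- as.numeric(aperm(field$values, c(3, 2, 1)))  # DX data is z-fastest
  grp <- split(vals, ceiling(seq_along(vals) / 3))
  writeLines(vapply(grp, function(g) paste(sprintf("%.8e", g), collapse = " "),
                    character(1)), con)
  writeLines(sprintf('attribute "dep" string "positions"'), con)
  invisible(path)
}
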