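## Water trajectory input/output. Two plain-text dialects: multi-model PDB
## (waters only, MODEL/ENDMDL) and a delimited frame table with columns
## frame, mol, atom (O/H1/H2), x, y, z.

.water_resnames <- c("HOH", "WAT", "TIP3", "SOL", "T3P")

#' Construct a water frame set
#'
#' @param waters data.frame with one row per water observation: columns
#'   `frame` (integer, 1..n_frames), `mol` (molecule id), `ox`,`oy`,`oz`,
#'   `h1x`..`h2z` (oxygen and hydrogen coordinates, Angstrom).
#' @param n_frames total frame count; defaults to `max(waters$frame)`.
#'   Frames with no pocket water are legal, so `n_frames` may exceed the
#'   number of distinct frame labels present.
#' @param validate check O-H bond lengths (must lie in 0.7--1.3 Angstrom,
#'   accommodating flexible-water models).
#' @return object of class `water_frames`.
#' @export
water_frames <- function(waters, n_frames = NULL, validate = TRUE) {
  need <- c("frame", "mol", "ox", "oy", "oz",
            "h1x", "h1y", "h1z", "h2x", "h2y", "h2z")
  miss <- setdiff(need, names(waters))
  if (length(miss)) stop("water table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(n_frames)) n_frames <- if (nrow(waters)) max(waters$frame) else 0L
  if (n_frames < 1L) stop("a water frame set needs at least one frame")
  if (validate && nrow(waters)) {
    d1 <- sqrt((waters$h1x - waters$ox)^2 + (waters$h1y - waters$oy)^2 +
                 (waters$h1z - waters$oz)^2)
    d2 <- sqrt((waters$h2x - waters$ox)^2 + (waters$h2y - waters$oy)^2 +
                 (waters$h2z - waters$oz)^2)
    bad <- which(d1 < 0.7 | d1 > 1.3 | d2 < 0.7 | d2 > 1.3)
    if (length(bad))
      stop("O-H bond length outside [0.7, 1.3] A for water mol ",
           waters$mol[bad[1]], " in frame ", waters$frame[bad[1]])
  }
  rownames(waters) <- NULL
  structure(list(n_frames = as.integer(n_frames), waters = waters),
            class = "water_frames")
}

#' Read a water trajectory
#'
#' @param path file path.
#' @param dialect `"multimodel-pdb"` (MODEL/ENDMDL blocks containing only
#'   water residues) or `"frame-table"` (delimited text, header columns
#'   `frame`, `mol`, `atom` in O/H1/H2, `x`, `y`, `z`). Frame labels in a
#'   table may start at any integer; they are renumbered 1..N preserving
#'   order, so a table with frames \{0, 1, 1\} yields `n_frames = 2`.
#' @return `water_frames` object.
#' @export
read_water_frames <- function(path, dialect = c("multimodel-pdb", "frame-table")) {
  dialect <- match.arg(dialect)
  if (dialect == "frame-table") .read_water_table(path) else .read_water_pdb(path)
}

.water_from_atom_records <- function(frame, mol, atom, x, y, z) {
  atom <- toupper(atom)
  atom[atom %in% c("OW", "OH2")] <- "O"
  atom[atom %in% c("HW1", "1H")] <- "H1"
  atom[atom %in% c("HW2", "2H")] <- "H2"
  key <- paste(frame, mol)
  parts <- split(seq_along(key), factor(key, levels = unique(key)))
  rows <- lapply(parts, function(idx) {
    if (length(idx) != 3L || !setequal(atom[idx], c("O", "H1", "H2")))
      stop("water mol ", mol[idx[1]], " in frame ", frame[idx[1]],
           " does not have exactly atoms O, H1, H2")
    io <- idx[atom[idx] == "O"]; i1 <- idx[atom[idx] == "H1"]
    i2 <- idx[atom[idx] == "H2"]
    data.frame(frame = frame[io], mol = mol[io],
               ox = x[io], oy = y[io], oz = z[io],
               h1x = x[i1], h1y = y[i1], h1z = z[i1],
               h2x = x[i2], h2y = y[i2], h2z = z[i2])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.read_water_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("frame", "mol", "atom", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("frame table must have columns: ", paste(need, collapse = ", "))
  lev <- sort(unique(tab$frame))
  fr <- match(tab$frame, lev)
  waters <- .water_from_atom_records(fr, tab$mol, tab$atom, tab$x, tab$y, tab$z)
  water_frames(waters, n_frames = length(lev))
}

.read_water_pdb <- function(path) {
  lines <- readLines(path)
  model <- 0L
  in_model <- FALSE
  frame <- integer(0); mol <- integer(0); atom <- character(0)
  x <- numeric(0); y <- numeric(0); z <- numeric(0)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1, 6)
    if (startsWith(tag, "MODEL")) {
      model <- model + 1L; in_model <- TRUE
    } else if (startsWith(tag, "ENDMDL")) {
      in_model <- FALSE
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      if (!in_model && model == 0L) model <- 1L
      resid <- trimws(substr(line, 18, 20))
      if (!resid %in% .water_resnames)
        stop("non-water residue '", resid, "' at line ", ln,
             " of water trajectory")
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                           substr(line, 39, 46),
                                           substr(line, 47, 54))))
      if (anyNA(xyz)) stop("malformed PDB coordinate field at line ", ln)
      frame <- c(frame, model)
      mol <- c(mol, as.integer(substr(line, 23, 26)))
      atom <- c(atom, trimws(substr(line, 13, 16)))
      x <- c(x, xyz[1]); y <- c(y, xyz[2]); z <- c(z, xyz[3])
    }
  }
  if (!length(frame)) stop("no water atoms found in ", path)
  waters <- .water_from_atom_records(frame, mol, atom, x, y, z)
  water_frames(waters, n_frames = max(model, 1L))
}

#' Write a water trajectory
#'
#' @param frames `water_frames` object.
#' @param path output path.
#' @param dialect output format, as in [read_water_frames()].
#' @export
write_water_frames <- function(frames, path,
                               dialect = c("multimodel-pdb", "frame-table")) {
  dialect <- match.arg(dialect)
  w <- frames$waters
  if (dialect == "frame-table") {
    long <- data.frame(
      frame = rep(w$frame, each = 3L),
      mol = rep(w$mol, each = 3L),
      atom = rep(c("O", "H1", "H2"), nrow(w)),
      x = as.vector(rbind(w$ox, w$h1x, w$h2x)),
      y = as.vector(rbind(w$oy, w$h1y, w$h2y)),
      z = as.vector(rbind(w$oz, w$h1z, w$h2z)))
    utils::write.table(format(long, digits = 15, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (f in seq_len(frames$n_frames)) {
      writeLines(sprintf("MODEL %8d", f), con)
      sub <- w[w$frame == f, , drop = FALSE]
      serial <- 0L
      for (i in seq_len(nrow(sub))) {
        coords <- rbind(c(sub$ox[i], sub$oy[i], sub$oz[i]),
                        c(sub$h1x[i], sub$h1y[i], sub$h1z[i]),
                        c(sub$h2x[i], sub$h2y[i], sub$h2z[i]))
        names3 <- c("O", "H1", "H2"); els <- c("O", "H", "H")
        for (a in 1:3) {
          serial <- serial + 1L
          writeLines(sprintf(
            "HETATM%5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, names3[a], "HOH", sub$mol[i] %% 10000L,
            coords[a, 1], coords[a, 2], coords[a, 3], els[a]), con)
        }
      }
      writeLines("ENDMDL", con)
    }
  }
  invisible(path)
}

#' @export
print.water_frames <- function(x, ...) {
  cat("water_frames:", x$n_frames, "frames,", nrow(x$waters),
      "water observations\n")
  invisible(x)
}
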