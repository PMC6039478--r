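## SDF V2000 ligand libraries. The reader keeps `M  CHG` formal-charge
## blocks and aromatic bond flags (bond type 4), both of which the feature
## perception rules depend on. Conformers of one ligand are grouped by
## identical title (or a data tag).

#' Construct a ligand record
#'
#' @param id ligand identifier.
#' @param label one of `"active"`, `"decoy"`, `"unknown"`.
#' @param conformers list of conformers; each is a list with `atoms`
#'   (data.frame: `element`, `x`, `y`, `z`, `charge`) and `bonds`
#'   (data.frame: `i`, `j`, `order`, `aromatic`). The bond graph must be
#'   identical across conformers.
#' @return object of class `ligand_record`.
#' @export
ligand_record <- function(id, label = "unknown", conformers = list()) {
  label <- match.arg(label, c("active", "decoy", "unknown"))
  if (!length(conformers)) stop("ligand '", id, "' has no conformers")
  ref <- conformers[[1]]
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    same <- nrow(cf$atoms) == nrow(ref$atoms) &&
      identical(cf$atoms$element, ref$atoms$element) &&
      identical(cf$bonds[c("i", "j", "order")], ref$bonds[c("i", "j", "order")])
    if (!same)
      stop("ligand '", id, "': bond graph differs between conformers 1 and ", k)
  }
  structure(list(id = id, label = label, conformers = conformers),
            class = "ligand_record")
}

.parse_sdf_block <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  at_lines <- lines[4 + seq_len(na)]
  atoms <- data.frame(
    element = trimws(substr(at_lines, 32, 34)),
    x = as.numeric(substr(at_lines, 1, 10)),
    y = as.numeric(substr(at_lines, 11, 20)),
    z = as.numeric(substr(at_lines, 21, 30)),
    charge = 0,
    stringsAsFactors = FALSE)
  bonds <- if (nb > 0) {
    bd_lines <- lines[4 + na + seq_len(nb)]
    type <- as.integer(substr(bd_lines, 7, 9))
    data.frame(i = as.integer(substr(bd_lines, 1, 3)),
               j = as.integer(substr(bd_lines, 4, 6)),
               order = ifelse(type == 4L, 1.5, type),
               aromatic = type == 4L)
  } else data.frame(i = integer(0), j = integer(0), order = numeric(0),
                    aromatic = logical(0))
  rest <- lines[-seq_len(4 + na + nb)]
  for (pl in grep("^M  CHG", rest, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(pl, 7, nchar(pl))), "\\s+")[[1]])
    n <- flds[1]
    for (k in seq_len(n)) atoms$charge[flds[2 * k]] <- flds[2 * k + 1]
  }
  tags <- list()
  tag_idx <- grep("^> ", rest)
  for (ti in tag_idx) {
    nm <- sub(".*<([^>]+)>.*", "\\1", rest[ti])
    if (ti + 1 <= length(rest)) tags[[nm]] <- rest[ti + 1]
  }
  list(title = trimws(lines[1]),
       conformer = list(atoms = atoms, bonds = bonds), tags = tags)
}

#' Read a ligand library from SDF (V2000)
#'
#' Conformers of the same ligand are grouped by identical molecule title,
#' or by the value of an SDF data tag if `group_by` is given. Molecules
#' whose coordinates are all-zero in z (2D depictions) trigger a warning
#' and, under `strict = TRUE`, are skipped.
#'
#' @param path SDF file path.
#' @param label label attached to all records: `"active"`, `"decoy"` or
#'   `"unknown"`. Alternatively a data tag name via `label_tag`.
#' @param group_by optional SDF data tag used as the grouping key.
#' @param label_tag optional SDF data tag holding per-molecule labels.
#' @param strict reject 2D molecules instead of keeping them.
#' @return list of [ligand_record()] objects.
#' @export
read_ligands <- function(path, label = "unknown", group_by = NULL,
                         label_tag = NULL, strict = FALSE) {
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) {
    warning("empty SDF file: ", path)
    return(list())
  }
  starts <- c(1L, ends[-length(ends)] + 1L)
  keys <- character(0); mols <- list(); labels <- character(0)
  for (b in seq_along(ends)) {
    blk <- lines[starts[b]:(ends[b] - 1L)]
    blk <- blk[nzchar(blk) | seq_along(blk) <= 3]
    if (length(blk) < 4) next
    parsed <- .parse_sdf_block(blk)
    if (all(abs(parsed$conformer$atoms$z) < 1e-9)) {
      warning("molecule '", parsed$title, "' looks 2D (all z = 0)",
              if (strict) "; skipped" else "")
      if (strict) next
    }
    key <- if (!is.null(group_by)) parsed$tags[[group_by]] else parsed$title
    if (is.null(key) || !nzchar(key)) key <- parsed$title
    lab <- if (!is.null(label_tag) && !is.null(parsed$tags[[label_tag]]))
      parsed$tags[[label_tag]] else label
    keys <- c(keys, key); labels <- c(labels, lab)
    mols[[length(mols) + 1L]] <- parsed$conformer
  }
  out <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    out[[length(out) + 1L]] <-
      ligand_record(key, labels[idx[1]], mols[idx])
  }
  out
}

#' Write a ligand library to SDF (V2000)
#'
#' @param records list of `ligand_record` objects.
#' @param path output path.
#' @param label_tag data tag under which each record's label is stored.
#' @export
write_ligands <- function(records, path, label_tag = "label") {
  con <- file(path, "w"); on.exit(close(con))
  for (rec in records) {
    for (cf in rec$conformers) {
      at <- cf$atoms; bd <- cf$bonds
      writeLines(rec$id, con)
      writeLines("  waterpharm", con)
      writeLines("", con)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(at), nrow(bd)), con)
      for (i in seq_len(nrow(at)))
        writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                           at$x[i], at$y[i], at$z[i], at$element[i]), con)
      for (i in seq_len(nrow(bd)))
        writeLines(sprintf("%3d%3d%3d  0  0  0  0", bd$i[i], bd$j[i],
                           if (bd$aromatic[i]) 4L else as.integer(bd$order[i])),
                   con)
      chg <- which(at$charge != 0)
      if (length(chg))
        writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                          paste0(sprintf("%4d%4d", chg, at$charge[chg]),
                                 collapse = "")), con)
      writeLines("M  END", con)
      writeLines(paste0(">  <", label_tag, ">"), con)
      writeLines(rec$label, con)
      writeLines("", con)
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}

#' @export
print.ligand_record <- function(x, ...) {
  cat("ligand_record '", x$id, "' (", x$label, "): ",
      length(x$conformers), " conformer(s), ",
      nrow(x$conformers[[1]]$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}
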