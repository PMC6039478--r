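## Pharmacophore model container and its on-disk format ("wpm/1"): a
## versioned, human-readable text file; one `feature` line per feature,
## `meta` lines for provenance.

.feature_types <- c("A", "D", "H", "R", "N", "P")
.directed_types <- c("A", "D", "R")

#' Construct a pharmacophore model
#'
#' @param features data.frame with columns `id` (character), `type` (one of
#'   A/D/H/R/N/P), `x`,`y`,`z` (Angstrom), `dx`,`dy`,`dz` (unit direction,
#'   `NA` when absent; required for A, D and R, forbidden otherwise), `tol`
#'   (tolerance radius, Angstrom) and `sites` (comma-joined source site
#'   ids). Zero rows give a valid empty model.
#' @param meta named list of character scalars (target name, thresholds,
#'   creation parameters). `max_features` (default 8) bounds the feature
#'   count.
#' @return object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features = NULL, meta = list()) {
  if (is.null(features))
    features <- data.frame(id = character(0), type = character(0),
                           x = numeric(0), y = numeric(0), z = numeric(0),
                           dx = numeric(0), dy = numeric(0), dz = numeric(0),
                           tol = numeric(0), sites = character(0),
                           stringsAsFactors = FALSE)
  max_features <- as.integer(meta$max_features %||% 8L)
  if (nrow(features) > max_features)
    stop("model has ", nrow(features), " features; maximum is ", max_features)
  bad <- setdiff(features$type, .feature_types)
  if (length(bad)) stop("unknown feature type code(s): ", paste(bad, collapse = ", "))
  has_dir <- !is.na(features$dx)
  need_dir <- features$type %in% .directed_types
  if (any(has_dir != need_dir))
    stop("direction vectors must be present exactly for types ",
         paste(.directed_types, collapse = "/"))
  if (any(need_dir)) {
    nrm <- sqrt(features$dx[need_dir]^2 + features$dy[need_dir]^2 +
                  features$dz[need_dir]^2)
    if (any(abs(nrm - 1) > 1e-6)) stop("direction vectors must be unit length")
  }
  meta$max_features <- as.character(max_features)
  rownames(features) <- NULL
  structure(list(features = features, meta = meta),
            class = "pharmacophore_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature string of a model
#'
#' The sorted type letters of the model's features (e.g. `"ADDHHH"`), the
#' conventional shorthand for a pharmacophore hypothesis.
#'
#' @param model `pharmacophore_model`.
#' @return character scalar (empty string for an empty model).
#' @export
feature_string <- function(model) {
  paste(sort(model$features$type), collapse = "")
}

.fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))

#' Write a pharmacophore model file
#'
#' @param model `pharmacophore_model`.
#' @param path output path (conventionally `.wpm`).
#' @export
write_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# waterpharm pharmacophore model", con)
  writeLines("format: wpm/1", con)
  for (nm in names(model$meta))
    writeLines(paste0("meta\t", nm, "\t", model$meta[[nm]]), con)
  f <- model$features
  for (i in seq_len(nrow(f))) {
    sites <- if (is.na(f$sites[i]) || !nzchar(f$sites[i])) "." else f$sites[i]
    writeLines(paste("feature", f$id[i], f$type[i],
                     .fmt_num(f$x[i]), .fmt_num(f$y[i]), .fmt_num(f$z[i]),
                     .fmt_num(f$dx[i]), .fmt_num(f$dy[i]), .fmt_num(f$dz[i]),
                     .fmt_num(f$tol[i]), sites, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a pharmacophore model file
#'
#' @param path path to a `wpm/1` file written by [write_model()].
#' @return `pharmacophore_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^format: wpm/1", lines)))
    stop("not a waterpharm model file (missing 'format: wpm/1'): ", path)
  meta <- list()
  rows <- list()
  for (line in lines) {
    if (startsWith(line, "meta\t")) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      meta[[parts[2]]] <- if (length(parts) >= 3) parts[3] else ""
    } else if (startsWith(line, "feature\t")) {
      p <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(p) != 11) stop("malformed feature line: ", line)
      if (!p[3] %in% .feature_types)
        stop("unknown feature type code '", p[3], "' in ", path)
      num <- function(s) if (s == ".") NA_real_ else as.numeric(s)
      rows[[length(rows) + 1L]] <- data.frame(
        id = p[2], type = p[3], x = num(p[4]), y = num(p[5]), z = num(p[6]),
        dx = num(p[7]), dy = num(p[8]), dz = num(p[9]), tol = num(p[10]),
        sites = if (p[11] == ".") "" else p[11], stringsAsFactors = FALSE)
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  pharmacophore_model(features, meta)
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("pharmacophore_model:", nrow(x$features), "feature(s)")
  if (nrow(x$features)) cat(" [", feature_string(x), "]", sep = "")
  cat("\n")
  if (nrow(x$features)) {
    f <- x$features
    for (i in seq_len(nrow(f)))
      cat(sprintf("  %-4s %s  (%7.2f, %7.2f, %7.2f)  tol %.2f\n",
                  f$id[i], f$type[i], f$x[i], f$y[i], f$z[i], f$tol[i]))
  }
  invisible(x)
}
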