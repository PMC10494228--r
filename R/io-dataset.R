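## Dataset I/O. Abstract model coordinates travel as CSV (columns x1..xd,
## E1..En); molecular data travel as extended XYZ with the n energies in
## per-frame comment-line fields E0=..., E1=..., .... Numbers are written
## with 17 significant digits so write -> read round trips are bit exact.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a dataset to CSV or extended XYZ
#'
#' @param dataset a \linkS4class{SampledDataset}.
#' @param path output file path.
#' @param format \code{"csv"} (model coordinates) or \code{"extxyz"}
#'   (molecular data; requires element symbols in the dataset).
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(dataset, path, format = c("csv", "extxyz")) {
  format <- match.arg(format)
  if (!is(dataset, "SampledDataset"))
    stopInput("'dataset' must be a SampledDataset")
  X <- coords(dataset); E <- energies(dataset)
  if (format == "csv") {
    header <- c(paste0("x", seq_len(ncol(X))), paste0("E", seq_len(ncol(E))))
    lines <- c(paste(header, collapse = ","),
               vapply(seq_len(nrow(X)), function(i)
                 paste(.fmt(c(X[i, ], E[i, ])), collapse = ","),
                 character(1)))
    writeLines(lines, path)
  } else {
    els <- elements(dataset)
    if (!length(els))
      stopInput("extxyz output requires element symbols in the dataset")
    nAtoms <- length(els)
    lines <- character(0)
    for (i in seq_len(nrow(X))) {
      efields <- paste0("E", seq_len(ncol(E)) - 1L, "=", .fmt(E[i, ]),
                        collapse = " ")
      pos <- matrix(X[i, ], ncol = 3L, byrow = TRUE)
      lines <- c(lines, as.character(nAtoms),
                 paste0("Properties=species:S:1:pos:R:3 ", efields),
                 vapply(seq_len(nAtoms), function(a)
                   paste(els[a], paste(.fmt(pos[a, ]), collapse = " ")),
                   character(1)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a dataset from CSV or extended XYZ
#'
#' Energies are re-sorted ascending on load; a warning names the rows or
#' frames whose stored order was not ascending. Malformed rows are reported
#' with their line numbers.
#'
#' @param path input file path.
#' @param format \code{"csv"} or \code{"extxyz"}.
#' @return a \linkS4class{SampledDataset}.
#' @export
readDataset <- function(path, format = c("csv", "extxyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopInput("file not found: %s", path)
  lines <- readLines(path)
  last <- max(0L, which(nzchar(trimws(lines))))   # drop trailing blanks
  lines <- lines[seq_len(last)]
  if (!length(lines))
    stopInput("empty dataset: %s contains no data", path)
  if (format == "csv") .readCSVDataset(lines, path) else
    .readExtXYZDataset(lines, path)
}

.readCSVDataset <- function(lines, path) {
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  xCols <- grep("^x[0-9]+$", header)
  eCols <- grep("^E[0-9]+$", header)
  if (!length(xCols) || length(eCols) < 2L)
    stopInput("%s: header must contain columns x1..xd and E1..En", path)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stopInput("empty dataset: %s has a header but no rows", path)
  vals <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    if (length(f) != length(header))
      stopInput("%s line %d: expected %d fields, found %d",
                path, i + 1L, length(header), length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stopInput("%s line %d: non-numeric field", path, i + 1L)
    v
  })
  M <- do.call(rbind, vals)
  X <- M[, xCols, drop = FALSE]
  E <- M[, eCols, drop = FALSE]
  E <- .resortEnergies(E, paste("row(s)"))
  colnames(X) <- header[xCols]; colnames(E) <- paste0("E", seq_len(ncol(E)))
  new("SampledDataset", coords = X, energies = E, elements = character(),
      provenance = list(generator = "readDataset", path = path))
}

.resortEnergies <- function(E, what) {
  bad <- which(apply(E, 1L, is.unsorted))
  if (length(bad)) {
    warning(sprintf("energies re-sorted ascending in %s %s", what,
                    paste(utils::head(bad, 5L), collapse = ", ")))
    E[bad, ] <- t(apply(E[bad, , drop = FALSE], 1L, sort))
  }
  E
}

.readExtXYZDataset <- function(lines, path) {
  i <- 1L; frame <- 0L
  coordsList <- list(); energyList <- list(); els <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nAtoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nAtoms) || nAtoms < 1L)
      stopInput("%s line %d (frame %d): expected an atom count",
                path, i, frame)
    if (i + 1L + nAtoms > length(lines))
      stopInput("%s frame %d: truncated (needs %d atom lines)",
                path, frame, nAtoms)
    comment <- lines[i + 1L]
    eMatches <- regmatches(comment,
      gregexpr("E[0-9]+=[-+0-9.eE]+", comment))[[1L]]
    if (length(eMatches) < 2L)
      stopInput("%s frame %d: expected at least 2 energy fields E0=, E1=, ...; found %d",
                path, frame, length(eMatches))
    idx <- as.integer(sub("=.*", "", sub("^E", "", eMatches)))
    ev <- as.numeric(sub("^E[0-9]+=", "", eMatches))[order(idx)]
    if (!identical(sort(idx), seq_len(length(idx)) - 1L))
      stopInput("%s frame %d: energy fields must be E0..E%d",
                path, frame, length(idx) - 1L)
    fEls <- character(nAtoms); pos <- matrix(0, nAtoms, 3L)
    for (a in seq_len(nAtoms)) {
      f <- strsplit(trimws(lines[i + 1L + a]), "[[:space:]]+")[[1L]]
      if (length(f) < 4L)
        stopInput("%s line %d (frame %d): malformed atom line",
                  path, i + 1L + a, frame)
      fEls[a] <- f[1L]
      p <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(p))
        stopInput("%s line %d (frame %d): non-numeric coordinates",
                  path, i + 1L + a, frame)
      pos[a, ] <- p
    }
    if (is.null(els)) els <- fEls
    else if (!identical(els, fEls))
      stopInput("%s frame %d: element list differs from frame 1", path, frame)
    if (length(energyList) && length(ev) != length(energyList[[1L]]))
      stopInput("%s frame %d: inconsistent number of energies (%d vs %d)",
                path, frame, length(ev), length(energyList[[1L]]))
    coordsList[[frame]] <- as.numeric(t(pos))
    energyList[[frame]] <- ev
    i <- i + 2L + nAtoms
  }
  E <- do.call(rbind, energyList)
  E <- .resortEnergies(E, "frame(s)")
  colnames(E) <- paste0("E", seq_len(ncol(E)))
  new("SampledDataset", coords = do.call(rbind, coordsList), energies = E,
      elements = els,
      provenance = list(generator = "readDataset", path = path))
}
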