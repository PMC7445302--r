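#' Write conformations as a multi-frame XYZ file
#'
#' Standard XYZ: per frame an atom-count line, a comment line carrying the
#' architecture, seed and frame index, then one `ELEM x y z` line per bead
#' with 6 decimal places. The core bead is labelled `N` for visibility, all
#' other beads `C`. Three-dimensional conformations only.
#'
#' @param confs a `"conformation"` or a list of them (e.g. from
#'   [simulate.rosette_topology()] or [run_md()] frames).
#' @param path output file path.
#' @param seed optional seed to record in the comment line (defaults to the
#'   `"seed"` attribute of `confs` if present).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(confs, path, seed = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  stopifnot(is.list(confs), length(confs) >= 1)
  if (is.null(seed)) seed <- attr(confs, "seed")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  for (i in seq_along(confs)) {
    cf <- confs[[i]]
    stopifnot(inherits(cf, "conformation"))
    x <- cf$coords
    if (ncol(x) != 3) stop("XYZ output requires dim = 3")
    top <- cf$topology
    writeLines(as.character(nrow(x)), con)
    writeLines(sprintf("fc=%d fr=%d n=%d seed=%s frame=%d",
                       top$fc, top$fr, top$n,
                       if (is.null(seed)) "NA" else format(seed), i), con)
    elem <- c("N", rep("C", nrow(x) - 1L))
    writeLines(sprintf("%s %.6f %.6f %.6f", elem, x[, 1], x[, 2], x[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' Companion reader for [write_xyz()] round trips.
#'
#' @param path file path.
#' @return List of coordinate matrices, each with the comment line stored in
#'   attribute `"comment"`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    m <- as.integer(lines[i])
    comment <- lines[i + 1L]
    block <- lines[i + 1L + seq_len(m)]
    parts <- strsplit(trimws(block), "\\s+")
    x <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    attr(x, "comment") <- comment
    frames[[length(frames) + 1L]] <- x
    i <- i + 2L + m
  }
  frames
}

#' Write a results table as CSV with a configuration header
#'
#' Writes comment lines (`# key: value`) recording the package version and
#' the supplied configuration, followed by a standard CSV table. Headers are
#' ignored by [read_results()].
#'
#' @param records data frame of results (may have zero rows).
#' @param path output file path.
#' @param config named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, config = list()) {
  stopifnot(is.data.frame(records))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(sprintf("# rosette %s",
                     as.character(utils::packageVersion("rosette"))), con)
  for (nm in names(config)) {
    writeLines(sprintf("# %s: %s", nm, paste(format(config[[nm]]),
                                             collapse = " ")), con)
  }
  write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path file path.
#' @return Data frame (header comment lines skipped).
#' @export
read_results <- function(path) {
  read.csv(path, comment.char = "#")
}
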