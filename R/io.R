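## Trajectory readers/writers.
##
## Extended-XYZ dialect: per-atom extra columns are declared in the comment
## line via Properties=species:S:1:pos:R:3[:charge:R:1][:dipole_sta:R:3]
## [:dipole_ind:R:3], with Lattice="ax ay az bx by bz cx cy cz" and Time=<ps>.
## Tinker ARC carries positions only (electrostatics, if needed, are supplied
## separately).

## parse key=value tokens of an extxyz comment line, honouring quotes
parse_extxyz_comment <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

parse_properties_schema <- function(s) {
  toks <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(toks) %% 3 != 0)
    stop("malformed Properties schema: ", s)
  n <- length(toks) / 3
  data.frame(name = toks[3 * seq_len(n) - 2],
             type = toks[3 * seq_len(n) - 1],
             ncol = as.integer(toks[3 * seq_len(n)]),
             stringsAsFactors = FALSE)
}

lattice_to_box <- function(s) {
  v <- as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  if (length(v) != 9) stop("Lattice must contain 9 numbers")
  m <- matrix(v, 3, 3, byrow = TRUE)
  if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-10))
    stop("triclinic boxes are not supported; box must be orthorhombic")
  diag(m)
}

read_extxyz_frames <- function(lines) {
  frames <- list()
  i <- 1L; fidx <- 0L
  nlines <- length(lines)
  while (i <= nlines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      stop(sprintf("parse error at frame %d: invalid atom count line '%s'", fidx, lines[i]))
    if (i + 1L + nat > nlines)
      stop(sprintf("structural error at frame %d: expected %d atom lines, file truncated", fidx, nat))
    meta <- parse_extxyz_comment(lines[i + 1L])
    if (is.null(meta$Lattice))
      stop(sprintf("parse error at frame %d: missing Lattice", fidx))
    box <- lattice_to_box(meta$Lattice)
    schema <- parse_properties_schema(
      if (!is.null(meta$Properties)) meta$Properties else "species:S:1:pos:R:3")
    ncols <- sum(schema$ncol)
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(toks) != ncols)
    if (length(bad))
      stop(sprintf("structural error at frame %d: atom line %d has %d fields, expected %d",
                   fidx, bad[1], lengths(toks)[bad[1]], ncols))
    tab <- matrix(unlist(toks), nrow = nat, byrow = TRUE)
    col <- 1L
    species <- NULL; pos <- NULL; charges <- NULL; dsta <- NULL; dind <- NULL
    time <- if (!is.null(meta$Time)) as.numeric(meta$Time) else fidx - 1
    for (r in seq_len(nrow(schema))) {
      cols <- col:(col + schema$ncol[r] - 1L); col <- col + schema$ncol[r]
      block <- tab[, cols, drop = FALSE]
      if (schema$type[r] == "R") {
        block <- matrix(as.numeric(block), nrow = nat)
        if (any(is.na(block)))
          stop(sprintf("parse error at frame %d: non-numeric value in column '%s'", fidx, schema$name[r]))
      }
      switch(schema$name[r],
             species = { species <- block[, 1] },
             pos = { pos <- block },
             charge = { charges <- block[, 1] },
             dipole_sta = { dsta <- block },
             dipole_ind = { dind <- block })
    }
    if (is.null(pos))
      stop(sprintf("parse error at frame %d: Properties lacks a pos field", fidx))
    frames[[fidx]] <- list(
      frame = cr_frame(pos, box, time = time, charges = charges,
                       dipoles_static = dsta, dipoles_induced = dind),
      species = species)
    i <- i + 2L + nat
  }
  frames
}

read_arc_frames <- function(lines) {
  frames <- list()
  i <- 1L; fidx <- 0L
  nlines <- length(lines)
  is_box_line <- function(s) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
    length(v) == 6 && !any(is.na(v))
  }
  while (i <= nlines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nat <- suppressWarnings(as.integer(hdr[1]))
    if (is.na(nat) || nat <= 0L)
      stop(sprintf("parse error at frame %d: invalid ARC header '%s'", fidx, lines[i]))
    i <- i + 1L
    box <- NULL
    if (i <= nlines && is_box_line(lines[i])) {
      v <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      if (any(abs(v[4:6] - 90) > 1e-6))
        stop("triclinic boxes are not supported; box angles must be 90 degrees")
      box <- v[1:3]
      i <- i + 1L
    }
    if (is.null(box))
      stop(sprintf("structural error at frame %d: ARC frame lacks a periodic box line", fidx))
    if (i + nat - 1L > nlines)
      stop(sprintf("structural error at frame %d: expected %d atom lines, file truncated", fidx, nat))
    toks <- strsplit(trimws(lines[i:(i + nat - 1L)]), "\\s+")
    bad <- which(lengths(toks) < 6L)
    if (length(bad))
      stop(sprintf("structural error at frame %d: atom line %d is too short", fidx, bad[1]))
    species <- vapply(toks, function(t) gsub("[0-9].*$", "", t[2]), character(1))
    pos <- t(vapply(toks, function(t) as.numeric(t[3:5]), numeric(3)))
    if (any(is.na(pos)))
      stop(sprintf("parse error at frame %d: non-numeric coordinate", fidx))
    frames[[fidx]] <- list(frame = cr_frame(pos, box, time = fidx - 1),
                           species = species)
    i <- i + nat
  }
  frames
}

#' Read a trajectory file
#'
#' Supports extended-XYZ (with optional declared per-atom charge/dipole
#' columns) and Tinker ARC (positions only). Methanol-like topology is
#' inferred from the element pattern when no topology is supplied.
#'
#' @param path file path.
#' @param format `"extxyz"` or `"tinker-arc"`; `"auto"` guesses from the file
#'   extension (`.arc` is Tinker, anything else extended-XYZ).
#' @param topology optional [cr_topology()] overriding inference.
#' @param field optional [cr_field()] attached to the trajectory.
#' @return a [cr_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "extxyz", "tinker-arc"),
                            topology = NULL, field = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.arc$", path, ignore.case = TRUE)) "tinker-arc" else "extxyz"
  lines <- readLines(path)
  parsed <- switch(format,
                   "extxyz" = read_extxyz_frames(lines),
                   "tinker-arc" = read_arc_frames(lines))
  if (length(parsed) == 0L) stop("no frames found in ", path)
  counts <- vapply(parsed, function(p) nrow(p$frame$positions), integer(1))
  if (length(unique(counts)) != 1L)
    stop(sprintf("structural error at frame %d: atom count %d differs from frame 1 (%d)",
                 which(counts != counts[1])[1], counts[counts != counts[1]][1], counts[1]))
  if (is.null(topology)) topology <- cr_topology(parsed[[1]]$species)
  cr_trajectory(lapply(parsed, `[[`, "frame"), topology = topology, field = field)
}

#' Write a trajectory as extended-XYZ
#'
#' Emits one extended-XYZ block per frame with a `Properties` schema declaring
#' any charge/dipole columns present, and `Lattice`/`Time` metadata.
#'
#' @param traj a [cr_trajectory()] with a topology.
#' @param path output file path.
#' @param digits number of significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(traj, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  elements <- traj$topology$elements
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  for (fr in traj$frames) {
    n <- nrow(fr$positions)
    props <- "species:S:1:pos:R:3"
    cols <- list(elements, fmt(fr$positions))
    if (!is.null(fr$charges)) {
      props <- paste0(props, ":charge:R:1")
      cols <- c(cols, list(fmt(fr$charges)))
    }
    if (!is.null(fr$dipoles_static)) {
      props <- paste0(props, ":dipole_sta:R:3")
      cols <- c(cols, list(fmt(fr$dipoles_static)))
    }
    if (!is.null(fr$dipoles_induced)) {
      props <- paste0(props, ":dipole_ind:R:3")
      cols <- c(cols, list(fmt(fr$dipoles_induced)))
    }
    lat <- paste(fmt(diag(fr$box) |> as.numeric()), collapse = " ")
    writeLines(as.character(n), con)
    writeLines(sprintf('Lattice="%s" Properties=%s Time=%s',
                       lat, props, fmt(fr$time)), con)
    mat <- do.call(cbind, lapply(cols, function(x) {
      if (is.matrix(x)) x else matrix(x, ncol = 1)
    }))
    writeLines(apply(mat, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Compute the polarization time series of a trajectory
#'
#' Applies [box_polarization()] to every frame.
#'
#' @param traj a [cr_trajectory()] whose frames carry charges.
#' @return data.frame with columns `time`, `Px`, `Py`, `Pz` (ps, e*Angstrom).
#' @export
polarization_series <- function(traj) {
  P <- t(vapply(traj$frames, box_polarization, numeric(3)))
  data.frame(time = frame_times(traj), Px = P[, 1], Py = P[, 2], Pz = P[, 3])
}
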