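## File formats: two-column decay text, GRO / PDB coordinates (PDB is the
## only Angstrom surface; everything internal is nm), delimited topology
## and moiety tables, YAML run configuration.

#' Write a decay curve as two-column delimited text
#'
#' Header comment lines carry the lifetime, Forster radius and channel
#' width when present in the metadata. Counts are written when available,
#' otherwise the normalized intensity.
#'
#' @param decay a \code{\link{DecayCurve}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDecay <- function(decay, path) {
  stopifnot(is(decay, "DecayCurve"))
  md <- decay@metadata
  hdr <- c("# nanoFRET decay curve",
           sprintf("# channel_ns = %.10g", decay@channelWidth))
  if (!is.null(md$tauD)) hdr <- c(hdr, sprintf("# tauD_ns = %.10g", md$tauD))
  if (!is.null(md$R0)) hdr <- c(hdr, sprintf("# R0_nm = %.10g", md$R0))
  useCounts <- length(decay@counts) > 0
  hdr <- c(hdr, sprintf("# columns = time_ns %s",
                        if (useCounts) "counts" else "intensity"))
  val <- if (useCounts) decay@counts else decay@intensity
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.10g\t%.10g", decay@time, val), con)
  invisible(path)
}

#' Read a decay curve from two-column delimited text
#'
#' Accepts the format written by \code{\link{writeDecay}}: optional
#' \code{#} comment header, then one \code{time value} pair per line.
#' Metadata present in the header is parsed; header-less files are
#' accepted with metadata marked absent. Non-monotone time grids and
#' negative counts produce errors naming the first offending line.
#'
#' @param path input file.
#' @param counts logical; interpret the value column as photon counts
#'   (default: taken from the header, else counts when all values are
#'   integers).
#' @return A \code{\link{DecayCurve}}.
#' @export
readDecay <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("decay file not found: ", path)
  lines <- readLines(path)
  isHdr <- grepl("^\\s*#", lines)
  md <- list()
  for (h in lines[isHdr]) {
    m <- regmatches(h, regexec("#\\s*([A-Za-z0-9_]+)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[3]))
      md[[m[2]]] <- if (is.na(v)) m[3] else v
    }
  }
  dataLineNo <- which(!isHdr & nzchar(trimws(lines)))
  if (length(dataLineNo) < 2L) stop("decay file has fewer than 2 data rows")
  parts <- strsplit(trimws(lines[dataLineNo]), "[\\s,;]+", perl = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop("line ", dataLineNo[bad[1]], ": expected two columns")
  tv <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1:2])),
               numeric(2))
  nonNum <- which(apply(is.na(tv), 2L, any))
  if (length(nonNum))
    stop("line ", dataLineNo[nonNum[1]], ": non-numeric value")
  t <- tv[1, ]; v <- tv[2, ]
  nm <- which(diff(t) <= 0)
  if (length(nm))
    stop("line ", dataLineNo[nm[1] + 1L],
         ": time grid not strictly increasing")
  isCounts <- if (!is.null(counts)) counts
  else if (!is.null(md$columns)) identical(md$columns, "counts") ||
    grepl("counts", paste(lines[isHdr], collapse = " "))
  else all(v == round(v)) && max(v) > 1
  neg <- which(v < 0)
  if (length(neg) && isCounts)
    stop("line ", dataLineNo[neg[1]], ": negative counts")
  cw <- if (!is.null(md$channel_ns)) md$channel_ns else t[2] - t[1]
  keep <- md[setdiff(names(md), c("columns", "channel_ns"))]
  names(keep) <- sub("_ns$|_nm$", "", names(keep))
  if (isCounts)
    DecayCurve(t, counts = v, channelWidth = cw, metadata = keep)
  else DecayCurve(t, intensity = v, channelWidth = cw, metadata = keep)
}

## ---------------------------------------------------------------------
## Coordinate files

.parseGROFrame <- function(lines, start) {
  n <- as.integer(trimws(lines[start + 1L]))
  if (is.na(n)) stop("GRO: bad atom count at line ", start + 1L)
  rows <- lines[(start + 2L):(start + 1L + n)]
  coords <- t(vapply(rows, function(l) {
    c(as.numeric(substr(l, 21, 28)), as.numeric(substr(l, 29, 36)),
      as.numeric(substr(l, 37, 44)))
  }, numeric(3)))
  resname <- trimws(substr(rows, 6, 10))
  atomname <- trimws(substr(rows, 11, 15))
  resid <- as.integer(substr(rows, 1, 5))
  boxLine <- strsplit(trimws(lines[start + 2L + n]), "\\s+")[[1]]
  box <- as.numeric(boxLine[1:3])
  rownames(coords) <- NULL
  list(coords = coords, box = box, resname = resname,
       atomname = atomname, resid = resid, nextStart = start + 3L + n)
}

#' Read GRO or PDB coordinates (multi-frame accepted)
#'
#' Coordinates are returned in nm regardless of dialect (PDB Angstroms are
#' divided by 10); the periodic box comes from the GRO box line or the PDB
#' \code{CRYST1} record (0 when absent). All frames must have the same
#' atom count.
#'
#' @param path coordinate file.
#' @param dialect \code{"auto"} (by extension), \code{"gro"} or
#'   \code{"pdb"}.
#' @return List with \code{frames} (list of n x 3 matrices, nm),
#'   \code{box} (length 3, nm), \code{atomname}, \code{resname},
#'   \code{resid}.
#' @export
readStructure <- function(path, dialect = c("auto", "gro", "pdb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb"
               else "gro"
  if (dialect == "gro") .readGRO(path) else .readPDB(path)
}

.readGRO <- function(path) {
  lines <- readLines(path)
  frames <- list(); meta <- NULL
  start <- 1L
  while (start <= length(lines) && nzchar(trimws(lines[start]))) {
    fr <- .parseGROFrame(lines, start)
    if (is.null(meta)) meta <- fr
    else if (nrow(fr$coords) != nrow(meta$coords))
      stop("GRO: atom count differs between frames")
    frames[[length(frames) + 1L]] <- fr$coords
    start <- fr$nextStart
    while (start <= length(lines) && !nzchar(trimws(lines[start])))
      start <- start + 1L
  }
  list(frames = frames, box = meta$box, atomname = meta$atomname,
       resname = meta$resname, resid = meta$resid)
}

.readPDB <- function(path) {
  lines <- readLines(path)
  box <- c(0, 0, 0)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr))
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33))) / 10
  frames <- list(); cur <- list(); meta <- NULL
  atomname <- character(); resname <- character(); resid <- integer()
  flush <- function() {
    if (!length(cur)) return()
    m <- do.call(rbind, cur)
    if (length(frames) && nrow(m) != nrow(frames[[1]]))
      stop("PDB: atom count differs between MODEL frames")
    frames[[length(frames) + 1L]] <<- m
    cur <<- list()
  }
  for (l in lines) {
    rec <- substr(l, 1, 6)
    if (rec == "ATOM  " || rec == "HETATM") {
      xyz <- as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                          substr(l, 47, 54))) / 10
      cur[[length(cur) + 1L]] <- xyz
      if (!length(frames)) {
        atomname <- c(atomname, trimws(substr(l, 13, 16)))
        resname <- c(resname, trimws(substr(l, 18, 21)))
        resid <- c(resid, suppressWarnings(as.integer(substr(l, 23, 26))))
      }
    } else if (rec == "ENDMDL") flush()
  }
  flush()
  if (!length(frames)) stop("PDB: no ATOM records in ", path)
  list(frames = frames, box = box, atomname = atomname,
       resname = resname, resid = resid)
}

#' Write coordinates in GRO or PDB dialect
#'
#' @param coords n x 3 matrix (nm) or list of such matrices (multi-frame).
#' @param box length-3 box (nm).
#' @param path output file.
#' @param dialect \code{"gro"} or \code{"pdb"} (PDB written in Angstroms).
#' @param atomname,resname,resid per-atom annotation (defaults generated).
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(coords, box, path, dialect = c("gro", "pdb"),
                           atomname = NULL, resname = NULL, resid = NULL) {
  dialect <- match.arg(dialect)
  frames <- .asFrameList(coords)
  n <- nrow(frames[[1]])
  if (is.null(atomname)) atomname <- sprintf("A%d", seq_len(n) %% 1000)
  if (is.null(resname)) resname <- rep("MOL", n)
  if (is.null(resid)) resid <- rep(1L, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (dialect == "gro") {
      writeLines(sprintf("nanoFRET frame %d", f), con)
      writeLines(sprintf("%5d", n), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         resid %% 100000, substr(resname, 1, 5),
                         substr(atomname, 1, 5), seq_len(n) %% 100000,
                         m[, 1], m[, 2], m[, 3]), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]),
                 con)
    } else {
      if (f == 1L && any(box > 0))
        writeLines(sprintf(
          "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
          box[1] * 10, box[2] * 10, box[3] * 10), con)
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(n) %% 100000, substr(atomname, 1, 4),
        substr(resname, 1, 4), resid %% 10000,
        m[, 1] * 10, m[, 2] * 10, m[, 3] * 10), con)
      writeLines("ENDMDL", con)
    }
  }
  if (dialect == "pdb") writeLines("END", con)
  invisible(path)
}

#' Read a delimited topology (atoms + bonds) table
#'
#' The atoms table needs columns \code{atom, element, charge, sigma,
#' epsilon, mol, species}; the optional bonds table has two atom-id
#' columns. En-dash/minus variants in numeric columns are normalized.
#'
#' @param atomsPath delimited atoms table (whitespace, comma or tab).
#' @param bondsPath optional delimited bonds table.
#' @return A \code{\link{Topology}}.
#' @export
readTopology <- function(atomsPath, bondsPath = NULL) {
  atoms <- .readDelim(atomsPath)
  for (cn in c("charge", "sigma", "epsilon"))
    if (is.character(atoms[[cn]]))
      atoms[[cn]] <- as.numeric(.normalizeMinus(atoms[[cn]]))
  bonds <- if (!is.null(bondsPath)) as.matrix(.readDelim(bondsPath)[, 1:2])
           else matrix(integer(), ncol = 2)
  Topology(atoms, bonds)
}

#' Read a delimited atom-to-moiety map
#'
#' @param path table with columns \code{atom}, \code{moiety}.
#' @return A \code{\link{MoietyMap}}.
#' @export
readMoietyMap <- function(path) {
  tab <- .readDelim(path)
  MoietyMap(tab$atom, tab$moiety)
}

.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  read.table(path, header = TRUE, sep = sep, comment.char = "#",
             stringsAsFactors = FALSE)
}

## en-dash / typographic-minus normalization for numeric table input
.normalizeMinus <- function(x) {
  gsub("−|–|—", "-", x)
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration holds the stage parameters and the master seed;
#' every CLI run writes its resolved configuration beside its outputs so
#' reruns are reproducible from the config alone.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname readRunConfig
#' @param config named list to serialize.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## ---------------------------------------------------------------------
## Configuration snapshots

#' Write / read configuration snapshots as delimited text
#'
#' One record per disc (\code{x_nm, y_nm}) or per probe (\code{kind, x_nm,
#' y_nm, leaflet, in_domain}), tab-separated with a comment header
#' carrying the box, radius and bilayer separation, so simulated
#' geometries can be archived and re-read losslessly.
#'
#' @param object a \code{\link{DomainConfiguration}} or
#'   \code{\link{ProbeConfiguration}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSnapshot <- function(object, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is(object, "DomainConfiguration")) {
    writeLines(c("# nanoFRET domain snapshot",
                 sprintf("# boxLength_nm = %.10g", object@boxLength),
                 sprintf("# radius_nm = %.10g", object@radius),
                 "x_nm\ty_nm"), con)
    if (nrow(object@centers))
      writeLines(sprintf("%.10g\t%.10g", object@centers[, 1],
                         object@centers[, 2]), con)
  } else if (is(object, "ProbeConfiguration")) {
    writeLines(c("# nanoFRET probe snapshot",
                 sprintf("# boxLength_nm = %.10g", object@boxLength),
                 sprintf("# bilayerSep_nm = %.10g", object@bilayerSep),
                 "kind\tx_nm\ty_nm\tleaflet\tin_domain"), con)
    row <- function(kind, xy, leaf, ind)
      sprintf("%s\t%.10g\t%.10g\t%d\t%d", kind, xy[, 1], xy[, 2],
              leaf, as.integer(ind))
    if (nrow(object@donorXY))
      writeLines(row("donor", object@donorXY, object@donorLeaflet,
                     object@donorInDomain), con)
    if (nrow(object@acceptorXY))
      writeLines(row("acceptor", object@acceptorXY,
                     object@acceptorLeaflet, object@acceptorInDomain),
                 con)
  } else stop("unsupported snapshot object: ", class(object))
  invisible(path)
}

#' @rdname writeSnapshot
#' @export
readSnapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("#\\s*([A-Za-z0-9_]+)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- as.numeric(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  tab <- read.table(text = body, header = TRUE, sep = "\t")
  if (grepl("domain snapshot", lines[1])) {
    new("DomainConfiguration",
        centers = if (nrow(tab)) as.matrix(tab[, c("x_nm", "y_nm")])
                  else matrix(numeric(), ncol = 2),
        radius = meta$radius_nm, boxLength = meta$boxLength_nm)
  } else {
    d <- tab[tab$kind == "donor", ]
    a <- tab[tab$kind == "acceptor", ]
    new("ProbeConfiguration",
        donorXY = unname(as.matrix(d[, c("x_nm", "y_nm")])),
        donorLeaflet = as.integer(d$leaflet),
        donorInDomain = as.logical(d$in_domain),
        acceptorXY = unname(as.matrix(a[, c("x_nm", "y_nm")])),
        acceptorLeaflet = as.integer(a$leaflet),
        acceptorInDomain = as.logical(a$in_domain),
        boxLength = meta$boxLength_nm, bilayerSep = meta$bilayerSep_nm)
  }
}
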