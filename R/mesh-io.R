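## mesh_core: mesh file I/O. Native text format and Gmsh MSH v2 ASCII.
##
## Native text layout:
##   header line:  "<ntets> <nverts>"
##   nverts lines: "x y z"
##   ntets lines:  four zero-based vertex indices
## Indices are zero-based on disk, one-based in memory. Connectivity is never
## read from a file; it is rebuilt by tetMesh().

#' Read a tetrahedral mesh from file
#'
#' @param path file path.
#' @param format \code{"auto"} (sniff), \code{"text"} (native format) or
#'   \code{"msh2"} (Gmsh MSH v2 ASCII, volume elements of type 4).
#' @return a \linkS4class{TetMesh}.
#' @export
readMesh <- function(path, format = c("auto", "text", "msh2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && grepl("^\\$MeshFormat", first)) "msh2" else "text"
  }
  switch(format, text = readMeshText(path), msh2 = readMeshMsh2(path))
}

#' Write a tetrahedral mesh to file
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param path output path.
#' @param format \code{"text"} or \code{"msh2"}.
#' @return invisibly \code{path}.
#' @export
writeMesh <- function(mesh, path, format = c("text", "msh2")) {
  format <- match.arg(format)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(nTets(mesh), nVertices(mesh)), con)
    writeLines(apply(format(mesh@vertices, digits = 17, trim = TRUE,
                            scientific = FALSE), 1L, paste, collapse = " "), con)
    writeLines(apply(mesh@tets - 1L, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
                 as.character(nVertices(mesh))), con)
    writeLines(paste(seq_len(nVertices(mesh)),
                     apply(format(mesh@vertices, digits = 17, trim = TRUE,
                                  scientific = FALSE), 1L, paste, collapse = " ")),
               con)
    writeLines(c("$EndNodes", "$Elements", as.character(nTets(mesh))), con)
    ## elm-number elm-type(4=tet) number-of-tags tag.. node-list (one-based)
    writeLines(paste(seq_len(nTets(mesh)), 4L, 2L, 0L, 0L,
                     apply(mesh@tets, 1L, paste, collapse = " ")), con)
    writeLines("$EndElements", con)
  }
  invisible(path)
}

readMeshText <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty mesh file ", path)
  hdr <- scan(text = lines[1L], quiet = TRUE)
  if (length(hdr) != 2L || any(hdr < 0) || any(hdr != floor(hdr)))
    stop("parse error at line 1: header must be 'ntets nverts'")
  ntets <- as.integer(hdr[1L]); nverts <- as.integer(hdr[2L])
  if (length(lines) < 1L + nverts + ntets)
    stop("parse error: expected ", 1L + nverts + ntets, " lines, found ",
         length(lines))
  vl <- lines[1L + seq_len(nverts)]
  verts <- matrix(0, nverts, 3L)
  for (i in seq_len(nverts)) {
    x <- suppressWarnings(scan(text = vl[i], quiet = TRUE))
    if (length(x) != 3L || any(is.na(x)))
      stop("parse error at line ", 1L + i, ": expected 3 coordinates")
    verts[i, ] <- x
  }
  tl <- lines[1L + nverts + seq_len(ntets)]
  tets <- matrix(0L, ntets, 4L)
  for (i in seq_len(ntets)) {
    x <- suppressWarnings(scan(text = tl[i], quiet = TRUE))
    if (length(x) != 4L || any(is.na(x)) || any(x != floor(x)))
      stop("parse error at line ", 1L + nverts + i,
           ": expected 4 zero-based vertex indices")
    tets[i, ] <- as.integer(x) + 1L
  }
  tetMesh(verts, tets)
}

readMeshMsh2 <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    beg <- which(lines == paste0("$", name))
    end <- which(lines == paste0("$End", name))
    if (length(beg) != 1L || length(end) != 1L || end <= beg)
      stop("unsupported-format error: missing $", name, " section")
    lines[(beg + 1L):(end - 1L)]
  }
  nodes <- sect("Nodes")
  nn <- as.integer(nodes[1L])
  nod <- scan(text = nodes[1L + seq_len(nn)], quiet = TRUE)
  nod <- matrix(nod, nn, 4L, byrow = TRUE)
  ## node ids may be sparse; map id -> row
  idmap <- integer(max(nod[, 1L]))
  idmap[as.integer(nod[, 1L])] <- seq_len(nn)
  verts <- nod[, 2:4, drop = FALSE]
  elems <- sect("Elements")
  ne <- as.integer(elems[1L])
  tets <- vector("list", ne)
  nt <- 0L
  for (i in seq_len(ne)) {
    x <- scan(text = elems[1L + i], quiet = TRUE)
    type <- as.integer(x[2L]); ntags <- as.integer(x[3L])
    nodesOf <- x[(4L + ntags):length(x)]
    if (type == 4L) {
      if (length(nodesOf) != 4L)
        stop("parse error: tetrahedron element with ", length(nodesOf), " nodes")
      nt <- nt + 1L
      tets[[nt]] <- idmap[as.integer(nodesOf)]
    }
    ## other element types (points, lines, triangles) are surface/markup
    ## entities and are skipped; they do not define the volume mesh
  }
  if (nt == 0L)
    stop("unsupported-format error: no tetrahedral (type 4) elements in ", path)
  tets <- do.call(rbind, tets[seq_len(nt)])
  tetMesh(verts, tets)
}
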