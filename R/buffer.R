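## partition_parallel: the remote change buffer.
##
## An append-only vector of (destination tet, species, accumulated change)
## integer triples, one buffer per (source rank, neighbour rank) pair. For
## each (tet', S) the registering side keeps a location marker pointing at
## where that pair's entry was last stored. On registration the entry at the
## marked location is compared against (tet', S): a match means accumulate
## in place; a mismatch means the buffer has been flushed (reset) since the
## marker was written, so a fresh entry is appended and the marker updated.
## Both paths are amortized constant time. A buffer is cleared by flushing,
## so its live size is bounded by (#remotely hosted neighbour tets) x
## (#diffusive species) and is zero when no cross-rank diffusion occurred.

#' Create an empty remote change buffer
#'
#' @return a \code{RemoteChangeBuffer} (environment-backed, mutated in
#'   place by \code{\link{registerRemoteChange}} and
#'   \code{\link{flushBuffer}}).
#' @export
newRemoteChangeBuffer <- function() {
  b <- new.env(parent = emptyenv())
  b$dest <- integer(0)
  b$species <- integer(0)
  b$m <- integer(0)
  b$markers <- new.env(parent = emptyenv(), hash = TRUE)
  class(b) <- "RemoteChangeBuffer"
  b
}

#' Register an accumulated remote molecule change
#'
#' @param buffer a \code{RemoteChangeBuffer}.
#' @param tet destination tet id (1-based, hosted by the receiving rank).
#' @param species species index (1-based).
#' @param delta molecule count change, >= 1.
#' @return invisibly the buffer.
#' @export
registerRemoteChange <- function(buffer, tet, species, delta) {
  if (delta < 1) stop("delta must be >= 1")
  key <- paste0(tet, ".", species)
  idx <- buffer$markers[[key]]
  if (!is.null(idx) && idx <= length(buffer$dest) &&
      buffer$dest[idx] == tet && buffer$species[idx] == species) {
    buffer$m[idx] <- buffer$m[idx] + as.integer(delta)
  } else {
    ## marker stale (buffer was flushed since) or never set: append
    buffer$dest <- c(buffer$dest, as.integer(tet))
    buffer$species <- c(buffer$species, as.integer(species))
    buffer$m <- c(buffer$m, as.integer(delta))
    buffer$markers[[key]] <- length(buffer$dest)
  }
  invisible(buffer)
}

#' Number of live entries
#' @param buffer a \code{RemoteChangeBuffer}.
#' @return integer.
#' @export
bufferSize <- function(buffer) length(buffer$dest)

#' Current live entries without flushing
#' @param buffer a \code{RemoteChangeBuffer}.
#' @return integer matrix with columns tet, species, m.
#' @export
bufferEntries <- function(buffer) {
  cbind(tet = buffer$dest, species = buffer$species, m = buffer$m)
}

#' Flush a buffer: return its entries and clear it
#'
#' Markers are left in place; subsequent registrations detect the reset via
#' the entry-data mismatch and append fresh entries.
#'
#' @param buffer a \code{RemoteChangeBuffer}.
#' @return integer matrix with columns tet, species, m (possibly 0 rows).
#' @export
flushBuffer <- function(buffer) {
  out <- bufferEntries(buffer)
  buffer$dest <- integer(0)
  buffer$species <- integer(0)
  buffer$m <- integer(0)
  out
}

#' @export
print.RemoteChangeBuffer <- function(x, ...) {
  cat("RemoteChangeBuffer:", bufferSize(x), "live entries\n")
  invisible(x)
}
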