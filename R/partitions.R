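## Compact per-frame partition series.
##
## Long runs are represented by an N x F integer membership matrix (0 = lone,
## k = chain index within the frame, labels dense per column) plus frame
## times, instead of a list of full partition objects. Both forms are
## accepted by the lifecycle functions.

#' Normalize partitions to a compact membership series
#'
#' @param x a list of `cr_chain_partition` (from [find_chains()]), an
#'   `cr_kmc_run`, or an N x F integer membership matrix.
#' @param times frame times (ps); defaults to 0, 1, ... when not available
#'   from `x`.
#' @return an object of class `cr_partition_series`: list with `membership`
#'   (N x F integer matrix, dense labels per column) and `times`.
#' @export
as_partition_series <- function(x, times = NULL) {
  if (inherits(x, "cr_partition_series")) {
    if (!is.null(times)) x$times <- times
    return(x)
  }
  if (inherits(x, "cr_kmc_run")) {
    return(structure(list(membership = x$membership, times = x$times),
                     class = "cr_partition_series"))
  }
  if (is.matrix(x)) {
    m <- x
  } else if (is.list(x) && length(x) && inherits(x[[1]], "cr_chain_partition")) {
    m <- vapply(x, `[[`, integer(x[[1]]$n_molecules), "membership")
    if (x[[1]]$n_molecules == 1L) m <- matrix(m, nrow = 1)
  } else {
    stop("cannot interpret x as a partition series")
  }
  storage.mode(m) <- "integer"
  # densify labels per column
  for (f in seq_len(ncol(m))) {
    col <- m[, f]
    pos <- col > 0L
    if (any(pos)) {
      ids <- sort(unique(col[pos]))
      if (length(ids) != max(ids)) m[pos, f] <- match(col[pos], ids)
    }
  }
  if (is.null(times)) times <- seq_len(ncol(m)) - 1
  if (length(times) != ncol(m)) stop("times must match the number of frames")
  structure(list(membership = m, times = as.numeric(times)),
            class = "cr_partition_series")
}

#' @export
print.cr_partition_series <- function(x, ...) {
  cat(sprintf("<cr_partition_series> %d molecules x %d frames\n",
              nrow(x$membership), ncol(x$membership)))
  invisible(x)
}
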