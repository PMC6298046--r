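#' Label connected components of a binary mask
#'
#' Deterministic connected-component labeling on a logical matrix using
#' iterative minimum-label propagation: every foreground pixel starts with
#' its own linear index as label and repeatedly takes the minimum label over
#' its neighborhood until a fixed point is reached. Components are then
#' renumbered 1, 2, ... in order of their first (row-major) pixel.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param connectivity 8 (default, includes diagonals) or 4.
#' @return integer matrix of the same shape; 0 = background, k = component k.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  mask <- mask != 0
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  lab <- matrix(Inf, nr, nc)  # background = Inf so it never propagates
  lab[mask] <- which(mask)    # column-major linear index as provisional label

  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- shift_matrix(lab, s[1], s[2], fill = Inf)
      sh[!mask] <- Inf
      upd <- mask & (sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber in row-major order of first appearance
  rm_order <- as.vector(t(lab))
  ids <- unique(rm_order[is.finite(rm_order)])
  out <- matrix(0L, nr, nc)
  out[mask] <- match(lab[mask], ids)
  out
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}

#' Sizes of labeled components
#' @param lab integer label matrix from [label_components()].
#' @return named integer vector of component sizes (names = labels).
#' @export
component_sizes <- function(lab) {
  v <- lab[lab > 0]
  if (!length(v)) return(integer(0))
  tab <- tabulate(v)
  stats::setNames(tab, seq_along(tab))
}

# Count, for each foreground pixel, the number of foreground neighbors.
neighbor_counts <- function(mask, connectivity = 8L) {
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  cnt <- matrix(0, nrow(mask), ncol(mask))
  m <- mask * 1
  for (s in shifts) cnt <- cnt + shift_matrix(m, s[1], s[2], fill = 0)
  cnt
}
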