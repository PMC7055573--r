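# Connected-component machinery with explicit 4/8-connectivity. Masks are
# H x W integer matrices indexed column-major; the frontier-based BFS below
# expands whole frontiers at once so labeling stays fast on full-size cubes.

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  } else {
    stop("invalid input: connectivity must be 4 or 8", call. = FALSE)
  }
}

# Neighbors of linear indices `idx` inside an h x w grid, deduplicated.
grid_neighbors <- function(idx, h, w, offsets) {
  if (length(idx) == 0) return(integer(0))
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  out <- integer(0)
  for (off in offsets) {
    r <- rows + off[1L]; c_ <- cols + off[2L]
    ok <- r >= 1L & r <= h & c_ >= 1L & c_ <= w
    out <- c(out, (c_[ok] - 1L) * h + r[ok])
  }
  unique(out)
}

#' Label connected foreground components of a binary mask
#'
#' @param mask A [label_mask()] or binary matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + corner neighbors).
#' @return Integer matrix of component labels (0 = background), with
#'   components numbered in order of their first pixel in column-major scan.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- as_mask_matrix(mask)
  offsets <- neighbor_offsets(connectivity)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  todo <- which(m == 1L)
  cur <- 0L
  for (seed_px in todo) {
    if (lab[seed_px] != 0L) next
    cur <- cur + 1L
    frontier <- seed_px
    lab[frontier] <- cur
    while (length(frontier) > 0) {
      nb <- grid_neighbors(frontier, h, w, offsets)
      nb <- nb[m[nb] == 1L & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Fill enclosed background holes in a binary mask
#'
#' A hole is a background region not reachable from the image border under
#' the background connectivity. Background is flood-filled from every border
#' background pixel; unreached background pixels are set to foreground.
#' Foreground is never removed, and masks without holes pass through
#' unchanged.
#'
#' @param mask A [label_mask()] or binary matrix.
#' @param connectivity Background connectivity, 4 (default) or 8. The default
#'   4 pairs with 8-connected foreground, the standard duality that avoids
#'   topological paradoxes.
#' @return A [label_mask()] with holes filled.
#' @export
fill_holes <- function(mask, connectivity = 4) {
  m <- as_mask_matrix(mask)
  id <- if (inherits(mask, "label_mask")) mask$id else "mask"
  offsets <- neighbor_offsets(connectivity)
  h <- nrow(m); w <- ncol(m)
  border <- unique(c(seq_len(h), (w - 1L) * h + seq_len(h),
                     (seq_len(w) - 1L) * h + 1L, (seq_len(w) - 1L) * h + h))
  reached <- matrix(FALSE, h, w)
  frontier <- border[m[border] == 0L]
  reached[frontier] <- TRUE
  while (length(frontier) > 0) {
    nb <- grid_neighbors(frontier, h, w, offsets)
    nb <- nb[m[nb] == 0L & !reached[nb]]
    reached[nb] <- TRUE
    frontier <- nb
  }
  filled <- m
  filled[m == 0L & !reached] <- 1L
  label_mask(filled, id = id)
}

#' Keep only the largest connected foreground component
#'
#' Components are measured in pixels; ties go to the component whose
#' smallest `(row, col)` pixel is lexicographically smallest. An empty mask
#' returns empty with a warning (an empty detection is a valid, if poor,
#' outcome).
#'
#' @param mask A [label_mask()] or binary matrix.
#' @param connectivity Foreground connectivity, 8 (default) or 4.
#' @return An object of class `refined_mask`: `mask` (a [label_mask()]),
#'   `n_components_before`, `filled_pixels` (0 here; see [refine()]).
#' @export
largest_component <- function(mask, connectivity = 8) {
  m <- as_mask_matrix(mask)
  id <- if (inherits(mask, "label_mask")) mask$id else "mask"
  lab <- label_components(m, connectivity)
  n_comp <- max(lab)
  if (n_comp == 0L) {
    warning("empty mask: no foreground component to keep", call. = FALSE)
    return(structure(list(mask = label_mask(m * 0L, id = id),
                          n_components_before = 0L, filled_pixels = 0L),
                     class = "refined_mask"))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # anchor = first pixel of the component in row-major (row, col) order
    h <- nrow(m)
    anchors <- vapply(best, function(k) {
      idx <- which(lab == k)
      rows <- ((idx - 1L) %% h) + 1L
      cols <- ((idx - 1L) %/% h) + 1L
      min((rows - 1L) * ncol(m) + cols)
    }, numeric(1))
    best <- best[which.min(anchors)]
  }
  keep <- (lab == best) * 1L
  structure(list(mask = label_mask(matrix(keep, nrow(m)), id = id),
                 n_components_before = n_comp, filled_pixels = 0L),
            class = "refined_mask")
}

#' Refine a binary detection mask
#'
#' The morphological clean-up applied to pixel-wise detections: fill enclosed
#' holes, then keep the biggest connected component. The result has exactly
#' one hole-free component (or none, if the input was empty) and the
#' operation is idempotent.
#'
#' @param mask A [label_mask()] or binary matrix.
#' @param fg_connectivity Foreground connectivity for component labeling
#'   (default 8).
#' @param bg_connectivity Background connectivity for hole filling
#'   (default 4).
#' @return An object of class `refined_mask` with elements `mask`
#'   (a [label_mask()]), `n_components_before` (component count after hole
#'   filling) and `filled_pixels` (background pixels converted by the fill).
#' @export
refine <- function(mask, fg_connectivity = 8, bg_connectivity = 4) {
  m <- as_mask_matrix(mask)
  filled <- fill_holes(mask, connectivity = bg_connectivity)
  out <- largest_component(filled, connectivity = fg_connectivity)
  out$filled_pixels <- sum(filled$mask) - sum(m)
  out
}

#' @export
print.refined_mask <- function(x, ...) {
  cat(sprintf("<refined_mask '%s'> %d px kept of %d component(s), %d hole px filled\n",
              x$mask$id, sum(x$mask$mask), x$n_components_before,
              x$filled_pixels))
  invisible(x)
}
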