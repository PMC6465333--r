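#' Cell geometry: matched 2D cell and nucleus label masks
#'
#' Holds a 2D cell label mask and a nucleus label mask with identical labels
#' (nucleus `i` belongs to cell `i`), mirroring the common analysis design of
#' 2D outlines applied to 3D spot data. The cytoplasm of a cell is its cell
#' area minus its nucleus; per-cell analyses are restricted to the cytoplasm.
#' Cells whose cytoplasm is empty are retained in the masks but flagged
#' non-analysable in the report.
#'
#' @param cells integer matrix of cell labels (0 = background).
#' @param nuclei integer matrix of nucleus labels, same shape, labels matched
#'   to `cells`.
#' @return An object of class `cell_geometry` with fields `cells`, `nuclei`,
#'   `labels` (analysable labels) and `report` (per-label data frame with
#'   areas and diagnostics).
#' @seealso [load_geometry()] for matching independently labelled masks.
#' @export
cell_geometry <- function(cells, nuclei) {
  stopifnot(is.matrix(cells), is.matrix(nuclei),
            all(dim(cells) == dim(nuclei)))
  storage.mode(cells) <- "integer"
  storage.mode(nuclei) <- "integer"
  labs <- sort(setdiff(unique(as.vector(cells)), 0L))
  nuc_labs <- sort(setdiff(unique(as.vector(nuclei)), 0L))
  if (length(setdiff(nuc_labs, labs)))
    stop("nucleus labels without a matching cell label: ",
         paste(setdiff(nuc_labs, labs), collapse = ", "))
  # nucleus must lie inside its cell
  bad <- nuclei > 0L & cells != nuclei
  if (any(bad))
    stop(sum(bad), " nucleus pixel(s) fall outside the matching cell; ",
         "use load_geometry() to reconcile independently drawn masks")
  rep <- data.frame(
    label = labs,
    cell_area = vapply(labs, function(l) sum(cells == l), integer(1)),
    nucleus_area = vapply(labs, function(l) sum(nuclei == l), integer(1))
  )
  rep$cytoplasm_area <- rep$cell_area - rep$nucleus_area
  rep$analysable <- rep$cytoplasm_area > 0L & rep$nucleus_area > 0L
  rep$note <- ifelse(rep$analysable, "",
                     ifelse(rep$nucleus_area == 0L, "no nucleus",
                            "empty cytoplasm"))
  structure(list(cells = cells, nuclei = nuclei,
                 labels = rep$label[rep$analysable], report = rep),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> %d x %d px, %d cell(s), %d analysable\n",
              nrow(x$cells), ncol(x$cells), nrow(x$report), length(x$labels)))
  invisible(x)
}

#' Logical cytoplasm mask of one cell
#'
#' @param geometry a [cell_geometry()].
#' @param cell_id cell label.
#' @return Logical matrix, `TRUE` on cytoplasm pixels of `cell_id`.
#' @export
cytoplasm_mask <- function(geometry, cell_id) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (!cell_id %in% geometry$report$label)
    stop("unknown cell_id ", cell_id, "; valid labels: ",
         paste(geometry$report$label, collapse = ", "))
  geometry$cells == cell_id & geometry$nuclei != cell_id
}

#' Build a `cell_geometry` from independently labelled cell and nucleus masks
#'
#' Intended for manually outlined cells and nuclei, whose label numbering is
#' arbitrary. Each nucleus is matched to the cell label covering most of its
#' area; matched pairs are relabelled `1..K` consistently. Nuclei overlapping
#' no cell are rejected, nucleus pixels spilling outside the matched cell are
#' clipped, and cells without any nucleus are dropped; all such events appear
#' in the returned report. Applying the function to its own output is the
#' identity.
#'
#' @param cell_mask integer label matrix or path to a label TIFF.
#' @param nucleus_mask integer label matrix or path, same shape.
#' @return A [cell_geometry()]; its `report` gains `orig_cell_label`,
#'   `orig_nucleus_label` and `clipped_px` columns, and an attribute
#'   `rejected` lists dropped labels with reasons.
#' @export
load_geometry <- function(cell_mask, nucleus_mask) {
  if (is.character(cell_mask)) cell_mask <- read_label_mask(cell_mask)
  if (is.character(nucleus_mask)) nucleus_mask <- read_label_mask(nucleus_mask)
  stopifnot(is.matrix(cell_mask), is.matrix(nucleus_mask),
            all(dim(cell_mask) == dim(nucleus_mask)))
  storage.mode(cell_mask) <- "integer"
  storage.mode(nucleus_mask) <- "integer"

  nuc_labs <- sort(setdiff(unique(as.vector(nucleus_mask)), 0L))
  rejected <- data.frame(kind = character(), label = integer(),
                         reason = character())
  pairs <- list()
  taken <- integer()
  for (nl in nuc_labs) {
    sel <- nucleus_mask == nl
    over <- cell_mask[sel]
    over <- over[over > 0L]
    if (!length(over)) {
      rejected <- rbind(rejected, data.frame(
        kind = "nucleus", label = nl, reason = "no overlapping cell"))
      next
    }
    tab <- sort(table(over), decreasing = TRUE)
    cl <- as.integer(names(tab)[1])
    if (cl %in% taken) {
      rejected <- rbind(rejected, data.frame(
        kind = "nucleus", label = nl,
        reason = sprintf("cell %d already matched to another nucleus", cl)))
      next
    }
    taken <- c(taken, cl)
    pairs[[length(pairs) + 1L]] <- c(nucleus = nl, cell = cl)
  }
  cell_labs <- sort(setdiff(unique(as.vector(cell_mask)), 0L))
  for (cl in setdiff(cell_labs, taken))
    rejected <- rbind(rejected, data.frame(
      kind = "cell", label = cl, reason = "no nucleus"))

  new_cells <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  new_nuclei <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  clipped <- integer(length(pairs))
  orig_c <- orig_n <- integer(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    orig_n[i] <- p[["nucleus"]]; orig_c[i] <- p[["cell"]]
    cs <- cell_mask == p[["cell"]]
    ns <- nucleus_mask == p[["nucleus"]]
    clipped[i] <- sum(ns & !cs)
    new_cells[cs] <- i
    new_nuclei[ns & cs] <- i
  }
  geom <- cell_geometry(new_cells, new_nuclei)
  ord <- match(geom$report$label, seq_along(pairs))
  geom$report$orig_cell_label <- orig_c[ord]
  geom$report$orig_nucleus_label <- orig_n[ord]
  geom$report$clipped_px <- clipped[ord]
  attr(geom, "rejected") <- rejected
  geom
}
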