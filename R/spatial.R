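#' Sliding-window spatial incidence design
#'
#' Builds the 11 incidence matrices of the cross-shaped spatial sliding
#' window used by the field-trial mixed model: each plot is linked to a
#' shared spatial-effect vector `s` (one effect per grid position) at the
#' plot itself plus 10 neighbouring positions -- three up and three down
#' the column, two left and two right along the row.  Edge plots link to
#' fewer positions (out-of-field neighbours are dropped).
#'
#' @param layout data frame with integer `row` and `col` plot coordinates
#'   (one row per plot, in observation order).
#' @return list with `S` (list of 11 sparse incidence matrices, plots x
#'   positions), `W` (their sum: total incidence, at most 11 ones per
#'   row), `positions` (data frame of grid positions indexing `s`) and
#'   `offsets`.
#' @export
build_spatial_design <- function(layout) {
  stopifnot(all(c("row", "col") %in% names(layout)))
  rows <- as.integer(layout$row); cols <- as.integer(layout$col)
  if (length(unique(rows)) < 2 && length(unique(cols)) < 2)
    stop("spatial window needs at least 2 rows or 2 columns")
  pos <- unique(data.frame(row = rows, col = cols))
  pos <- pos[order(pos$row, pos$col), , drop = FALSE]
  rownames(pos) <- NULL
  key <- function(r, c) paste(r, c, sep = "_")
  pos_index <- stats::setNames(seq_len(nrow(pos)), key(pos$row, pos$col))
  offsets <- rbind(
    c(0, 0),
    c(-1, 0), c(-2, 0), c(-3, 0),
    c(1, 0), c(2, 0), c(3, 0),
    c(0, -1), c(0, -2),
    c(0, 1), c(0, 2))
  n <- length(rows)
  S <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    r <- rows + offsets[i, 1]
    c <- cols + offsets[i, 2]
    j <- unname(pos_index[key(r, c)])
    keep <- !is.na(j)
    S[[i]] <- Matrix::sparseMatrix(i = which(keep), j = j[keep], x = 1,
                                   dims = c(n, nrow(pos)))
  }
  W <- Reduce(`+`, S)
  list(S = S, W = W, positions = pos, offsets = offsets)
}
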