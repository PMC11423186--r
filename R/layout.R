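#' Electrode layouts
#'
#' An electrode layout is a tibble with one row per recording element and
#' columns `electrode_id` (integer label), `x_um`, `y_um` (positions in
#' micrometres) and `is_reference` (logical). Positions must be unique and at
#' least 1 µm apart. [electrode_layout()] validates an arbitrary table;
#' [grid_layout()] builds a rectangular grid; [default_mea_layout()] is the
#' 32-element chip geometry used throughout: a 6 x 6 grid at 200 µm pitch with
#' the four corners absent, so 32 electrodes interrogate a
#' 1000 µm x 1000 µm region.
#'
#' @param electrode_id Integer electrode labels.
#' @param x_um,y_um Electrode positions in µm.
#' @param is_reference Logical; reference (non-recording) electrodes.
#' @return A tibble of class `electrode_layout`.
#' @examples
#' layout <- default_mea_layout()
#' nrow(layout) # 32
#' @export
electrode_layout <- function(electrode_id, x_um, y_um, is_reference = FALSE) {
  lay <- tibble::tibble(
    electrode_id = as.integer(electrode_id),
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um),
    is_reference = rep_len(as.logical(is_reference), length(electrode_id))
  )
  if (nrow(lay) == 0) abort("layout must contain at least one electrode")
  if (anyDuplicated(lay$electrode_id)) abort("electrode ids must be unique")
  if (anyNA(lay$x_um) || anyNA(lay$y_um)) abort("electrode positions must be finite")
  if (nrow(lay) > 1) {
    d <- as.matrix(stats::dist(cbind(lay$x_um, lay$y_um)))
    diag(d) <- Inf
    if (min(d) < 1) abort("electrode positions must be pairwise >= 1 um apart")
  }
  class(lay) <- c("electrode_layout", class(lay))
  lay
}

#' @rdname electrode_layout
#' @param nx,ny Number of columns / rows of the grid.
#' @param pitch_um Electrode pitch in µm (default 200).
#' @export
grid_layout <- function(nx, ny, pitch_um = 200) {
  g <- expand.grid(col = seq_len(nx) - 1L, row = seq_len(ny) - 1L)
  electrode_layout(
    electrode_id = seq_len(nrow(g)),
    x_um = g$col * pitch_um,
    y_um = g$row * pitch_um
  )
}

#' @rdname electrode_layout
#' @export
default_mea_layout <- function() {
  g <- expand.grid(col = 0:5, row = 0:5)
  corner <- (g$col %in% c(0, 5)) & (g$row %in% c(0, 5))
  g <- g[!corner, ]
  electrode_layout(
    electrode_id = seq_len(nrow(g)),
    x_um = g$col * 200,
    y_um = g$row * 200
  )
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf(
    "<electrode_layout> %d electrodes, span %g x %g um\n",
    nrow(x), diff(range(x$x_um)), diff(range(x$y_um))
  ))
  NextMethod()
}

layout_subset <- function(layout, ids) {
  keep <- layout$electrode_id %in% ids
  if (!any(keep)) abort("no electrodes left after subsetting layout")
  out <- layout[keep, , drop = FALSE]
  class(out) <- unique(c("electrode_layout", class(out)))
  out
}
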