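#' Electrode layout of a 6 x 10 epiretinal array
#'
#' Builds the electrode site table of an Argus II-style microelectrode array:
#' sixty 200 um platinum discs in a 6 x 10 rectangular grid at 525 um pitch,
#' labelled A1-F10 (rows A-F, columns 1-10), centred on the origin of the
#' retinal plane.
#'
#' @param pitch_um centre-to-centre electrode spacing (um); must exceed the
#'   electrode diameter.
#' @param diameter_um electrode disc diameter (um).
#' @return An object of class `array_layout`: a list with `electrodes`
#'   (data.frame with `label`, `row`, `col`, `x_mm`, `y_mm`, `diameter_um`),
#'   `pitch_um`, `diameter_um`, and `substrate_outline` (matrix of polygon
#'   vertices, mm).
#' @examples
#' lay <- make_argus2_layout()
#' nrow(lay$electrodes)  # 60
#' @export
make_argus2_layout <- function(pitch_um = 525, diameter_um = 200) {
  stopifnot(pitch_um > diameter_um, diameter_um > 0)
  rows <- 6L
  cols <- 10L
  pitch_mm <- pitch_um / 1000
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  electrodes <- data.frame(
    label = paste0(LETTERS[grid$row], grid$col),
    row = grid$row,
    col = grid$col,
    x_mm = (grid$col - (cols + 1) / 2) * pitch_mm,
    y_mm = (grid$row - (rows + 1) / 2) * pitch_mm,
    diameter_um = diameter_um,
    stringsAsFactors = FALSE
  )
  margin <- pitch_mm / 2 + diameter_um / 1000
  xr <- range(electrodes$x_mm) + c(-margin, margin)
  yr <- range(electrodes$y_mm) + c(-margin, margin)
  outline <- cbind(
    x_mm = c(xr[1], xr[2], xr[2], xr[1]),
    y_mm = c(yr[1], yr[1], yr[2], yr[2])
  )
  structure(
    list(electrodes = electrodes, pitch_um = pitch_um,
         diameter_um = diameter_um, substrate_outline = outline),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("<array_layout> %d electrodes, %g um discs at %g um pitch\n",
              nrow(x$electrodes), x$diameter_um, x$pitch_um))
  invisible(x)
}

layout_electrode <- function(layout, label) {
  i <- match(label, layout$electrodes$label)
  if (is.na(i)) stop("unknown electrode label: ", label)
  layout$electrodes[i, ]
}
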