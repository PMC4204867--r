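#' Compute the vocal tract area function for one control frame
#'
#' Maps the seven articulatory parameters (jaw, tongue dorsum position and
#' shape, tongue apex, lip aperture, lip protrusion, larynx height) through
#' the linear-component coefficient table to per-section cross-sectional
#' areas, clamps negative areas to zero (reported as closure / touch), and
#' scales areas and lengths by the configured tract scale. The
#' velopharyngeal port area maps affinely from p10 in \[-1, 1\] to
#' \[0, maxPortArea\].
#'
#' @param frame a control frame (see [controlFrame()]).
#' @param config a [SynthConfig-class].
#' @return an [AreaFunction-class] object.
#' @examples
#' af <- computeAreaFunction(controlFrame(rep(0, 10)), synthConfig())
#' all(sectionAreas(af) > 0)
#' @export
computeAreaFunction <- function(frame, config) {
  p <- controlFrame(frame)
  co <- config@coefficients
  areas <- co[, "neutral_area"] +
    co[, "jaw"] * p[1] + co[, "dorsum_pos"] * p[2] +
    co[, "dorsum_shape"] * p[3] + co[, "apex"] * p[4] +
    co[, "lip_aperture"] * p[5]
  areas <- pmax(0, areas) * config@tractScale
  baseLen <- config@tractLength / nrow(co) * config@tractScale
  lengths <- baseLen *
    pmax(0.25, 1 + co[, "len_protrusion"] * p[6] + co[, "len_larynx"] * p[7])
  port <- (p[10] + 1) / 2 * config@maxPortArea
  new("AreaFunction", sectionAreas = unname(areas),
      sectionLengths = unname(lengths), nasalPortArea = unname(port))
}

# Area functions + touch for a whole trajectory (frames x 10 matrix),
# vectorized over frames. Returns areas/lengths as nSections x nFrames
# matrices.
areaTouchTrack <- function(frames, config) {
  frames <- asFrameMatrix(frames)
  co <- config@coefficients
  A <- co[, c("jaw", "dorsum_pos", "dorsum_shape", "apex", "lip_aperture")]
  areas <- pmax(drop(co[, "neutral_area"] +
                       A %*% t(frames[, 1:5, drop = FALSE])), 0)
  dim(areas) <- c(nrow(co), nrow(frames))
  areas <- areas * config@tractScale
  baseLen <- config@tractLength / nrow(co) * config@tractScale
  lengths <- baseLen * pmax(
    1 + outer(co[, "len_protrusion"], frames[, 6]) +
        outer(co[, "len_larynx"], frames[, 7]), 0.25)
  port <- (frames[, 10] + 1) / 2 * config@maxPortArea
  touch <- colSums(areas == 0) > 0
  touchIndex <- ifelse(touch, apply(areas, 2, which.min), NA_integer_)
  list(areas = areas, lengths = lengths, port = port,
       touch = touch, touchIndex = as.integer(touchIndex))
}

asFrameMatrix <- function(frames) {
  if (is.numeric(frames) && is.null(dim(frames))) frames <- matrix(frames, nrow = 1)
  if (is.list(frames) && !is.data.frame(frames))
    frames <- do.call(rbind, frames)
  frames <- as.matrix(frames)
  if (ncol(frames) != 10L)
    stop("control frames must have 10 columns (p1..p10)")
  if (nrow(frames) < 1L) stop("at least one control frame is required")
  frames
}
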