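#' Decode a pose-network heatmap by the local-maximum method
#'
#' A pose network emits one score heatmap per joint per frame; the joint
#' coordinate is read off as the location of the maximum score. Ties are
#' broken by the smallest row-major index (scan rows top to bottom, left to
#' right). Confidence is the maximum score clamped to \[0, 1\] (network
#' heatmaps score in that range); a perfectly flat grid carries no location
#' information, so it decodes to (0, 0) with confidence 0 and a warning.
#'
#' Coordinates are zero-based pixels: `x` is the column and `y` the row of
#' the maximum.
#'
#' @param grid numeric matrix of finite scores (rows x cols).
#' @param joint joint label, `"elbow"` or `"wrist"`.
#' @param frame_index zero-based frame index the heatmap belongs to.
#' @return A one-row data frame with `frame`, `joint`, `x`, `y`,
#'   `confidence` and `source = "network"`.
#' @export
#' @examples
#' h <- matrix(0, 32, 32); h[21, 11] <- 1
#' decode_heatmap(h)  # x = 10, y = 20
decode_heatmap <- function(grid, joint = "wrist", frame_index = 0L) {
  if (!is.matrix(grid) || !is.numeric(grid) || length(grid) < 1L) {
    stop_dtuemp("heatmap must be a non-empty numeric matrix")
  }
  if (any(!is.finite(grid))) stop_dtuemp("heatmap contains non-finite scores")
  joint <- match.arg(joint, c("elbow", "wrist"))

  rng <- range(grid)
  if (rng[1] == rng[2]) {
    warning("degenerate heatmap (all scores equal); decoding to (0, 0)",
            call. = FALSE)
    return(data.frame(frame = as.integer(frame_index), joint = joint,
                      x = 0, y = 0, confidence = 0, source = "network",
                      stringsAsFactors = FALSE))
  }

  # Row-major tie-break: scan by row, then column.
  byrow <- as.vector(t(grid))
  k <- which.max(byrow)           # first maximum in row-major order
  row0 <- (k - 1L) %/% ncol(grid) # zero-based
  col0 <- (k - 1L) %% ncol(grid)
  conf <- min(1, max(0, rng[2]))
  data.frame(frame = as.integer(frame_index), joint = joint,
             x = as.numeric(col0), y = as.numeric(row0),
             confidence = conf, source = "network",
             stringsAsFactors = FALSE)
}
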