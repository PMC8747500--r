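#' Construct a localization table
#'
#' A localization table holds one imaging channel of a single-molecule
#' localization microscopy "molecular list": one row per resolved
#' single-molecule signal with planar coordinates in nanometres, plus
#' optional acquisition frame, photon intensity and localization
#' uncertainty. It is the universal input of the analysis pipeline. The
#' coordinate convention is the common SMLM export one: x rightward,
#' y downward, origin at the top-left of the camera field.
#'
#' @param x,y Numeric coordinates in nanometres. Must be finite.
#' @param frame Optional non-negative integer acquisition frame per record.
#' @param intensity Optional photon count per record.
#' @param uncertainty Optional localization uncertainty in nm (non-negative).
#' @param channel_label Non-empty label naming the channel, e.g. `"claudin5"`,
#'   `"zo1"`, `"occludin"` or `"tracer"`.
#' @param extra Optional data frame of additional columns carried through
#'   unchanged (row order preserved).
#'
#' @return An object of class `localization_table` (a data frame with
#'   columns `x` and `y` and any optional columns, plus a `channel_label`
#'   attribute).
#' @export
#' @examples
#' locs <- localization_table(x = c(100, 150), y = c(200, 250),
#'                            channel_label = "claudin5")
#' nrow(locs)
localization_table <- function(x, y, frame = NULL, intensity = NULL,
                               uncertainty = NULL, channel_label,
                               extra = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_tj("x and y must have equal length", class = "tjstorm_validation_error")
  if (length(x) && !all(is.finite(x) & is.finite(y)))
    stop_tj("coordinates must be finite", class = "tjstorm_validation_error")
  if (missing(channel_label) || !nzchar(channel_label[1]))
    stop_tj("channel_label must be a non-empty string",
            class = "tjstorm_validation_error")
  df <- data.frame(x = x, y = y)
  if (!is.null(frame)) {
    frame <- as.integer(frame)
    if (any(frame < 0L, na.rm = TRUE))
      stop_tj("frame must be non-negative", class = "tjstorm_validation_error")
    df$frame <- frame
  }
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  if (!is.null(uncertainty)) {
    uncertainty <- as.numeric(uncertainty)
    if (any(uncertainty < 0, na.rm = TRUE))
      stop_tj("uncertainty must be non-negative",
              class = "tjstorm_validation_error")
    df$uncertainty <- uncertainty
  }
  if (!is.null(extra)) {
    if (nrow(df) && nrow(extra) != nrow(df))
      stop_tj("extra columns must match record count",
              class = "tjstorm_validation_error")
    df <- cbind(df, extra)
  }
  structure(df,
            channel_label = as.character(channel_label[1]),
            class = c("localization_table", "data.frame"))
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table> channel '%s': %d records\n",
              channel_label(x), nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  x range [%.1f, %.1f] nm; y range [%.1f, %.1f] nm\n",
                min(x$x), max(x$x), min(x$y), max(x$y)))
    utils::str(utils::head(as.data.frame(x), 3))
  }
  invisible(x)
}

#' Channel label of a localization table
#' @param table A `localization_table`.
#' @return The channel label string.
#' @export
channel_label <- function(table) attr(table, "channel_label", exact = TRUE)

# Subsetting keeps the class and channel label.
#' @export
`[.localization_table` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("x", "y") %in% names(out))) {
    attr(out, "channel_label") <- channel_label(x)
    class(out) <- c("localization_table", "data.frame")
  }
  out
}
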