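# Molecular-list CSV and ROI JSON readers/writers plus a QC renderer.
# No science lives here: unit handling and validation only.

#' Describe a molecular-list CSV dialect
#'
#' ThunderSTORM-style molecular lists carry units in bracketed header
#' suffixes (`"x [nm]"`). The dialect names the coordinate and optional
#' columns; units are inferred from the bracket suffix (`nm`, `um`/`µm`)
#' unless overridden with `x_unit_nm`/`y_unit_nm` (nanometres per file unit,
#' e.g. a camera pixel size).
#'
#' @param x_col,y_col Header names of the coordinate columns.
#' @param frame_col,intensity_col,uncertainty_col Optional column headers;
#'   `NA` columns are silently absent.
#' @param x_unit_nm,y_unit_nm Optional explicit conversion factors
#'   (nm per file unit) overriding bracket inference.
#' @param sep Field separator.
#' @return A `molecular_list_dialect` object.
#' @export
molecular_list_dialect <- function(x_col = "x [nm]", y_col = "y [nm]",
                                   frame_col = "frame",
                                   intensity_col = "intensity [photon]",
                                   uncertainty_col = "uncertainty [nm]",
                                   x_unit_nm = NULL, y_unit_nm = NULL,
                                   sep = ",") {
  structure(list(x_col = x_col, y_col = y_col, frame_col = frame_col,
                 intensity_col = intensity_col,
                 uncertainty_col = uncertainty_col,
                 x_unit_nm = x_unit_nm, y_unit_nm = y_unit_nm, sep = sep),
            class = "molecular_list_dialect")
}

# nm per unit, from a bracketed header suffix; default nm when no bracket.
.unit_from_header <- function(header) {
  m <- regmatches(header, regexpr("\\[([^]]+)\\]", header))
  if (!length(m)) return(1)
  unit <- tolower(trimws(gsub("\\[|\\]", "", m)))
  switch(unit,
         "nm" = 1,
         "um" = 1000, "µm" = 1000, "μm" = 1000,
         "photon" = 1, "photons" = 1, "a.u." = 1,
         stop_tj("unknown unit '", unit, "' in column header '", header,
                 "'; set x_unit_nm/y_unit_nm in the dialect",
                 class = "tjstorm_format_error"))
}

.numeric_or_die <- function(col, name, path) {
  if (is.numeric(col)) return(as.numeric(col))
  parsed <- suppressWarnings(as.numeric(col))
  bad <- which(is.na(parsed) & !is.na(col) & nzchar(trimws(col)))
  na_in <- which(is.na(col) | !nzchar(trimws(col)))
  first_bad <- c(bad, na_in)[1]
  if (!is.na(first_bad))
    stop_tj(sprintf("non-numeric value '%s' in column '%s' at data row %d of %s",
                    col[first_bad], name, first_bad, path),
            class = "tjstorm_parse_error")
  parsed
}

#' Read a molecular list
#'
#' Reads a per-molecule localization CSV into a [localization_table],
#' converting coordinates to nanometres per the dialect. Unknown extra
#' columns are preserved verbatim; row order is preserved.
#'
#' @param path CSV file path.
#' @param channel_label Channel label to attach (default: file stem).
#' @param dialect A [molecular_list_dialect()].
#' @return A [localization_table].
#' @export
read_molecular_list <- function(path, channel_label = NULL,
                                dialect = molecular_list_dialect()) {
  if (!file.exists(path))
    stop_tj("file not found: ", path, class = "tjstorm_io_error")
  raw <- utils::read.csv(path, check.names = FALSE, sep = dialect$sep,
                         stringsAsFactors = FALSE)
  for (need in c(dialect$x_col, dialect$y_col)) {
    if (!need %in% names(raw))
      stop_tj("missing coordinate column '", need, "' in ", path,
              class = "tjstorm_format_error")
  }
  xs <- .numeric_or_die(raw[[dialect$x_col]], dialect$x_col, path)
  ys <- .numeric_or_die(raw[[dialect$y_col]], dialect$y_col, path)
  xf <- dialect$x_unit_nm %||% .unit_from_header(dialect$x_col)
  yf <- dialect$y_unit_nm %||% .unit_from_header(dialect$y_col)
  opt <- function(colname) {
    if (!is.na(colname) && !is.null(colname) && colname %in% names(raw))
      raw[[colname]] else NULL
  }
  unc <- opt(dialect$uncertainty_col)
  if (!is.null(unc))
    unc <- .numeric_or_die(unc, dialect$uncertainty_col, path) *
      .unit_from_header(dialect$uncertainty_col)
  known <- c(dialect$x_col, dialect$y_col, dialect$frame_col,
             dialect$intensity_col, dialect$uncertainty_col)
  extra_cols <- setdiff(names(raw), known[!is.na(known)])
  extra <- if (length(extra_cols) && nrow(raw)) raw[extra_cols] else NULL
  localization_table(
    x = xs * xf, y = ys * yf,
    frame = opt(dialect$frame_col),
    intensity = opt(dialect$intensity_col),
    uncertainty = unc,
    channel_label = channel_label %||% sub("\\.[^.]*$", "", basename(path)),
    extra = extra
  )
}

#' Write a molecular list
#'
#' Writes a [localization_table] as a molecular-list CSV in the given
#' dialect (coordinates converted from internal nm to the dialect's units).
#' [read_molecular_list()] inverts it up to float formatting (15 significant
#' digits, well below 1e-3 nm for microscope-scale coordinates).
#'
#' @param table A [localization_table].
#' @param path Output CSV path.
#' @param dialect A [molecular_list_dialect()].
#' @return `path`, invisibly.
#' @export
write_molecular_list <- function(table, path,
                                 dialect = molecular_list_dialect()) {
  xf <- dialect$x_unit_nm %||% .unit_from_header(dialect$x_col)
  yf <- dialect$y_unit_nm %||% .unit_from_header(dialect$y_col)
  out <- data.frame(x = table$x / xf, y = table$y / yf)
  names(out) <- c(dialect$x_col, dialect$y_col)
  if (!is.null(table$frame) && !is.na(dialect$frame_col))
    out[[dialect$frame_col]] <- table$frame
  if (!is.null(table$intensity) && !is.na(dialect$intensity_col))
    out[[dialect$intensity_col]] <- table$intensity
  if (!is.null(table$uncertainty) && !is.na(dialect$uncertainty_col))
    out[[dialect$uncertainty_col]] <-
      table$uncertainty / .unit_from_header(dialect$uncertainty_col)
  known <- c("x", "y", "frame", "intensity", "uncertainty")
  for (col in setdiff(names(table), known)) out[[col]] <- table[[col]]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_tj("cannot write ", path, ": ", conditionMessage(ok),
            class = "tjstorm_io_error")
  invisible(path)
}

#' Construct a capillary ROI
#'
#' A capillary region of interest is the annotated cross-section of one
#' cortical capillary (the "endothelial unit"): a simple closed polygon in
#' nanometres delimiting the lumen/capillary boundary, with a label tagging
#' sample, age or genotype.
#'
#' @param vertices Two-column numeric matrix (x, y in nm), ordered; >= 3
#'   vertices; the polygon must be simple with positive area.
#' @param label Free-text tag.
#' @return A `capillary_roi` object.
#' @export
capillary_roi <- function(vertices, label = "capillary") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L)
    stop_tj("vertices must be a 2-column matrix", class = "tjstorm_validation_error")
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 3L)
    stop_tj("ROI polygon needs at least 3 vertices",
            class = "tjstorm_validation_error")
  if (!all(is.finite(vertices)))
    stop_tj("ROI vertices must be finite", class = "tjstorm_validation_error")
  if (!polygon_is_simple(vertices[, 1], vertices[, 2]))
    stop_tj("ROI polygon is self-intersecting or degenerate",
            class = "tjstorm_validation_error")
  if (polygon_area(vertices[, 1], vertices[, 2]) <= 0)
    stop_tj("ROI polygon has zero area", class = "tjstorm_validation_error")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, label = as.character(label)),
            class = "capillary_roi")
}

#' @export
print.capillary_roi <- function(x, ...) {
  cat(sprintf("<capillary_roi> '%s': %d vertices, area %.3f um^2, diameter %.2f um\n",
              x$label, nrow(x$vertices), roi_area_um2(x),
              estimate_diameter(x)))
  invisible(x)
}

#' ROI area in square micrometres
#' @param roi A [capillary_roi()].
#' @return Area in um^2.
#' @export
roi_area_um2 <- function(roi) {
  polygon_area(roi$vertices[, 1], roi$vertices[, 2]) / 1e6
}

#' ROI perimeter in micrometres
#' @param roi A [capillary_roi()].
#' @return Perimeter in um.
#' @export
roi_perimeter_um <- function(roi) {
  polygon_perimeter(roi$vertices[, 1], roi$vertices[, 2]) / 1e3
}

#' Read a capillary ROI from JSON
#'
#' Schema: `{"label": "...", "unit": "nm", "vertices": [[x, y], ...]}` with
#' vertices ordered around a simple closed polygon. `unit` may be `"nm"`
#' (default) or `"um"`.
#'
#' @param path JSON file path.
#' @return A [capillary_roi()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path))
    stop_tj("file not found: ", path, class = "tjstorm_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$vertices))
    stop_tj("ROI JSON lacks a 'vertices' field: ", path,
            class = "tjstorm_format_error")
  v <- as.matrix(obj$vertices)
  f <- switch(tolower(obj$unit %||% "nm"),
              nm = 1, um = 1000, "µm" = 1000,
              stop_tj("unknown ROI unit '", obj$unit, "'",
                      class = "tjstorm_format_error"))
  capillary_roi(v * f, label = obj$label %||% "capillary")
}

#' Write a capillary ROI to JSON
#' @param roi A [capillary_roi()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  jsonlite::write_json(
    list(label = roi$label, unit = "nm",
         vertices = unname(roi$vertices)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render localization channels to rasters (QC)
#'
#' Histogram mode bins each record into one pixel (integer counts; image sum
#' equals the record count). Gaussian mode spreads each record as a
#' unit-mass bivariate Gaussian of width equal to its localization
#' uncertainty (or `sigma_default_nm`), integrated exactly over pixels
#' within 5 sigma and normalized so each record contributes total mass 1.
#'
#' The raster origin defaults to (0, 0) when all coordinates are
#' non-negative (the camera-field convention), otherwise to the data
#' bounding box snapped to the pixel grid. Row 1 / column 1 of the matrix is
#' the pixel whose lower coordinate corner is the origin.
#'
#' @param tables A [localization_table] or list of them.
#' @param pixel_nm Pixel size in nm (> 0).
#' @param mode `"histogram"` or `"gaussian"`.
#' @param sigma_default_nm Kernel width for records lacking an uncertainty.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)` in nm.
#' @return A named list of numeric matrices (one per channel), with
#'   attributes `origin_nm` and `pixel_nm`.
#' @export
render_localizations <- function(tables, pixel_nm, mode = c("histogram", "gaussian"),
                                 sigma_default_nm = 20, extent = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(pixel_nm) || pixel_nm <= 0)
    stop_tj("pixel_nm must be positive", class = "tjstorm_parameter_error")
  if (inherits(tables, "localization_table")) tables <- list(tables)
  allx <- unlist(lapply(tables, `[[`, "x"))
  ally <- unlist(lapply(tables, `[[`, "y"))
  if (is.null(extent)) {
    if (!length(allx)) extent <- c(0, pixel_nm, 0, pixel_nm)
    else if (all(allx >= 0) && all(ally >= 0))
      extent <- c(0, max(allx), 0, max(ally))
    else
      extent <- c(floor(min(allx) / pixel_nm) * pixel_nm, max(allx),
                  floor(min(ally) / pixel_nm) * pixel_nm, max(ally))
  }
  nxp <- max(1L, ceiling((extent[2] - extent[1]) / pixel_nm + 1e-9))
  nyp <- max(1L, ceiling((extent[4] - extent[3]) / pixel_nm + 1e-9))
  out <- lapply(tables, function(tab) {
    img <- matrix(0, nrow = nyp, ncol = nxp)
    if (!nrow(tab)) return(img)
    if (mode == "histogram") {
      ix <- pmin(nxp, pmax(1L, floor((tab$x - extent[1]) / pixel_nm) + 1L))
      iy <- pmin(nyp, pmax(1L, floor((tab$y - extent[3]) / pixel_nm) + 1L))
      for (k in seq_along(ix)) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + 1
    } else {
      sig <- tab$uncertainty %||% rep(sigma_default_nm, nrow(tab))
      sig[is.na(sig) | sig <= 0] <- sigma_default_nm
      xe <- extent[1] + pixel_nm * (0:nxp)
      ye <- extent[3] + pixel_nm * (0:nyp)
      for (k in seq_len(nrow(tab))) {
        s <- sig[k]
        cx <- which(xe[-1] >= tab$x[k] - 5 * s & xe[-(nxp + 1)] <= tab$x[k] + 5 * s)
        cy <- which(ye[-1] >= tab$y[k] - 5 * s & ye[-(nyp + 1)] <= tab$y[k] + 5 * s)
        if (!length(cx) || !length(cy)) next
        wx <- pnorm(xe[cx + 1L], tab$x[k], s) - pnorm(xe[cx], tab$x[k], s)
        wy <- pnorm(ye[cy + 1L], tab$y[k], s) - pnorm(ye[cy], tab$y[k], s)
        ker <- outer(wy, wx)
        ker <- ker / sum(ker)   # unit mass per record after truncation/clipping
        img[cy, cx] <- img[cy, cx] + ker
      }
    }
    img
  })
  names(out) <- vapply(tables, channel_label, character(1))
  structure(out, origin_nm = c(extent[1], extent[3]), pixel_nm = pixel_nm)
}
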