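#' Read a paired time series from delimited text
#'
#' Parses CSV/TSV (header optional) or plain whitespace-separated ASCII
#' columns — the layout of classic physiological exports such as the Santa
#' Fe cardiorespiratory files (heart rate, chest volume, oxygen saturation
#' as space-separated columns) — and selects two column groups as the X and
#' Y processes.
#'
#' @param path file path.
#' @param format `"auto"` (from extension and content), `"csv"`, `"tsv"`,
#'   or `"whitespace"`.
#' @param columns_x,columns_y column indices or names selecting the X and
#'   Y processes (each may select several columns for vector-valued steps).
#' @param header `"auto"` (detect a non-numeric first row), `TRUE`, or
#'   `FALSE`.
#' @param alphabet passed to [paired_sequences()].
#' @return A [paired_sequences()] object.
#' @export
read_paired_series <- function(path,
                               format = c("auto", "csv", "tsv", "whitespace"),
                               columns_x = 1L, columns_y = 2L,
                               header = "auto",
                               alphabet = c("auto", "real", "discrete")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    stop(sprintf("file '%s' is empty", path), call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv" || grepl(",", first, fixed = TRUE)) "csv"
    else if (ext == "tsv" || grepl("\t", first, fixed = TRUE)) "tsv"
    else "whitespace"
  }
  sep <- switch(format, csv = ",", tsv = "\t", whitespace = "")
  if (identical(header, "auto")) {
    fields <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(fields)))
  }
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = header,
                      strip.white = TRUE, fill = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) {
      stop(sprintf("ragged or malformed rows in '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  pick <- function(cols, nm) {
    if (is.character(cols)) {
      missing <- setdiff(cols, names(df))
      if (length(missing) > 0L) {
        stop(sprintf("column(s) %s for '%s' not present in '%s'",
                     paste(sQuote(missing), collapse = ", "), nm, path),
             call. = FALSE)
      }
      sel <- df[cols]
    } else {
      if (any(cols < 1L | cols > ncol(df))) {
        stop(sprintf("column index for '%s' outside 1..%d in '%s'",
                     nm, ncol(df), path), call. = FALSE)
      }
      sel <- df[cols]
    }
    M <- as.matrix(sel)
    if (!is.numeric(M)) {
      stop(sprintf("non-numeric values in the '%s' columns of '%s'", nm,
                   path), call. = FALSE)
    }
    M
  }
  paired_sequences(pick(columns_x, "x"), pick(columns_y, "y"),
                   alphabet = alphabet)
}

#' Write a paired time series as delimited text
#'
#' @param pair a [paired_sequences()].
#' @param path output path.
#' @param format `"csv"` (default), `"tsv"`, or `"whitespace"`.
#' @param header write a `x1..,y1..` header row (default TRUE for csv/tsv).
#' @return `path`, invisibly.
#' @export
write_paired_series <- function(pair, path,
                                format = c("csv", "tsv", "whitespace"),
                                header = format != "whitespace") {
  stopifnot(inherits(pair, "paired_sequences"))
  format <- match.arg(format)
  sep <- switch(format, csv = ",", tsv = "\t", whitespace = " ")
  M <- cbind(pair$x, pair$y)
  colnames(M) <- c(paste0("x", seq_len(pair$d_x)),
                   paste0("y", seq_len(pair$d_y)))
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Serialize an InfoMat
#'
#' JSON (`.json`) stores the full object — `m`, `log_base`,
#' `estimator_tag`, and the entries in row-major order — and round-trips
#' bit-exactly.  CSV stores the bare `m x m` entry grid at full precision
#' (base and tag are supplied again at read time).
#'
#' @param M an [infomat()].
#' @param path output path; the format follows the extension (`.json` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_infomat <- function(M, path) {
  check_infomat(M)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    # entries are formatted with %.17g so doubles survive bit-exactly
    ent <- sprintf("%.17g", as.vector(t(M$entries)))
    writeLines(sprintf(
      '{"m": %d, "log_base": %s, "estimator_tag": %s, "entries": [%s]}',
      M$m, jsonlite::toJSON(M$log_base, auto_unbox = TRUE),
      jsonlite::toJSON(M$estimator_tag, auto_unbox = TRUE),
      paste(ent, collapse = ", ")), path)
  } else if (ext == "csv") {
    utils::write.table(
      matrix(sprintf("%.17g", M$entries), M$m, M$m), path,
      sep = ",", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    stop("unsupported InfoMat extension: use .json or .csv", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_infomat
#' @param log_base,estimator_tag metadata applied when reading the bare CSV
#'   dialect (ignored for JSON, which stores its own).
#' @return `read_infomat` returns an [infomat()].
#' @export
read_infomat <- function(path, log_base = "e", estimator_tag = "unspecified") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed InfoMat JSON '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
    need <- c("m", "log_base", "estimator_tag", "entries")
    if (!all(need %in% names(obj))) {
      stop(sprintf("InfoMat JSON '%s' missing field(s): %s", path,
                   paste(setdiff(need, names(obj)), collapse = ", ")),
           call. = FALSE)
    }
    m <- as.integer(obj$m)
    if (length(obj$entries) != m * m) {
      stop(sprintf(
        "InfoMat JSON '%s': %d entries but m = %d requires %d",
        path, length(obj$entries), m, m * m), call. = FALSE)
    }
    infomat(matrix(as.numeric(obj$entries), m, m, byrow = TRUE),
            log_base = obj$log_base, estimator_tag = obj$estimator_tag)
  } else if (ext == "csv") {
    E <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    if (nrow(E) != ncol(E)) {
      stop(sprintf("InfoMat CSV '%s': %d rows but %d columns", path,
                   nrow(E), ncol(E)), call. = FALSE)
    }
    infomat(E, log_base = log_base, estimator_tag = estimator_tag)
  } else {
    stop("unsupported InfoMat extension: use .json or .csv", call. = FALSE)
  }
}

#' Render an InfoMat heatmap
#'
#' Draws the matrix with the convention used throughout: the horizontal
#' axis is the X-process time index \eqn{i}, the vertical axis the
#' Y-process time index \eqn{j}, both with 1-based tick labels, and the
#' color bar is labelled with the matrix's log base.  Directed information
#' X to Y is thus the area above-right of the diagonal.  Negative raw
#' estimates can be clipped to zero for display (the stored matrix is never
#' modified).
#'
#' @param M an [infomat()].
#' @param path output image path; `.png` always works, `.svg` where the
#'   graphics device supports it.
#' @param color_scale `"linear"` (default) or `"clipped_at_zero"`.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(M, path,
                           color_scale = c("linear", "clipped_at_zero"),
                           width = 5, height = 4.2) {
  check_infomat(M)
  color_scale <- match.arg(color_scale)
  E <- M$entries
  if (color_scale == "clipped_at_zero") E <- pmax(E, 0)
  df <- data.frame(i = rep(seq_len(M$m), times = M$m),
                   j = rep(seq_len(M$m), each = M$m),
                   value = as.vector(E))
  unit <- if (M$log_base == "e") "nats" else "bits"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_continuous(breaks = seq_len(M$m), expand = c(0, 0)) +
    ggplot2::scale_y_continuous(breaks = seq_len(M$m), expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(name = unit) +
    ggplot2::labs(x = "X-process time index",
                  y = "Y-process time index",
                  title = sprintf("InfoMat (%s estimator)",
                                  M$estimator_tag)) +
    ggplot2::theme_minimal()
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    suppressMessages(ggplot2::ggsave(path, p, width = width, height = height,
                                     dpi = 150))
  } else if (ext == "svg") {
    if (!capabilities("cairo")) {
      stop("svg output requires cairo graphics support", call. = FALSE)
    }
    grDevices::svg(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    print(p)
  } else {
    stop("unsupported heatmap extension: use .png or .svg", call. = FALSE)
  }
  invisible(path)
}
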