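# Deterministic SVG rendering of a matrix model.
#
# Visual encodings, layered per cell:
#   - curated effect: hue (green responsive, red resistant); its evidence
#     level sets both bar length and saturation (longer + more saturated =
#     higher evidence);
#   - bioactivity potency: black overlay bar whose width shrinks with lower
#     potency; inactive pairs draw a diagonal slash instead of a bar;
#   - tumor-type rows: a horizontal line marks a (tumor, mutation) link.
# The output is plain-text SVG assembled with fixed number formatting, so
# identical (matrix, config) inputs give byte-identical documents.

#' Visual-encoding configuration for the matrix renderer
#'
#' @param responsive_hue,resistant_hue fill colors (hex) for
#'   responsive/resistant curated effects.
#' @param saturation_ramp five values in (0, 1], strictly increasing with
#'   evidence rank; fraction of full saturation for ranks 1..5.
#' @param potency_width_fractions three strictly decreasing values in
#'   (0, 1]: overlay-bar width fraction for highly_potent, potent,
#'   weakly_potent.
#' @param cell_width,cell_height cell geometry in px.
#' @param font_family,font_size label font.
#' @return a list of class `render_config`.
#' @export
render_config <- function(responsive_hue = "#2E8B57",
                          resistant_hue = "#C0392B",
                          saturation_ramp = c(0.2, 0.4, 0.6, 0.8, 1.0),
                          potency_width_fractions = c(highly_potent = 1.0,
                                                      potent = 0.6,
                                                      weakly_potent = 0.3),
                          cell_width = 46, cell_height = 30,
                          font_family = "Helvetica", font_size = 11) {
  if (length(saturation_ramp) != 5L || any(diff(saturation_ramp) <= 0) ||
      any(saturation_ramp <= 0) || any(saturation_ramp > 1)) {
    stop("saturation_ramp must be 5 strictly increasing values in (0, 1]",
         call. = FALSE)
  }
  if (length(potency_width_fractions) != 3L ||
      any(diff(unname(potency_width_fractions)) >= 0) ||
      any(potency_width_fractions <= 0) || any(potency_width_fractions > 1)) {
    stop("potency_width_fractions must be 3 strictly decreasing values in (0, 1]",
         call. = FALSE)
  }
  structure(list(responsive_hue = responsive_hue,
                 resistant_hue = resistant_hue,
                 saturation_ramp = saturation_ramp,
                 potency_width_fractions = stats::setNames(
                   unname(potency_width_fractions),
                   c("highly_potent", "potent", "weakly_potent")),
                 cell_width = cell_width, cell_height = cell_height,
                 font_family = font_family, font_size = font_size),
            class = "render_config")
}

# Mix a hex color toward white: s = 1 keeps the full hue, s -> 0 fades out.
desaturate_to_white <- function(hex, s) {
  rgb <- grDevices::col2rgb(hex)[, 1]
  mixed <- round((1 - s) * 255 + s * rgb)
  sprintf("#%02X%02X%02X", mixed[1], mixed[2], mixed[3])
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_id <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

fmt <- function(x) sprintf("%.2f", x)

#' Render a matrix model as a static SVG document
#'
#' Produces a self-contained SVG of the drug-by-target matrix with the
#' layered encodings described in [render_config()]. Rendering is a pure
#' function of `(m, config, drug_order)`: the same inputs always produce a
#' byte-identical document. Each cell group carries a stable `id`
#' (`cell-<drug>-<target>`) so a front end can attach behaviour.
#'
#' @param m a `matrix_model` with at least one column.
#' @param config a [render_config()].
#' @param path optional output path; when given, the SVG is written there.
#' @param drug_order optional permutation of `m$drug_rows` giving the row
#'   order (e.g. the output of a sorting procedure).
#' @return the SVG document as a single character string, invisibly when
#'   `path` is given.
#' @export
render_matrix <- function(m, config = render_config(), path = NULL,
                          drug_order = NULL) {
  stopifnot(inherits(m, "matrix_model"), inherits(config, "render_config"))
  if (nrow(m$columns) == 0L) stop("cannot render a matrix with zero columns", call. = FALSE)
  if (is.null(drug_order)) drug_order <- m$drug_rows
  stopifnot(setequal(drug_order, m$drug_rows))

  cw <- config$cell_width; ch <- config$cell_height
  fs <- config$font_size
  row_labels <- c(display_of(m$tumors, m$tumor_rows),
                  display_of(m$drugs, drug_order))
  label_w <- max(c(40, nchar(row_labels) * fs * 0.62)) + 10
  header_h <- fs + 14
  gap <- if (length(m$tumor_rows)) 8 else 0
  n_col <- nrow(m$columns)
  n_tum <- length(m$tumor_rows)
  n_drug <- length(drug_order)
  width <- label_w + n_col * cw + 10
  height <- header_h + n_tum * ch + gap + n_drug * ch + 10

  col_x <- label_w + (seq_len(n_col) - 1) * cw
  tum_y <- header_h + (seq_len(n_tum) - 1) * ch
  drug_y0 <- header_h + n_tum * ch + gap
  drug_y <- drug_y0 + (seq_len(n_drug) - 1) * ch

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="%s" font-size="%d">',
            ceiling(width), ceiling(height), xml_escape(config$font_family), fs),
    '<rect width="100%" height="100%" fill="#FFFFFF"/>'
  )

  # column headers
  for (j in seq_len(n_col)) {
    out <- c(out, sprintf(
      '<text x="%s" y="%s" text-anchor="middle">%s</text>',
      fmt(col_x[j] + cw / 2), fmt(header_h - 6),
      xml_escape(m$columns$display[j])))
  }

  cell_bg <- function(x, y) sprintf(
    '<rect x="%s" y="%s" width="%s" height="%s" fill="#FFFFFF" stroke="#CCCCCC" stroke-width="1"/>',
    fmt(x), fmt(y), fmt(cw), fmt(ch))

  # tumor-type rows: horizontal line where the mutation occurs in that tumor
  for (i in seq_len(n_tum)) {
    tk <- m$tumor_rows[i]
    out <- c(out, sprintf(
      '<text x="%s" y="%s" text-anchor="end">%s</text>',
      fmt(label_w - 6), fmt(tum_y[i] + ch / 2 + fs * 0.35),
      xml_escape(display_of(m$tumors, tk))))
    for (j in seq_len(n_col)) {
      ck <- m$columns$key[j]
      x <- col_x[j]; y <- tum_y[i]
      linked <- any(m$tumor_cells$tumor_key == tk & m$tumor_cells$target_key == ck)
      grp <- sprintf('<g id="tumor-%s-%s">', svg_id(tk), svg_id(ck))
      body <- cell_bg(x, y)
      if (linked) {
        body <- c(body, sprintf(
          '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555555" stroke-width="2"/>',
          fmt(x + 5), fmt(y + ch / 2), fmt(x + cw - 5), fmt(y + ch / 2)))
      }
      out <- c(out, grp, body, '</g>')
    }
  }

  # drug rows: layered CGI bar + DTC overlay
  hue_of <- c(responsive = config$responsive_hue, resistant = config$resistant_hue)
  for (i in seq_len(n_drug)) {
    dk <- drug_order[i]
    out <- c(out, sprintf(
      '<text x="%s" y="%s" text-anchor="end">%s</text>',
      fmt(label_w - 6), fmt(drug_y[i] + ch / 2 + fs * 0.35),
      xml_escape(display_of(m$drugs, dk))))
    for (j in seq_len(n_col)) {
      ck <- m$columns$key[j]
      cc <- cell_row(m, dk, ck)
      x <- col_x[j]; y <- drug_y[i]
      body <- cell_bg(x, y)
      bar_w <- cw * 0.6
      bar_x <- x + (cw - bar_w) / 2
      base_y <- y + ch - 3
      max_h <- ch - 6
      if (cc$has_cgi) {
        rank <- cc$cgi_rank
        h <- max_h * rank / 5
        fill <- desaturate_to_white(hue_of[[cc$cgi_effect]],
                                    config$saturation_ramp[rank])
        body <- c(body, sprintf(
          '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
          fmt(bar_x), fmt(base_y - h), fmt(bar_w), fmt(h), fill))
      }
      if (cc$has_dtc) {
        if (cc$dtc_potency == "inactive") {
          body <- c(body, sprintf(
            '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="2"/>',
            fmt(x + 4), fmt(y + ch - 4), fmt(x + cw - 4), fmt(y + 4)))
        } else {
          wfrac <- config$potency_width_fractions[[cc$dtc_potency]]
          ow <- bar_w * wfrac
          oh <- max_h * 0.45
          body <- c(body, sprintf(
            '<rect x="%s" y="%s" width="%s" height="%s" fill="#000000"/>',
            fmt(x + (cw - ow) / 2), fmt(base_y - oh), fmt(ow), fmt(oh)))
        }
      }
      out <- c(out, sprintf('<g id="cell-%s-%s" data-state="%s">',
                            svg_id(dk), svg_id(ck), cc$state),
               body, '</g>')
    }
  }

  out <- c(out, '</svg>')
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(doc), con)
    return(invisible(doc))
  }
  doc
}
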