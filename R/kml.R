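# KML 2.2 export for Google Earth: one Placemark per occurrence, the EOO
# hull and the AOO cells as Polygons when results are present. KML wants
# lon,lat coordinate order and closed linear rings (first tuple repeated
# last). Hidden occurrences are exported too, with a distinct style, so the
# file documents the full dataset and not just the analysed subset.

kml_coord <- function(lon, lat) sprintf("%.6f,%.6f,0", lon, lat)

kml_style <- function(doc, id, color, scale = 1) {
  st <- xml2::xml_add_child(doc, "Style", id = id)
  ic <- xml2::xml_add_child(st, "IconStyle")
  xml2::xml_add_child(ic, "color", color)
  xml2::xml_add_child(ic, "scale", format(scale))
  ps <- xml2::xml_add_child(st, "PolyStyle")
  xml2::xml_add_child(ps, "color", color)
  invisible(st)
}

kml_polygon <- function(parent, name, ring_lonlat, style) {
  pm <- xml2::xml_add_child(parent, "Placemark")
  xml2::xml_add_child(pm, "name", name)
  xml2::xml_add_child(pm, "styleUrl", paste0("#", style))
  poly <- xml2::xml_add_child(pm, "Polygon")
  ob <- xml2::xml_add_child(poly, "outerBoundaryIs")
  lr <- xml2::xml_add_child(ob, "LinearRing")
  # close the ring
  ring <- rbind(ring_lonlat, ring_lonlat[1, , drop = FALSE])
  xml2::xml_add_child(lr, "coordinates",
                      paste(kml_coord(ring[, 1], ring[, 2]), collapse = " "))
  invisible(pm)
}

#' Export a project to KML
#'
#' Writes every occurrence as a Placemark (name = record id, description
#' from its metadata); records without coordinates are skipped. When the
#' project holds analysis results, the EOO hull is written as one Polygon
#' and every occupied AOO cell as a Polygon (corners recovered from the cell
#' indices via the stored projection parameters). Visible and hidden
#' occurrences use distinct styles.
#'
#' @param project A [geocat_project()] with at least one occurrence.
#' @param path Output `.kml` path.
#' @return `path`, invisibly.
#' @export
export_kml <- function(project, path) {
  stopifnot(inherits(project, "geocat_project"))
  r <- project$occurrence_set$records
  if (nrow(r) == 0L) stop("project has no occurrences")
  root <- xml2::xml_new_root("kml", xmlns = "http://www.opengis.net/kml/2.2")
  doc <- xml2::xml_add_child(root, "Document")
  xml2::xml_add_child(doc, "name", project$taxon_name)
  kml_style(doc, "occ-visible", "ff0000ff")
  kml_style(doc, "occ-hidden", "7f888888", scale = 0.7)
  kml_style(doc, "eoo-hull", "7f00ff00")
  kml_style(doc, "aoo-cell", "7fff8800")

  for (i in seq_len(nrow(r))) {
    if (is.na(r$lat[i]) || is.na(r$lon[i])) next
    pm <- xml2::xml_add_child(doc, "Placemark")
    xml2::xml_add_child(pm, "name", r$id[i])
    meta <- r$metadata[[i]]
    if (length(meta)) {
      xml2::xml_add_child(pm, "description",
                          paste(names(meta), meta, sep = ": ", collapse = "; "))
    }
    xml2::xml_add_child(pm, "styleUrl",
                        if (r$visible[i]) "#occ-visible" else "#occ-hidden")
    pt <- xml2::xml_add_child(pm, "Point")
    xml2::xml_add_child(pt, "coordinates", kml_coord(r$lon[i], r$lat[i]))
  }

  res <- project$results
  if (!is.null(res)) {
    hull <- res$eoo$hull_lonlat
    if (!is.null(hull) && length(hull) >= 3L) {
      ring <- do.call(rbind, lapply(hull, function(v) as.numeric(unlist(v))))
      kml_polygon(doc, "EOO hull", ring, "eoo-hull")
    }
    cells <- res$aoo$cells
    pp <- project$parameters$projection
    if (!is.null(cells) && length(cells) && !is.null(pp)) {
      params <- projection_params(pp$lon0, pp$lat_ts, pp$R)
      w <- res$aoo$cell_width_km
      for (k in seq_along(cells)) {
        cl <- cells[[k]]
        x0 <- as.numeric(cl$i) * w; y0 <- as.numeric(cl$j) * w
        corners <- project_inverse(c(x0, x0 + w, x0 + w, x0),
                                   c(y0, y0, y0 + w, y0 + w), params)
        kml_polygon(doc, sprintf("AOO cell (%d,%d)", as.integer(cl$i),
                                 as.integer(cl$j)),
                    cbind(corners$lon, corners$lat), "aoo-cell")
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
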