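# Root System Markup Language (RSML) I/O. One file holds one scene with one
# <plant> element per root system; seminal roots are top-level <root>
# elements and laterals are nested <root> elements inside their parent.
# Plant metadata (line, nupe_class, nitrate, group_code) and lateral
# attachment positions travel in <properties> blocks. Coordinates are
# written with six decimal places, so geometry round-trips to 1e-6 mm and
# repeated writes of the same cohort are byte-identical.

fmt_num <- function(z) sprintf("%.6f", z)

rsml_add_root <- function(parent_node, system, curve_index, id_prefix,
                          children_of) {
  cv <- system$curves[[curve_index]]
  rt <- xml2::xml_add_child(parent_node, "root",
                            ID = sprintf("%s.%d", id_prefix, curve_index),
                            label = cv$order)
  if (cv$order == "lateral") {
    props <- xml2::xml_add_child(rt, "properties")
    xml2::xml_add_child(props, "property", name = "attachment_arclength",
                        value = fmt_num(cv$attachment_arclength))
  }
  geom <- xml2::xml_add_child(rt, "geometry")
  poly <- xml2::xml_add_child(geom, "polyline")
  pts <- cv$points
  for (i in seq_len(nrow(pts)))
    xml2::xml_add_child(poly, "point", x = fmt_num(pts[i, 1]),
                        y = fmt_num(pts[i, 2]))
  for (ch in children_of[[curve_index]])
    rsml_add_root(rt, system, ch, id_prefix, children_of)
  invisible(rt)
}

#' Write a cohort to an RSML file
#'
#' @param cohort a `root_cohort` or list of [root_system()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(cohort, path) {
  doc <- xml2::xml_new_root("rsml")
  md <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(md, "version", "1")
  xml2::xml_add_child(md, "unit", "mm")
  xml2::xml_add_child(md, "software", "rootlda")
  scene <- xml2::xml_add_child(doc, "scene")
  for (system in cohort) {
    pl <- xml2::xml_add_child(scene, "plant", ID = system$plant_id,
                              label = system$meta$line)
    props <- xml2::xml_add_child(pl, "properties")
    for (nm in c("line", "nupe_class", "nitrate", "group_code"))
      xml2::xml_add_child(props, "property", name = nm,
                          value = as.character(system$meta[[nm]]))
    orders <- vapply(system$curves, function(cv) cv$order, character(1))
    children_of <- lapply(seq_along(system$curves), function(i)
      which(orders == "lateral" &
              vapply(system$curves, function(cv)
                identical(cv$parent_index, i), logical(1))))
    for (i in which(orders == "seminal"))
      rsml_add_root(pl, system, i, system$plant_id, children_of)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

rsml_points <- function(root_node) {
  poly <- xml2::xml_find_first(root_node, "./geometry/polyline")
  pts <- xml2::xml_find_all(poly, "./point")
  cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
        y = as.numeric(xml2::xml_attr(pts, "y")))
}

rsml_property <- function(node, name) {
  xml2::xml_attr(xml2::xml_find_first(
    node, sprintf("./properties/property[@name='%s']", name)), "value")
}

#' Read a cohort from an RSML file
#'
#' Reads files written by [write_rsml()]: nested `<root>` elements are
#' interpreted as laterals of the enclosing seminal root.
#'
#' @param path RSML file path.
#' @return a `root_cohort` list of [root_system()] objects.
#' @export
read_rsml <- function(path) {
  doc <- xml2::read_xml(path)
  plants <- xml2::xml_find_all(doc, "./scene/plant")
  systems <- lapply(plants, function(pl) {
    meta <- plant_meta(rsml_property(pl, "line"),
                       rsml_property(pl, "nupe_class"),
                       rsml_property(pl, "nitrate"),
                       as.integer(rsml_property(pl, "group_code")))
    sem_nodes <- xml2::xml_find_all(pl, "./root")
    curves <- lapply(sem_nodes, function(sn)
      root_curve(rsml_points(sn), "seminal"))
    # laterals after all seminals, grouped by parent in document order
    for (parent_idx in seq_along(sem_nodes)) {
      plen <- arc_length(curves[[parent_idx]])
      for (ln in xml2::xml_find_all(sem_nodes[[parent_idx]], "./root")) {
        # written coordinates carry 1e-6 rounding; clamp the stored
        # attachment position to the re-read parent's arc length
        att <- min(as.numeric(rsml_property(ln, "attachment_arclength")), plen)
        curves[[length(curves) + 1L]] <- root_curve(
          rsml_points(ln), "lateral", parent_index = parent_idx,
          attachment_arclength = att)
      }
    }
    seed <- curves[[1L]]$points[1L, ]
    root_system(xml2::xml_attr(pl, "ID"), seed, curves, meta)
  })
  structure(systems, class = "root_cohort")
}
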