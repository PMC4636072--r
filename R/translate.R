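# Query and data translation between specialized archetypes (one column per
# analyte) and the generalized archetype that stores name/value/unit triples
# in a multiple-occurrence group. The EAV mapping file supplies the
# correspondences; the display name of each specialized item (in the mapping's
# language set) is the value written to the generalized name item.

# mapping lookup: specialized item name -> list(name_target, fields =
# named list suffix -> target item path)
mapping_index <- function(mapping) {
  idx <- list()
  for (i in seq_len(nrow(mapping$name_entries))) {
    item <- basename_path(eav_item_path(mapping$name_entries$source[i]))
    idx[[item]] <- list(name_target = mapping$name_entries$target[i],
                        set = mapping$name_entries$set[i], fields = list())
  }
  for (i in seq_len(nrow(mapping$field_entries))) {
    src <- mapping$field_entries$source[i]
    item <- basename_path(eav_item_path(src))
    sfx <- eav_field_suffix(src)
    if (is.null(idx[[item]]))
      idx[[item]] <- list(name_target = NULL, set = "en", fields = list())
    idx[[item]]$fields[[sfx]] <- mapping$field_entries$target[i]
  }
  idx
}

# Full generalized path for a short target like "[Result]/value/value":
# resolves to group_path + item, and the field suffix.
generalized_target <- function(generalized, target_path) {
  r <- resolve_generalized_target(generalized, target_path)
  if (is.null(r))
    abort2("unresolved_target", "target path absent from generalized archetype: %s",
           target_path)
  list(path = paste0(r$group$path, "/[", r$item$name, "]"),
       suffix = eav_field_suffix(target_path) %||%
         primary_field_suffix(r$item$type))
}

#' Translate a specialized query to the generalized archetype
#'
#' Every condition `(item X, field f, cmp v)` becomes the same-repetition
#' pair `(name item = display-name-of-X)` AND `(mapped field item cmp v)`;
#' distinct analytes translate to distinct repetition groups, so a
#' conjunction over several analytes means "some repetition for each,
#' within the same instance".
#'
#' @param spec Query spec whose clauses target the specialized archetype.
#' @param mapping EAV mapping for that archetype.
#' @param suite Archetype suite (holds both archetypes).
#' @return A query spec targeting the generalized archetype.
#' @export
translate_specialized_query <- function(spec, mapping, suite) {
  stopifnot(inherits(spec, "arm_query"))
  specialized <- suite[[mapping$specialized_archetype_id]]
  generalized <- suite[[mapping$generalized_archetype_id]]
  if (is.null(specialized) || is.null(generalized))
    abort2("unknown_archetype", "mapping archetypes absent from suite")
  idx <- mapping_index(mapping)
  clauses <- lapply(spec$clauses, function(cl) {
    if (!identical(cl$archetype_id, mapping$specialized_archetype_id))
      abort2("untranslatable", "clause targets %s, mapping covers %s",
             cl$archetype_id, mapping$specialized_archetype_id)
    conds <- list()
    for (k in seq_along(cl$conditions)) {
      cn <- cl$conditions[[k]]
      item <- basename_path(cn$path)
      m <- idx[[item]]
      if (is.null(m) || is.null(m$name_target))
        abort2("untranslatable", "condition path absent from mapping: %s", cn$path)
      node <- find_node(specialized, cn$path, suite)
      if (is.null(node))
        abort2("untranslatable", "condition path absent from archetype: %s", cn$path)
      sfx <- cn$suffix %||% primary_field_suffix(node$node$type)
      ft <- m$fields[[sfx]]
      if (is.null(ft))
        abort2("untranslatable", "field %s of %s absent from mapping", sfx, item)
      name_loc <- generalized_target(generalized, m$name_target)
      fld_loc <- generalized_target(generalized, ft)
      gtag <- paste0("xl", k)
      display <- ontology_text(specialized, find_node(specialized, cn$path,
                                                      suite)$node$path %||% cn$path,
                               m$set %||% "en")
      conds <- c(conds, list(
        condition(name_loc$path, "=", display, suffix = name_loc$suffix,
                  group = gtag),
        condition(fld_loc$path, cn$op, cn$value, suffix = fld_loc$suffix,
                  group = gtag)))
    }
    query_clause(mapping$generalized_archetype_id, conds,
                 subject_path = cl$subject_path)
  })
  query_spec(clauses, grouping = spec$grouping, projection = spec$projection)
}

#' Translate a generalized query to specialized archetypes
#'
#' The inverse direction: a same-repetition pair (name item = X, field cmp v)
#' becomes a plain condition on the specialized item whose display name is X;
#' one spec is produced per specialized archetype whose mapping covers all
#' named analytes, and their results union.
#'
#' @param spec Query spec targeting the generalized archetype, whose
#'   conditions are same-repetition (name, field) pairs.
#' @param mappings List of EAV mappings (one per specialized archetype).
#' @param suite Archetype suite.
#' @return List of query specs over specialized archetypes.
#' @export
translate_generalized_query <- function(spec, mappings, suite) {
  stopifnot(inherits(spec, "arm_query"))
  lapply_specs <- list()
  for (mapping in mappings) {
    specialized <- suite[[mapping$specialized_archetype_id]]
    idx <- mapping_index(mapping)
    ok <- TRUE
    clauses <- list()
    for (cl in spec$clauses) {
      tags <- vapply(cl$conditions, function(c) c$group %||% NA_character_, "")
      conds <- list()
      for (tg in unique(tags)) {
        pair <- cl$conditions[tags == tg]
        name_cond <- NULL; field_cond <- NULL
        for (cn in pair) {
          if (identical(cn$op, "=") && is.character(cn$value) &&
              !is.null(find_display_item(specialized, cn$value))) name_cond <- cn
          else field_cond <- cn
        }
        if (is.null(name_cond) || is.null(field_cond)) { ok <- FALSE; break }
        item <- find_display_item(specialized, name_cond$value)
        m <- idx[[item$name]]
        if (is.null(m)) { ok <- FALSE; break }
        conds <- c(conds, list(condition(item$path, field_cond$op,
                                         field_cond$value)))
      }
      if (!ok) break
      clauses <- c(clauses, list(query_clause(mapping$specialized_archetype_id,
                                              conds, cl$subject_path)))
    }
    if (ok)
      lapply_specs[[length(lapply_specs) + 1L]] <-
        query_spec(clauses, grouping = spec$grouping,
                   projection = spec$projection)
  }
  lapply_specs
}

find_display_item <- function(arch, display, language = "en") {
  for (n in arch_nodes_flat(arch)) {
    if (identical(n$kind, "basic") &&
        identical(ontology_text(arch, n$path, language), display))
      return(n)
  }
  NULL
}

#' Convert a specialized instance to its generalized form
#'
#' Shared structural items (those also present in the generalized archetype)
#' copy across; each populated mapped analyte becomes one repetition of the
#' generalized group, with the name item holding the analyte's display name
#' and the mapped fields holding its values.
#'
#' @param inst Specialized instance.
#' @param mapping EAV mapping.
#' @param suite Archetype suite.
#' @return An instance of the generalized archetype.
#' @export
specialized_to_generalized <- function(inst, mapping, suite) {
  specialized <- suite[[mapping$specialized_archetype_id]]
  generalized <- suite[[mapping$generalized_archetype_id]]
  cinst <- validate_instance(inst, specialized, suite)
  idx <- mapping_index(mapping)
  # locate the generalized group via the first name target
  if (!nrow(mapping$name_entries))
    abort2("untranslatable", "mapping has no name entries")
  gt <- resolve_generalized_target(generalized, mapping$name_entries$target[1L])
  group_path <- gt$group$path

  # copy items shared with the generalized archetype (same path, basic kind)
  gen_flat <- arch_nodes_flat(generalized)
  gen_paths <- vapply(gen_flat, `[[`, "", "path")
  data <- list()
  spec_flat <- arch_nodes_flat(specialized)
  mapped_names <- names(idx)
  for (n in spec_flat) {
    if (!identical(n$kind, "basic")) next
    if (n$name %in% mapped_names) next
    if (!(n$path %in% gen_paths)) next
    rec <- tree_value_record(cinst$data, n$path)
    if (!is.null(rec)) data <- set_tree_record(data, n$path, rec)
  }
  # also copy slots/collections content shared one-to-one (annotation etc.)
  reps <- list()
  for (item in mapped_names) {
    m <- idx[[item]]
    node <- find_item_by_name(specialized, item)
    if (is.null(node)) next
    rec <- tree_value_record(cinst$data, node$path)
    if (is.null(rec) || !length(rec)) next
    rep <- list()
    nt <- generalized_target(generalized, m$name_target)
    rep <- set_rep_field(rep, group_path, nt$path, nt$suffix,
                         ontology_text(specialized, node$path, m$set %||% "en"))
    for (sfx in names(m$fields)) {
      v <- rec[[sfx]]
      if (is.null(v)) next
      ft <- generalized_target(generalized, m$fields[[sfx]])
      tnode <- find_node(generalized, ft$path, suite)$node
      tkind <- resolve_field_columns(tnode$type)
      tk <- tkind$kind[match(ft$suffix, tkind$suffix)]
      if (identical(tk, "NVARCHAR")) v <- format_value_text(v)
      rep <- set_rep_field(rep, group_path, ft$path, ft$suffix, v)
    }
    reps <- c(reps, list(rep))
  }
  data <- assign_group_reps(data, group_path, reps)
  # the generalized archetype's identification item is not part of any
  # mapping; derive a deterministic value (the copied order identifier when
  # present, else a digest of the instance content)
  for (n in generalized$nodes) {
    if (identical(n$kind, "basic") && n$occurrence$lower >= 1L &&
        is.null(data[[n$name]])) {
      src <- tree_value_record(cinst$data, "[receiverOrderIdentifier]")
      idv <- if (!is.null(src) && !is.null(src$value)) paste0("G", src$value)
      else paste0("G", fnv1a32(canonical_json(cinst$data)))
      fld <- primary_field_suffix(n$type)
      data[[n$name]] <- stats::setNames(list(idv), fld)
    }
  }
  validate_instance(archetype_instance(generalized$id, data), generalized, suite)
}

format_value_text <- function(v) {
  if (is.character(v)) v
  else formatC(v, digits = 15, format = "g")
}

tree_value_record <- function(data, path) {
  cur <- data
  for (s in path_segments(path)) {
    cur <- cur[[s]]
    if (is.null(cur)) return(NULL)
  }
  cur
}

set_tree_record <- function(data, path, rec) {
  segs <- path_segments(path)
  assign_rec <- function(node, i) {
    if (i > length(segs)) return(rec)
    node[[segs[[i]]]] <- assign_rec(node[[segs[[i]]]] %||% list(), i + 1L)
    node
  }
  assign_rec(data %||% list(), 1L)
}

# set a field inside a repetition record, where `path` is the full
# generalized path and `group_path` its repeating prefix
set_rep_field <- function(rep, group_path, path, suffix, value) {
  rest <- path_segments(path)[-seq_along(path_segments(group_path))]
  cur <- rep
  assign_rec <- function(node, i) {
    if (i > length(rest)) { node[[suffix]] <- value; return(node) }
    node[[rest[[i]]]] <- assign_rec(node[[rest[[i]]]] %||% list(), i + 1L)
    node
  }
  assign_rec(rep, 1L)
}

assign_group_reps <- function(data, group_path, reps) {
  segs <- path_segments(group_path)
  assign_rec <- function(node, i) {
    if (i > length(segs)) return(reps)
    node[[segs[[i]]]] <- assign_rec(node[[segs[[i]]]] %||% list(), i + 1L)
    node
  }
  assign_rec(data %||% list(), 1L)
}
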