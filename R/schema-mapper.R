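# Archetype relational mapping: turns archetypes plus templates carrying ARM
# constraints into a relational schema model with provenance.
#
# Mapping rules, applied per archetype:
#   1. each (root) archetype maps to a table; versions of one concept share a
#      table when compatible (see merge_versions);
#   2. single-occurrence basic items map to columns (one per resolved field),
#      multiple-occurrence basic items to a standalone table with a foreign
#      key back to the archetype's key;
#   3. the identification data item carries the unique clustered index; if
#      none exists a generated "id" column (invisible to archetype paths) is
#      added and clustered;
#   4. query data items carry non-clustered indexes;
#   5. single-occurrence slots embed the target archetype's items into the
#      current table, multiple-occurrence slots map to a foreign-key column
#      in the *target* archetype's table;
#   6. single-occurrence collections are flattened, multiple-occurrence
#      collections map to standalone tables with a foreign key;
#   7. query data items propagate (like the identification item) into the
#      standalone child tables of multiple-occurrence slots/collections as
#      indexed columns, unless suppressed by the template;
#   8. names follow make_names (class letter + CamelCase concept; child
#      tables append the collection path; columns join item names and field
#      suffix; deterministic shortening).

#' Schema mapping configuration
#'
#' @param profile Naming profile, see [naming_profile()].
#' @param name_limit Identifier length limit.
#' @param standalone_all Map every archetype to a standalone table, including
#'   those only used embedded (default: only "root" archetypes — those not
#'   exclusively specialization parents or single-occurrence slot targets —
#'   get standalone tables, which is how the worked schema is laid out).
#' @param dv_proportion_extended See [resolve_field_columns()].
#' @export
schema_config <- function(profile = naming_profile(), name_limit = 64L,
                          standalone_all = FALSE, dv_proportion_extended = FALSE) {
  profile$name_limit <- name_limit
  list(profile = profile, name_limit = name_limit,
       standalone_all = standalone_all,
       dv_proportion_extended = dv_proportion_extended)
}

column_def <- function(name, storage_kind, nullable, role,
                       provenance = "generated", propagated_from = NULL) {
  list(name = name, storage_kind = storage_kind, nullable = nullable,
       role = role, provenance = provenance, propagated_from = propagated_from)
}

index_def <- function(columns, clustered = FALSE, unique = FALSE)
  list(columns = columns, clustered = clustered, unique = unique)

new_table <- function(name, origin, source_archetypes) {
  list(name = name, origin = origin, source_archetypes = source_archetypes,
       key_col = NULL, columns = list(), indexes = list(), foreign_keys = list())
}

tbl_add_col <- function(tbl, col) {
  if (col$name %in% vapply(tbl$columns, `[[`, "", "name"))
    abort2("name_collision", "column name collision in %s: %s", tbl$name, col$name)
  tbl$columns[[length(tbl$columns) + 1L]] <- col
  tbl
}

tbl_add_index <- function(tbl, idx) {
  if (idx$clustered &&
      any(vapply(tbl$indexes, function(i) isTRUE(i$clustered), TRUE)))
    abort2("two_clustered", "table %s already has a clustered index", tbl$name)
  tbl$indexes[[length(tbl$indexes) + 1L]] <- idx
  tbl
}

empty_provenance <- function()
  data.frame(archetype_id = character(), node_path = character(),
             suffix = character(), table = character(), column = character(),
             stringsAsFactors = FALSE)

empty_embedded <- function()
  data.frame(inner_archetype_id = character(), inner_path = character(),
             table = character(), column = character(), stringsAsFactors = FALSE)

new_schema <- function(config) {
  structure(list(tables = list(), provenance = empty_provenance(),
                 embedded = empty_embedded(), arch_table = character(),
                 plans = list(), templates = list(), eav_maps = list(),
                 migration_plans = list(), config = config),
            class = "arm_schema")
}

join_path <- function(prefix, name)
  paste0(prefix, if (nzchar(prefix)) "/" else "", "[", name, "]")

# ---------------------------------------------------------------------------
# Node-tree walk producing the flat column / group / many-slot plan.
# `segs` carries the column-name segments (collections excluded, slots kept);
# `tsegs` carries the table-name segments (every segment kept).

walk_nodes <- function(nodes, arch, suite, tpl, config,
                       prefix = "", segs = character(), tsegs = character(),
                       nullable = FALSE, visited = character(),
                       inner_arch = NULL) {
  cols <- list(); groups <- list(); many_slots <- list(); embedded <- list()
  for (n in nodes) {
    p <- join_path(prefix, n$name)
    occ <- n$occurrence
    ov <- tpl$optionality_overrides[[p]]
    if (!is.null(ov)) occ <- occurrence(ov)
    null_here <- nullable || occ$lower == 0L
    if (identical(n$kind, "basic")) {
      fields <- resolve_field_columns(n$type, config$dv_proportion_extended)
      if (!occ_many(occ)) {
        for (i in seq_len(nrow(fields))) {
          cname <- column_name_from(c(segs, n$name), fields$suffix[i], config$profile)
          cols[[length(cols) + 1L]] <- list(
            column = cname, path = p, suffix = fields$suffix[i],
            kind = fields$kind[i], nullable = null_here, type = n$type)
          if (!is.null(inner_arch))
            embedded[[length(embedded) + 1L]] <- list(
              inner_archetype_id = inner_arch$id, inner_path = n$path,
              column = cname)
        }
      } else {
        sub <- list(cols = lapply(seq_len(nrow(fields)), function(i) list(
          column = column_name_from(n$name, fields$suffix[i], config$profile),
          path = "", suffix = fields$suffix[i], kind = fields$kind[i],
          nullable = TRUE, type = n$type)),
          groups = list(), many_slots = list(), embedded = list())
        groups[[length(groups) + 1L]] <- list(
          path = p, node = n, origin = "MULTI_ITEM",
          tsegs = c(tsegs, n$name), sub = sub)
      }
    } else if (identical(n$kind, "collection")) {
      if (!occ_many(occ)) {
        r <- walk_nodes(n$children, arch, suite, tpl, config, p, segs,
                        c(tsegs, n$name), null_here, visited, inner_arch)
        cols <- c(cols, r$cols); groups <- c(groups, r$groups)
        many_slots <- c(many_slots, r$many_slots); embedded <- c(embedded, r$embedded)
      } else {
        sub <- walk_nodes(n$children, arch, suite, tpl, config, "", character(),
                          character(), FALSE, visited, inner_arch)
        groups[[length(groups) + 1L]] <- list(
          path = p, node = n, origin = "COLLECTION",
          tsegs = c(tsegs, n$name), sub = sub)
      }
    } else { # slot
      target <- suite[[n$target]]
      if (is.null(target))
        abort2("unresolved_slot", "unresolved slot target %s at %s", n$target, p)
      if (!occ_many(occ)) {
        if (target$id %in% visited)
          abort2("slot_cycle", "slot cycle: %s embeds %s", arch$id, target$id)
        r <- walk_nodes(target$nodes, arch, suite, tpl, config, p,
                        c(segs, n$name), c(tsegs, n$name), null_here,
                        c(visited, target$id), inner_arch %||% target)
        # provenance of embedding records the target archetype too
        r$embedded <- lapply(r$embedded, function(e) e)
        cols <- c(cols, r$cols); groups <- c(groups, r$groups)
        many_slots <- c(many_slots, r$many_slots); embedded <- c(embedded, r$embedded)
      } else {
        many_slots[[length(many_slots) + 1L]] <-
          list(path = p, target = n$target)
      }
    }
  }
  list(cols = cols, groups = groups, many_slots = many_slots, embedded = embedded)
}

#' Embed a single-occurrence slot target into the current archetype
#'
#' Returns the target archetype's nodes re-pathed under the slot path, as
#' they appear inline in the current archetype's table. Embedding recurses
#' through nested single-occurrence slots; a cycle (an archetype embedding
#' itself through any chain) is an error.
#'
#' @param current Archetype holding the slot.
#' @param slot Slot node (`upper` must be 1).
#' @param target The target archetype.
#' @param suite Named archetype list for nested slots.
#' @return List of re-pathed nodes.
#' @export
embed_slot <- function(current, slot, target, suite = list()) {
  if (occ_many(slot$occurrence))
    abort2("not_embeddable", "slot %s has upper bound *; it maps as a foreign key",
           slot$name)
  reroot <- function(nodes, prefix, visited) {
    lapply(nodes, function(n) {
      n$path <- join_path(prefix, n$name)
      if (identical(n$kind, "collection"))
        n$children <- reroot(n$children, n$path, visited)
      if (identical(n$kind, "slot") && !occ_many(n$occurrence)) {
        if (n$target %in% visited)
          abort2("slot_cycle", "slot cycle: %s embeds %s", current$id, n$target)
        tgt <- suite[[n$target]]
        if (!is.null(tgt))
          n$embedded <- reroot(tgt$nodes, n$path, c(visited, n$target))
      }
      n
    })
  }
  if (identical(current$id, target$id))
    abort2("slot_cycle", "slot cycle: %s embeds itself", current$id)
  reroot(target$nodes, join_path("", slot$name), c(current$id, target$id))
}

# ---------------------------------------------------------------------------

resolve_constraint_column <- function(cols, path) {
  hits <- Filter(function(c) identical(c$path, path), cols)
  if (!length(hits))
    abort2("unresolved_path", "ARM constraint path not mapped to a column: %s", path)
  hits[[1L]]
}

is_suppressed <- function(tpl, group_path, qdi_path) {
  for (s in tpl$arm$suppressed_propagations) {
    if (identical(normalize_eav_path(s$group %||% s[[1L]]), group_path) &&
        identical(normalize_eav_path(s$query_item %||% s[[2L]]), qdi_path))
      return(TRUE)
  }
  FALSE
}

# Build the child table(s) for one multi-occurrence group (recursively) and
# return (tables, plan_group, provenance rows).
build_group <- function(g, parent_table, parent_key_col, main_table, qdi_cols,
                        tpl, arch_id, config, base_name) {
  tname <- shorten_identifier(
    paste0(base_name, paste(vapply(g$tsegs, camel, ""), collapse = "")),
    config$name_limit)
  tbl <- new_table(tname, g$origin, arch_id)
  tbl <- tbl_add_col(tbl, column_def("id", "INTEGER", FALSE, "GENERATED_ID"))
  tbl$key_col <- "id"
  tbl <- tbl_add_index(tbl, index_def("id", clustered = TRUE, unique = TRUE))
  fk_col <- shorten_identifier(paste0(parent_table, "_", parent_key_col),
                               config$name_limit)
  fk_kind <- "NVARCHAR"
  attr_kind <- attr(parent_key_col, "kind")
  tbl <- tbl_add_col(tbl, column_def(fk_col, attr_kind %||% "NVARCHAR", FALSE,
                                     "FOREIGN_KEY"))
  tbl$foreign_keys[[1L]] <- list(column = fk_col, target_table = parent_table,
                                 target_column = as.character(parent_key_col))
  tbl <- tbl_add_index(tbl, index_def(fk_col))
  tbl <- tbl_add_col(tbl, column_def("ordinal", "INTEGER", FALSE, "GENERATED_ID"))

  prov <- empty_provenance()
  for (cc in g$sub$cols) {
    full_path <- if (nzchar(cc$path)) paste0(g$path, "/", cc$path) else g$path
    tbl <- tbl_add_col(tbl, column_def(cc$column, cc$kind, TRUE, "DATA",
                                       provenance = list(archetype_id = arch_id,
                                                         node_path = full_path,
                                                         suffix = cc$suffix)))
    prov <- rbind(prov, data.frame(archetype_id = arch_id, node_path = full_path,
                                   suffix = cc$suffix, table = tname,
                                   column = cc$column, stringsAsFactors = FALSE))
  }
  propagated <- list()
  for (q in qdi_cols) {
    if (is_suppressed(tpl, g$path, q$path)) next
    pname <- shorten_identifier(paste0(main_table, "_", q$column), config$name_limit)
    tbl <- tbl_add_col(tbl, column_def(pname, q$kind, TRUE, "PROPAGATED_QUERY",
                                       propagated_from = list(table = main_table,
                                                              column = q$column)))
    tbl <- tbl_add_index(tbl, index_def(pname))
    propagated[[length(propagated) + 1L]] <- list(column = pname,
                                                  parent_column = q$column,
                                                  qdi_path = q$path)
  }
  plan_group <- list(table = tname, group_path = g$path, fk_col = fk_col,
                     key_col = "id", ordinal_col = "ordinal",
                     origin = g$origin,
                     cols = g$sub$cols, propagated = propagated,
                     groups = list())
  tables <- list(tbl)
  kc <- "id"; attr(kc, "kind") <- "INTEGER"
  for (sg in g$sub$groups) {
    r <- build_group(sg, tname, kc, main_table, qdi_cols, tpl,
                     arch_id, config, base_name)
    tables <- c(tables, r$tables)
    plan_group$groups[[sg$path]] <- r$plan
    prov <- rbind(prov, r$prov)
  }
  list(tables = tables, plan = plan_group, prov = prov)
}

map_one <- function(arch, tpl, suite, schema, config, keep_version = FALSE) {
  base_name <- table_base_name(arch, config$profile, keep_version = keep_version)
  tname <- shorten_identifier(base_name, config$name_limit)
  if (tname %in% names(schema$tables))
    abort2("name_collision", "table name collision: %s", tname)
  plan_res <- walk_nodes(arch$nodes, arch, suite, tpl, config)

  tbl <- new_table(tname, "ARCHETYPE_MAIN", arch$id)
  key_info <- NULL
  idi <- tpl$arm$identification_item
  cols <- plan_res$cols
  if (!is.null(idi)) {
    kc <- resolve_constraint_column(cols, idi)
    key_info <- list(type = "idi", column = kc$column, path = idi,
                     suffix = kc$suffix, kind = kc$kind)
    # key column first, then document order
    cols <- c(list(kc), Filter(function(c) !identical(c$column, kc$column), cols))
  } else {
    tbl <- tbl_add_col(tbl, column_def("id", "INTEGER", FALSE, "GENERATED_ID"))
    key_info <- list(type = "generated", column = "id", kind = "INTEGER")
  }
  prov <- empty_provenance(); emb <- empty_embedded()
  for (cc in cols) {
    tbl <- tbl_add_col(tbl, column_def(cc$column, cc$kind, cc$nullable, "DATA",
                                       provenance = list(archetype_id = arch$id,
                                                         node_path = cc$path,
                                                         suffix = cc$suffix)))
    prov <- rbind(prov, data.frame(archetype_id = arch$id, node_path = cc$path,
                                   suffix = cc$suffix, table = tname,
                                   column = cc$column, stringsAsFactors = FALSE))
  }
  for (e in plan_res$embedded)
    emb <- rbind(emb, data.frame(inner_archetype_id = e$inner_archetype_id,
                                 inner_path = e$inner_path, table = tname,
                                 column = e$column, stringsAsFactors = FALSE))
  tbl$key_col <- key_info$column
  tbl <- tbl_add_index(tbl, index_def(key_info$column, clustered = TRUE, unique = TRUE))

  qdi_cols <- list()
  for (q in tpl$arm$query_items) {
    qc <- resolve_constraint_column(plan_res$cols, q)
    tbl <- tbl_add_index(tbl, index_def(qc$column))
    qdi_cols[[length(qdi_cols) + 1L]] <- qc
  }

  plan <- list(archetype_id = arch$id, table = tname, key = key_info,
               main_cols = plan_res$cols, groups = list(),
               many_slots = plan_res$many_slots)
  schema$tables[[tname]] <- tbl
  kc <- key_info$column; attr(kc, "kind") <- key_info$kind %||% "INTEGER"
  for (g in plan_res$groups) {
    r <- build_group(g, tname, kc, tname, qdi_cols, tpl, arch$id, config, base_name)
    for (t in r$tables) {
      if (t$name %in% names(schema$tables))
        abort2("name_collision", "table name collision: %s", t$name)
      schema$tables[[t$name]] <- t
    }
    plan$groups[[g$path]] <- r$plan
    prov <- rbind(prov, r$prov)
  }
  schema$provenance <- rbind(schema$provenance, prov)
  schema$embedded <- rbind(schema$embedded, emb)
  schema$arch_table[[arch$id]] <- tname
  schema$plans[[arch$id]] <- plan
  schema$templates[[arch$id]] <- tpl
  schema
}

null_template <- function(archetype_id)
  template(paste0(archetype_id, ".oet"), archetype_id)

# Root archetypes: not exclusively specialization parents or ONE-slot targets.
root_ids <- function(archetypes, config) {
  ids <- names(archetypes)
  if (isTRUE(config$standalone_all)) return(ids)
  one_targets <- character(); many_targets <- character()
  parents <- character()
  for (a in archetypes) {
    if (!is.null(a$parent)) parents <- c(parents, a$parent)
    for (n in arch_nodes_flat(a)) {
      if (identical(n$kind, "slot")) {
        if (occ_many(n$occurrence)) many_targets <- c(many_targets, n$target)
        else one_targets <- c(one_targets, n$target)
      }
    }
  }
  union(setdiff(ids, union(one_targets, parents)), intersect(many_targets, ids))
}

#' Map archetypes and templates to a relational schema
#'
#' Applies the eight mapping rules and returns the schema model: tables with
#' typed columns, one clustered unique index per table on the identification
#' (or generated) key, non-clustered indexes on query data items, foreign
#' keys for multi-occurrence groups and slots, propagated query columns in
#' child tables, and a provenance map from archetype paths to columns.
#'
#' @param archetypes List of archetypes (named by id, or names are derived).
#' @param templates List of templates (at most one per archetype).
#' @param eav_maps List of EAV mappings (kept on the schema for query
#'   translation).
#' @param config See [schema_config()].
#' @return An `arm_schema`.
#' @export
map_schema <- function(archetypes, templates = list(), eav_maps = list(),
                       config = schema_config()) {
  if (is.null(names(archetypes)) || any(!nzchar(names(archetypes))))
    names(archetypes) <- vapply(archetypes, `[[`, "", "id")
  tpl_by_arch <- list()
  for (tpl in templates) {
    if (!is.null(tpl_by_arch[[tpl$archetype_id]]))
      abort2("duplicate_template", "more than one template for %s", tpl$archetype_id)
    arch <- archetypes[[tpl$archetype_id]]
    if (is.null(arch))
      abort2("template_mismatch", "template %s names unknown archetype %s",
             tpl$template_id, tpl$archetype_id)
    v <- validate_template(tpl, arch, suite = archetypes)
    if (nrow(v))
      abort2("invalid_template", "template %s invalid: %s", tpl$template_id,
             paste(v$message, collapse = "; "))
    tpl_by_arch[[tpl$archetype_id]] <- tpl
  }
  schema <- new_schema(config)
  roots <- root_ids(archetypes, config)
  for (id in roots) {
    tpl <- tpl_by_arch[[id]] %||% null_template(id)
    schema <- map_one(archetypes[[id]], tpl, archetypes, schema, config)
  }
  # rule 5, upper *: FK column (plus propagated query items) in the target table
  for (id in roots) {
    plan <- schema$plans[[id]]
    for (ms in plan$many_slots) {
      tgt_table <- schema$arch_table[[ms$target]]
      if (is.null(tgt_table))
        abort2("unresolved_slot", "many-slot target %s has no standalone table", ms$target)
      src_tbl <- schema$tables[[plan$table]]
      fk_col <- shorten_identifier(paste0(plan$table, "_", plan$key$column),
                                   config$name_limit)
      tt <- schema$tables[[tgt_table]]
      tt <- tbl_add_col(tt, column_def(fk_col, plan$key$kind %||% "INTEGER", TRUE,
                                       "FOREIGN_KEY"))
      tt$foreign_keys[[length(tt$foreign_keys) + 1L]] <-
        list(column = fk_col, target_table = plan$table,
             target_column = plan$key$column)
      tt <- tbl_add_index(tt, index_def(fk_col))
      tpl <- schema$templates[[id]]
      propagated <- list()
      for (q in tpl$arm$query_items) {
        if (is_suppressed(tpl, ms$path, q)) next
        qc <- resolve_constraint_column(plan$main_cols, q)
        pname <- shorten_identifier(paste0(plan$table, "_", qc$column),
                                    config$name_limit)
        tt <- tbl_add_col(tt, column_def(pname, qc$kind, TRUE, "PROPAGATED_QUERY",
                                         propagated_from = list(table = plan$table,
                                                                column = qc$column)))
        tt <- tbl_add_index(tt, index_def(pname))
        propagated[[length(propagated) + 1L]] <-
          list(column = pname, parent_column = qc$column, qdi_path = q)
      }
      schema$tables[[tgt_table]] <- tt
      # record the linkage on both plans
      schema$plans[[id]]$many_slot_links[[ms$path]] <-
        list(target = ms$target, target_table = tgt_table, fk_col = fk_col,
             propagated = propagated)
    }
  }
  schema$eav_maps <- eav_maps
  schema
}

# ---------------------------------------------------------------------------
# Version handling

#' Merge a new archetype version into a schema
#'
#' `REVISION` pairs share one table: the new version's extra columns are
#' added nullable and both versions read/write the same table.
#' `NEW_VERSION` under `TABLE_PER_VERSION` maps the new version to its own
#' table with the version retained in the name; under `MERGE_AND_CONVERT` a
#' new table is created and a migration plan (create/copy/verify/drop) is
#' attached for [apply_migration()]. A `SPECIALIZATION` always maps to a
#' distinct table.
#'
#' @param schema Schema containing `old`'s table.
#' @param old,new The two archetype versions.
#' @param strategy `"TABLE_PER_VERSION"` or `"MERGE_AND_CONVERT"` (only
#'   consulted for NEW_VERSION pairs).
#' @param template Template for `new`; defaults to `old`'s template.
#' @param conversions Named list (target column -> `list(source, transform)`)
#'   supplying value conversions for MERGE_AND_CONVERT; transforms are
#'   `"identity"`, `"cast_number"`, `"cast_text"`.
#' @param suite Archetype suite for slot resolution.
#' @return The extended schema (with `$migration_plans` possibly appended).
#' @export
merge_versions <- function(schema, old, new,
                           strategy = c("TABLE_PER_VERSION", "MERGE_AND_CONVERT"),
                           template = NULL, conversions = NULL, suite = NULL) {
  strategy <- match.arg(strategy)
  rel <- classify_relationship(old, new)
  config <- schema$config
  suite <- suite %||% stats::setNames(list(old, new), c(old$id, new$id))
  tpl <- template %||% schema$templates[[old$id]] %||% null_template(new$id)
  tpl$archetype_id <- new$id

  if (rel == "SPECIALIZATION") {
    return(map_one(new, tpl, suite, schema, config))
  }
  if (rel == "REVISION") {
    old_table <- schema$arch_table[[old$id]]
    if (is.null(old_table)) abort2("unknown_table", "%s is not mapped", old$id)
    # map the new version into a scratch schema, then union columns
    scratch <- map_one(new, tpl, suite, new_schema(config), config)
    merged <- schema$tables[[old_table]]
    for (tname in names(scratch$tables)) {
      nt <- scratch$tables[[tname]]
      if (identical(tname, old_table)) {
        have <- vapply(merged$columns, `[[`, "", "name")
        for (col in nt$columns) {
          if (!(col$name %in% have)) {
            col$nullable <- TRUE   # new-only columns must accept old rows
            merged <- tbl_add_col(merged, col)
          }
        }
        merged$source_archetypes <- union(merged$source_archetypes, new$id)
        schema$tables[[old_table]] <- merged
      } else if (is.null(schema$tables[[tname]])) {
        schema$tables[[tname]] <- nt
      } else {
        schema$tables[[tname]]$source_archetypes <-
          union(schema$tables[[tname]]$source_archetypes, new$id)
      }
    }
    schema$arch_table[[new$id]] <- old_table
    schema$plans[[new$id]] <- scratch$plans[[new$id]]
    schema$templates[[new$id]] <- tpl
    schema$provenance <- rbind(schema$provenance, scratch$provenance)
    return(schema)
  }
  # NEW_VERSION
  schema2 <- map_one(new, tpl, suite, schema, config, keep_version = TRUE)
  if (strategy == "TABLE_PER_VERSION") return(schema2)

  old_table <- schema$arch_table[[old$id]]
  new_table_name <- schema2$arch_table[[new$id]]
  plan <- build_migration_plan(schema2, old_table, new_table_name, conversions)
  schema2$migration_plans[[length(schema2$migration_plans) + 1L]] <- plan
  schema2
}

#' @rdname merge_versions
#' @param old_table,new_table Table names within `schema`.
#' @export
build_migration_plan <- function(schema, old_table, new_table, conversions = NULL) {
  ot <- schema$tables[[old_table]]; nt <- schema$tables[[new_table]]
  if (is.null(ot) || is.null(nt))
    abort2("unknown_table", "migration requires both tables in the schema")
  old_by_prov <- list()
  for (col in ot$columns) {
    if (is.list(col$provenance))
      old_by_prov[[paste0(col$provenance$node_path, "#", col$provenance$suffix)]] <-
        col$name
  }
  old_names <- vapply(ot$columns, `[[`, "", "name")
  mapping <- list()
  for (col in nt$columns) {
    src <- NULL; transform <- "identity"
    conv <- conversions[[col$name]]
    if (!is.null(conv)) {
      src <- conv$source; transform <- conv$transform %||% "identity"
    } else if (is.list(col$provenance)) {
      src <- old_by_prov[[paste0(col$provenance$node_path, "#",
                                 col$provenance$suffix)]]
    } else if (col$name %in% old_names) {
      src <- col$name     # generated/fk columns copied by name
    }
    if (is.null(src) && !col$nullable && !identical(col$role, "GENERATED_ID"))
      abort2("missing_conversion",
             "no field conversion specified for not-null column %s.%s",
             new_table, col$name)
    if (!is.null(src))
      mapping[[length(mapping) + 1L]] <-
        list(target = col$name, source = src, transform = transform)
  }
  structure(list(source_table = old_table, target_table = new_table,
                 steps = c("create_target", "copy", "verify_counts", "drop_source"),
                 mapping = mapping),
            class = "arm_migration_plan")
}

# ---------------------------------------------------------------------------
# Serialization of the schema model (golden-schema format)

#' Serialize a schema model to JSON
#' @param schema Schema.
#' @return JSON text (canonical: tables in mapping order).
#' @export
schema_to_json <- function(schema) {
  tabs <- lapply(schema$tables, function(t) list(
    name = t$name, origin = t$origin,
    source_archetypes = as.list(t$source_archetypes),
    key = t$key_col,
    columns = lapply(t$columns, function(c) compact(list(
      name = c$name, kind = c$storage_kind, nullable = c$nullable,
      role = c$role,
      provenance = if (is.list(c$provenance))
        list(archetype_id = c$provenance$archetype_id,
             node_path = c$provenance$node_path, suffix = c$provenance$suffix)
      else "generated",
      propagated_from = c$propagated_from))),
    indexes = lapply(t$indexes, function(i) list(
      columns = as.list(i$columns), clustered = isTRUE(i$clustered),
      unique = isTRUE(i$unique))),
    foreign_keys = t$foreign_keys))
  as.character(jsonlite::toJSON(list(tables = unname(tabs)),
                                auto_unbox = TRUE, pretty = TRUE, digits = NA))
}

#' Structural summary used to compare a schema against a golden model
#' @param x Schema (`arm_schema`) or parsed golden JSON (list).
#' @return A canonical list structure.
#' @export
schema_structure <- function(x) {
  if (inherits(x, "arm_schema")) x <- jsonlite::fromJSON(schema_to_json(x),
                                                         simplifyVector = FALSE)
  tabs <- lapply(x$tables, function(t) {
    idx <- lapply(t$indexes, function(i)
      list(columns = unlist(i$columns), clustered = isTRUE(i$clustered),
           unique = isTRUE(i$unique)))
    idx <- idx[order(vapply(idx, function(i) paste(i$columns, collapse = ","), ""))]
    list(name = t$name, origin = t$origin, key = t$key,
         columns = lapply(t$columns, function(c)
           list(name = c$name, kind = c$kind, nullable = isTRUE(c$nullable),
                role = c$role)),
         indexes = idx,
         foreign_keys = lapply(t$foreign_keys, function(f)
           list(column = f$column, target_table = f$target_table,
                target_column = f$target_column)))
  })
  tabs[order(vapply(tabs, `[[`, "", "name"))]
}
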