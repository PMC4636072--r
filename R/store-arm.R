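# ARM store: persists archetype instances into the generated relational
# schema and answers queries by stepwise simple statements (per-condition key
# sets intersected in R), mirroring how the mapped database is meant to be
# used: no nested joins, child tables reached through foreign keys and
# propagated query columns.

#' An ARM store handle
#'
#' Couples an engine database with the schema and the archetype suite.
#'
#' @param schema Schema model.
#' @param suite Named list of archetypes.
#' @return An `arm_store` (environment).
#' @export
arm_store <- function(schema, suite) {
  st <- arm_db()
  deploy_schema(st, schema)
  st$suite <- suite
  class(st) <- c("arm_store", "arm_db")
  st
}

store_plan <- function(store, archetype_id) {
  p <- store$schema$plans[[archetype_id]]
  if (is.null(p))
    abort2("unknown_archetype", "archetype not mapped to this schema: %s",
           archetype_id)
  p
}

# Value of one column binding from a canonical data tree (full outer path).
tree_value_at <- function(data, path, suffix) {
  segs <- path_segments(path)
  cur <- data
  for (s in segs) {
    cur <- cur[[s]]
    if (is.null(cur)) return(NA)
  }
  cur[[suffix]] %||% NA
}

#' Store an instance through the ARM mapping
#'
#' Single-occurrence leaves (including embedded slot content and flattened
#' collections) are written as columns of the main row; every repetition of
#' a multiple-occurrence group becomes a child-table row carrying the foreign
#' key, its ordinal, and the propagated query-item values copied from the
#' parent row.
#'
#' @param store ARM store.
#' @param instance Instance (validated and canonicalized on the way in).
#' @return The instance key (identification value, or generated key), as a
#'   character scalar.
#' @export
store_instance <- function(store, instance) {
  arch <- store$suite[[instance$archetype_id]]
  if (is.null(arch))
    abort2("unknown_archetype", "unknown archetype %s", instance$archetype_id)
  inst <- validate_instance(instance, arch, store$suite)
  plan <- store_plan(store, instance$archetype_id)

  row <- list()
  for (cc in plan$main_cols)
    row[[cc$column]] <- tree_value_at(inst$data, cc$path, cc$suffix)
  if (plan$key$type == "generated") {
    key <- db_next_id(store, plan$table)
    row[["id"]] <- key
  } else {
    key <- row[[plan$key$column]]
    if (is.null(key) || is.na(key))
      abort2("missing_identification", "identification value absent for %s",
             instance$archetype_id)
  }
  db_insert(store, plan$table, lapply(row, function(v) v))
  for (g in plan$groups)
    store_group(store, g, inst$data, key, row)
  key <- as.character(key)
  key
}

# repetitions of the group node within `data` (list, possibly empty)
group_reps <- function(data, group_path) {
  segs <- path_segments(group_path)
  cur <- data
  for (s in segs) {
    cur <- cur[[s]]
    if (is.null(cur)) return(list())
  }
  cur
}

store_group <- function(store, g, data, parent_key, parent_row) {
  reps <- group_reps(data, g$group_path)
  if (!length(reps)) return(invisible())
  rows <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    rep <- reps[[i]]
    row <- list(id = db_next_id(store, g$table))
    row[[g$fk_col]] <- parent_key
    row[[g$ordinal_col]] <- i - 1L
    for (cc in g$cols) {
      v <- if (nzchar(cc$path)) tree_value_at(rep, cc$path, cc$suffix)
      else rep[[cc$suffix]] %||% NA
      row[[cc$column]] <- v
    }
    for (pp in g$propagated)
      row[[pp$column]] <- parent_row[[pp$parent_column]] %||% NA
    rows[[i]] <- row
    for (sg in g$groups)
      store_group(store, sg, rep, row$id, row)
  }
  cols <- names(rows[[1L]])
  batch <- stats::setNames(lapply(cols, function(cn)
    unlist(lapply(rows, function(r) {
      v <- r[[cn]]; if (is.null(v) || length(v) == 0L) NA else v
    }))), cols)
  db_insert(store, g$table, batch)
  invisible()
}

set_tree_value <- function(data, path, suffix, value) {
  segs <- path_segments(path)
  assign_rec <- function(node, i) {
    if (i > length(segs)) {
      node[[suffix]] <- value
      return(node)
    }
    node[[segs[[i]]]] <- assign_rec(node[[segs[[i]]]] %||% list(), i + 1L)
    node
  }
  assign_rec(data %||% list(), 1L)
}

#' Retrieve a stored instance by key
#'
#' Reconstructs the full value tree: main-row columns, child-table rows in
#' ordinal order for every multiple-occurrence group, embedded slot content
#' inline. The result is structurally equal to the canonical form of the
#' stored instance.
#'
#' @param store ARM store.
#' @param archetype_id Archetype id.
#' @param key Instance key.
#' @return The instance.
#' @export
retrieve_instance <- function(store, archetype_id, key) {
  plan <- store_plan(store, archetype_id)
  tab <- db_table(store, plan$table)
  kv <- tab[[plan$key$column]]
  hit <- if (is.character(kv)) which(kv == as.character(key))
  else which(kv == as.integer(key))
  if (!length(hit)) abort2("not_found", "no %s instance with key %s",
                           archetype_id, key)
  rowi <- hit[[1L]]
  data <- list()
  for (cc in plan$main_cols) {
    v <- tab[[cc$column]][[rowi]]
    if (!is.na(v)) data <- set_tree_value(data, cc$path, cc$suffix, v)
  }
  pk <- tab[[plan$key$column]][[rowi]]
  for (g in plan$groups)
    data <- retrieve_group(store, g, data, pk)
  arch <- store$suite[[archetype_id]]
  validate_instance(archetype_instance(archetype_id, data), arch, store$suite)
}

retrieve_group <- function(store, g, data, parent_key) {
  tab <- db_table(store, g$table)
  fkv <- tab[[g$fk_col]]
  hits <- if (is.character(fkv)) which(fkv == as.character(parent_key))
  else which(fkv == as.integer(parent_key))
  hits <- hits[order(tab[[g$ordinal_col]][hits])]
  reps <- lapply(hits, function(i) {
    rep <- list()
    for (cc in g$cols) {
      v <- tab[[cc$column]][[i]]
      if (is.na(v)) next
      rep <- if (nzchar(cc$path)) set_tree_value(rep, cc$path, cc$suffix, v)
      else { rep[[cc$suffix]] <- v; rep }
    }
    for (sg in g$groups)
      rep <- retrieve_group(store, sg, rep, tab[[g$key_col]][[i]])
    rep
  })
  segs <- path_segments(g$group_path)
  assign_rec <- function(node, i) {
    if (i == length(segs)) { node[[segs[[i]]]] <- reps; return(node) }
    node[[segs[[i]]]] <- assign_rec(node[[segs[[i]]]] %||% list(), i + 1L)
    node
  }
  assign_rec(data, 1L)
}
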