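# Node+Path reference backend: one table per concept, each row holding
# <instance key, repetition ordinal, node path, serialized node value>. The
# path of every data item is stored fully denormalized per row — that
# redundancy is the phenomenon this backend exists to exhibit — and queries
# are path-predicate scans with per-instance grouping; no schema-specific
# indexes beyond the instance key exist.
#
# Serialization is a typed-prefix text encoding so numeric comparisons can
# deserialize before comparing: "t:" text, "i:" integer, "f:" float (17
# significant digits, lossless for doubles).

np_serialize <- function(value, kind) {
  switch(kind,
         NVARCHAR = paste0("t:", as.character(value)),
         INTEGER = paste0("i:", as.integer(value)),
         FLOAT = paste0("f:", formatC(as.numeric(value), digits = 17,
                                      format = "g")))
}

np_deserialize <- function(s) {
  kind <- substr(s, 1L, 1L)
  body <- substring(s, 3L)
  switch(kind,
         t = body,
         i = as.integer(body),
         f = as.numeric(body),
         abort2("bad_serialization", "unknown value tag in %s", s))
}

#' A Node+Path store handle
#'
#' One engine table per root concept, named like the ARM main table of the
#' same archetype so reports line up across backends.
#'
#' @param schema Schema model (used for concept naming and key rules only).
#' @param suite Named archetype list.
#' @return An `np_store`.
#' @export
np_store <- function(schema, suite) {
  st <- arm_db()
  for (id in names(schema$plans)) {
    plan <- schema$plans[[id]]
    db_create_table(st, plan$table,
                    columns = c(instance_key = "NVARCHAR", ordinal = "INTEGER",
                                node_path = "NVARCHAR", val = "NVARCHAR"),
                    unique_sets = list(c("instance_key", "ordinal", "node_path")))
  }
  st$schema <- schema
  st$suite <- suite
  class(st) <- c("np_store", "arm_db")
  st
}

# Flatten a canonical value tree into <ordinal, path, serialized value> rows.
np_leaf_rows <- function(nodes, data, suite, prefix, ordinal, counter_env) {
  rows <- list()
  for (n in nodes) {
    v <- data[[n$name]]
    if (is.null(v)) next
    p <- join_path(prefix, n$name)
    many <- occ_many(n$occurrence)
    reps <- if (many) v else list(v)
    for (i in seq_along(reps)) {
      o <- if (many) ordinal * 100000L + (i - 1L) else ordinal
      rep <- reps[[i]]
      if (identical(n$kind, "basic")) {
        fields <- resolve_field_columns(n$type)
        for (j in seq_len(nrow(fields))) {
          fv <- rep[[fields$suffix[j]]]
          if (is.null(fv)) next
          rows[[length(rows) + 1L]] <- list(
            ordinal = o, node_path = paste0(p, "/value/", fields$suffix[j]),
            val = np_serialize(fv, fields$kind[j]))
        }
      } else {
        kids <- if (identical(n$kind, "collection")) n$children
        else suite[[n$target]]$nodes
        rows <- c(rows, np_leaf_rows(kids, rep, suite, p, o, counter_env))
      }
    }
  }
  rows
}

#' Store an instance in the Node+Path backend
#'
#' Writes one row per populated leaf field plus one registration row
#' (path `"#key"`) carrying the key, so empty instances remain addressable.
#' Keys follow the same rule as the ARM store: the identification value when
#' the template declares one, otherwise a per-concept counter.
#'
#' @param store Node+Path store.
#' @param instance Instance.
#' @return Instance key (character).
#' @export
np_store_instance <- function(store, instance) {
  arch <- store$suite[[instance$archetype_id]]
  if (is.null(arch))
    abort2("unknown_archetype", "unknown archetype %s", instance$archetype_id)
  inst <- validate_instance(instance, arch, store$suite)
  plan <- store_plan(store, instance$archetype_id)
  if (plan$key$type == "generated") {
    key <- as.character(db_next_id(store, plan$table))
  } else {
    vals <- instance_field_values(inst, arch, plan$key$path, plan$key$suffix,
                                  store$suite)
    if (!length(vals))
      abort2("missing_identification", "identification value absent for %s",
             instance$archetype_id)
    key <- as.character(vals[[1L]])
  }
  leaf <- np_leaf_rows(arch$nodes, inst$data, store$suite, "", 0L, NULL)
  n <- length(leaf)
  db_insert(store, plan$table, list(
    instance_key = rep(key, n + 1L),
    ordinal = c(0L, vapply(leaf, function(r) as.integer(r$ordinal), 0L)),
    node_path = c("#key", vapply(leaf, `[[`, "", "node_path")),
    val = c(np_serialize(key, "NVARCHAR"), vapply(leaf, `[[`, "", "val"))))
  key
}

#' Retrieve an instance from the Node+Path backend
#' @param store Node+Path store.
#' @param archetype_id Archetype id.
#' @param key Instance key.
#' @return The instance (canonical form).
#' @export
np_retrieve_instance <- function(store, archetype_id, key) {
  plan <- store_plan(store, archetype_id)
  tab <- db_table(store, plan$table)
  rows <- tab[tab$instance_key == as.character(key), ]
  if (!nrow(rows)) abort2("not_found", "no %s instance with key %s",
                          archetype_id, key)
  arch <- store$suite[[archetype_id]]
  data <- np_rebuild(arch$nodes, rows, store$suite, "", 0L)
  validate_instance(archetype_instance(archetype_id, data), arch, store$suite)
}

np_rebuild <- function(nodes, rows, suite, prefix, ordinal) {
  out <- list()
  for (n in nodes) {
    p <- join_path(prefix, n$name)
    many <- occ_many(n$occurrence)
    if (identical(n$kind, "basic")) {
      fields <- resolve_field_columns(n$type)
      build_leaf <- function(o) {
        rec <- list()
        for (j in seq_len(nrow(fields))) {
          path_j <- paste0(p, "/value/", fields$suffix[j])
          hit <- rows$val[rows$node_path == path_j & rows$ordinal == o]
          if (length(hit)) rec[[fields$suffix[j]]] <- np_deserialize(hit[[1L]])
        }
        rec
      }
      if (many) {
        pfx <- paste0(p, "/value/")
        ords <- sort(unique(rows$ordinal[startsWith(rows$node_path, pfx) &
                                           rows$ordinal %/% 100000L == ordinal]))
        out[[n$name]] <- lapply(ords, build_leaf)
      } else {
        rec <- build_leaf(ordinal)
        if (length(rec)) out[[n$name]] <- rec
      }
    } else {
      kids <- if (identical(n$kind, "collection")) n$children
      else suite[[n$target]]$nodes
      if (many) {
        pfx <- paste0(p, "/")
        ords <- sort(unique(rows$ordinal[startsWith(rows$node_path, pfx) &
                                           rows$ordinal %/% 100000L == ordinal]))
        out[[n$name]] <- lapply(ords, function(o)
          np_rebuild(kids, rows, suite, p, o))
      } else {
        sub <- np_rebuild(kids, rows, suite, p, ordinal)
        if (length(sub)) out[[n$name]] <- sub
      }
    }
  }
  # multiple-occurrence nodes always materialize, even when empty
  for (n in nodes) {
    if (occ_many(n$occurrence) && is.null(out[[n$name]])) out[[n$name]] <- list()
  }
  out
}

np_field_path <- function(arch, path, suffix, suite) {
  r <- find_node(arch, path, suite)
  if (is.null(r)) abort2("unresolved_path", "path does not resolve: %s", path)
  suffix <- suffix %||% primary_field_suffix(r$node$type)
  paste0(path, "/value/", suffix)
}

np_clause_keys <- function(store, clause) {
  plan <- store_plan(store, clause$archetype_id)
  arch <- store$suite[[clause$archetype_id]]
  tab <- db_table(store, plan$table)
  all_keys <- unique(tab$instance_key[tab$node_path == "#key"])
  conds <- clause$conditions
  if (!length(conds)) return(all_keys)
  tags <- vapply(conds, function(c) c$group %||% NA_character_, "")
  bundles <- split(seq_along(conds), ifelse(is.na(tags),
                                            paste0("#", seq_along(conds)), tags))
  keysets <- list()
  for (b in bundles) {
    cset <- conds[b]
    per_cond <- lapply(cset, function(cn) {
      p <- np_field_path(arch, cn$path, cn$suffix, store$suite)
      sel <- tab$node_path == p
      ok <- sel
      ok[sel] <- compare_values(lapply(tab$val[sel], np_deserialize),
                                cn$op, cn$value)
      paste0(tab$instance_key[ok], "\r", tab$ordinal[ok])
    })
    hit_pairs <- per_cond[[1L]]
    for (k in per_cond[-1L]) hit_pairs <- intersect(hit_pairs, k)
    if (length(cset) == 1L) {
      keys <- unique(sub("\r.*$", "", per_cond[[1L]]))
    } else {
      keys <- unique(sub("\r.*$", "", hit_pairs))   # same-repetition bundle
    }
    keysets[[length(keysets) + 1L]] <- keys
  }
  out <- keysets[[1L]]
  for (k in keysets[-1L]) out <- intersect(out, k)
  out
}

#' Run a query against the Node+Path backend
#'
#' Same result contract as [run_query()], implemented by full path-predicate
#' scans of the concept table (the backend has no per-field indexes, so every
#' condition reads all rows whose path matches).
#'
#' @param store Node+Path store.
#' @param spec Query spec.
#' @return An `arm_resultset`.
#' @export
np_run_query <- function(store, spec) {
  stopifnot(inherits(spec, "arm_query"))
  if (spec$grouping == "subject") {
    subj_sets <- lapply(spec$clauses, function(cl) {
      keys <- np_clause_keys(store, cl)
      arch <- store$suite[[cl$archetype_id]]
      plan <- store_plan(store, cl$archetype_id)
      tab <- db_table(store, plan$table)
      sp <- np_field_path(arch, cl$subject_path, NULL, store$suite)
      sel <- tab$node_path == sp & tab$instance_key %in% keys
      unique(vapply(tab$val[sel], function(s) as.character(np_deserialize(s)), ""))
    })
    out <- subj_sets[[1L]]
    for (s in subj_sets[-1L]) out <- intersect(out, s)
    return(result_set("subject",
                      lapply(out, function(s) list(key = s, values = NULL))))
  }
  cl <- spec$clauses[[1L]]
  keys <- np_clause_keys(store, cl)
  matches <- lapply(keys, function(k) {
    values <- if (identical(spec$projection, "NONE")) NULL else {
      inst <- np_retrieve_instance(store, cl$archetype_id, k)
      if (identical(spec$projection, "ALL")) inst$data
      else {
        out <- list()
        for (p in spec$projection) {
          segs <- path_segments(p)
          cur <- inst$data
          for (s in segs) cur <- cur[[s]]
          out[[p]] <- cur
        }
        out
      }
    }
    list(key = k, values = values)
  })
  result_set("instance", matches)
}
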