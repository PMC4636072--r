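# Backend-neutral query specifications and result sets.
#
# A query is a conjunction of conditions over archetype fields. A condition
# on a multiple-occurrence group holds when some repetition satisfies it;
# conditions sharing a `group` tag must be satisfied within the same
# repetition (used by specialized-over-generalized translation). A spec may
# hold several clauses targeting different archetypes; their results are
# intersected at subject level ("find all patients with ... and ...").

#' Query condition
#' @param path Bracketed node path of a basic item.
#' @param op Comparator: `=`, `>=`, `<=`, `LIKE`.
#' @param value Literal (character or numeric).
#' @param suffix Field suffix; default the type's primary field (resolved at
#'   execution).
#' @param group Optional same-repetition group tag.
#' @return A condition record.
#' @export
condition <- function(path, op, value, suffix = NULL, group = NA_character_) {
  if (!op %in% c("=", ">=", "<=", "LIKE"))
    abort2("bad_comparator", "unsupported comparator: %s", op)
  list(path = path, op = op, value = value, suffix = suffix, group = group)
}

#' Query clause over one archetype
#' @param archetype_id Target archetype.
#' @param conditions List of [condition()]s (empty = all instances).
#' @param subject_path Path of the subject (patient) item used for subject
#'   grouping; default `"[patient]"`.
#' @export
query_clause <- function(archetype_id, conditions = list(),
                         subject_path = "[patient]") {
  list(archetype_id = archetype_id, conditions = conditions,
       subject_path = subject_path)
}

#' Query specification
#'
#' @param clauses One [query_clause()] or a list of them (several clauses
#'   intersect at subject level and require subject grouping).
#' @param grouping `"instance"` or `"subject"`.
#' @param projection `"ALL"`, `"NONE"`, or a character vector of node paths
#'   whose values are returned per match.
#' @return An `arm_query` object.
#' @export
query_spec <- function(clauses, grouping = c("instance", "subject"),
                       projection = "NONE") {
  grouping <- match.arg(grouping)
  if (!is.null(clauses$archetype_id)) clauses <- list(clauses)
  if (length(clauses) > 1L && grouping != "subject")
    abort2("bad_query", "multi-archetype queries require subject grouping")
  structure(list(clauses = clauses, grouping = grouping,
                 projection = projection),
            class = "arm_query")
}

#' Result set
#'
#' Keys ascend deterministically; `matches` holds one record per key with
#' any projected values; the digest summarizes the full canonical content.
#'
#' @param grouping Grouping unit.
#' @param matches List of `list(key, values)` records.
#' @return An `arm_resultset`.
#' @export
result_set <- function(grouping, matches) {
  keys <- vapply(matches, function(m) as.character(m$key), "")
  if (anyDuplicated(keys)) abort2("duplicate_keys", "duplicate result keys")
  ord <- match(sort_keys(keys), keys)
  matches <- matches[ord]
  rs <- structure(list(grouping = grouping, keys = keys[ord],
                       matches = matches, digest = NA_character_),
                  class = "arm_resultset")
  rs$digest <- fnv1a32(canonical_json(list(grouping, rs$keys,
                                           lapply(matches, `[[`, "values"))))
  rs
}

#' Compare two result sets for equality of content
#' @param a,b Result sets.
#' @export
result_equal <- function(a, b) identical(a$digest, b$digest)

# Shared comparator semantics: numeric literals compare numerically (values
# parsed when stored as text, e.g. the generalized result item), text
# literals compare byte-wise; LIKE translates % and _ wildcards.
compare_values <- function(values, op, literal) {
  if (!length(values)) return(logical(0))
  v <- unlist(values)
  if (is.numeric(literal)) {
    nv <- suppressWarnings(as.numeric(v))
    res <- switch(op, "=" = nv == literal, ">=" = nv >= literal,
                  "<=" = nv <= literal,
                  "LIKE" = abort2("bad_comparator", "LIKE needs a text literal"))
    res & !is.na(res)
  } else {
    cv <- as.character(v)
    if (op == "LIKE") {
      rx <- gsub("%", ".*", gsub("_", ".", glob_escape(literal), fixed = TRUE),
                 fixed = TRUE)
      res <- grepl(paste0("^", rx, "$"), cv)
    } else {
      res <- switch(op, "=" = cv == literal, ">=" = cv >= literal,
                    "<=" = cv <= literal)
    }
    res & !is.na(res)
  }
}

glob_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# ---------------------------------------------------------------------------
# ARM execution: stepwise simple statements, key-set intersection.

# Locate the table/column carrying (archetype, path, suffix).
resolve_condition_column <- function(schema, archetype_id, path, suffix) {
  prov <- schema$provenance
  hit <- prov[prov$archetype_id == archetype_id & prov$node_path == path, ,
              drop = FALSE]
  if (is.null(suffix)) {
    if (!nrow(hit))
      abort2("unresolved_path", "no column for %s %s", archetype_id, path)
    hit <- hit[1L, , drop = FALSE]
  } else {
    hit <- hit[hit$suffix == suffix, , drop = FALSE]
    if (!nrow(hit))
      abort2("unresolved_path", "no column for %s %s/%s", archetype_id, path, suffix)
  }
  list(table = hit$table[[1L]], column = hit$column[[1L]],
       suffix = hit$suffix[[1L]])
}

# find the plan group (recursively) whose table is `tname`
find_plan_group <- function(groups, tname) {
  for (g in groups) {
    if (identical(g$table, tname)) return(g)
    r <- find_plan_group(g$groups, tname)
    if (!is.null(r)) return(r)
  }
  NULL
}

arm_clause_keys <- function(store, clause) {
  schema <- store$schema
  plan <- store_plan(store, clause$archetype_id)
  main_tab <- db_table(store, plan$table)
  all_keys <- as.character(main_tab[[plan$key$column]])

  conds <- clause$conditions
  if (!length(conds)) return(all_keys)

  # partition: group tags bundle same-repetition conditions
  tags <- vapply(conds, function(c) c$group %||% NA_character_, "")
  bundles <- split(seq_along(conds), ifelse(is.na(tags),
                                            paste0("#", seq_along(conds)), tags))
  keysets <- list()
  for (b in bundles) {
    cset <- conds[b]
    locs <- lapply(cset, function(cn)
      resolve_condition_column(schema, clause$archetype_id, cn$path, cn$suffix))
    tabs <- unique(vapply(locs, `[[`, "", "table"))
    if (length(tabs) != 1L && length(cset) > 1L)
      abort2("bad_query", "same-repetition conditions must target one group")
    tname <- tabs[[1L]]
    tab <- db_table(store, tname)
    ok <- rep(TRUE, nrow(tab))
    for (i in seq_along(cset))
      ok <- ok & compare_values(as.list(tab[[locs[[i]]$column]]),
                                cset[[i]]$op, cset[[i]]$value)
    if (identical(tname, plan$table)) {
      keys <- as.character(tab[[plan$key$column]][ok])
    } else {
      g <- find_plan_group(plan$groups, tname)
      if (is.null(g))
        abort2("bad_query", "condition column lies outside the archetype: %s", tname)
      # climb: child rows -> parent keys (groups nest at most into the main
      # table through their fk chain)
      keys <- unique(as.character(tab[[g$fk_col]][ok]))
      # nested group: resolve up to the main table
      parent <- find_parent_group(plan$groups, g$table)
      while (!is.null(parent)) {
        ptab <- db_table(store, parent$table)
        keys <- unique(as.character(
          ptab[[parent$fk_col]][as.character(ptab[[parent$key_col]]) %in% keys]))
        parent <- find_parent_group(plan$groups, parent$table)
      }
    }
    keysets[[length(keysets) + 1L]] <- unique(keys)
  }
  out <- keysets[[1L]]
  for (k in keysets[-1L]) out <- intersect(out, k)
  out
}

find_parent_group <- function(groups, child_table, parent = NULL) {
  for (g in groups) {
    if (identical(g$table, child_table)) return(parent)
    r <- find_parent_group(g$groups, child_table, g)
    if (!is.null(r) || !is.null(find_plan_group(g$groups, child_table)))
      return(r)
  }
  NULL
}

arm_subject_of <- function(store, clause, keys) {
  plan <- store_plan(store, clause$archetype_id)
  loc <- resolve_condition_column(store$schema, clause$archetype_id,
                                  clause$subject_path, NULL)
  tab <- db_table(store, plan$table)
  tk <- as.character(tab[[plan$key$column]])
  as.character(tab[[loc$column]][match(keys, tk)])
}

project_values <- function(store, clause, key, projection) {
  if (identical(projection, "NONE")) return(NULL)
  inst <- retrieve_instance(store, clause$archetype_id, key)
  if (identical(projection, "ALL")) return(inst$data)
  out <- list()
  for (p in projection) {
    segs <- path_segments(p)
    cur <- inst$data
    for (s in segs) cur <- cur[[s]]
    out[[p]] <- cur
  }
  out
}

#' Run a query against the ARM store
#'
#' Execution is stepwise: each condition (or same-repetition bundle) is
#' evaluated as one simple scan of the table holding its column, producing a
#' key set; key sets are intersected; child-table hits climb foreign keys to
#' main-table keys. Subject grouping maps keys through the subject column
#' and, with several clauses, intersects per-archetype subject sets.
#'
#' @param store ARM store.
#' @param spec [query_spec()].
#' @return An `arm_resultset`.
#' @export
run_query <- function(store, spec) {
  stopifnot(inherits(spec, "arm_query"))
  if (spec$grouping == "subject") {
    subj_sets <- lapply(spec$clauses, function(cl) {
      keys <- arm_clause_keys(store, cl)
      s <- arm_subject_of(store, cl, keys)
      unique(s[!is.na(s)])
    })
    out <- subj_sets[[1L]]
    for (s in subj_sets[-1L]) out <- intersect(out, s)
    return(result_set("subject", lapply(out, function(s) list(key = s,
                                                              values = NULL))))
  }
  cl <- spec$clauses[[1L]]
  keys <- arm_clause_keys(store, cl)
  matches <- lapply(keys, function(k)
    list(key = k, values = project_values(store, cl, k, spec$projection)))
  result_set("instance", matches)
}
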