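# Brute-force in-memory oracle: evaluates a query spec directly over a list
# of instances, with the same condition semantics as the store backends.
# Used in tests and acceptance runs as the independent reference.

#' Assign instance keys the way the stores do
#'
#' Identification values where the schema has an IDI; otherwise a counter in
#' stream order per concept (both backends allocate generated keys in
#' insertion order, so the oracle reproduces them exactly).
#'
#' @param instances List of instances, in store order.
#' @param schema Schema model.
#' @param suite Archetype suite.
#' @return Character vector of keys, parallel to `instances`.
#' @export
oracle_assign_keys <- function(instances, schema, suite) {
  counters <- new.env(parent = emptyenv())
  vapply(instances, function(inst) {
    plan <- schema$plans[[inst$archetype_id]]
    if (is.null(plan)) abort2("unknown_archetype", "unmapped archetype %s",
                              inst$archetype_id)
    if (plan$key$type == "generated") {
      k <- (counters[[plan$table]] %||% 0L) + 1L
      counters[[plan$table]] <- k
      as.character(k)
    } else {
      arch <- suite[[inst$archetype_id]]
      v <- instance_field_values(validate_instance(inst, arch, suite), arch,
                                 plan$key$path, plan$key$suffix, suite)
      as.character(v[[1L]])
    }
  }, "")
}

# Locate the first multiple-occurrence node along a path; returns the group
# path and the remaining segments inside it, or NULL when the path never
# repeats.
split_at_group <- function(arch, path, suite) {
  segs <- path_segments(path)
  for (i in seq_along(segs)) {
    r <- find_node(arch, make_path(segs[seq_len(i)]), suite)
    if (is.null(r)) abort2("unresolved_path", "path does not resolve: %s", path)
    if (occ_many(r$node$occurrence))
      return(list(group_path = make_path(segs[seq_len(i)]),
                  rest = segs[-seq_len(i)]))
  }
  NULL
}

# value of a condition field inside one repetition record
rep_field_value <- function(rep, rest, suffix) {
  cur <- rep
  for (s in rest) {
    cur <- cur[[s]]
    if (is.null(cur)) return(NULL)
  }
  cur[[suffix]]
}

# does one instance satisfy a condition bundle? A bundle of several
# conditions must hold within the same repetition of the shared group.
oracle_satisfies <- function(inst, arch, suite, cset) {
  if (length(cset) == 1L) {
    cn <- cset[[1L]]
    vals <- instance_field_values(inst, arch, cn$path, cn$suffix, suite)
    return(any(compare_values(vals, cn$op, cn$value)))
  }
  parts <- lapply(cset, function(cn) {
    g <- split_at_group(arch, cn$path, suite)
    if (is.null(g))
      abort2("bad_query", "same-repetition condition on a non-repeating path: %s",
             cn$path)
    r <- find_node(arch, cn$path, suite)
    list(group = g$group_path, rest = g$rest,
         suffix = cn$suffix %||% primary_field_suffix(r$node$type))
  })
  gp <- unique(vapply(parts, `[[`, "", "group"))
  if (length(gp) != 1L)
    abort2("bad_query", "same-repetition conditions must share one group")
  reps <- group_reps(inst$data, gp)
  for (rep in reps) {
    ok <- TRUE
    for (i in seq_along(cset)) {
      v <- rep_field_value(rep, parts[[i]]$rest, parts[[i]]$suffix)
      if (is.null(v) || !any(compare_values(list(v), cset[[i]]$op,
                                            cset[[i]]$value))) {
        ok <- FALSE; break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Prepare an in-memory oracle over an instance list
#'
#' Canonicalizes every instance and assigns keys once, so repeated
#' [oracle_query()] calls only pay for condition evaluation.
#'
#' @param instances List of instances (store order).
#' @param schema Schema model.
#' @param suite Archetype suite.
#' @return An `arm_oracle` object.
#' @export
oracle_prepare <- function(instances, schema, suite) {
  structure(list(
    keys = oracle_assign_keys(instances, schema, suite),
    canon = lapply(instances, function(i)
      validate_instance(i, suite[[i$archetype_id]], suite)),
    by_arch = split(seq_along(instances),
                    vapply(instances, `[[`, "", "archetype_id")),
    suite = suite),
    class = "arm_oracle")
}

#' Evaluate a query spec over in-memory instances
#'
#' @param instances List of instances (store order) or a prepared
#'   [oracle_prepare()] object.
#' @param spec Query spec.
#' @param schema Schema model (key assignment, subject resolution).
#' @param suite Archetype suite.
#' @return An `arm_resultset`, comparable with the backends' results.
#' @export
oracle_query <- function(instances, spec, schema = NULL, suite = NULL) {
  prep <- if (inherits(instances, "arm_oracle")) instances
  else oracle_prepare(instances, schema, suite)
  suite <- suite %||% prep$suite
  keys <- prep$keys
  canon <- prep$canon
  by_arch <- prep$by_arch
  clause_hits <- function(cl) {
    idx <- by_arch[[cl$archetype_id]] %||% integer()
    arch <- suite[[cl$archetype_id]]
    tags <- vapply(cl$conditions, function(c) c$group %||% NA_character_, "")
    bundles <- split(seq_along(cl$conditions),
                     ifelse(is.na(tags), paste0("#", seq_along(cl$conditions)),
                            tags))
    keep <- vapply(idx, function(i) {
      all(vapply(bundles, function(b)
        oracle_satisfies(canon[[i]], arch, suite, cl$conditions[b]), TRUE))
    }, TRUE)
    idx[keep]
  }
  if (spec$grouping == "subject") {
    subj_sets <- lapply(spec$clauses, function(cl) {
      idx <- clause_hits(cl)
      arch <- suite[[cl$archetype_id]]
      s <- unlist(lapply(idx, function(i) {
        v <- instance_field_values(canon[[i]], arch, cl$subject_path, NULL, suite)
        if (length(v)) as.character(v[[1L]]) else NA_character_
      }))
      unique(s[!is.na(s)])
    })
    out <- subj_sets[[1L]] %||% character()
    for (s in subj_sets[-1L]) out <- intersect(out, s)
    return(result_set("subject",
                      lapply(out, function(s) list(key = s, values = NULL))))
  }
  cl <- spec$clauses[[1L]]
  idx <- clause_hits(cl)
  matches <- lapply(idx, function(i) {
    values <- if (identical(spec$projection, "NONE")) NULL
    else if (identical(spec$projection, "ALL")) canon[[i]]$data
    else {
      out <- list()
      for (p in spec$projection) {
        segs <- path_segments(p)
        cur <- canon[[i]]$data
        for (s in segs) cur <- cur[[s]]
        out[[p]] <- cur
      }
      out
    }
    list(key = keys[[i]], values = values)
  })
  result_set("instance", matches)
}
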