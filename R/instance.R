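# Archetype instances: value trees mirroring an archetype's node tree.
#
# Representation (canonical form):
#   * a basic leaf is a named list of populated fields, keyed by resolved
#     field suffix, in registry order: list(magnitude = 7.4, units = "mmHg");
#   * a single-occurrence collection or embedded slot is a named list of its
#     populated children; it is omitted entirely when empty;
#   * a multiple-occurrence node is an unnamed list of repetitions (always
#     present, possibly empty — an empty repetition list is data, not
#     absence); each repetition of a collection is a named list of children,
#     of a basic item the leaf record itself;
#   * a multiple-occurrence slot is an unnamed list of nested value trees for
#     the target archetype.

#' Construct an archetype instance
#' @param archetype_id Archetype id the value tree conforms to.
#' @param data Named value tree (see package conventions).
#' @return An `arm_instance`.
#' @export
archetype_instance <- function(archetype_id, data) {
  structure(list(archetype_id = archetype_id, data = data),
            class = "arm_instance")
}

leaf_rtype_ok <- function(value, kind) {
  switch(kind,
         NVARCHAR = is.character(value) || is.factor(value),
         INTEGER = is.numeric(value) && all(value == as.integer(value)),
         FLOAT = is.numeric(value))
}

canonical_leaf <- function(value, type, config_ext = FALSE) {
  fields <- resolve_field_columns(type, config_ext)
  if (!is.list(value))
    abort2("bad_leaf", "leaf value must be a named field list")
  unknown <- setdiff(names(value), fields$suffix)
  if (length(unknown))
    abort2("bad_leaf", "unknown field(s) %s for type %s",
           paste(unknown, collapse = ","), type)
  out <- list()
  for (i in seq_len(nrow(fields))) {
    fx <- value[[fields$suffix[i]]]
    if (is.null(fx) || (length(fx) == 1L && is.na(fx))) next
    if (length(fx) != 1L)
      abort2("bad_leaf", "field %s must hold a single value", fields$suffix[i])
    if (!leaf_rtype_ok(fx, fields$kind[i]))
      abort2("bad_leaf", "field %s of %s must be %s", fields$suffix[i], type,
             fields$kind[i])
    out[[fields$suffix[i]]] <-
      if (fields$kind[i] == "NVARCHAR") as.character(fx)
      else if (fields$kind[i] == "INTEGER") as.integer(fx) else as.numeric(fx)
  }
  out
}

# Validate and canonicalize one level of nodes against a data tree.
canon_nodes <- function(nodes, data, suite, where, config_ext = FALSE) {
  if (is.null(data)) data <- list()
  if (!is.list(data)) abort2("bad_tree", "expected a named list at %s", where)
  known <- vapply(nodes, `[[`, "", "name")
  unknown <- setdiff(names(data), known)
  if (length(unknown))
    abort2("bad_tree", "unknown node(s) at %s: %s", where,
           paste(unknown, collapse = ", "))
  out <- list()
  for (n in nodes) {
    v <- data[[n$name]]
    here <- paste0(where, "/[", n$name, "]")
    many <- occ_many(n$occurrence)
    if (many) {
      reps <- v %||% list()
      if (!is.list(reps) || !is.null(names(reps)))
        abort2("occurrence_violation",
               "%s repeats; supply an unnamed repetition list", here)
      creps <- lapply(seq_along(reps), function(i)
        canon_one(n, reps[[i]], suite, paste0(here, "#", i), config_ext))
      # a repetition carrying no values is indistinguishable from absence
      out[[n$name]] <- creps[vapply(creps, length, 0L) > 0L]
    } else {
      if (is.null(v)) {
        if (n$occurrence$lower >= 1L)
          abort2("missing_mandatory", "mandatory node absent: %s", here)
        next
      }
      # a single-occurrence node given as an unnamed multi-element list is an
      # occurrence violation
      if (is.list(v) && is.null(names(v)) && length(v) > 1L)
        abort2("occurrence_violation", "%s admits a single occurrence", here)
      if (is.list(v) && is.null(names(v)) && length(v) == 1L) v <- v[[1L]]
      cv <- canon_one(n, v, suite, here, config_ext)
      if (length(cv)) out[[n$name]] <- cv
      else if (n$occurrence$lower >= 1L)
        abort2("missing_mandatory", "mandatory node empty: %s", here)
    }
  }
  out
}

canon_one <- function(n, v, suite, where, config_ext) {
  switch(n$kind,
         basic = canonical_leaf(v, n$type, config_ext),
         collection = canon_nodes(n$children, v, suite, where, config_ext),
         slot = {
           target <- suite[[n$target]]
           if (is.null(target))
             abort2("unresolved_slot", "unresolved slot target %s at %s",
                    n$target, where)
           canon_nodes(target$nodes, v, suite, where, config_ext)
         })
}

#' Validate an instance against its archetype and canonicalize it
#'
#' Checks occurrence constraints (mandatory leaves present, single-occurrence
#' nodes hold at most one value), field names and value kinds, and returns
#' the canonical form (fields in registry order, repetition lists always
#' present on multiple-occurrence nodes, empty optional nodes omitted).
#'
#' @param inst Instance.
#' @param archetype Its archetype.
#' @param suite Named archetype list for slot traversal.
#' @return Canonicalized `arm_instance`.
#' @export
validate_instance <- function(inst, archetype, suite = list()) {
  stopifnot(inherits(inst, "arm_instance"))
  if (!identical(inst$archetype_id, archetype$id))
    abort2("archetype_mismatch", "instance is of %s, archetype is %s",
           inst$archetype_id, archetype$id)
  archetype_instance(inst$archetype_id,
                     canon_nodes(archetype$nodes, inst$data, suite, ""))
}

# Fetch the value(s) at (node path, field suffix). Returns a list of values
# (one per reachable repetition); single-occurrence paths yield 0 or 1.
instance_values_at <- function(data, nodes, suite, segs, suffix) {
  if (!length(segs)) return(list())
  nm <- segs[[1L]]
  names_here <- vapply(nodes, `[[`, "", "name")
  j <- match(nm, names_here)
  if (is.na(j)) abort2("unresolved_path", "path segment not found: %s", nm)
  n <- nodes[[j]]
  v <- data[[nm]]
  if (is.null(v)) return(list())
  step <- function(one) {
    if (length(segs) == 1L) {
      if (!identical(n$kind, "basic"))
        abort2("bad_path", "path must end at a basic item")
      val <- one[[suffix]]
      if (is.null(val)) list() else list(val)
    } else {
      kids <- switch(n$kind,
                     collection = n$children,
                     slot = suite[[n$target]]$nodes,
                     abort2("bad_path", "cannot descend into a basic item"))
      instance_values_at(one, kids, suite, segs[-1L], suffix)
    }
  }
  if (occ_many(n$occurrence)) {
    out <- list()
    for (rep in v) out <- c(out, step(rep))
    out
  } else step(v)
}

#' Values at a path/field within an instance
#' @param inst Instance (canonical form).
#' @param archetype Its archetype.
#' @param path Bracketed node path.
#' @param suffix Field suffix (default: the type's primary field).
#' @param suite Archetype suite.
#' @return List of values, one per repetition that populates the field.
#' @export
instance_field_values <- function(inst, archetype, path, suffix = NULL,
                                  suite = list()) {
  r <- find_node(archetype, path, suite)
  if (is.null(r)) abort2("unresolved_path", "path does not resolve: %s", path)
  suffix <- suffix %||% primary_field_suffix(r$node$type)
  instance_values_at(inst$data, archetype$nodes, suite, path_segments(path), suffix)
}

# ---------------------------------------------------------------------------
# JSON interchange

#' Serialize an instance to JSON / parse it back
#' @param inst Instance.
#' @return JSON string.
#' @export
instance_to_json <- function(inst)
  canonical_json(list(archetype_id = inst$archetype_id, data = inst$data))

#' @rdname instance_to_json
#' @param json JSON string.
#' @export
instance_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  archetype_instance(x$archetype_id, x$data)
}

#' Read / write instances as JSON-lines
#' @param instances List of instances.
#' @param path File path.
#' @export
write_instances_jsonl <- function(instances, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (inst in instances) writeLines(instance_to_json(inst), con)
  invisible(path)
}

#' @rdname write_instances_jsonl
#' @export
read_instances_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], instance_from_json)
}
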