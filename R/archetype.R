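# Archetypes: constraint models over a small reference model, each expressing
# one clinical concept as a tree of basic data items, collection structures
# (CLUSTER / ITEM_TREE / ITEM_LIST) and slots where other archetypes plug in.
#
# Node paths use the bracketed ontology-name dialect: "[Structure]/[Result]".

.collection_kinds <- c("CLUSTER", "ITEM_TREE", "ITEM_LIST")

#' Occurrence constraint
#'
#' @param x String `"l..u"` with lower 0 or 1 and upper `1` or `*`,
#'   or an occurrence object (returned unchanged).
#' @return List with elements `lower` (0/1) and `upper` (`"1"` or `"*"`).
#' @export
occurrence <- function(x = "0..1") {
  if (is.list(x) && !is.null(x$lower)) x <- occ_string(x)
  if (!is_string(x) || !grepl("^[01]\\.\\.(1|\\*)$", x))
    abort2("bad_occurrence", "invalid occurrence: %s", format(x))
  parts <- strsplit(x, "..", fixed = TRUE)[[1L]]
  structure(list(lower = as.integer(parts[[1L]]), upper = parts[[2L]]),
            class = "arm_occurrence")
}

occ_string <- function(o) paste0(o$lower, "..", o$upper)
occ_many <- function(o) identical(o$upper, "*")

#' Archetype node constructors
#'
#' `basic_item()` declares a leaf data item of a registered basic type;
#' `collection_item()` a CLUSTER/ITEM_TREE/ITEM_LIST grouping child nodes;
#' `slot_item()` a point where a target archetype plugs in.
#'
#' @param name Ontology display name of the node (also its path segment).
#' @param type Basic data type name (see [basic_type_names()]).
#' @param occurrence Occurrence string, e.g. `"0..1"`, `"1..*"`.
#' @param kind Collection kind: CLUSTER, ITEM_TREE or ITEM_LIST.
#' @param children List of child nodes (nonempty).
#' @param target Archetype id the slot accepts.
#' @return A node object (tagged list).
#' @export
basic_item <- function(name, type, occurrence = "0..1") {
  if (!is_basic_type(type))
    abort2("unknown_basic_type", "unknown basic type name: %s", type)
  structure(list(kind = "basic", name = name, type = type,
                 occurrence = occurrence(occurrence)),
            class = "arm_node")
}

#' @rdname basic_item
#' @export
collection_item <- function(name, kind, children, occurrence = "1..1") {
  kind <- match.arg(kind, .collection_kinds)
  if (length(children) == 0L)
    abort2("empty_collection", "collection %s has no children", name)
  structure(list(kind = "collection", name = name, collection_kind = kind,
                 children = children, occurrence = occurrence(occurrence)),
            class = "arm_node")
}

#' @rdname basic_item
#' @export
slot_item <- function(name, target, occurrence = "0..1") {
  structure(list(kind = "slot", name = name, target = target,
                 occurrence = occurrence(occurrence)),
            class = "arm_node")
}

#' Parse an archetype id string
#'
#' @param id String such as `"openEHR-EHR-OBSERVATION.lab_test-general.v1"`.
#' @return List with `domain`, `rm_class`, `concept`, `version`.
#' @export
parse_archetype_id <- function(id) {
  m <- regexec("^openEHR-([A-Za-z0-9]+)-([A-Z_]+)\\.([^.]+)\\.v([0-9]+)$", id)
  g <- regmatches(id, m)[[1L]]
  if (length(g) != 5L)
    abort2("bad_archetype_id", "malformed archetype id: %s", id)
  list(domain = g[[2L]], rm_class = g[[3L]], concept = g[[4L]],
       version = as.integer(g[[5L]]))
}

#' Construct an archetype
#'
#' Paths are assigned from the containment hierarchy; every node receives an
#' English ontology entry defaulting to its declared name. Invariants
#' (unique paths, nonempty node list, specialization concept naming) are
#' checked immediately.
#'
#' @param id Archetype id string (`openEHR-<domain>-<class>.<concept>.v<N>`).
#' @param nodes List of root nodes built with [basic_item()] and friends.
#' @param parent Optional id of the specialization parent.
#' @param ontology Optional named list: path -> named list(language -> text).
#' @return An `arm_archetype` object.
#' @export
archetype <- function(id, nodes, parent = NULL, ontology = list()) {
  idp <- parse_archetype_id(id)
  if (length(nodes) == 0L) abort2("empty_archetype", "empty archetype: %s", id)
  if (!is.null(parent)) {
    pp <- parse_archetype_id(parent)
    if (!startsWith(idp$concept, paste0(pp$concept, "-")))
      abort2("bad_specialization",
             "specialized concept '%s' must extend parent concept '%s' with a '-' suffix",
             idp$concept, pp$concept)
  }
  nodes <- assign_paths(nodes, "")
  a <- structure(list(id = id, id_parts = idp, parent = parent,
                      nodes = nodes, ontology = ontology),
                 class = "arm_archetype")
  paths <- vapply(arch_nodes_flat(a), `[[`, "", "path")
  dup <- paths[duplicated(paths)]
  if (length(dup))
    abort2("duplicate_path", "duplicate path in %s: %s", id, dup[[1L]])
  # default ontology text: the declared node name, language "en"
  for (p in paths) {
    if (is.null(a$ontology[[p]]) || length(a$ontology[[p]]) == 0L)
      a$ontology[[p]] <- list(en = basename_path(p))
  }
  a
}

assign_paths <- function(nodes, prefix) {
  lapply(nodes, function(n) {
    n$path <- paste0(prefix, if (nzchar(prefix)) "/" else "", "[", n$name, "]")
    if (identical(n$kind, "collection"))
      n$children <- assign_paths(n$children, n$path)
    n
  })
}

basename_path <- function(path) {
  seg <- path_segments(path)
  seg[[length(seg)]]
}

#' Split a bracketed path into name segments
#' @param path Path such as `"[Structure]/[Result]"`.
#' @return Character vector of segment names.
#' @export
path_segments <- function(path) {
  m <- gregexpr("\\[([^]]*)\\]", path)[[1L]]
  if (m[[1L]] == -1L) abort2("bad_path", "malformed node path: %s", path)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  vapply(seq_along(starts),
         function(i) substr(path, starts[i] + 1L, starts[i] + lens[i] - 2L), "")
}

make_path <- function(segments) paste0("[", segments, "]", collapse = "/")

# Depth-first list of all nodes (with paths assigned).
arch_nodes_flat <- function(a) {
  walk <- function(nodes) {
    out <- list()
    for (n in nodes) {
      out <- c(out, list(n))
      if (identical(n$kind, "collection")) out <- c(out, walk(n$children))
    }
    out
  }
  walk(a$nodes)
}

#' Find a node by path within an archetype
#'
#' Optionally resolves through slot nodes when `suite` (a named list of
#' archetypes keyed by id) is supplied: a path segment naming a slot
#' continues inside the slot's target archetype.
#'
#' @param a Archetype.
#' @param path Bracketed node path.
#' @param suite Optional named list of archetypes for slot traversal.
#' @return List `(node, through)` where `through` lists traversed slot nodes;
#'   `NULL` when the path does not resolve.
#' @export
find_node <- function(a, path, suite = NULL) {
  segs <- path_segments(path)
  nodes <- a$nodes
  through <- list()
  node <- NULL
  for (i in seq_along(segs)) {
    names_here <- vapply(nodes, `[[`, "", "name")
    j <- match(segs[[i]], names_here)
    if (is.na(j)) return(NULL)
    node <- nodes[[j]]
    if (i < length(segs)) {
      if (identical(node$kind, "collection")) {
        nodes <- node$children
        through <- c(through, list(node))
      } else if (identical(node$kind, "slot") && !is.null(suite)) {
        tgt <- suite[[node$target]]
        if (is.null(tgt)) return(NULL)
        nodes <- tgt$nodes
        through <- c(through, list(node))
      } else return(NULL)
    }
  }
  list(node = node, through = through)
}

#' Ontology display text for a node path
#' @param a Archetype.
#' @param path Node path.
#' @param language Language tag, default `"en"`.
#' @return Display text (falls back to the node name).
#' @export
ontology_text <- function(a, path, language = "en") {
  entry <- a$ontology[[path]]
  if (!is.null(entry) && !is.null(entry[[language]])) return(entry[[language]])
  if (!is.null(entry) && length(entry)) return(entry[[1L]])
  basename_path(path)
}

# ---------------------------------------------------------------------------
# Serialization: YAML/JSON dialect (one archetype per document)

node_to_list <- function(n) {
  base <- list(name = n$name, occurrence = occ_string(n$occurrence))
  switch(n$kind,
         basic = c(base, list(type = n$type)),
         collection = c(base, list(collection = n$collection_kind,
                                   children = lapply(n$children, node_to_list))),
         slot = c(base, list(slot = n$target)))
}

node_from_list <- function(x) {
  if (!is.list(x) || is.null(x$name))
    abort2("syntax_error", "node entry lacks a name")
  occ <- x$occurrence %||% "0..1"
  if (!is.null(x$type)) basic_item(x$name, x$type, occ)
  else if (!is.null(x$collection)) {
    if (is.null(x$children) || length(x$children) == 0L)
      abort2("empty_collection", "collection %s has no children", x$name)
    collection_item(x$name, x$collection,
                    lapply(x$children, node_from_list), occ)
  }
  else if (!is.null(x$slot)) slot_item(x$name, x$slot, occ)
  else abort2("syntax_error", "node '%s' is neither basic, collection nor slot", x$name)
}

#' Serialize an archetype to its YAML dialect
#' @param a Archetype.
#' @return A single YAML string that [parse_archetype()] re-parses to a
#'   structurally equal archetype.
#' @export
serialize_archetype <- function(a) {
  doc <- list(archetype_id = a$id,
              parent = a$parent,
              nodes = lapply(a$nodes, node_to_list),
              ontology = a$ontology)
  yaml::as.yaml(doc)
}

#' Parse an archetype from its YAML/JSON dialect
#'
#' @param definition_text Document text (YAML; JSON is a YAML subset).
#' @param known_ids Optional character vector of archetype ids; when given, a
#'   `parent` referencing an id outside this set raises a dangling-parent
#'   error.
#' @return An `arm_archetype`.
#' @export
parse_archetype <- function(definition_text, known_ids = NULL) {
  doc <- tryCatch(yaml::yaml.load(definition_text),
                  error = function(e)
                    abort2("syntax_error", "archetype syntax error: %s",
                           conditionMessage(e)))
  if (!is.list(doc) || is.null(doc$archetype_id))
    abort2("syntax_error", "document lacks archetype_id")
  if (is.null(doc$nodes) || length(doc$nodes) == 0L)
    abort2("empty_archetype", "empty archetype: %s", doc$archetype_id)
  parent <- doc$parent
  if (!is.null(parent) && !is.null(known_ids) && !(parent %in% known_ids))
    abort2("dangling_parent", "unknown specialization parent: %s", parent)
  archetype(doc$archetype_id,
            nodes = lapply(doc$nodes, node_from_list),
            parent = parent,
            ontology = doc$ontology %||% list())
}

#' Read an archetype dialect file
#' @param path File path (UTF-8 YAML).
#' @param known_ids Passed to [parse_archetype()].
#' @export
read_archetype <- function(path, known_ids = NULL) {
  parse_archetype(paste(readLines(path, encoding = "UTF-8"), collapse = "\n"),
                  known_ids = known_ids)
}

# Structural equality ignoring environments/attribute order.
arch_equal <- function(a, b) {
  identical(canonical_json(list(a$id, a$parent, lapply(a$nodes, node_to_list),
                                a$ontology[order(names(a$ontology))])),
            canonical_json(list(b$id, b$parent, lapply(b$nodes, node_to_list),
                                b$ontology[order(names(b$ontology))])))
}

# ---------------------------------------------------------------------------
# Version relationships

#' Classify the semantic relationship between two archetype versions
#'
#' `REVISION`: every node of `old` is present in `new` with identical kind and
#' basic type, the lower occurrence bound unchanged and the upper bound equal
#' or widened (`1` to `*`), with only additions otherwise; old data remains
#' valid under `new`. `SPECIALIZATION`: `new`'s concept extends `old`'s with a
#' `-` suffix and constraints are equal or stronger (occurrence ranges
#' narrowed or kept). `NEW_VERSION`: anything incompatible — a changed basic
#' type, a removed node, any change of the lower bound (including mandatory
#' made optional), or a narrowed upper bound on the same concept.
#' Ontology/description changes are ignored.
#'
#' @param old,new Archetypes sharing a concept lineage.
#' @return One of `"REVISION"`, `"SPECIALIZATION"`, `"NEW_VERSION"`.
#' @export
classify_relationship <- function(old, new) {
  oc <- old$id_parts$concept; nc <- new$id_parts$concept
  specializes <- startsWith(nc, paste0(oc, "-"))
  if (!identical(oc, nc) && !specializes)
    abort2("no_lineage", "no lineage between %s and %s", old$id, new$id)

  onodes <- arch_nodes_flat(old)
  nnodes <- arch_nodes_flat(new)
  nmap <- stats::setNames(nnodes, vapply(nnodes, `[[`, "", "path"))

  status <- "compatible"   # escalates to "incompatible"
  strengthened_only <- TRUE
  for (on in onodes) {
    nn <- nmap[[on$path]]
    if (is.null(nn) || !identical(nn$kind, on$kind) ||
        (identical(on$kind, "basic") && !identical(nn$type, on$type)) ||
        (identical(on$kind, "slot") && !identical(nn$target, on$target))) {
      status <- "incompatible"; break
    }
    lo_changed <- nn$occurrence$lower != on$occurrence$lower
    up_narrowed <- occ_many(on$occurrence) && !occ_many(nn$occurrence)
    up_widened  <- !occ_many(on$occurrence) && occ_many(nn$occurrence)
    if (specializes) {
      # strengthening may raise the lower bound or narrow the upper bound
      if (nn$occurrence$lower < on$occurrence$lower || up_widened)
        strengthened_only <- FALSE
    } else {
      if (lo_changed || up_narrowed) { status <- "incompatible"; break }
    }
  }
  if (specializes) {
    if (status == "compatible" && strengthened_only) "SPECIALIZATION"
    else "NEW_VERSION"
  } else if (status == "compatible") "REVISION" else "NEW_VERSION"
}
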