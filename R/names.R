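# Identifier naming. Table names start with the reference-model class letter
# (OBSERVATION -> O, INSTRUCTION -> I, demographic PERSON -> D, CLUSTER -> C)
# followed by the CamelCase concept name with the version stripped; child
# tables append the CamelCase names along the collection/item path. Column
# names join the data-item names along the path with "_" plus the resolved
# field suffix, omitting collection segments (structural containers carry no
# naming weight) while keeping slot segments; a trailing
# repetition of the item name is collapsed so an item "id" with field "id"
# yields column "id". Over-long names are truncated and suffixed with a
# 4-hex-digit digest of the full name so they stay unique.

.default_profile <- list(
  prefix = c(OBSERVATION = "O", INSTRUCTION = "I", PERSON = "D", CLUSTER = "C",
             ITEM_TREE = "T", PARTY_IDENTITY = "P", EVALUATION = "E",
             ACTION = "A", ADMIN_ENTRY = "N"),
  name_limit = 64L,
  column_source = "ontology"   # or "path": raw path text instead of display text
)

#' Default naming profile
#' @return List with `prefix` (rm-class letter map), `name_limit`,
#'   `column_source`.
#' @export
naming_profile <- function() .default_profile

# CamelCase a display name: split on whitespace/underscore/hyphen, capitalize
# the first letter of every word, keep interior case ("pH" -> "PH",
# "lab_test-general" -> "LabTestGeneral").
camel <- function(name, capitalize_first = TRUE) {
  words <- strsplit(name, "[\\s_\\-]+", perl = TRUE)[[1L]]
  words <- words[nzchar(words)]
  if (!length(words)) return("")
  cap <- function(w) paste0(toupper(substr(w, 1L, 1L)), substring(w, 2L))
  if (capitalize_first) words <- vapply(words, cap, "")
  else if (length(words) > 1L) words <- c(words[1L], vapply(words[-1L], cap, ""))
  paste(words, collapse = "")
}

# Column-name segment: single words keep their own case, multi-word names
# join CamelCase with the first word untouched ("Test item" -> "TestItem").
column_segment <- function(name) camel(name, capitalize_first = FALSE)

#' Deterministically shorten an identifier to a length limit
#'
#' Names within the limit pass through; longer names are truncated and the
#' tail replaced by `_` plus the first four hex digits of the FNV-1a digest
#' of the full name.
#'
#' @param name Identifier.
#' @param limit Maximum length (positive).
#' @return Identifier of length `<= limit`.
#' @export
shorten_identifier <- function(name, limit = 64L) {
  stopifnot(limit > 8L)
  if (nchar(name) <= limit) return(name)
  paste0(substr(name, 1L, limit - 5L), "_", substr(fnv1a32(name), 1L, 4L))
}

table_base_name <- function(archetype, profile = naming_profile(),
                            keep_version = FALSE) {
  cls <- archetype$id_parts$rm_class
  letter <- profile$prefix[[cls]]
  if (is.null(letter))
    abort2("unknown_rm_class", "no table prefix configured for rm class %s", cls)
  nm <- paste0(letter, camel(archetype$id_parts$concept))
  if (keep_version) nm <- paste0(nm, "V", archetype$id_parts$version)
  nm
}

# Column name from the item-path display names (collection segments already
# removed by the caller) and a field suffix.
column_name_from <- function(segments, suffix, profile = naming_profile()) {
  segs <- vapply(segments, column_segment, "")
  if (length(segs) && identical(segs[[length(segs)]], suffix))
    segs <- segs[-length(segs)]           # collapse "id" + "id" -> "id"
  shorten_identifier(paste(c(segs, suffix), collapse = "_"), profile$name_limit)
}

#' Derive table or column identifiers from an archetype
#'
#' With neither `node_path` nor `field_suffix`, returns the archetype's table
#' name. With a `node_path` naming a collection or multi-occurrence item,
#' returns the child-table name (table name plus the CamelCase path names).
#' With both `node_path` and `field_suffix`, returns the column name.
#'
#' @param archetype Archetype.
#' @param node_path Optional bracketed node path.
#' @param field_suffix Optional resolved field suffix.
#' @param limit Identifier length limit.
#' @param profile Naming profile (see [naming_profile()]).
#' @param suite Optional archetype suite for slot traversal.
#' @return A single identifier string.
#' @export
make_names <- function(archetype, node_path = NULL, field_suffix = NULL,
                       limit = naming_profile()$name_limit,
                       profile = naming_profile(), suite = NULL) {
  profile$name_limit <- limit
  base <- table_base_name(archetype, profile)
  if (is.null(node_path))
    return(shorten_identifier(base, limit))
  segs <- path_segments(node_path)
  # display names along the path
  acc <- character(); disp <- character(); coll <- logical()
  nodes <- archetype$nodes; arch <- archetype
  for (i in seq_along(segs)) {
    prefix_path <- make_path(segs[seq_len(i)])
    r <- find_node(archetype, prefix_path, suite)
    if (is.null(r)) abort2("unresolved_path", "path does not resolve: %s", node_path)
    n <- r$node
    disp <- c(disp, if (identical(profile$column_source, "path")) n$name
              else ontology_text(arch, prefix_path) %||% n$name)
    coll <- c(coll, identical(n$kind, "collection"))
  }
  if (is.null(field_suffix)) {
    nm <- paste0(base, paste(vapply(disp, camel, ""), collapse = ""))
    return(shorten_identifier(nm, limit))
  }
  column_name_from(disp[!coll], field_suffix, profile)
}
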