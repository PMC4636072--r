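# Registry of the openEHR basic data types the mapper understands.
#
# Each entry lists the type's fields in order, with either a primitive storage
# kind (NVARCHAR, INTEGER, FLOAT) or a reference to another registry entry
# (kind prefixed with "#"), expanded recursively when columns are resolved.
# Reference chains are acyclic and reach a primitive within three hops.

.basic_type_table <- list(
  CodePhrase   = list(list(field = "code",         kind = "NVARCHAR")),
  DvBoolean    = list(list(field = "value",        kind = "INTEGER")),
  DvCodedText  = list(list(field = "definingCode", kind = "#CodePhrase")),
  DvCount      = list(list(field = "magnitude",    kind = "INTEGER")),
  DvDateTime   = list(list(field = "value",        kind = "NVARCHAR")),
  DvEHRURI     = list(list(field = "value",        kind = "NVARCHAR")),
  DvIdentifier = list(list(field = "id",           kind = "NVARCHAR")),
  DvMultimedia = list(list(field = "uri",          kind = "#DvURI")),
  DvProportion = list(list(field = "precision",    kind = "INTEGER")),
  DvQuantity   = list(list(field = "magnitude",    kind = "FLOAT"),
                      list(field = "units",        kind = "NVARCHAR")),
  DvText       = list(list(field = "value",        kind = "NVARCHAR")),
  DvURI        = list(list(field = "value",        kind = "NVARCHAR")),
  GenericID    = list(list(field = "value",        kind = "NVARCHAR"),
                      list(field = "name",         kind = "NVARCHAR")),
  Link         = list(list(field = "target",       kind = "#DvEHRURI"))
)

#' Names of the registered basic data types
#' @return Character vector of type names.
#' @export
basic_type_names <- function() names(.basic_type_table)

#' Test whether a name is a registered basic data type
#' @param type_name Candidate type name.
#' @export
is_basic_type <- function(type_name) {
  is_string(type_name) && type_name %in% names(.basic_type_table)
}

#' Field specification of a basic data type
#'
#' @param type_name Registered basic type name.
#' @return List of `list(field, kind)` entries in declaration order; `kind`
#'   is a primitive storage kind or a `#`-prefixed reference to another type.
#' @export
basic_type_spec <- function(type_name) {
  if (!is_basic_type(type_name))
    abort2("unknown_basic_type", "unknown basic type name: %s", type_name)
  .basic_type_table[[type_name]]
}

#' Resolve the storage columns of a basic data type
#'
#' Expands `#`-references recursively: the resulting column suffix is the
#' field names along the reference chain joined by `_`, and the storage kind
#' is the primitive kind at the end of the chain.
#'
#' @param type_name Registered basic type name.
#' @param dv_proportion_extended When `TRUE`, `DvProportion` additionally
#'   resolves `numerator`/`denominator` FLOAT columns beyond its declared
#'   `precision` field. Off by default.
#' @return A data.frame with columns `suffix` and `kind`
#'   (kind in NVARCHAR/INTEGER/FLOAT), in declaration order.
#' @export
resolve_field_columns <- function(type_name, dv_proportion_extended = FALSE) {
  spec <- basic_type_spec(type_name)
  expand <- function(fields, prefix, depth) {
    if (depth > 3L)
      abort2("type_chain_too_deep", "reference chain exceeds 3 hops in %s", type_name)
    out <- list()
    for (f in fields) {
      suffix <- if (nzchar(prefix)) paste(prefix, f$field, sep = "_") else f$field
      if (startsWith(f$kind, "#")) {
        ref <- substring(f$kind, 2L)
        out <- c(out, list(expand(basic_type_spec(ref), suffix, depth + 1L)))
      } else {
        out <- c(out, list(data.frame(suffix = suffix, kind = f$kind,
                                      stringsAsFactors = FALSE)))
      }
    }
    do.call(rbind, out)
  }
  res <- expand(spec, "", 1L)
  if (type_name == "DvProportion" && isTRUE(dv_proportion_extended)) {
    res <- rbind(res, data.frame(suffix = c("numerator", "denominator"),
                                 kind = c("FLOAT", "FLOAT"),
                                 stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}

# Primary field of a type: the first resolved column; used when an ARM
# constraint names a data item without naming a field.
primary_field_suffix <- function(type_name) {
  resolve_field_columns(type_name)$suffix[[1L]]
}

# Map a storage kind to the R column type used by the embedded engine.
storage_rtype <- function(kind) {
  switch(kind,
         NVARCHAR = "character",
         INTEGER  = "integer",
         FLOAT    = "double",
         abort2("unknown_storage_kind", "unknown storage kind: %s", kind))
}
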