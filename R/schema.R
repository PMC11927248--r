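#' Define an item response scale
#'
#' A scale lists the scored response labels in worst-to-best order (after
#' any recoding and reverse-coding) plus the labels that are valid answers
#' but cannot be placed on the continuum (e.g. "Don't know").
#'
#' @param kind One of `"likert"`, `"binary"`, `"categorical"`.
#' @param labels Character vector of scored labels, worst to best. Its
#'   length is the item's category count `c`.
#' @param non_scored Character vector of non-scorable labels.
#' @return An object of class `rrt_scale`.
#' @export
response_scale <- function(kind = c("likert", "binary", "categorical"),
                           labels, non_scored = character()) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  non_scored <- as.character(non_scored)
  if (length(labels) < 2L)
    stop("a response scale needs at least 2 scored categories", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicated scored labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  overlap <- intersect(labels, non_scored)
  if (length(overlap))
    stop("labels both scored and non-scored: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  structure(list(kind = kind,
                 n_scored_categories = length(labels),
                 scored_labels = labels,
                 non_scored_labels = non_scored),
            class = "rrt_scale")
}

#' Define a recode rule for an item
#'
#' Maps every raw response label of an item to a scored label, to the
#' non-scored sentinel, or to column-level median imputation. Several raw
#' labels mapping to the same scored label represent merged categories.
#'
#' @param item_id Item the rule belongs to.
#' @param mapping Named character vector: names are raw labels, values are
#'   scored labels of the item's scale or the special targets
#'   `".non_scored"` and `".median"`.
#' @return An object of class `rrt_recode`.
#' @export
recode_rule <- function(item_id, mapping) {
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("recode mapping must be fully named by raw label", call. = FALSE)
  if (anyDuplicated(names(mapping)))
    stop("raw label appears twice in recode rule for item ", item_id,
         call. = FALSE)
  structure(list(item_id = item_id,
                 mapping = vapply(mapping, as.character, character(1))),
            class = "rrt_recode")
}

#' Define a questionnaire item
#'
#' @param id Unique item identifier.
#' @param scale An [response_scale()] object.
#' @param prompt Prompt key / display text (defaults to the id).
#' @param reverse Logical; reverse-code this item during cleaning so that
#'   higher codes always mean better treatment.
#' @param recode Optional [recode_rule()].
#' @return An object of class `rrt_item`.
#' @export
item_definition <- function(id, scale, prompt = id, reverse = FALSE,
                            recode = NULL) {
  stopifnot(inherits(scale, "rrt_scale"))
  if (!is.null(recode)) {
    stopifnot(inherits(recode, "rrt_recode"))
    targets <- recode$mapping
    bad <- setdiff(setdiff(targets, c(".non_scored", ".median")),
                   scale$scored_labels)
    if (length(bad))
      stop("recode targets not in scale of item ", id, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = as.character(id), prompt = as.character(prompt),
                 scale = scale, reverse = isTRUE(reverse), recode = recode),
            class = "rrt_item")
}

#' Assemble a questionnaire schema
#'
#' @param items List of [item_definition()] objects.
#' @param version Schema version tag.
#' @return An object of class `rrt_schema`. All invariants are checked and
#'   every violation is reported at once.
#' @export
questionnaire_schema <- function(items, version = "1.0") {
  problems <- character()
  if (!length(items)) problems <- c(problems, "schema has no items")
  ok <- vapply(items, inherits, logical(1), "rrt_item")
  if (any(!ok)) problems <- c(problems, "non-item entries in item list")
  ids <- vapply(items[ok], function(i) i$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    problems <- c(problems, paste0("duplicated item id: ", dup))
  if (length(problems))
    stop("invalid schema:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  names(items) <- ids
  structure(list(items = items, version = as.character(version)),
            class = "rrt_schema")
}

#' @export
print.rrt_schema <- function(x, ...) {
  cat("Questionnaire schema (version ", x$version, "): ",
      length(x$items), " items\n", sep = "")
  invisible(x)
}

#' Item ids of a schema, in order
#' @param schema An `rrt_schema`.
#' @export
schema_ids <- function(schema) names(schema$items)

#' Category counts c_i of a schema, in item order
#' @param schema An `rrt_schema`.
#' @export
schema_ncat <- function(schema) {
  vapply(schema$items, function(i) i$scale$n_scored_categories, integer(1))
}

#' Apply an item's recode rule to one raw label
#'
#' @param raw_label A raw response label.
#' @param item An [item_definition()].
#' @return A scored integer code `0..c-1`, or the sentinels [NON_SCORED] /
#'   [MEDIAN_IMPUTE].
#' @export
apply_recode <- function(raw_label, item) {
  stopifnot(inherits(item, "rrt_item"))
  raw_label <- as.character(raw_label)
  if (!is.null(item$recode)) {
    map <- item$recode$mapping
    if (!raw_label %in% names(map))
      stop("unknown label for item ", item$id, ": '", raw_label, "'",
           call. = FALSE)
    target <- map[[raw_label]]
    if (target == ".non_scored") return(NON_SCORED)
    if (target == ".median") return(MEDIAN_IMPUTE)
    return(match(target, item$scale$scored_labels) - 1L)
  }
  if (raw_label %in% item$scale$scored_labels)
    return(match(raw_label, item$scale$scored_labels) - 1L)
  if (raw_label %in% item$scale$non_scored_labels)
    return(NON_SCORED)
  stop("unknown label for item ", item$id, ": '", raw_label, "'",
       call. = FALSE)
}

#' Reverse-code scored responses
#'
#' Maps code `v` on a `c`-category item to `c - 1 - v`, so that applying
#' the function twice is the identity. `NA` passes through.
#'
#' @param value Integer code(s) in `0..c-1`.
#' @param c Category count (scalar or vector recycled against `value`).
#' @return Reversed code(s).
#' @export
reverse_code <- function(value, c) {
  if (any(c < 2, na.rm = TRUE))
    stop("category count must be >= 2", call. = FALSE)
  bad <- !is.na(value) & (value < 0 | value > c - 1)
  if (any(bad))
    stop("value out of range 0..c-1: ",
         paste(value[bad], collapse = ", "), call. = FALSE)
  as.integer(c) - 1L - as.integer(value)
}

# ---- serialization -------------------------------------------------------

schema_to_list <- function(schema) {
  list(spec_version = schema$version,
       items = lapply(unname(schema$items), function(it) {
         out <- list(id = it$id, prompt = it$prompt, kind = it$scale$kind,
                     labels = as.list(it$scale$scored_labels),
                     non_scored = as.list(it$scale$non_scored_labels),
                     reverse = it$reverse)
         if (!is.null(it$recode)) out$recode <- as.list(it$recode$mapping)
         out
       }))
}

list_to_schema <- function(x, where = "schema") {
  if (is.null(x$items))
    stop("malformed ", where, ": no 'items' list", call. = FALSE)
  items <- lapply(x$items, function(e) {
    sc <- response_scale(kind = e$kind,
                         labels = unlist(e$labels),
                         non_scored = as.character(unlist(e$non_scored)))
    rec <- NULL
    if (!is.null(e$recode))
      rec <- recode_rule(e$id, unlist(e$recode))
    item_definition(id = e$id, scale = sc,
                    prompt = if (is.null(e$prompt)) e$id else e$prompt,
                    reverse = isTRUE(e$reverse), recode = rec)
  })
  questionnaire_schema(items, version = if (is.null(x$spec_version)) "1.0"
                       else x$spec_version)
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

#' Load a questionnaire schema from a YAML or JSON file
#'
#' @param path File path; format chosen by extension (`.json` = JSON,
#'   anything else YAML).
#' @return An `rrt_schema`.
#' @export
load_schema <- function(path) {
  list_to_schema(read_structured(path), where = path)
}

#' Write a questionnaire schema to YAML
#'
#' The emitter is canonical: loading a file written by this function and
#' re-writing it reproduces the file byte for byte.
#'
#' @param schema An `rrt_schema`.
#' @param path Output path.
#' @export
write_schema <- function(schema, path) {
  writeLines(yaml::as.yaml(schema_to_list(schema)), path)
  invisible(path)
}

# ---- factor specifications ----------------------------------------------

#' Build a factor specification set
#'
#' A factor specification names each latent factor and lists the items that
#' belong to it with their signed pattern loadings `w_i`.
#'
#' @param factors Named list; each element a named numeric vector of
#'   loadings (names = item ids).
#' @param omegas Optional named numeric vector of published reliabilities.
#' @param version Version tag.
#' @return An object of class `rrt_factors`.
#' @export
factor_spec <- function(factors, omegas = NULL, version = "1.0") {
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    stop("factors must be named", call. = FALSE)
  problems <- character()
  for (f in names(factors)) {
    w <- factors[[f]]
    if (is.null(names(w)) || any(!nzchar(names(w))))
      problems <- c(problems, paste0("factor '", f, "': unnamed loadings"))
    if (any(w == 0))
      problems <- c(problems, paste0("factor '", f, "': zero loading"))
  }
  ids <- unlist(lapply(factors, names), use.names = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    problems <- c(problems,
                  paste0("item in more than one factor: ", dup))
  if (length(problems))
    stop("invalid factor specification:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(factors = factors, omegas = omegas,
                 version = as.character(version)),
            class = "rrt_factors")
}

#' @export
print.rrt_factors <- function(x, ...) {
  cat("Factor specification: ", length(x$factors), " factors, ",
      length(unlist(lapply(x$factors, names))), " items\n", sep = "")
  for (f in names(x$factors))
    cat("  ", f, " (", length(x$factors[[f]]), " items)\n", sep = "")
  invisible(x)
}

#' All item ids covered by a factor specification
#' @param spec An `rrt_factors` object.
#' @export
factor_spec_ids <- function(spec) {
  unlist(lapply(spec$factors, names), use.names = FALSE)
}

#' Load a factor specification from YAML or JSON
#' @param path File path.
#' @return An `rrt_factors` object.
#' @export
load_factor_spec <- function(path) {
  x <- read_structured(path)
  if (is.null(x$factors))
    stop("malformed factor specification: no 'factors' list", call. = FALSE)
  facs <- list()
  omegas <- numeric()
  for (e in x$factors) {
    w <- vapply(e$items, function(it) as.numeric(it$loading), numeric(1))
    names(w) <- vapply(e$items, function(it) as.character(it$id),
                       character(1))
    facs[[e$name]] <- w
    if (!is.null(e$omega)) omegas[e$name] <- as.numeric(e$omega)
  }
  factor_spec(facs, omegas = if (length(omegas)) omegas else NULL,
              version = if (is.null(x$spec_version)) "1.0"
              else x$spec_version)
}

#' Write a factor specification to YAML
#' @param spec An `rrt_factors` object.
#' @param path Output path.
#' @export
write_factor_spec <- function(spec, path) {
  out <- list(spec_version = spec$version,
              factors = lapply(names(spec$factors), function(f) {
                w <- spec$factors[[f]]
                e <- list(name = f)
                if (!is.null(spec$omegas) && f %in% names(spec$omegas))
                  e$omega <- unname(spec$omegas[f])
                e$items <- lapply(names(w), function(id)
                  list(id = id, loading = unname(w[id])))
                e
              }))
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

#' Check a factor specification against a schema
#'
#' @param spec An `rrt_factors` object.
#' @param schema An `rrt_schema`.
#' @return Invisibly `TRUE`; errors list every unknown item.
#' @export
validate_factor_spec <- function(spec, schema) {
  unknown <- setdiff(factor_spec_ids(spec), schema_ids(schema))
  if (length(unknown))
    stop("factor specification references items absent from schema: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# ---- domain grouping -----------------------------------------------------

#' Define the responsiveness / respectful-treatment domain grouping
#'
#' @param responsiveness Factor names forming the responsiveness domain.
#' @param respectful Factor names forming the respectful-treatment domain.
#' @return An object of class `rrt_domains`.
#' @export
domain_grouping <- function(responsiveness, respectful) {
  overlap <- intersect(responsiveness, respectful)
  if (length(overlap))
    stop("factors in both domains: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  structure(list(responsiveness = as.character(responsiveness),
                 respectful = as.character(respectful)),
            class = "rrt_domains")
}

#' Load a domain grouping from YAML or JSON
#' @param path File path.
#' @export
load_grouping <- function(path) {
  x <- read_structured(path)
  if (is.null(x$domains))
    stop("malformed grouping file: no 'domains' entry", call. = FALSE)
  domain_grouping(unlist(x$domains$responsiveness),
                  unlist(x$domains$respectful))
}

#' Write a domain grouping to YAML
#' @param grouping An `rrt_domains` object.
#' @param path Output path.
#' @export
write_grouping <- function(grouping, path) {
  writeLines(yaml::as.yaml(list(
    spec_version = "1.0",
    domains = list(responsiveness = as.list(grouping$responsiveness),
                   respectful = as.list(grouping$respectful)))), path)
  invisible(path)
}
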