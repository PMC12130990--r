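#' Tree-structured cell-type schema harmonizing model vocabularies
#'
#' Segmentation models trained on different datasets predict different
#' cell-type vocabularies (MoNuSAC: epithelial, lymphocyte, neutrophil,
#' macrophage; PanNuke: neoplastic/non-neoplastic epithelial, connective,
#' inflammatory, dead). A `type_schema` arranges all categories in a tree
#' rooted at `"cell"` so that child labels are always consistent with their
#' parents, maps each model's raw labels onto tree nodes, and assigns every
#' node a *match level* -- the ancestor at which cross-model type equality is
#' evaluated during merging. Output categories for merged pairs take the most
#' specific node of the two along their shared lineage (so a MoNuSAC
#' "lymphocyte" merged with a PanNuke "inflammatory" is reported as
#' lymphocyte).
#'
#' @param parent Named character vector mapping each node to its parent; the
#'   root has parent `NA`.
#' @param model_map Named list: per model id, a named character vector mapping
#'   raw labels to node names.
#' @param match_level Named character vector mapping nodes to the
#'   ancestor-or-self node used for the equality test. Defaults to each
#'   node's depth-1 ancestor (its child-of-root ancestor, or itself for
#'   depth-1 nodes).
#' @return An object of class `type_schema`.
#' @export
type_schema <- function(parent, model_map, match_level = NULL) {
  nodes <- names(parent)
  root <- nodes[is.na(parent)]
  if (length(root) != 1L) stop("schema must have exactly one root node")
  bad <- setdiff(stats::na.omit(unname(parent)), nodes)
  if (length(bad)) stop("parent refers to undeclared node(s): ",
                        paste(bad, collapse = ", "))
  # cycle check: every node must reach the root
  for (nd in nodes) {
    seen <- character(0)
    cur <- nd
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("cycle in schema tree at node '", nd, "'")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  if (is.null(match_level)) {
    match_level <- vapply(nodes, function(nd) depth1_ancestor(nd, parent), "")
  } else {
    miss <- setdiff(nodes, names(match_level))
    if (length(miss)) {
      match_level[miss] <- vapply(miss, function(nd) depth1_ancestor(nd, parent), "")
    }
    match_level <- match_level[nodes]
  }
  for (nd in nodes) {
    if (!is_ancestor_or_self(match_level[[nd]], nd, parent)) {
      stop("match_level of '", nd, "' must be an ancestor-or-self node")
    }
  }
  for (mid in names(model_map)) {
    targets <- unname(model_map[[mid]])
    bad <- setdiff(targets, nodes)
    if (length(bad)) {
      stop("model '", mid, "' maps label(s) to unknown node(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(parent = parent, root = root, match_level = match_level,
                 model_map = model_map),
            class = "type_schema")
}

# depth-1 ancestor = the child of the root on the node's lineage
# (the root itself and depth-1 nodes return themselves / the node).
depth1_ancestor <- function(node, parent) {
  cur <- node
  while (!is.na(parent[[cur]]) && !is.na(parent[[parent[[cur]]]])) {
    cur <- parent[[cur]]
  }
  cur
}

is_ancestor_or_self <- function(a, b, parent) {
  cur <- b
  repeat {
    if (identical(cur, a)) return(TRUE)
    if (is.na(parent[[cur]])) return(FALSE)
    cur <- parent[[cur]]
  }
}

#' Default schema for the MoNuSAC / PanNuke model pair
#'
#' The shipped tree is `cell -> {epithelial -> {neoplastic epithelial,
#' non-neoplastic epithelial}, inflammatory -> {lymphocyte, neutrophil,
#' macrophage}, connective, dead}` with every leaf matched at its depth-1
#' parent, so a MoNuSAC "epithelial" and a PanNuke "non-neoplastic
#' epithelial" agree, as do "lymphocyte" and "inflammatory".
#'
#' @return A `type_schema`.
#' @export
default_type_schema <- function() {
  parent <- c(cell = NA_character_,
              epithelial = "cell", inflammatory = "cell",
              connective = "cell", dead = "cell",
              "neoplastic epithelial" = "epithelial",
              "non-neoplastic epithelial" = "epithelial",
              lymphocyte = "inflammatory", neutrophil = "inflammatory",
              macrophage = "inflammatory")
  model_map <- list(
    monusac = c(epithelial = "epithelial", lymphocyte = "lymphocyte",
                neutrophil = "neutrophil", macrophage = "macrophage"),
    pannuke = c("neoplastic epithelial" = "neoplastic epithelial",
                "non-neoplastic epithelial" = "non-neoplastic epithelial",
                connective = "connective", inflammatory = "inflammatory",
                dead = "dead"))
  type_schema(parent, model_map)
}

#' Load a cell-type schema from a YAML/JSON config file
#'
#' The config has three sections: `tree` (nested maps, single root),
#' optional `match_level` (node -> ancestor overrides; unlisted nodes use the
#' depth-1 rule), and `models` (per model id, a `labels` map of raw label ->
#' node). With `path = NULL` the shipped default schema
#' ([default_type_schema()]) is returned; a copy of the equivalent config
#' ships at `system.file("extdata", "default_schema.yaml", package =
#' "nucleimerge")`.
#'
#' @param path Config file path, or `NULL` for the default.
#' @return A `type_schema`.
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path)) return(default_type_schema())
  if (!file.exists(path)) stop("schema file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tree) || length(cfg$tree) != 1L) {
    stop("schema config must have a 'tree' section with a single root")
  }
  parent <- flatten_tree(cfg$tree)
  if (is.null(cfg$models) || !length(cfg$models)) {
    stop("schema config must declare at least one model under 'models'")
  }
  model_map <- lapply(cfg$models, function(m) {
    if (is.null(m$labels) || !length(m$labels)) {
      stop("each model needs a non-empty 'labels' map")
    }
    vapply(m$labels, as.character, "")
  })
  match_level <- if (!is.null(cfg$match_level)) {
    vapply(cfg$match_level, as.character, "")
  }
  type_schema(parent, model_map, match_level)
}

flatten_tree <- function(tree, parent_name = NA_character_) {
  out <- character(0)
  for (nm in names(tree)) {
    out[nm] <- parent_name
    kids <- tree[[nm]]
    if (is.list(kids) && length(kids)) out <- c(out, flatten_tree(kids, nm))
  }
  if (anyDuplicated(names(out))) {
    stop("node name(s) repeated in tree: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  }
  out
}

#' Map a model's raw label to its schema node
#' @param label Raw label string.
#' @param model_id Model id declared in the schema.
#' @param schema A `type_schema`.
#' @return Node name (string).
#' @export
schema_node <- function(label, model_id, schema) {
  mm <- schema$model_map[[model_id]]
  if (is.null(mm)) stop("model '", model_id, "' not declared in schema")
  node <- mm[label]
  if (is.na(node)) {
    stop("label '", label, "' of model '", model_id, "' not mapped in schema")
  }
  unname(node)
}

#' Cross-model type equality test
#'
#' Two raw labels match when their schema nodes share the same match-level
#' ancestor. This is the type-equality test the merging loop applies to a
#' nearest-neighbor pair: symmetric and reflexive for mapped labels.
#'
#' @param label_a,label_b Raw labels.
#' @param model_a,model_b The owning model ids.
#' @param schema A `type_schema`.
#' @return Logical scalar.
#' @export
types_match <- function(label_a, model_a, label_b, model_b, schema) {
  na <- schema_node(label_a, model_a, schema)
  nb <- schema_node(label_b, model_b, schema)
  identical(unname(schema$match_level[[na]]), unname(schema$match_level[[nb]]))
}

#' Output category for a merged pair of labels
#'
#' For a pair that passed [types_match()], the reported category is the more
#' specific node of the two along their shared lineage (lymphocyte over
#' inflammatory, non-neoplastic epithelial over epithelial). When neither
#' node is an ancestor of the other (possible only in user schemas where two
#' distinct leaves share a match level), the second model's node is kept,
#' mirroring the merge rule that the merged type comes from the second set.
#'
#' @inheritParams types_match
#' @return Node name (string).
#' @export
output_category <- function(label_a, model_a, label_b, model_b, schema) {
  if (!types_match(label_a, model_a, label_b, model_b, schema)) {
    stop("output_category called on a non-matching pair: '", label_a,
         "' (", model_a, ") vs '", label_b, "' (", model_b, ")")
  }
  na <- schema_node(label_a, model_a, schema)
  nb <- schema_node(label_b, model_b, schema)
  if (is_ancestor_or_self(na, nb, schema$parent)) return(nb)
  if (is_ancestor_or_self(nb, na, schema$parent)) return(na)
  nb
}

#' @export
print.type_schema <- function(x, ...) {
  cat("<type_schema> ", length(x$parent), " nodes, root '", x$root, "'\n",
      sep = "")
  for (mid in names(x$model_map)) {
    cat("  model '", mid, "': ",
        paste(names(x$model_map[[mid]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' All assignable (non-root) category nodes of a schema
#' @param schema A `type_schema`.
#' @return Character vector of node names in declaration order.
#' @export
schema_categories <- function(schema) {
  setdiff(names(schema$parent), schema$root)
}
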