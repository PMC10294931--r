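#' Construct a risk-index hierarchy
#'
#' A `risk_hierarchy` is a weighted tree with exactly four levels:
#' one *total* node (the overall risk value R), *primary* indices,
#' *secondary* indices and *tertiary* indices. Every non-root node carries
#' the weight of its contribution to its parent; the weights of each
#' sibling group must sum to 1 (within `tol`, because published
#' coefficients are typically rounded to four decimal places).
#'
#' @param nodes data frame with columns `id`, `label`, `level`
#'   (`"total"`, `"primary"`, `"secondary"` or `"tertiary"`), `parent`
#'   (`NA` for the root) and `weight` (`NA` for the root, otherwise in
#'   (0, 1]).
#' @param model_name,model_version identification strings stored with the
#'   hierarchy and echoed in reports.
#' @param tol tolerance on each sibling group's weight sum
#'   (default `1e-4`).
#' @return An object of class `risk_hierarchy`.
#' @seealso [load_hierarchy()] to read a hierarchy from a model
#'   configuration file, [default_hierarchy()] for the bundled model,
#'   [sibling_weight_groups()] for the per-parent weight groups.
#' @export
#' @examples
#' nodes <- data.frame(
#'   id     = c("R", "A", "B", "a1", "a11"),
#'   label  = c("total", "only primary", "unused", "only secondary",
#'              "only tertiary"),
#'   level  = c("total", "primary", "primary", "secondary", "tertiary"),
#'   parent = c(NA, "R", "R", "A", "a1"),
#'   weight = c(NA, 0.5, 0.5, 1, 1)
#' )
#' h <- risk_hierarchy(nodes, model_name = "toy")
#' h
risk_hierarchy <- function(nodes, model_name = "unnamed",
                           model_version = "0", tol = 1e-4) {
  required <- c("id", "label", "level", "parent", "weight")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes)))
    stop("`nodes` must be a data frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  nodes$level <- as.character(nodes$level)
  nodes$parent <- as.character(nodes$parent)
  nodes$weight <- as.numeric(nodes$weight)

  .validate_nodes(nodes, tol = tol)
  root_id <- nodes$id[nodes$level == "total"]

  structure(
    list(nodes = nodes, root_id = root_id,
         model_name = as.character(model_name),
         model_version = as.character(model_version),
         tol = tol),
    class = "risk_hierarchy"
  )
}

# Full structural validation: unique ids, a single total root, parent
# levels one step up, positive weights, sibling sums, no orphans.
.validate_nodes <- function(nodes, tol = 1e-4) {
  levels_ok <- c("total", "primary", "secondary", "tertiary")
  bad <- setdiff(unique(nodes$level), levels_ok)
  if (length(bad))
    stop("unknown node level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  dup <- unique(nodes$id[duplicated(nodes$id)])
  if (length(dup))
    stop("duplicate node id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)

  roots <- nodes$id[nodes$level == "total"]
  if (length(roots) != 1L)
    stop("the hierarchy must contain exactly one 'total' node, found ",
         length(roots), call. = FALSE)
  if (!is.na(nodes$parent[nodes$id == roots]))
    stop("the total node '", roots, "' must not have a parent",
         call. = FALSE)

  nonroot <- nodes[nodes$level != "total", , drop = FALSE]
  if (anyNA(nonroot$parent))
    stop("node(s) without a parent: ",
         paste(nonroot$id[is.na(nonroot$parent)], collapse = ", "),
         call. = FALSE)
  missing_parent <- setdiff(nonroot$parent, nodes$id)
  if (length(missing_parent))
    stop("parent id(s) not present in the node set: ",
         paste(missing_parent, collapse = ", "), call. = FALSE)

  parent_level <- nodes$level[match(nonroot$parent, nodes$id)]
  expected <- c(primary = "total", secondary = "primary",
                tertiary = "secondary")
  wrong <- parent_level != expected[nonroot$level]
  if (any(wrong))
    stop("node(s) attached to a parent of the wrong level: ",
         paste(sprintf("%s (parent %s)", nonroot$id[wrong],
                       nonroot$parent[wrong]), collapse = ", "),
         call. = FALSE)

  w <- nonroot$weight
  if (anyNA(w) || any(!is.finite(w)))
    stop("node(s) with missing or non-finite weight: ",
         paste(nonroot$id[is.na(w) | !is.finite(w)], collapse = ", "),
         call. = FALSE)
  if (any(w <= 0 | w > 1))
    stop("node weight(s) outside (0, 1]: ",
         paste(sprintf("%s = %g", nonroot$id[w <= 0 | w > 1],
                       w[w <= 0 | w > 1]), collapse = ", "),
         call. = FALSE)

  sums <- tapply(nonroot$weight, nonroot$parent, sum)
  off <- abs(sums - 1) > tol
  if (any(off))
    stop("sibling weight group(s) do not sum to 1 (tolerance ", tol, "): ",
         paste(sprintf("children of %s sum to %.4f", names(sums)[off],
                       sums[off]), collapse = "; "),
         call. = FALSE)
  invisible(TRUE)
}

#' Load a risk hierarchy from a model configuration file
#'
#' Model configurations are YAML documents holding the node table (and,
#' for a full model, the scoring rubric, grade thresholds and random-index
#' table; see [load_model()]). `load_hierarchy()` extracts and validates
#' just the weighted index tree.
#'
#' @param config path to a YAML model configuration, or an already parsed
#'   configuration list.
#' @inheritParams risk_hierarchy
#' @return A validated [risk_hierarchy] object.
#' @export
#' @examples
#' h <- load_hierarchy(system.file("extdata", "aquarisk_model.yaml",
#'                                 package = "aquarisk"))
#' table(h$nodes$level)
load_hierarchy <- function(config, tol = 1e-4) {
  cfg <- .read_config(config)
  if (is.null(cfg$nodes))
    stop("model configuration has no 'nodes' section", call. = FALSE)
  nodes <- .nodes_from_config(cfg$nodes)
  risk_hierarchy(nodes,
                 model_name = cfg$model_name %||% "unnamed",
                 model_version = cfg$model_version %||% "0",
                 tol = tol)
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("model configuration file not found: ", config, call. = FALSE)
    cfg <- tryCatch(yaml::read_yaml(config), error = function(e)
      stop("cannot parse model configuration '", config, "': ",
           conditionMessage(e), call. = FALSE))
  } else if (is.list(config)) {
    cfg <- config
  } else {
    stop("`config` must be a file path or a parsed configuration list",
         call. = FALSE)
  }
  cfg
}

.nodes_from_config <- function(node_list) {
  rows <- lapply(seq_along(node_list), function(i) {
    n <- node_list[[i]]
    if (is.null(n$id) || is.null(n$level))
      stop("node record ", i, " is malformed: every node needs 'id' and ",
           "'level' (offending record: ",
           paste(deparse(n), collapse = " "), ")", call. = FALSE)
    if (!identical(n$level, "total") && (is.null(n$parent) || is.null(n$weight)))
      stop("node record '", n$id, "' is malformed: non-root nodes need ",
           "'parent' and 'weight'", call. = FALSE)
    data.frame(id = as.character(n$id),
               label = as.character(n$label %||% n$id),
               level = as.character(n$level),
               parent = as.character(n$parent %||% NA_character_),
               weight = as.numeric(n$weight %||% NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sibling weight groups of a hierarchy
#'
#' Returns one row per internal node: its children and their weight sum.
#' For the bundled default model this yields 17 groups (1 at the total
#' level, 4 primary-to-secondary, 12 secondary-to-tertiary), each summing
#' to 1.0000 within the printing tolerance.
#'
#' @param h a [risk_hierarchy].
#' @return Data frame with columns `parent`, `n_children`, `weight_sum`
#'   and a list column `children` of child id vectors, in hierarchy order.
#' @export
#' @examples
#' sibling_weight_groups(default_hierarchy())
sibling_weight_groups <- function(h) {
  stopifnot(inherits(h, "risk_hierarchy"))
  nodes <- h$nodes
  nonroot <- nodes[nodes$level != "total", , drop = FALSE]
  parents <- unique(nonroot$parent)
  parents <- parents[order(match(parents, nodes$id))]
  res <- lapply(parents, function(p) {
    kids <- nonroot[nonroot$parent == p, , drop = FALSE]
    data.frame(parent = p, n_children = nrow(kids),
               weight_sum = sum(kids$weight), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$children <- lapply(parents, function(p)
    nonroot$id[nonroot$parent == p])
  out
}

#' @export
print.risk_hierarchy <- function(x, ...) {
  counts <- table(factor(x$nodes$level,
                         levels = c("total", "primary", "secondary",
                                    "tertiary")))
  cat("<risk_hierarchy> ", x$model_name, " (version ", x$model_version,
      ")\n", sep = "")
  cat("  nodes:", paste(sprintf("%d %s", counts, names(counts)),
                        collapse = ", "), "\n")
  cat("  root: ", x$root_id, "\n", sep = "")
  invisible(x)
}

# children ids of `parent`, in node-table order
.children <- function(h, parent) {
  h$nodes$id[!is.na(h$nodes$parent) & h$nodes$parent == parent]
}

# tertiary index ids, in hierarchy (table) order
#' Tertiary index ids of a hierarchy, in canonical order
#' @param h a [risk_hierarchy].
#' @return Character vector of tertiary index ids.
#' @export
tertiary_ids <- function(h) {
  stopifnot(inherits(h, "risk_hierarchy"))
  h$nodes$id[h$nodes$level == "tertiary"]
}

#' Serialize a hierarchy back to a configuration list
#'
#' Inverse of [load_hierarchy()]: the returned list can be written with
#' `yaml::write_yaml()` and re-loaded without any change to ids, labels,
#' levels, parents or weights.
#'
#' @param h a [risk_hierarchy].
#' @return A configuration list with `model_name`, `model_version` and
#'   `nodes` entries.
#' @export
hierarchy_to_config <- function(h) {
  stopifnot(inherits(h, "risk_hierarchy"))
  nodes <- lapply(seq_len(nrow(h$nodes)), function(i) {
    r <- h$nodes[i, ]
    n <- list(id = r$id, label = r$label, level = r$level)
    if (!is.na(r$parent)) n$parent <- r$parent
    if (!is.na(r$weight)) n$weight <- r$weight
    n
  })
  list(model_name = h$model_name, model_version = h$model_version,
       nodes = nodes)
}
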