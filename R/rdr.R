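#' @title Single-classification ripple-down-rules engine
#' @description
#' A generic ripple-down-rules (RDR) engine. An RDR tree is a binary tree of
#' production rules: each node carries a logical condition, a conclusion and
#' the *cornerstone case* that motivated it. Inference walks the tree from the
#' root: when a node's condition holds the walk descends into the *except*
#' child (a refinement of the current conclusion), otherwise into the *alt*
#' child (an alternative rule); the conclusion of the last node whose
#' condition held is returned. The root carries the always-true condition, so
#' a conclusion always exists. Knowledge acquisition attaches each new rule at
#' the exact point where a case was misclassified and is only accepted if no
#' previously registered cornerstone case changes its conclusion.
#' @name rdr
NULL

RDR_OPS <- c("==", "!=", "<", "<=", ">", ">=", "present", "absent")

#' Build a case
#'
#' A case is a flat attribute -> value record. Values may be numeric, string
#' or logical; an attribute that is not in the case is *absent*, which is
#' distinct from zero and from the empty string.
#'
#' @param ... named attribute values, or a single named list.
#' @return an object of class `rdr_case` (a named list).
#' @examples
#' rdr_case(plasma_leucine = 250, age_months = 3)
#' @export
rdr_case <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.list(args[[1L]])) {
    args <- args[[1L]]
  }
  args <- args[!vapply(args, is.null, logical(1))]
  nm <- names(args)
  if (length(args) > 0L && (is.null(nm) || any(!nzchar(nm)))) {
    stop("all case attributes must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate case attribute: ", nm[duplicated(nm)][1L], call. = FALSE)
  }
  structure(args, class = "rdr_case")
}

#' Build a condition
#'
#' A condition is a conjunction of atomic comparisons, each an
#' (attribute, operator, literal) triple. Operators are `==`, `!=`, `<`,
#' `<=`, `>`, `>=`, `present`, `absent`. The empty conjunction is the
#' always-true condition used at the root of every tree.
#'
#' @param ... atoms created with [rdr_atom()], or a single list of atoms.
#' @return an object of class `rdr_condition`.
#' @examples
#' rdr_condition(rdr_atom("plasma_leucine", ">", 200))
#' rdr_condition()  # always true
#' @export
rdr_condition <- function(...) {
  atoms <- list(...)
  if (length(atoms) == 1L && !inherits(atoms[[1L]], "rdr_atom") &&
      is.list(atoms[[1L]])) {
    atoms <- atoms[[1L]]
  }
  atoms <- lapply(atoms, function(a) {
    if (inherits(a, "rdr_atom")) a else rdr_atom(a$attr, a$op, a$value)
  })
  structure(list(atoms = atoms), class = "rdr_condition")
}

#' @rdname rdr_condition
#' @param attr attribute name the comparison reads.
#' @param op comparison operator (one of the eight listed above).
#' @param value literal to compare against; ignored for `present`/`absent`.
#' @export
rdr_atom <- function(attr, op, value = NULL) {
  stopifnot(is.character(attr), length(attr) == 1L, nzchar(attr))
  if (!is.character(op) || length(op) != 1L || !(op %in% RDR_OPS)) {
    stop("unknown operator '", op, "' in atom on attribute '", attr,
         "' (known: ", paste(RDR_OPS, collapse = " "), ")", call. = FALSE)
  }
  if (!(op %in% c("present", "absent")) && is.null(value)) {
    stop("atom (", attr, " ", op, ") requires a literal value", call. = FALSE)
  }
  structure(list(attr = attr, op = op, value = value), class = "rdr_atom")
}

#' Evaluate a condition on a case
#'
#' Evaluation is total and side-effect free: any comparison against an
#' attribute that is absent from the case evaluates to `FALSE`, except for the
#' `absent` operator which is `TRUE` exactly then. This lets partially
#' specified cases fall through to default rules rather than erroring.
#'
#' @param condition an [rdr_condition()].
#' @param case an [rdr_case()].
#' @return `TRUE` iff every atom of the conjunction holds on the case.
#' @export
evaluate_condition <- function(condition, case) {
  stopifnot(inherits(condition, "rdr_condition"), inherits(case, "rdr_case"))
  for (a in condition$atoms) {
    if (!inherits(a, "rdr_atom") || !(a$op %in% RDR_OPS)) {
      stop("unknown operator in atom on attribute '",
           if (is.list(a)) a$attr else "?", "'", call. = FALSE)
    }
    present <- a$attr %in% names(case)
    ok <- switch(a$op,
      "present" = present,
      "absent"  = !present,
      {
        if (!present) FALSE else {
          v <- case[[a$attr]]
          cmp <- switch(a$op,
            "==" = isTRUE(v == a$value),
            "!=" = isTRUE(v != a$value),
            "<"  = isTRUE(v <  a$value),
            "<=" = isTRUE(v <= a$value),
            ">"  = isTRUE(v >  a$value),
            ">=" = isTRUE(v >= a$value))
          cmp
        }
      })
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' Build a conclusion
#'
#' @param label non-empty classification label.
#' @param payload named list of free-form directives (e.g. multiplicative
#'   adjustment factors consumed by the dosing pipeline).
#' @param explanation human-readable justification shown to the caregiver.
#' @return an object of class `rdr_conclusion`.
#' @export
rdr_conclusion <- function(label, payload = list(), explanation = "") {
  stopifnot(is.character(label), length(label) == 1L)
  if (!nzchar(label)) stop("conclusion label must be non-empty", call. = FALSE)
  structure(list(label = label, payload = payload, explanation = explanation),
            class = "rdr_conclusion")
}

new_rdr_node <- function(id, condition, conclusion, cornerstone,
                         except = NULL, alt = NULL) {
  list(id = id, condition = condition, conclusion = conclusion,
       cornerstone = cornerstone, except = except, alt = alt)
}

#' Create a ripple-down-rules tree
#'
#' The new tree has a single root node whose condition is always true; its
#' conclusion is the system's default (fired when no refinement applies).
#'
#' @param default_conclusion the [rdr_conclusion()] of the root/default rule.
#' @return an object of class `rdr_tree`.
#' @export
rdr_tree <- function(default_conclusion) {
  stopifnot(inherits(default_conclusion, "rdr_conclusion"))
  root <- new_rdr_node("n1", rdr_condition(), default_conclusion, rdr_case())
  structure(list(nodes = stats::setNames(list(root), "n1"), root = "n1",
                 cornerstones = list()),
            class = "rdr_tree")
}

validate_rdr_tree <- function(tree) {
  stopifnot(inherits(tree, "rdr_tree"))
  ids <- names(tree$nodes)
  if (anyDuplicated(ids)) stop("duplicate node id in tree", call. = FALSE)
  if (!(tree$root %in% ids)) stop("root id not among nodes", call. = FALSE)
  if (length(tree$nodes[[tree$root]]$condition$atoms) != 0L) {
    stop("root condition must be the always-true condition", call. = FALSE)
  }
  # acyclic + single-parent reachability: walk from root, each node seen once
  seen <- character(0)
  walk <- function(id) {
    if (is.null(id)) return(invisible())
    if (!(id %in% ids)) stop("child id '", id, "' not in tree", call. = FALSE)
    if (id %in% seen) stop("node '", id, "' reachable twice", call. = FALSE)
    seen <<- c(seen, id)
    walk(tree$nodes[[id]]$except)
    walk(tree$nodes[[id]]$alt)
  }
  walk(tree$root)
  if (length(seen) != length(ids)) {
    stop("unreachable node(s): ",
         paste(setdiff(ids, seen), collapse = ", "), call. = FALSE)
  }
  invisible(tree)
}

#' Run RDR inference on a case
#'
#' Standard single-classification traversal: at each node, if the condition
#' holds the node is recorded as last-satisfied and the walk descends into
#' the except child, otherwise into the alt child; the walk stops when the
#' needed child is missing and the last-satisfied node's conclusion is
#' returned. The root always satisfies, so the result is total.
#'
#' @param tree an [rdr_tree()].
#' @param case an [rdr_case()].
#' @return list with `conclusion` (an `rdr_conclusion`) and `fired_path`
#'   (character vector of node ids visited, in order).
#' @export
rdr_infer <- function(tree, case) {
  stopifnot(inherits(tree, "rdr_tree"), inherits(case, "rdr_case"))
  cur <- tree$root
  last_satisfied <- NULL
  path <- character(0)
  while (!is.null(cur)) {
    node <- tree$nodes[[cur]]
    path <- c(path, cur)
    if (evaluate_condition(node$condition, case)) {
      last_satisfied <- cur
      cur <- node$except
    } else {
      cur <- node$alt
    }
  }
  list(conclusion = tree$nodes[[last_satisfied]]$conclusion,
       fired_path = path)
}

# Where would inference attach a refuting rule? Returns the node the walk
# ended at and whether its condition was true (-> except slot) or not (-> alt).
rdr_attachment_point <- function(tree, case) {
  cur <- tree$root
  repeat {
    node <- tree$nodes[[cur]]
    sat <- evaluate_condition(node$condition, case)
    nxt <- if (sat) node$except else node$alt
    if (is.null(nxt)) return(list(id = cur, satisfied = sat))
    cur <- nxt
  }
}

#' Add a rule to an RDR tree (knowledge acquisition)
#'
#' Attaches a new rule at the point where inference on the misclassified case
#' ended: as the except child if that node's condition held for the case,
#' else as the alt child. The misclassified case is stored as the rule's
#' cornerstone. The addition is rejected -- and the tree returned unchanged
#' is never the case -- if the new condition does not hold on its own
#' cornerstone, or if any previously registered cornerstone case would change
#' conclusion (the caller must then supply a condition that discriminates).
#'
#' @param tree an [rdr_tree()].
#' @param misclassified the [rdr_case()] the current tree gets wrong.
#' @param new_condition an [rdr_condition()] true on `misclassified`.
#' @param new_conclusion the [rdr_conclusion()] the case should receive.
#' @return the updated tree.
#' @export
rdr_add_rule <- function(tree, misclassified, new_condition, new_conclusion) {
  stopifnot(inherits(tree, "rdr_tree"), inherits(misclassified, "rdr_case"),
            inherits(new_condition, "rdr_condition"),
            inherits(new_conclusion, "rdr_conclusion"))
  if (!evaluate_condition(new_condition, misclassified)) {
    stop("rule rejected: the new condition is false on its own cornerstone ",
         "case, so the rule would never fire for it", call. = FALSE)
  }
  at <- rdr_attachment_point(tree, misclassified)
  new_id <- paste0("n", length(tree$nodes) + 1L)
  while (new_id %in% names(tree$nodes)) new_id <- paste0(new_id, "x")
  candidate <- tree
  candidate$nodes[[new_id]] <-
    new_rdr_node(new_id, new_condition, new_conclusion, misclassified)
  slot <- if (at$satisfied) "except" else "alt"
  candidate$nodes[[at$id]][[slot]] <- new_id

  # cornerstone preservation: every stored cornerstone must keep its label
  for (cs in tree$cornerstones) {
    before <- rdr_infer(tree, cs$case)$conclusion$label
    after <- rdr_infer(candidate, cs$case)$conclusion$label
    if (!identical(before, after)) {
      stop("rule rejected: cornerstone case of node '", cs$node_id,
           "' would change conclusion from '", before, "' to '", after,
           "'; refine the condition to exclude it", call. = FALSE)
    }
  }
  candidate$cornerstones <- c(candidate$cornerstones,
                              list(list(node_id = new_id, case = misclassified)))
  candidate
}

# ---- JSON persistence ------------------------------------------------------

TREE_NODE_KEYS <- c("id", "condition", "conclusion", "cornerstone",
                    "except", "alt")

#' Serialize / restore an RDR tree as JSON
#'
#' The document is `{"version": 1, "nodes": [...], "root": id}`; each node is
#' `{"id", "condition": [{"attr","op","value"}], "conclusion":
#' {"label","payload","explanation"}, "cornerstone": {...}, "except": id|null,
#' "alt": id|null}`. Unknown keys are rejected; a restored tree infers
#' identically to the original on every case.
#'
#' @param tree an [rdr_tree()].
#' @param path file to write to / read from.
#' @return `save_tree` invisibly returns `path`; `load_tree` returns the tree.
#' @export
save_tree <- function(tree, path) {
  validate_rdr_tree(tree)
  nodes <- lapply(unname(tree$nodes), function(n) {
    list(
      id = n$id,
      condition = lapply(n$condition$atoms, function(a)
        list(attr = a$attr, op = a$op, value = a$value)),
      conclusion = list(label = n$conclusion$label,
                        payload = n$conclusion$payload,
                        explanation = n$conclusion$explanation),
      cornerstone = unclass(n$cornerstone),
      except = n$except, alt = n$alt
    )
  })
  doc <- list(version = 1L, nodes = nodes, root = tree$root)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_tree
#' @export
load_tree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  known_top <- c("version", "nodes", "root")
  extra <- setdiff(names(doc), known_top)
  if (length(extra)) stop("invalid tree document at $", extra[1L],
                          ": unknown key", call. = FALSE)
  for (k in known_top) {
    if (is.null(doc[[k]])) stop("invalid tree document at $", k,
                                ": missing", call. = FALSE)
  }
  nodes <- list()
  for (i in seq_along(doc$nodes)) {
    nd <- doc$nodes[[i]]
    where <- paste0("$nodes[", i, "]")
    extra <- setdiff(names(nd), TREE_NODE_KEYS)
    if (length(extra)) stop("invalid tree document at ", where, ".",
                            extra[1L], ": unknown key", call. = FALSE)
    for (k in c("id", "condition", "conclusion", "cornerstone")) {
      if (!(k %in% names(nd))) stop("invalid tree document at ", where, ".",
                                    k, ": missing", call. = FALSE)
    }
    atoms <- lapply(nd$condition, function(a)
      rdr_atom(a$attr, a$op, a$value))
    concl <- rdr_conclusion(nd$conclusion$label,
                            payload = if (is.null(nd$conclusion$payload))
                              list() else nd$conclusion$payload,
                            explanation = nd$conclusion$explanation %||% "")
    nodes[[nd$id]] <- new_rdr_node(
      nd$id, rdr_condition(atoms), concl, rdr_case(nd$cornerstone),
      except = nd$except, alt = nd$alt)
  }
  tree <- structure(list(nodes = nodes, root = doc$root,
                         cornerstones = lapply(nodes, function(n)
                           list(node_id = n$id, case = n$cornerstone))),
                    class = "rdr_tree")
  # drop the root's empty cornerstone from the replay registry
  tree$cornerstones <- Filter(function(cs) length(cs$case) > 0L,
                              unname(tree$cornerstones))
  validate_rdr_tree(tree)
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rdr_tree <- function(x, ...) {
  cat("RDR tree:", length(x$nodes), "node(s), root =", x$root, "\n")
  show <- function(id, depth, slot) {
    n <- x$nodes[[id]]
    atoms <- if (length(n$condition$atoms) == 0L) "<always>" else
      paste(vapply(n$condition$atoms, function(a)
        paste(a$attr, a$op, a$value %||% ""), character(1)), collapse = " & ")
    cat(strrep("  ", depth), slot, " [", id, "] if ", atoms, " -> ",
        n$conclusion$label, "\n", sep = "")
    if (!is.null(n$except)) show(n$except, depth + 1L, "except:")
    if (!is.null(n$alt)) show(n$alt, depth + 1L, "alt:")
  }
  show(x$root, 0L, "root:")
  invisible(x)
}
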