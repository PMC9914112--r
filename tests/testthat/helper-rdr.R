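# Independent brute-force RDR evaluator: recursive descent, written apart
# from the engine's iterative traversal. Returns the conclusion label, or
# NULL for a subtree that contributes nothing.
brute_infer_label <- function(tree, case) {
  descend <- function(id) {
    node <- tree$nodes[[id]]
    if (evaluate_condition(node$condition, case)) {
      refined <- if (!is.null(node$except)) descend(node$except)
      if (!is.null(refined)) refined else node$conclusion$label
    } else {
      if (!is.null(node$alt)) descend(node$alt)
    }
  }
  descend(tree$root)
}

CASE_ATTRS <- c("a", "b", "c", "d")

rand_case <- function() {
  present <- CASE_ATTRS[stats::runif(length(CASE_ATTRS)) < 0.7]
  vals <- stats::setNames(
    as.list(round(stats::runif(length(present), 0, 10), 1)), present)
  rdr_case(vals)
}

# a 1-2 atom condition guaranteed true on `case`
rand_true_condition <- function(case) {
  stopifnot(length(case) > 0)
  n_atoms <- sample(1:min(2, length(case)), 1)
  attrs <- sample(names(case), n_atoms)
  atoms <- lapply(attrs, function(at) {
    v <- case[[at]]
    op <- sample(c("<", "<=", ">", ">=", "==", "present"), 1)
    switch(op,
      "<"  = rdr_atom(at, "<", v + stats::runif(1, 0.1, 3)),
      "<=" = rdr_atom(at, "<=", v),
      ">"  = rdr_atom(at, ">", v - stats::runif(1, 0.1, 3)),
      ">=" = rdr_atom(at, ">=", v),
      "==" = rdr_atom(at, "==", v),
      "present" = rdr_atom(at, "present"))
  })
  rdr_condition(atoms)
}

# grow a random tree by knowledge acquisition; rejected rules are skipped
rand_tree <- function(n_rules) {
  tree <- rdr_tree(rdr_conclusion("default"))
  added <- 0L
  attempts <- 0L
  while (added < n_rules && attempts < n_rules * 10L) {
    attempts <- attempts + 1L
    case <- rand_case()
    if (length(case) == 0L) next
    concl <- rdr_conclusion(paste0("label_", sample(1:5, 1)))
    tree2 <- tryCatch(
      rdr_add_rule(tree, case, rand_true_condition(case), concl),
      error = function(e) NULL)
    if (!is.null(tree2)) {
      tree <- tree2
      added <- added + 1L
    }
  }
  tree
}
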