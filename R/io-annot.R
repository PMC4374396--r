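#' Annotated text output for simulated and reconstructed histories
#'
#' [write_guest_newick()] serialises a simulated gene tree as Newick
#' with bracketed annotation blocks (`[&type=...,host=...,time=...]`)
#' after each node, keeping loss tips so the full event history is
#' recoverable from the text; [write_event_log()] writes the event log
#' as a three-column TSV (`event`, `branch`, `time`).
#' [write_count_history()] serialises an ancestral count
#' reconstruction as the species-tree Newick with per-node
#' `[&count=...,delta=...]` annotations.
#'
#' @param gt A `guest_tree` from [simulate_guest()].
#' @param file Optional path; when `NULL` the string is returned
#'   (the TSV writer always needs a path).
#' @return The annotated Newick string (invisibly, when written to a
#'   file).
#' @export
write_guest_newick <- function(gt, file = NULL) {
  stopifnot(inherits(gt, "guest_tree"))
  nodes <- gt$nodes
  kids <- split(nodes$node, factor(nodes$parent, levels = nodes$node))
  ann <- function(i) {
    sprintf("[&type=%s%s,time=%s]", nodes$type[i],
            if (is.na(nodes$host_branch[i])) ""
            else paste0(",host=", nodes$host_branch[i]),
            format(nodes$time[i], digits = 10))
  }
  build <- function(i) {
    ch <- kids[[as.character(nodes$node[i])]]
    lab <- if (nodes$type[i] == "extant") {
      paste0(nodes$species[i], "|g", nodes$node[i])
    } else if (nodes$type[i] == "loss") {
      paste0("lost_g", nodes$node[i])
    } else {
      ""
    }
    core <- if (length(ch) == 0) lab else {
      paste0("(", paste(vapply(ch, function(j) {
        build(which(nodes$node == j))
      }, character(1)), collapse = ","), ")", lab)
    }
    paste0(core, ann(i))
  }
  roots <- which(is.na(nodes$parent))
  parts <- vapply(roots, build, character(1))
  txt <- if (length(parts) == 1) parts else {
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(txt, ";")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @rdname write_guest_newick
#' @export
write_event_log <- function(gt, file) {
  stopifnot(inherits(gt, "guest_tree"))
  utils::write.table(gt$events, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_guest_newick
#' @param history A `count_history` from [sankoff_counts()] or
#'   [ml_ancestral_counts()].
#' @param tree The `chronogram` the history was reconstructed on.
#' @export
write_count_history <- function(history, tree, file = NULL) {
  stopifnot(inherits(history, "count_history"))
  tree <- as_chronogram(tree)
  labs <- node_labels(tree)
  if (!setequal(labs, history$node)) {
    abort("`history` does not match the tree's nodes")
  }
  cnt <- setNames(history$count, history$node)
  dlt <- setNames(history$delta, history$node)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  lens <- setNames(rep(NA_real_, length(labs)), seq_along(labs))
  lens[as.character(tree$edge[, 2])] <- tree$edge.length
  build <- function(nd) {
    lab <- labs[nd]
    ann <- sprintf("[&count=%d%s]", cnt[[lab]],
                   if (is.na(dlt[[lab]])) ""
                   else paste0(",delta=", dlt[[lab]]))
    len <- if (is.na(lens[[as.character(nd)]])) "" else {
      paste0(":", format(lens[[as.character(nd)]], digits = 10))
    }
    ch <- kids[[as.character(nd)]]
    core <- if (is.null(ch)) lab else {
      paste0("(", paste(vapply(ch, build, character(1)), collapse = ","),
             ")", lab)
    }
    paste0(core, ann, len)
  }
  txt <- paste0(build(ape::Ntip(tree) + 1L), ";")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
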