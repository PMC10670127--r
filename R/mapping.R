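#' Map unknown perturbations onto the pathway via co-clustering groups
#'
#' Perturbations with a known pathway target (the enzyme inhibitors
#' annotated on the graph) anchor the mapping: an unknown perturbation (a
#' chemotherapy or autophagy modulator) that co-clusters with one or more
#' known inhibitors inherits those inhibitors' target enzyme edges and the
#' corresponding substrate nodes (where the metabolite accumulates when the
#' enzyme is blocked). Unknowns that group only with other unknowns — or
#' not at all — are reported as unmapped.
#'
#' @param groups list of co-clustering groups from [extract_pairs()]
#'   (character vectors of condition labels; optional `"height"` attribute
#'   per group).
#' @param graph a `pathway_graph` carrying inhibitor annotations.
#' @param known labels regarded as known anchors. Default: the eight
#'   sphingolipid-pathway enzyme inhibitors among the graph's annotations —
#'   autophagy modulators, although annotated on the stage edges, are *not*
#'   anchors (their profile clusters are to be mapped, not used for
#'   mapping).
#' @param unknown labels eligible for mapping; default everything in the
#'   groups that is not known (pass the full label set explicitly so that
#'   unknowns absent from every group are reported unmapped). If given
#'   explicitly, a group member that is neither known nor unknown is an
#'   error.
#' @return object of class `mapping_result`: tibble with one row per mapped
#'   unknown (`unknown`, `matched_known`, `nodes`, `edges` as list columns,
#'   `merge_height`), the unmapped labels in attribute `"unmapped"`.
#' @export
map_to_pathway <- function(groups, graph, known = NULL, unknown = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (is.null(known)) {
    known <- intersect(default_drug_panel()$sl_inhibitors,
                       unique(graph$inhibitors$inhibitor))
  }
  members <- unique(unlist(groups))
  if (!is.null(unknown)) {
    stray <- setdiff(members, c(known, unknown))
    if (length(stray)) {
      abort(paste("group member(s) in neither known nor unknown set:",
                  paste(stray, collapse = ", ")))
    }
  } else {
    unknown <- setdiff(members, known)
  }
  rows <- list()
  mapped <- character(0)
  for (g in groups) {
    k_in <- intersect(g, known)
    u_in <- intersect(g, unknown)
    if (length(k_in) == 0 || length(u_in) == 0) next
    edge_ids <- sort(unique(graph$inhibitors$edge_id[
      graph$inhibitors$inhibitor %in% k_in
    ]))
    node_ids <- sort(unique(graph$edges$substrate[graph$edges$id %in% edge_ids]))
    h <- attr(g, "height") %||% NA_real_
    for (u in u_in) {
      rows[[length(rows) + 1]] <- tibble(
        unknown = u, matched_known = list(sort(k_in)),
        nodes = list(node_ids), edges = list(edge_ids), merge_height = h
      )
    }
    mapped <- c(mapped, u_in)
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(unknown = character(0), matched_known = list(),
           nodes = list(), edges = list(), merge_height = numeric(0))
  structure(out, class = c("mapping_result", class(out)),
            unmapped = sort(setdiff(unknown, mapped)))
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> %d mapped unknown(s), %d unmapped\n",
              nrow(x), length(attr(x, "unmapped"))))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s -> %s (nodes: %s)\n", x$unknown[i],
                paste(x$matched_known[[i]], collapse = "+"),
                paste(x$nodes[[i]], collapse = ", ")))
  }
  if (length(attr(x, "unmapped"))) {
    cat("  unmapped:", paste(attr(x, "unmapped"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a mapping result to JSON
#'
#' @param mapping a `mapping_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mapping_json <- function(mapping, path) {
  jsonlite::write_json(
    list(mapped = as.data.frame(mapping), unmapped = attr(mapping, "unmapped")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
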