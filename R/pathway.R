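#' Build the default sphingolipid/autophagy pathway topology
#'
#' Encodes the metabolic fate of a fluorescent sphingomyelin analog in an
#' A549-like cell as a compartmentalized graph: sphingomyelin at the plasma
#' membrane (SM_PM) is converted to ceramide (CER_PM) and onward to
#' sphingosine and S1P; lysosomal, Golgi and ER pools are connected by
#' transport and by the macroautophagy stages phagophore (P), autophagosome
#' (AP) and autophagolysosome (AL). Metabolites that retain the BODIPY
#' fluorophore are flagged fluorescent; ceramidase products (sphingosine,
#' S1P) lose it. Each of the eight pathway inhibitors annotates its target
#' enzyme edge(s): SKI sphingosine kinase, PDMP glucosylceramide synthase,
#' DES acid sphingomyelinase + acid ceramidase, NCI neutral/alkaline
#' ceramidase at the plasma membrane, D609 sphingomyelin synthase, ACI acid
#' ceramidase in the lysosome, GW neutral sphingomyelinase, MYR serine
#' palmitoyltransferase (de novo arm). SPA annotates phagophore formation
#' and HCQ autophagolysosome acidification plus the acid-ceramidase context.
#' Edges not individually named in the source text of the study system are
#' reconstructed from the inhibitor-target descriptions and tagged
#' `reconstructed`.
#'
#' @return object of class `pathway_graph`: tibbles `nodes` (id, name,
#'   compartment, fluorescent, type), `edges` (id, substrate, product,
#'   enzyme, type, reconstructed), `inhibitors` (inhibitor -> edge id) and
#'   `drugs` (initially empty drug-mapping annotations).
#' @export
build_default_topology <- function() {
  nodes <- tibble::tribble(
    ~id,            ~name,                              ~compartment,      ~fluorescent, ~type,
    "SM_PM",        "sphingomyelin",                    "plasma membrane", TRUE,  "metabolite",
    "CER_PM",       "ceramide",                         "plasma membrane", TRUE,  "metabolite",
    "SO_PM",        "sphingosine",                      "plasma membrane", FALSE, "metabolite",
    "S1P",          "sphingosine 1-phosphate",          "cytosol",         FALSE, "metabolite",
    "SM_LYS",       "sphingomyelin",                    "lysosome",        TRUE,  "metabolite",
    "CER_LYS",      "ceramide",                         "lysosome",        TRUE,  "metabolite",
    "SO_LYS",       "sphingosine",                      "lysosome",        FALSE, "metabolite",
    "CER_ER",       "ceramide (de novo)",               "ER",              TRUE,  "metabolite",
    "CER_GOLGIIN",  "ceramide",                         "Golgi-in",        TRUE,  "metabolite",
    "CER_GOLGIOUT", "ceramide",                         "Golgi-out",       TRUE,  "metabolite",
    "GLU_CER",      "glucosylceramide",                 "Golgi-out",       TRUE,  "metabolite",
    "SM_GOLGI",     "sphingomyelin",                    "Golgi-in",        TRUE,  "metabolite",
    "SERPALM",      "serine + palmitoyl-CoA",           "ER",              FALSE, "precursor",
    "P",            "phagophore",                       "phagophore",      FALSE, "stage",
    "AP",           "autophagosome",                    "autophagosome",   TRUE,  "stage",
    "AL",           "autophagolysosome",                "autophagolysosome", TRUE, "stage"
  )
  edges <- tibble::tribble(
    ~id,          ~substrate,     ~product,       ~enzyme,                              ~type,        ~reconstructed,
    "e_nsmase",   "SM_PM",        "CER_PM",       "neutral sphingomyelinase",           "enzymatic",  TRUE,
    "e_ncdase",   "CER_PM",       "SO_PM",        "neutral/alkaline ceramidase",        "enzymatic",  FALSE,
    "e_sphk",     "SO_PM",        "S1P",          "sphingosine kinase",                 "enzymatic",  TRUE,
    "e_asmase",   "SM_LYS",       "CER_LYS",      "acid sphingomyelinase",              "enzymatic",  TRUE,
    "e_acdase",   "CER_LYS",      "SO_LYS",       "acid ceramidase",                    "enzymatic",  FALSE,
    "e_gcs",      "CER_GOLGIOUT", "GLU_CER",      "glucosylceramide synthase",          "enzymatic",  FALSE,
    "e_sms",      "CER_GOLGIIN",  "SM_GOLGI",     "sphingomyelin synthase",             "enzymatic",  TRUE,
    "e_spt",      "SERPALM",      "CER_ER",       "serine palmitoyltransferase",        "enzymatic",  TRUE,
    "t_cert",     "CER_ER",       "CER_GOLGIIN",  "ceramide transport (CERT)",          "transport",  TRUE,
    "t_flip",     "CER_GOLGIIN",  "CER_GOLGIOUT", "ceramide flip (Golgi)",              "transport",  TRUE,
    "t_secr",     "SM_GOLGI",     "SM_PM",        "secretory transport",                "transport",  TRUE,
    "s_phag",     "SM_PM",        "P",            "phagophore formation",               "stage",      FALSE,
    "s_ap",       "P",            "AP",           "autophagosome formation",            "stage",      FALSE,
    "s_al",       "AP",           "AL",           "autophagosome-lysosome fusion/acidification", "stage", FALSE,
    "s_deliver",  "AL",           "SM_LYS",       "lysosomal delivery",                 "stage",      TRUE
  )
  inhibitors <- tibble::tribble(
    ~inhibitor, ~edge_id,
    "SKI",  "e_sphk",
    "PDMP", "e_gcs",
    "DES",  "e_asmase",
    "DES",  "e_acdase",
    "NCI",  "e_ncdase",
    "D609", "e_sms",
    "ACI",  "e_acdase",
    "GW",   "e_nsmase",
    "MYR",  "e_spt",
    "SPA",  "s_phag",
    "HCQ",  "s_al",
    "HCQ",  "e_acdase"
  )
  g <- structure(
    list(nodes = nodes, edges = edges, inhibitors = inhibitors,
         drugs = tibble(drug = character(0), target_type = character(0),
                        target_id = character(0), provenance = character(0))),
    class = "pathway_graph"
  )
  validate_pathway_graph(g)
  g
}

#' Validate a pathway graph's structural invariants
#'
#' Checks that every edge endpoint is a node, every inhibitor annotation
#' references an existing edge, every sphingolipid-pathway inhibitor present
#' annotates at least one enzymatic or stage edge, and the graph is
#' connected.
#'
#' @param graph a `pathway_graph`.
#' @return invisibly `TRUE`; aborts on violation.
#' @export
validate_pathway_graph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  bad <- setdiff(c(graph$edges$substrate, graph$edges$product), graph$nodes$id)
  if (length(bad)) abort(paste("edge endpoints missing from nodes:", paste(bad, collapse = ", ")))
  bad <- setdiff(graph$inhibitors$edge_id, graph$edges$id)
  if (length(bad)) abort(paste("inhibitor annotations reference unknown edges:", paste(bad, collapse = ", ")))
  ig <- pathway_igraph(graph)
  if (!igraph::is_connected(ig, mode = "weak")) abort("pathway graph must be connected")
  if (nrow(graph$drugs)) {
    ok <- graph$drugs$target_id %in% c(graph$nodes$id, graph$edges$id)
    if (!all(ok)) {
      abort(paste("drug annotations reference unknown ids:",
                  paste(graph$drugs$target_id[!ok], collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d nodes, %d edges, %d inhibitor annotations, %d drug annotations\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$inhibitors), nrow(x$drugs)))
  invisible(x)
}

# igraph view of a pathway graph (edge/vertex attributes carried along)
pathway_igraph <- function(graph) {
  ed <- graph$edges %>%
    mutate(inhibitors = vapply(.data$id, function(e) {
      paste(sort(graph$inhibitors$inhibitor[graph$inhibitors$edge_id == e]),
            collapse = ";")
    }, character(1))) %>%
    select(from = "substrate", to = "product", edge_id = "id", "enzyme",
           "type", "reconstructed", "inhibitors")
  ig <- igraph::graph_from_data_frame(
    ed, directed = TRUE,
    vertices = graph$nodes %>% rename(name = "id", display_name = "name")
  )
  ig <- igraph::set_graph_attr(ig, "drugs_json",
                               as.character(jsonlite::toJSON(graph$drugs, digits = NA)))
  ig
}

#' Annotate drug-to-pathway mappings on the graph
#'
#' Adds the drug annotations of a [map_to_pathway()] result (drug, target
#' node/edge, provenance = co-clustered partner and merge height) to the
#' graph. Repeated identical calls are idempotent.
#'
#' @param graph a `pathway_graph`.
#' @param mapping a `mapping_result` from [map_to_pathway()], or a tibble
#'   with columns `drug`, `target_type`, `target_id`, `provenance`.
#' @return the annotated `pathway_graph`.
#' @export
annotate_drug_mapping <- function(graph, mapping) {
  ann <- if (inherits(mapping, "mapping_result")) {
    purrr::pmap_dfr(mapping, function(unknown, matched_known, nodes, edges,
                                      merge_height, ...) {
      prov <- sprintf("co-clustered with %s (merge height %.4g)",
                      paste(matched_known, collapse = "+"), merge_height)
      bind_rows(
        tibble(drug = unknown, target_type = "node", target_id = nodes,
               provenance = prov),
        tibble(drug = unknown, target_type = "edge", target_id = edges,
               provenance = prov)
      )
    })
  } else {
    as_tibble(mapping)
  }
  bad <- setdiff(ann$target_id, c(graph$nodes$id, graph$edges$id))
  if (length(bad)) {
    abort(paste("unknown pathway ids:", paste(bad, collapse = ", ")))
  }
  graph$drugs <- distinct(bind_rows(graph$drugs, ann))
  validate_pathway_graph(graph)
  graph
}

#' Export a pathway graph
#'
#' Serializes the graph as GraphML (via igraph; node/edge/annotation
#' attributes preserved), JSON (full fidelity), or SIF (one line per edge:
#' `substrate edge_id product`; attributes are not representable in SIF).
#'
#' @param graph a `pathway_graph`.
#' @param format `"json"`, `"graphml"` or `"sif"`.
#' @param path optional output file; when `NULL` the serialized text is
#'   returned.
#' @return the serialized text (invisibly when `path` is given).
#' @export
export_pathway_graph <- function(graph, format = c("json", "graphml", "sif"),
                                 path = NULL) {
  format <- match.arg(format)
  txt <- switch(format,
    json = as.character(jsonlite::toJSON(
      list(nodes = graph$nodes, edges = graph$edges,
           inhibitors = graph$inhibitors, drugs = graph$drugs),
      digits = NA, auto_unbox = FALSE
    )),
    graphml = {
      tf <- tempfile(fileext = ".graphml")
      igraph::write_graph(pathway_igraph(graph), tf, format = "graphml")
      paste(readLines(tf), collapse = "\n")
    },
    sif = paste(sprintf("%s\t%s\t%s", graph$edges$substrate, graph$edges$id,
                        graph$edges$product), collapse = "\n")
  )
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse a serialized pathway graph
#'
#' Inverse of [export_pathway_graph()]. GraphML and JSON round-trip the full
#' node/edge/annotation sets; SIF recovers nodes and edges only.
#'
#' @param text serialized graph text (or a file path that exists on disk).
#' @param format `"json"`, `"graphml"` or `"sif"`.
#' @return a `pathway_graph`.
#' @export
read_pathway_graph <- function(text, format = c("json", "graphml", "sif")) {
  format <- match.arg(format)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(text)
    g <- structure(
      list(nodes = as_tibble(obj$nodes), edges = as_tibble(obj$edges),
           inhibitors = as_tibble(obj$inhibitors),
           drugs = if (length(obj$drugs)) as_tibble(obj$drugs) else
             tibble(drug = character(0), target_type = character(0),
                    target_id = character(0), provenance = character(0))),
      class = "pathway_graph"
    )
    return(g)
  }
  if (format == "graphml") {
    tf <- tempfile(fileext = ".graphml")
    writeLines(text, tf)
    ig <- igraph::read_graph(tf, format = "graphml")
    vd <- igraph::as_data_frame(ig, what = "vertices")
    ed <- igraph::as_data_frame(ig, what = "edges")
    nodes <- tibble(id = vd$name, name = vd$display_name,
                    compartment = vd$compartment,
                    fluorescent = as.logical(vd$fluorescent), type = vd$type)
    edges <- tibble(id = ed$edge_id, substrate = ed$from, product = ed$to,
                    enzyme = ed$enzyme, type = ed$type,
                    reconstructed = as.logical(ed$reconstructed))
    inh <- purrr::map_dfr(seq_len(nrow(ed)), function(i) {
      if (!nzchar(ed$inhibitors[i])) return(NULL)
      tibble(inhibitor = strsplit(ed$inhibitors[i], ";", fixed = TRUE)[[1]],
             edge_id = ed$edge_id[i])
    }) %>% arrange(.data$inhibitor, .data$edge_id)
    drugs <- as_tibble(jsonlite::fromJSON(
      igraph::graph_attr(ig, "drugs_json")
    ))
    if (nrow(drugs) == 0) {
      drugs <- tibble(drug = character(0), target_type = character(0),
                      target_id = character(0), provenance = character(0))
    }
    return(structure(list(nodes = nodes, edges = edges, inhibitors = inh,
                          drugs = drugs), class = "pathway_graph"))
  }
  # SIF
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  edges <- tibble(
    id = vapply(parts, `[`, character(1), 2),
    substrate = vapply(parts, `[`, character(1), 1),
    product = vapply(parts, `[`, character(1), 3),
    enzyme = NA_character_, type = NA_character_, reconstructed = NA
  )
  nodes <- tibble(id = sort(unique(c(edges$substrate, edges$product))),
                  name = NA_character_, compartment = NA_character_,
                  fluorescent = NA, type = NA_character_)
  structure(
    list(nodes = nodes, edges = edges,
         inhibitors = tibble(inhibitor = character(0), edge_id = character(0)),
         drugs = tibble(drug = character(0), target_type = character(0),
                        target_id = character(0), provenance = character(0))),
    class = "pathway_graph"
  )
}
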