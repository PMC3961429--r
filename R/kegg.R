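# KGML (KEGG Markup Language) input.  Only the reaction elements and the
# compound entries are used: insertion analysis runs on the bipartite
# compound-reaction graph, not on the relation/enzyme graph.

#' Parse a KGML pathway file
#'
#' Extracts the compound entries and the `<reaction>` elements (substrate
#' and product compound ids, reversibility from the `type` attribute) of
#' one pathway map.  A `name` attribute listing several reaction ids
#' (`"rn:R00001 rn:R00002"`) yields one entry per id; duplicated ids
#' within a map are merged by unioning their substrates and products.
#'
#' @param path KGML XML file.
#' @return an object of class `pathway_fragment`: list with `map_id`,
#'   `compounds` (C-numbers) and `reactions` (list of `list(id,
#'   substrates, products, reversible)`).
#' @export
parse_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed KGML in '", path, "': ", conditionMessage(e))
  })
  map_id <- sub("^path:", "", xml2::xml_attr(doc, "name"))
  strip <- function(x) sub("^(cpd|rn|gl):", "", x)
  cpd_entries <- xml2::xml_find_all(doc, ".//entry[@type='compound']")
  compounds <- unique(strip(unlist(strsplit(
    xml2::xml_attr(cpd_entries, "name"), "\\s+"))))
  compounds <- compounds[grepl("^C\\d{5}$", compounds)]

  rxn_nodes <- xml2::xml_find_all(doc, ".//reaction")
  if (length(rxn_nodes) == 0L) {
    warning("no reaction elements in map ", map_id)
  }
  reactions <- list()
  for (node in rxn_nodes) {
    ids <- strip(unlist(strsplit(xml2::xml_attr(node, "name"), "\\s+")))
    ids <- ids[grepl("^R\\d{5}$", ids)]
    reversible <- identical(xml2::xml_attr(node, "type"), "reversible")
    subs <- strip(xml2::xml_attr(xml2::xml_find_all(node, "./substrate"), "name"))
    prods <- strip(xml2::xml_attr(xml2::xml_find_all(node, "./product"), "name"))
    subs <- subs[grepl("^C\\d{5}$", subs)]
    prods <- prods[grepl("^C\\d{5}$", prods)]
    if (!length(subs) || !length(prods)) next
    for (id in ids) {
      reactions[[id]] <- merge_rxn(reactions[[id]],
                                   list(id = id, substrates = subs,
                                        products = prods,
                                        reversible = reversible))
    }
  }
  compounds <- sort(union(compounds, unlist(lapply(reactions, function(r) {
    c(r$substrates, r$products)
  }))))
  reactions <- if (length(reactions)) unname(reactions[order(names(reactions))]) else list()
  structure(list(map_id = map_id, compounds = compounds,
                 reactions = reactions),
            class = "pathway_fragment")
}

merge_rxn <- function(old, new) {
  if (is.null(old)) return(new)
  list(id = new$id,
       substrates = sort(union(old$substrates, new$substrates)),
       products = sort(union(old$products, new$products)),
       # conflicting direction annotations across maps: union of
       # directions, i.e. reversible wins
       reversible = old$reversible || new$reversible)
}

#' @export
print.pathway_fragment <- function(x, ...) {
  cat(sprintf("<pathway_fragment> %s: %d compounds, %d reactions\n",
              x$map_id, length(x$compounds), length(x$reactions)))
  invisible(x)
}

#' Assemble host and reference networks from pathway fragments
#'
#' Takes the union of the reference fragments by reaction/compound id
#' (merging substrate and product sets of reactions occurring in several
#' maps), marks as host every reaction appearing in any host fragment,
#' decomposes reversible reactions into P/Q halves, and validates the
#' result.  Fragment order does not matter.
#'
#' @param reference list of `pathway_fragment`s forming the reference
#'   network (typically several `ko*` maps).
#' @param host list of `pathway_fragment`s forming the host network
#'   (typically organism-specific maps); reactions present in any host
#'   fragment are host even if they also occur in reference maps.
#' @param sources character vector of source compound C-numbers; all must
#'   occur in the merged network.
#' @param target target compound C-number; must occur in the merged
#'   network.
#' @param source_policy forwarded to [build_network()]; real maps often
#'   give sources incoming edges, which the default `"strip"` removes
#'   with a warning.
#' @return a `metnet` object.
#' @export
merge_maps <- function(reference, host = list(), sources, target,
                       source_policy = c("strip", "strict")) {
  if (inherits(reference, "pathway_fragment")) reference <- list(reference)
  if (inherits(host, "pathway_fragment")) host <- list(host)
  stopifnot(all(vapply(c(reference, host), inherits, TRUE, "pathway_fragment")))

  merged <- list()
  provenance <- list()
  for (frag in c(reference, host)) {
    for (r in frag$reactions) {
      merged[[r$id]] <- merge_rxn(merged[[r$id]], r)
      provenance[[r$id]] <- sort(union(provenance[[r$id]], frag$map_id))
    }
  }
  host_rxn_ids <- unique(unlist(lapply(host, function(f) {
    vapply(f$reactions, function(r) r$id, "")
  })))
  host_cpds <- sort(unique(unlist(lapply(host, function(f) f$compounds))))
  compounds <- sort(unique(c(
    unlist(lapply(c(reference, host), function(f) f$compounds)),
    unlist(lapply(merged, function(r) c(r$substrates, r$products))))))

  missing_src <- setdiff(sources, compounds)
  if (length(missing_src)) {
    stop("source compounds absent from the merged network: ",
         paste(missing_src, collapse = ", "))
  }
  if (!(target %in% compounds)) {
    stop("target compound ", target, " absent from the merged network")
  }
  spec <- list(
    compounds = compounds,
    reactions = lapply(unname(merged[order(names(merged))]), function(r) {
      r$host <- r$id %in% host_rxn_ids
      r
    }),
    sources = sort(unique(sources)),
    target = target,
    host_compounds = sort(union(host_cpds, sources))
  )
  net <- decompose_reversible(spec, source_policy = match.arg(source_policy))
  attr(net, "provenance") <- provenance
  net
}
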