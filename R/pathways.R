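#' Load a pathway library
#'
#' Reads a JSON pathway library: a list of pathways with `id`, `name`,
#' `compounds` (KEGG-style ids) and undirected `edges` over those
#' compounds. The compound universe is the union over all pathways. The
#' packaged default is a synthetic KEGG-modelled fixture covering the
#' pathways relevant to sea-urchin gonadal metabolites.
#'
#' @param path JSON file; defaults to the packaged synthetic library.
#' @return A `pathway_library`: `pathways` (named list with `id`, `name`,
#'   `compounds`, `edges`), `universe`.
#' @export
load_pathway_library <- function(path = system.file("extdata", "pathway_library_synthetic.json",
                                                    package = "metabodisc")) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  pathways <- lapply(raw$pathways, function(p) {
    cpds <- unlist(p$compounds)
    edges <- if (length(p$edges)) {
      do.call(rbind, lapply(p$edges, function(e) unlist(e)))
    } else matrix(character(), ncol = 2)
    stopifnot(all(edges %in% cpds), !any(edges[, 1] == edges[, 2]))
    list(id = p$id, name = p$name, compounds = cpds, edges = edges)
  })
  names(pathways) <- vapply(pathways, `[[`, "", "id")
  structure(list(pathways = pathways,
                 universe = unique(unlist(lapply(pathways, `[[`, "compounds")))),
            class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("<pathway_library> %d pathways, universe of %d compounds\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Species metabolite panels for pathway analysis
#'
#' The compound lists submitted to over-representation analysis for each
#' species. The *A. lixula* panel covers the osmolyte/methylamine/organic-
#' acid/nucleoside signature plus glycine — glycine belongs to the
#' betaine-sarcosine-glycine demethylation axis that anchors this species'
#' C1 signature, so it is carried in the pathway query even though its
#' free-pool concentration is higher in *P. lividus*. The *P. lividus*
#' panel covers the amino-acid/methylotrophic signature.
#'
#' @return Named list of two character vectors, `A_lixula` and
#'   `P_lividus`.
#' @export
species_panels <- function() {
  list(
    A_lixula = c("betaine", "taurine", "sarcosine", "glycine",
                 "trimethylamine", "trimethylamine N-oxide", "carnitine",
                 "creatine", "malonate", "methylmalonate", "uridine",
                 "xanthine"),
    P_lividus = c("lysine", "glycine", "glutamine", "formaldehyde",
                  "methanol", "3-carboxypropyl-trimethylammonium")
  )
}

#' Map compound names to KEGG-style identifiers
#'
#' Case-insensitive exact matching against a synonym table; duplicates
#' collapse to one id and unmapped names are returned, never dropped
#' silently.
#'
#' @param names Character vector of compound names.
#' @param synonyms Synonym table path (TSV with `query_name`, `kegg_id`)
#'   or a data frame; defaults to the packaged table.
#' @return List with `ids` (unique mapped ids) and `unmapped` (names with
#'   no match).
#' @export
map_compound_names <- function(names,
                               synonyms = system.file("extdata", "compound_synonyms.tsv",
                                                      package = "metabodisc")) {
  tab <- if (is.data.frame(synonyms)) synonyms else read.delim(synonyms, stringsAsFactors = FALSE)
  hit <- match(tolower(trimws(names)), tolower(tab$query_name))
  list(ids = unique(tab$kegg_id[hit[!is.na(hit)]]),
       unmapped = names[is.na(hit)])
}

#' Pathway topology impact from relative betweenness centrality
#'
#' Betweenness centrality of each pathway compound on the undirected
#' pathway graph, normalized by the pathway maximum; the impact is the sum
#' over hit compounds divided by the sum over all compounds. Graphs with no
#' through-traffic (all centralities zero) and empty hit sets return 0.
#'
#' @param hit_ids Compound ids matched in the pathway.
#' @param pathway One pathway entry of a `pathway_library` (needs
#'   `compounds` and `edges`).
#' @return Impact in \[0, 1\].
#' @export
pathway_impact <- function(hit_ids, pathway) {
  cpds <- pathway$compounds
  if (length(cpds) == 0) return(0)
  g <- igraph::graph_from_data_frame(
    as.data.frame(pathway$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = cpds, stringsAsFactors = FALSE))
  btw <- igraph::betweenness(g, directed = FALSE)
  if (max(btw) <= 0) return(0)
  rel <- btw / max(btw)
  sum(rel[cpds %in% hit_ids]) / sum(rel)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway of size `m` in a universe of `N` compounds and an
#' effective query of `n` compounds with `k` pathway hits, the raw p-value
#' is the upper hypergeometric tail `P(X >= k)`. Holm step-down and
#' Benjamini-Hochberg FDR are computed across all tested pathways, and
#' each pathway receives a topology impact score. Query compounds outside
#' the universe are discarded with a logged count.
#'
#' @param query_ids Compound ids (e.g. from [map_compound_names()]).
#' @param library A `pathway_library`.
#' @return An `ora_result` data frame: `pathway`, `name`, `total`,
#'   `expected`, `hits`, `raw_p`, `neg_log10_p`, `holm_p`, `fdr`,
#'   `impact`, `hit_ids`; attribute `n_discarded`.
#' @export
run_ora <- function(query_ids, library) {
  stopifnot(inherits(library, "pathway_library"))
  query <- unique(query_ids)
  eff <- intersect(query, library$universe)
  n_disc <- length(query) - length(eff)
  if (n_disc > 0) {
    message(n_disc, " query compound(s) not in the library universe were discarded")
  }
  if (length(eff) == 0) stop("no query compounds remain in the library universe")
  N <- length(library$universe)
  n_query <- length(eff)
  rows <- lapply(library$pathways, function(p) {
    m <- length(p$compounds)
    hits <- intersect(eff, p$compounds)
    k <- length(hits)
    data.frame(pathway = p$id, name = p$name, total = m,
               expected = n_query * m / N, hits = k,
               raw_p = phyper(k - 1, m, N - m, n_query, lower.tail = FALSE),
               impact = pathway_impact(hits, p),
               hit_ids = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$neg_log10_p <- -log10(out$raw_p)
  out$holm_p <- p.adjust(out$raw_p, method = "holm")
  out$fdr <- p.adjust(out$raw_p, method = "BH")
  out <- out[order(out$raw_p, out$name), c("pathway", "name", "total", "expected",
                                           "hits", "raw_p", "neg_log10_p",
                                           "holm_p", "fdr", "impact", "hit_ids")]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_disc
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Bubble-plot data for pathway results
#'
#' Exports the columns drawn in a MetaboAnalyst-style bubble plot: impact
#' on x, `-log10(raw p)` on y, matched-hit count as bubble size; ordered by
#' raw p with name tie-break.
#'
#' @param rows An `ora_result`.
#' @return Data frame with `name`, `impact`, `neg_log10_p`, `hits`,
#'   `raw_p`.
#' @export
bubble_data <- function(rows) {
  out <- rows[order(rows$raw_p, rows$name),
              c("name", "impact", "neg_log10_p", "hits", "raw_p")]
  rownames(out) <- NULL
  as.data.frame(out)
}
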