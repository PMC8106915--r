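SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sanitize_sid <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("_", x))
}

notes_lines <- function(notes) {
  ps <- xml2::xml_find_all(notes, ".//*[local-name()='p']")
  if (length(ps)) return(vapply(ps, xml2::xml_text, character(1)))
  strsplit(xml2::xml_text(notes), "\n", fixed = TRUE)[[1]]
}

parse_notes_field <- function(lines, key, split) {
  pat <- paste0("^\\s*", key, ":\\s*")
  hits <- grep(pat, lines, value = TRUE)
  if (length(hits) == 0L) return(character())
  vals <- sub(pat, "", hits)
  out <- unlist(strsplit(vals, split), use.names = FALSE)
  out <- trimws(out)
  out[nzchar(out)]
}

#' Read a metabolic network from SBML
#'
#' Accepts SBML Level 2 or Level 3 documents. One `ss_reaction` is created
#' per SBML reaction; compound ids are the SBML species ids verbatim; the
#' reversible flag is taken from the reaction's `reversible` attribute
#' (defaulting to `TRUE` when absent, per SBML Level 2 semantics).
#' Stoichiometric coefficients are read but discarded. Gene associations are
#' parsed from an fbc `geneProductAssociation` or from a
#' `GENE_ASSOCIATION:` line in the reaction notes, whichever is present
#' (notes win when both are); EC numbers come from an `EC_NUMBER:` notes line.
#'
#' @param path Path to an SBML file.
#' @param pipeline Optional pipeline label to attach to the network.
#' @return A [metabolic_network()].
#' @export
read_sbml <- function(path, pipeline = NA_character_) {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id) || !nzchar(model_id))
    model_id <- sub("\\.(sbml|xml)$", "", basename(path))
  rxn_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- lapply(rxn_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    rev_attr <- xml2::xml_attr(node, "reversible")
    reversible <- if (is.na(rev_attr)) TRUE else tolower(rev_attr) == "true"
    subs <- xml2::xml_attr(xml2::xml_find_all(
      node, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']"),
      "species")
    prods <- xml2::xml_attr(xml2::xml_find_all(
      node, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']"),
      "species")
    if (length(subs) + length(prods) == 0L)
      stopf("SBML reaction '%s' has no participants", rid)
    notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
    genes <- character(); ec <- character()
    if (!inherits(notes, "xml_missing")) {
      lines <- notes_lines(notes)
      genes <- parse_notes_field(lines, "GENE_ASSOCIATION",
                                 "\\s+(or|and|OR|AND)\\s+|[()]+")
      ec <- parse_notes_field(lines, "EC_NUMBER", "[;,\\s]+")
    }
    if (length(genes) == 0L) {
      gp <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
      if (length(gp)) {
        genes <- vapply(gp, function(g) {
          at <- xml2::xml_attrs(g)
          at[grepl("geneProduct$", names(at))][1]
        }, character(1))
      }
    }
    reaction(rid, subs, prods, reversible = reversible, genes = genes, ec = ec)
  })
  metabolic_network(model_id, reactions, pipeline)
}

#' Write a metabolic network to SBML Level 3
#'
#' The document carries both gene-association encodings understood by
#' [read_sbml()]: a `GENE_ASSOCIATION:` notes line (verbatim gene ids) and an
#' fbc `geneProductAssociation` (SId-sanitized references). EC numbers go into
#' an `EC_NUMBER:` notes line. Round-tripping through [read_sbml()] preserves
#' reaction ids, participant sets, reversibility, gene sets and EC sets.
#'
#' @param network A [metabolic_network()] with at least one reaction.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  if (length(network$reactions) == 0L)
    stopf("network '%s' has no reactions: nothing to serialize", network$id)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_L3_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model",
                               id = sanitize_sid(network$id),
                               "fbc:strict" = "false")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (cpd in compounds(network))
    xml2::xml_add_child(los, "species", id = cpd, constant = "false",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false")
  genes_all <- sorted_unique(unlist(lapply(network$reactions, `[[`, "genes"),
                                    use.names = FALSE))
  if (length(genes_all)) {
    lgp <- xml2::xml_add_child(model, "fbc:listOfGeneProducts")
    for (g in genes_all)
      xml2::xml_add_child(lgp, "fbc:geneProduct",
                          "fbc:id" = sanitize_sid(g), "fbc:label" = g)
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    rn <- xml2::xml_add_child(lor, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false")
    if (length(r$genes) || length(r$ec)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      if (length(r$genes))
        xml2::xml_add_child(body, "p",
                            paste0("GENE_ASSOCIATION: ",
                                   paste(r$genes, collapse = " or ")))
      if (length(r$ec))
        xml2::xml_add_child(body, "p",
                            paste0("EC_NUMBER: ",
                                   paste(r$ec, collapse = " ; ")))
    }
    if (length(r$genes)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      parent <- if (length(r$genes) > 1L)
        xml2::xml_add_child(gpa, "fbc:or") else gpa
      for (g in r$genes)
        xml2::xml_add_child(parent, "fbc:geneProductRef",
                            "fbc:geneProduct" = sanitize_sid(g))
    }
    if (length(r$reactants)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (cpd in r$reactants)
        xml2::xml_add_child(lr, "speciesReference", species = cpd,
                            stoichiometry = "1", constant = "true")
    }
    if (length(r$products)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (cpd in r$products)
        xml2::xml_add_child(lp, "speciesReference", species = cpd,
                            stoichiometry = "1", constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a seed-compound set (culture medium)
#'
#' Seeds may be given as a newline-delimited list of compound ids (CRLF
#' tolerated, duplicates dropped) or as an SBML document whose species list is
#' the seed set.
#'
#' @param path Path to the medium file.
#' @return Sorted character vector of compound ids.
#' @export
read_seeds <- function(path) {
  first <- readChar(path, 200L, useBytes = TRUE)
  if (length(first) == 0L) first <- ""
  if (grepl("^\\s*<", first)) {
    doc <- xml2::read_xml(path)
    sp <- xml2::xml_find_all(
      doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
    ids <- xml2::xml_attr(sp, "id")
  } else {
    ids <- readLines(path, warn = FALSE)
    ids <- trimws(sub("\r$", "", ids))
    ids <- ids[nzchar(ids)]
  }
  if (length(ids) == 0L) stopf("empty medium: no seed compounds in '%s'", path)
  sorted_unique(ids)
}

#' Read/write the TSV network dialect
#'
#' A lightweight tabular alternative to SBML with columns `reaction_id`,
#' `reactants`, `products` (semicolon-separated compound ids), `reversible`
#' (0/1), `genes` and `ec` (semicolon-separated).
#'
#' @param path File path.
#' @param id,pipeline Labels for the resulting network (read).
#' @return `read_network_tsv()` returns a [metabolic_network()];
#'   `write_network_tsv()` invisibly returns `path`.
#' @export
read_network_tsv <- function(path, id = NULL, pipeline = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("reaction_id", "reactants", "products", "reversible", "genes", "ec")
  if (!all(need %in% names(df)))
    stopf("network TSV must have columns: %s", paste(need, collapse = ", "))
  split_field <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)[[1]]
    trimws(out)[nzchar(trimws(out))]
  }
  reactions <- lapply(seq_len(nrow(df)), function(i)
    reaction(df$reaction_id[i],
             split_field(df$reactants[i]), split_field(df$products[i]),
             reversible = df$reversible[i] %in% c("1", "true", "TRUE"),
             genes = split_field(df$genes[i]), ec = split_field(df$ec[i])))
  metabolic_network(id %||% sub("\\.tsv$", "", basename(path)),
                    reactions, pipeline)
}

#' @rdname read_network_tsv
#' @param network A [metabolic_network()].
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  join <- function(x) paste(x, collapse = ";")
  df <- data.frame(
    reaction_id = reaction_ids(network),
    reactants = vapply(network$reactions, function(r) join(r$reactants), ""),
    products = vapply(network$reactions, function(r) join(r$products), ""),
    reversible = vapply(network$reactions,
                        function(r) if (r$reversible) "1" else "0", ""),
    genes = vapply(network$reactions, function(r) join(r$genes), ""),
    ec = vapply(network$reactions, function(r) join(r$ec), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
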