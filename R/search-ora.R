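#' @title Pathway search and overrepresentation analysis
#'
#' @description Resolved input entities are matched against the reference
#' proteoforms; every match is expanded to the reactions the reference
#' participates in and to the containing pathways, including all ancestors
#' up to the top level. Overrepresentation of each pathway is then scored
#' with a right-tail binomial test: matching one entity to a pathway is a
#' Bernoulli trial with success probability \code{p} equal to the pathway's
#' share of the database universe at the active granularity, and the
#' p-value is \code{Pr(X >= k)} for \code{k} matched entities out of
#' \code{n} input entities, followed by Benjamini-Hochberg correction over
#' all scored pathways.
#'
#' @name search_and_ora
NULL

#' Search reactions and pathways matching the input
#'
#' Protein-level input kinds (gene, variant, protein, peptide) match by
#' accession identity regardless of the configured matching type;
#' proteoform-level kinds (proteoform, modified peptide) use \code{config}.
#'
#' @param entities an \code{"input_entities"} object.
#' @param kb a \code{"knowledge_base"}.
#' @param config a \code{\link{matching_config}} used for proteoform-level
#'   input kinds.
#' @return A data.frame with one row per (input token, entity, matched
#'   reference, reaction, pathway) combination, pathways including every
#'   ancestor: columns \code{token}, \code{entity}, \code{reference},
#'   \code{reaction_id}, \code{reaction_name}, \code{pathway_id},
#'   \code{pathway_name}, \code{top_pathway_id}, \code{top_pathway_name},
#'   \code{role}, \code{context}.
#' @export
search_pathways <- function(entities, kb, config = matching_config()) {
  stopifnot(inherits(entities, "input_entities"),
            inherits(kb, "knowledge_base"))
  if (entities$kind %in% c("gene", "variant", "protein", "peptide")) {
    config <- matching_config("ACCESSION", 0L)
  }
  ent <- resolved_entities(entities)
  matches <- match_against_kb(lapply(ent, parse_proteoform), kb$proteoforms,
                              config)
  empty <- data.frame(token = character(), entity = character(),
                      reference = character(), reaction_id = character(),
                      reaction_name = character(), pathway_id = character(),
                      pathway_name = character(),
                      top_pathway_id = character(),
                      top_pathway_name = character(), role = character(),
                      context = character(), stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) return(empty)
  # reaction -> pathway memberships with hierarchy closure upwards
  pw_of_reaction <- split(kb$pathway_reactions$pathway_id,
                          kb$pathway_reactions$reaction_id)
  rows <- list()
  for (i in seq_len(nrow(matches))) {
    ref <- matches$reference[i]
    prt <- kb$participants[kb$participants$proteoform == ref, , drop = FALSE]
    if (nrow(prt) == 0L) next
    tokens <- entities$entities$token[entities$entities$entity ==
                                        matches$input[i]]
    for (r in seq_len(nrow(prt))) {
      direct <- pw_of_reaction[[prt$reaction_id[r]]]
      for (pw in direct) {
        lineage <- c(pw, pathway_ancestors(kb, pw))
        top <- lineage[length(lineage)]
        rows[[length(rows) + 1L]] <- data.frame(
          token = tokens, entity = matches$input[i], reference = ref,
          reaction_id = prt$reaction_id[r],
          reaction_name = prt$reaction_name[r],
          pathway_id = lineage, pathway_name = pathway_name(kb, lineage),
          top_pathway_id = top, top_pathway_name = pathway_name(kb, top),
          role = prt$role[r], context = prt$context[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$token, out$entity, out$reference, out$reaction_id,
                   out$pathway_id, out$role, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Right-tail binomial probability
#'
#' \code{Pr(X >= k)} for \code{X ~ Binomial(n, p)}, evaluated through the
#' numerically stable survival function (never by subtracting a CDF value
#' from 1 in double precision).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param p success probability in [0, 1].
#' @return A probability.
#' @examples
#' binomial_right_tail(2, 10, 0.1)  # 0.2639011...
#' @export
binomial_right_tail <- function(k, n, p) {
  if (!is.numeric(k) || !is.numeric(n) || !is.numeric(p) ||
      length(k) != 1L || length(n) != 1L || length(p) != 1L ||
      is.na(k) || is.na(n) || is.na(p) ||
      k < 0 || n < 0 || k > n || p < 0 || p > 1 ||
      k != as.integer(k) || n != as.integer(n)) {
    stop(condition_error("binomial_right_tail requires 0 <= k <= n ",
                         "(integers) and p in [0, 1]",
                         class = "proteopath_config_error"))
  }
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: sort ascending,
#' multiply by m/rank, enforce monotonicity from the largest rank downward,
#' cap at 1 and restore the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted vector in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop(condition_error("p-values must be numbers in [0, 1]",
                         class = "proteopath_config_error"))
  }
  stats::p.adjust(p_values, method = "BH")
}

#' The entity universe for overrepresentation analysis
#'
#' @param kb a \code{"knowledge_base"}.
#' @param granularity \code{"protein"} (distinct accessions) or
#'   \code{"proteoform"} (distinct reference proteoforms).
#' @return A list with \code{granularity} and \code{database_total}.
#' @export
ora_universe <- function(kb, granularity = c("protein", "proteoform")) {
  granularity <- match.arg(granularity)
  total <- if (granularity == "protein") length(kb_accessions(kb)) else
    length(kb$proteoforms)
  list(granularity = granularity, database_total = total)
}

# distinct pathway participant entities at a granularity, over the pathway's
# reaction closure (own + descendant reactions)
pathway_entity_sets <- function(kb, granularity) {
  prt <- kb$participants
  ids <- if (granularity == "protein") {
    vapply(prt$proteoform, function(s) parse_proteoform(s)$accession,
           character(1), USE.NAMES = FALSE)
  } else {
    prt$proteoform
  }
  by_reaction <- split(ids, prt$reaction_id)
  out <- list()
  for (pw in kb$pathways$pathway_id) {
    rids <- pathway_reaction_closure(kb, pw)
    out[[pw]] <- sort(unique(unlist(by_reaction[rids], use.names = FALSE)))
  }
  out
}

#' Pathway overrepresentation analysis
#'
#' One record per pathway with at least one matched entity. \code{k} counts
#' distinct matched input entities in the pathway (an entity appearing in
#' many reactions of one pathway counts once), \code{entities_total} the
#' pathway's distinct participants at the active granularity over its
#' reaction closure, \code{p = entities_total / database_total}, and
#' \code{n} the number of distinct resolved input entities present in the
#' knowledge-base universe (set \code{n_definition = "raw"} to count every
#' distinct resolved entity instead, mapped or not).
#'
#' @param search_rows output of \code{\link{search_pathways}}.
#' @param entities the \code{"input_entities"} that produced them.
#' @param kb a \code{"knowledge_base"}.
#' @param universe a list from \code{\link{ora_universe}}; defaults to the
#'   granularity implied by the input kind.
#' @param n_definition \code{"mapped"} (default) or \code{"raw"}.
#' @return A data.frame with columns \code{pathway_id}, \code{pathway_name},
#'   \code{entities_found}, \code{entities_total}, \code{n}, \code{p},
#'   \code{p_value}, \code{fdr}, sorted by increasing p-value.
#' @export
analyse_pathways <- function(search_rows, entities, kb, universe = NULL,
                             n_definition = c("mapped", "raw")) {
  stopifnot(inherits(entities, "input_entities"),
            inherits(kb, "knowledge_base"))
  n_definition <- match.arg(n_definition)
  if (is.null(universe)) {
    gran <- if (entities$kind %in% c("proteoform", "modified_peptide"))
      "proteoform" else "protein"
    universe <- ora_universe(kb, gran)
  }
  empty <- data.frame(pathway_id = character(), pathway_name = character(),
                      entities_found = integer(), entities_total = integer(),
                      n = integer(), p = numeric(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
  if (nrow(search_rows) == 0L) return(empty)

  project <- function(pf_strings) {
    if (universe$granularity == "protein") {
      unique(vapply(pf_strings, function(s) parse_proteoform(s)$accession,
                    character(1), USE.NAMES = FALSE))
    } else {
      unique(pf_strings)
    }
  }
  resolved <- resolved_entities(entities)
  matched_entities <- unique(search_rows$entity)
  n <- if (n_definition == "mapped") {
    if (universe$granularity == "protein") {
      # a protein-level entity is in the universe when its accession is
      acc <- vapply(resolved, function(s) parse_proteoform(s)$accession,
                    character(1), USE.NAMES = FALSE)
      length(unique(acc[acc %in% kb_accessions(kb)]))
    } else {
      length(project(matched_entities))
    }
  } else {
    length(project(resolved))
  }
  if (n == 0L) return(empty)

  # entity id at the active granularity for counting k per pathway
  search_rows$entity_id <- if (universe$granularity == "protein") {
    vapply(search_rows$entity, function(s) parse_proteoform(s)$accession,
           character(1), USE.NAMES = FALSE)
  } else {
    search_rows$entity
  }
  totals <- pathway_entity_sets(kb, universe$granularity)
  found <- lapply(split(search_rows$entity_id, search_rows$pathway_id),
                  unique)
  pw_ids <- sort(names(found))
  k <- vapply(pw_ids, function(pw) length(found[[pw]]), integer(1))
  entities_total <- vapply(pw_ids, function(pw) length(totals[[pw]]),
                           integer(1))
  p <- entities_total / universe$database_total
  p_value <- vapply(seq_along(pw_ids), function(i) {
    binomial_right_tail(min(k[i], n), n, p[i])
  }, numeric(1))
  out <- data.frame(pathway_id = pw_ids,
                    pathway_name = pathway_name(kb, pw_ids),
                    entities_found = k, entities_total = entities_total,
                    n = n, p = p, p_value = p_value,
                    fdr = bh_adjust(p_value), stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
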